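# Supervised stack: splitting, SVM/SVR tuning and training, kappa, random
# forest + importance reduction, PLSR, metrics, spectralprints.

test_that("the stratified split reproduces the 55/20 partition", {
  tm <- cached_study_tm()
  sp <- split_data(tm, 0.7, seed = 1L)
  expect_equal(ncol(sp$train$D), 55L)
  expect_equal(ncol(sp$test$D), 20L)
  expect_equal(sort(unique(as.character(sp$train$metadata$grade))),
               sort(unique(as.character(sp$test$metadata$grade))))
  expect_equal(as.vector(table(sp$train$metadata$grade)), rep(11L, 5))
  expect_identical(split_data(tm, 0.7, seed = 1L)$train_idx, sp$train_idx)
  expect_false(identical(split_data(tm, 0.7, seed = 2L)$train_idx,
                         sp$train_idx))
  expect_error(split_data(tm, 1), "strictly between")
})

test_that("CV folds are stratified and reproducible", {
  y <- factor(rep(letters[1:5], each = 15))
  folds <- make_cv_folds(y, k = 5L, seed = 3L)
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5)
    expect_equal(as.vector(table(y[folds == f])), rep(3L, 5))
  expect_identical(make_cv_folds(y, k = 5L, seed = 3L), folds)
})

test_that("Cohen's kappa follows its closed form", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # confusion matrix [[25,5],[10,10]]: p_o = 0.7,
  # p_e = (30*35 + 20*15)/50^2 = 0.54, kappa = 0.16/0.46
  pred <- rep(c("x", "x", "y", "y"), c(25, 5, 10, 10))
  act <- rep(c("x", "y", "x", "y"), c(25, 5, 10, 10))
  expect_equal(cohen_kappa(pred, act), (0.7 - 0.54) / (1 - 0.54))
  set.seed(12)
  kappas <- replicate(200, {
    a <- sample(rep(letters[1:4], 10))
    cohen_kappa(sample(a), a)
  })
  expect_lt(abs(mean(kappas)), 0.03)  # chance agreement
  expect_error(cohen_kappa(character(0), character(0)), "empty")
  expect_error(cohen_kappa("a", c("a", "b")), "lengths")
})

test_that("regression metrics follow their formulas", {
  y <- c(1, 3, 5, 7)
  m <- regression_metrics(y, y)
  expect_equal(m$rmse, 0)
  expect_equal(m$r_squared, 1)
  off <- regression_metrics(y + 5, y)
  expect_equal(off$rmse, 5)
  expect_equal(off$r_squared, 1)  # correlation convention ignores offset
  expect_lt(off$r_squared_traditional, 0)
  set.seed(13)
  p <- rnorm(30); a <- rnorm(30)
  mm <- regression_metrics(p, a)
  expect_equal(mm$rmse, sqrt(sum((p - a)^2) / 30))
  expect_equal(mm$r_squared, cor(p, a)^2)
  expect_equal(mm$r_squared_traditional,
               1 - sum((a - p)^2) / sum((a - mean(a))^2))
  expect_error(regression_metrics(p, rep(1, 30)), "zero variance")
})

test_that("the default SVM grid spans 41 x 41 = 1681 combinations", {
  fm <- formals(tune_svm)
  expect_length(eval(fm$log2_C_grid), 41L)
  expect_length(eval(fm$log2_sigma_grid), 41L)
  expect_equal(nrow(expand.grid(eval(fm$log2_C_grid),
                                eval(fm$log2_sigma_grid))), 1681L)
})

test_that("SVM tuning matches an independent grid replay", {
  tm <- cached_study_tm()
  small <- subset_samples(tm, tm$metadata$blend_pct %in% c(0, 100))
  tuned <- tune_svm(small, "classify", log2_C_grid = c(-2, 0, 2, 4),
                    log2_sigma_grid = c(-4, -2, 0), k = 3L, seed = 5L)
  expect_equal(nrow(tuned$cv_surface), 12L)
  expect_equal(max(tuned$cv_surface$metric), 1)  # separable classes
  # replay every combination with the exported folds
  X <- t(small$D); y <- droplevels(small$metadata$grade)
  replay <- apply(tuned$cv_surface[, 1:2], 1, function(g) {
    pred <- factor(rep(NA, length(y)), levels = levels(y))
    for (f in unique(tuned$folds)) {
      hold <- tuned$folds == f
      m <- kernlab::ksvm(X[!hold, ], y[!hold], type = "C-svc",
                         kernel = "rbfdot",
                         kpar = list(sigma = 2^g[["log2_sigma"]]),
                         C = 2^g[["log2_C"]], scaled = FALSE)
      pred[hold] <- kernlab::predict(m, X[hold, ])
    }
    mean(pred == y)
  })
  expect_equal(tuned$cv_surface$metric, unname(replay))
  # tie-break: highest accuracy, then smallest C, then smallest sigma
  top <- tuned$cv_surface[tuned$cv_surface$metric ==
                            max(tuned$cv_surface$metric), ]
  top <- top[order(top$log2_C, top$log2_sigma), ]
  expect_equal(tuned$C, 2^top$log2_C[1])
  expect_equal(tuned$sigma, 2^top$log2_sigma[1])
})

test_that("SVM training validates inputs and reports support vectors", {
  tm <- cached_study_tm()
  sp <- split_data(tm, 0.7, seed = 6L)
  folds <- make_cv_folds(droplevels(sp$train$metadata$grade), seed = 6L)
  res <- assess_model(train_svm(sp$train, C = 128, sigma = 0.5,
                                folds = folds), sp$test)
  expect_gte(res$cv_metrics$accuracy, 0.9)
  expect_gte(res$test_metrics$accuracy, 0.9)
  expect_gt(res$n_support_vectors, 0)
  expect_error(train_svm(sp$train, C = -1, sigma = 1), "positive")
  single <- subset_samples(tm, tm$metadata$blend_pct == 0)
  expect_error(train_svm(single, C = 1, sigma = 1), "single class")
})

test_that("SVR recovers a noiseless linear response within the tube", {
  set.seed(14)
  n <- 40
  X <- matrix(runif(n * 5), n)
  colnames(X) <- 50:54
  y <- X[, 1]  # exact linear response on [0, 1]
  tmx <- structure(list(
    D = t(X), mz_axis = 50:54,
    metadata = data.frame(sample_id = paste0("s", 1:n), lot = "A",
                          blend_pct = NA_real_, replicate = "R1",
                          grade = grade_from_blend(rep(NA_real_, n)))),
    class = "tis_matrix")
  tmx$metadata$blend_pct <- y
  res <- train_svr(tmx, C = 100, sigma = 1, epsilon = 0.05)
  pred <- predict(res, tmx)
  expect_lt(sqrt(mean((pred - y)^2)), 0.1)  # within the epsilon-tube scale
})

test_that("random forest defaults, sweep, and planted-marker importances", {
  expect_equal(signif(mtry_default(501, "classify"), 4), 22.38)
  expect_equal(mtry_default(501, "regress"), 167)
  tm <- cached_study_tm()
  folds <- make_cv_folds(tm$metadata$grade, seed = 7L)
  res <- rf_fit(tm, "classify", folds = folds, seed = 7L,
                ntree_grid = seq(10L, 30L, by = 10L), sweep = TRUE)
  expect_equal(res$hyperparameters$mtry, 22L)
  expect_equal(nrow(res$ntree_sweep), 3L)
  expect_true(all(res$ntree_sweep$metric > 0.5))
  expect_lt(res$oob_error, 0.3)
  expect_equal(max(res$importances), 100)
  # planted markers occupy the top importance ranks
  top9 <- names(sort(res$importances, decreasing = TRUE))[1:9]
  expect_gte(length(intersect(top9, rownames(default_marker_table()))), 7L)
  expect_error(rf_fit(tm, "classify", mtry = 502L), "exceed")
})

test_that("importance reduction thresholds and falls back sensibly", {
  fake <- structure(list(algorithm = "random_forest", task = "classify",
                         importances = c(`79` = 90, `92` = 80, `97` = 60,
                                         `300` = 10)),
                    class = "model_result")
  expect_equal(importance_reduce(fake, 70), c(79L, 92L))
  expect_equal(importance_reduce(fake, 0), c(79L, 92L, 97L, 300L))
  low <- fake; low$importances <- c(`79` = 5, `92` = 3, `97` = 1, `300` = 0)
  expect_warning(sel <- importance_reduce(low, 70, top_k = 2L), "top-k")
  expect_equal(sel, c(79L, 92L))
  nil <- fake; nil$importances <- NULL
  expect_error(importance_reduce(nil), "no importances")
})

test_that("a reduced refit uses only the selected channels", {
  tm <- cached_study_tm()
  sel <- c(79L, 92L, 95L, 97L, 118L, 157L, 188L, 221L)
  red <- subset_channels(tm, sel)
  expect_equal(red$mz_axis, sel)
  res <- rf_fit(red, "classify", seed = 8L)
  expect_equal(res$mz_used, sel)
  expect_equal(sort(as.integer(rownames(res$model$importance))), sel)
  expect_error(subset_channels(tm, c(92L, 9999L)), "outside")
  av <- channel_anova(tm, sel)
  expect_true(all(av$significant))
  expect_true(all(av$p < 0.05))
})

test_that("PLSR handles a rank-1 response and matches a reference PLS", {
  set.seed(15)
  # response exactly linear in one latent direction + small noise
  n <- 30; p <- 12
  t1 <- rnorm(n)
  X <- t1 %o% runif(p) + matrix(rnorm(n * p, sd = 0.01), n)
  colnames(X) <- 50 + seq_len(p) - 1
  y <- 2 * t1 + rnorm(n, sd = 0.05)
  tmx <- structure(list(
    D = t(X), mz_axis = as.integer(colnames(X)),
    metadata = data.frame(sample_id = paste0("s", 1:n), lot = "A",
                          blend_pct = y, replicate = "R1",
                          grade = grade_from_blend(rep(NA_real_, n)))),
    class = "tis_matrix")
  res <- pls_fit(tmx, max_components = 5, seed = 15L)
  # one component already reaches the noise floor
  expect_lt(res$rmse_curve$cv_rmse[1], 0.2)
  expect_lte(res$rmse_curve$cv_rmse[res$hyperparameters$ncomp],
             res$rmse_curve$cv_rmse[1])
  expect_lt(res$cv_metrics$rmse, 0.2)
  # cross-implementation oracle: mixOmics PLS1, regression mode, unscaled
  ref <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = FALSE)
  ref_pred <- predict(ref, X)$predict[, 1, 2]
  mine <- pls_fit(tmx, max_components = 2, folds = rep(1:2, 15), seed = 1L)
  mine$hyperparameters$ncomp
  mine$model$ncomp_used <- 2L
  expect_equal(unname(predict(mine, tmx)), unname(ref_pred),
               tolerance = 1e-8)
  expect_error(pls_fit(tmx, max_components = 0), "max_components")
})

test_that("PLSR importance concentrates on the dominant m/z 91 channel", {
  tm <- cached_study_tm()
  sp <- split_data(tm, 0.7, seed = 9L)
  res <- pls_fit(sp$train, max_components = 10, seed = 9L)
  expect_equal(names(which.max(res$importances)), "91")
  expect_equal(max(res$importances), 100)
  test_res <- assess_model(res, sp$test)
  expect_lt(test_res$test_metrics$rmse, 10)
  expect_gt(test_res$test_metrics$r_squared, 0.9)
})

test_that("spectralprints aggregate per-grade means of the markers", {
  tm <- cached_study_tm()
  mz_set <- c(79L, 92L, 95L, 97L, 118L, 157L, 188L, 221L)
  sp <- extract_spectralprint(tm, mz_set)
  # groupwise loop oracle
  for (g in colnames(sp$means)) {
    cols <- which(as.character(tm$metadata$grade) == g)
    for (i in seq_along(mz_set)) {
      acc <- 0
      for (cc in cols) acc <- acc + tm$D[match(mz_set[i], tm$mz_axis), cc]
      expect_equal(sp$means[i, g], acc / length(cols))
    }
  }
  expect_equal(unname(apply(sp$display, 2, max)), rep(1, 5))
  # single-sample grade: the print is that sample's values
  one <- subset_samples(tm, which(tm$metadata$sample_id == "0%_A_R1"))
  sp1 <- extract_spectralprint(one, mz_set)
  expect_equal(unname(sp1$means[, "None"]),
               one$D[match(mz_set, one$mz_axis), 1], ignore_attr = TRUE)
  expect_error(extract_spectralprint(tm, mz_set,
                                     rep("Mystery", 75)), "grade labels")
})
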