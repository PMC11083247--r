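# Supervised stack: Gaussian SVM / SVR (exponential grid search), random
# forest with permutation-importance reduction, NIPALS PLSR, and the shared
# metrics (accuracy, Cohen's kappa, RMSE, R-squared).

# design matrix (samples x channels) and response for a task
.xy <- function(x, task = c("classify", "regress")) {
  task <- match.arg(task)
  stopifnot(inherits(x, "tis_matrix"))
  X <- t(x$D)
  y <- if (task == "classify") droplevels(x$metadata$grade)
       else x$metadata$blend_pct
  list(x = X, y = y)
}

#' Stratified train/test split of a TIS matrix
#'
#' Random split stratified by odor grade so every class is represented on
#' both sides; with the standard 75-sample study and `train_fraction = 0.7`
#' this yields the 55 / 20 partition (ceiling of 0.7 x 15 per class).
#'
#' @param x A `tis_matrix` with grade metadata.
#' @param train_fraction Fraction of each class assigned to training
#'   (0 < fraction < 1).
#' @param seed Integer seed; the same seed always gives the same split.
#' @return List `train`, `test` (both `tis_matrix`) and `train_idx`.
#' @export
split_data <- function(x, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(x, "tis_matrix"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  g <- droplevels(x$metadata$grade)
  if (any(table(g) < 2L)) stop("need at least 2 samples per class to split")
  train_idx <- with_local_seed(seed, {
    unlist(lapply(split(seq_along(g), g), function(idx) {
      n_tr <- ceiling(train_fraction * length(idx))
      if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  if (length(train_idx) == 0L || length(train_idx) == ncol(x$D))
    stop("split leaves one side empty")
  list(train = subset_samples(x, train_idx),
       test = subset_samples(x, -train_idx),
       train_idx = train_idx)
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, stratified by class (or by the
#' discrete response levels for regression) so folds are balanced. Fold
#' indices are returned explicitly so any tuning loop can be replayed
#' externally.
#'
#' @param y Class factor or numeric response.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1...k), one per sample.
#' @export
make_cv_folds <- function(y, k = 5L, seed = 1L) {
  strata <- if (is.factor(y)) y else factor(y)
  if (nlevels(strata) > length(y) / 2)  # effectively continuous: rank bins
    strata <- factor(ceiling(rank(y, ties.method = "first") * k / length(y)))
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (idx in split(seq_along(y), strata)) {
      idx <- sample(idx)
      folds[idx] <- rep_len(sample(k), length(idx))
    }
  })
  folds
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` from the confusion
#' matrix of predicted vs actual labels.
#'
#' @param predicted,actual Vectors of equal length (coerced to factors on the
#'   union of their levels).
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(predicted, actual) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(actual)) stop("lengths differ")
  lev <- union(levels(factor(actual)), levels(factor(predicted)))
  cm <- table(factor(predicted, lev), factor(actual, lev))
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e == 1) return(1)  # degenerate single-cell table
  (p_o - p_e) / (1 - p_e)
}

#' Regression metrics
#'
#' RMSE and two flavours of R-squared: `r_squared` is the squared Pearson
#' correlation between predicted and actual (the convention of common
#' model-tuning frameworks, invariant to calibration offsets) and
#' `r_squared_traditional` is `1 - SS_res / SS_tot`.
#'
#' @param predicted,actual Numeric vectors of equal length (>= 2).
#' @return List `rmse`, `r_squared`, `r_squared_traditional`.
#' @export
regression_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("lengths differ")
  if (length(actual) < 2L) stop("need at least two observations")
  if (stats::sd(actual) == 0)
    stop("actual values have zero variance; R-squared undefined")
  rmse <- sqrt(mean((predicted - actual)^2))
  r2 <- if (stats::sd(predicted) == 0) 0
        else stats::cor(predicted, actual)^2
  list(rmse = rmse, r_squared = r2,
       r_squared_traditional = 1 - sum((actual - predicted)^2) /
         sum((actual - mean(actual))^2))
}

.new_model_result <- function(algorithm, task, model, hyperparameters,
                              cv_metrics = NULL, extra = list(),
                              importances = NULL, mz_used = NULL) {
  structure(c(list(algorithm = algorithm, task = task, model = model,
                   hyperparameters = hyperparameters,
                   cv_metrics = cv_metrics, test_metrics = NULL,
                   importances = importances, mz_used = mz_used),
              extra),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s (%s)\n", x$algorithm, x$task))
  cat("hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$cv_metrics))
    cat("CV:", paste(names(x$cv_metrics),
                     sprintf("%.4g", unlist(x$cv_metrics)),
                     sep = "=", collapse = ", "), "\n")
  if (!is.null(x$test_metrics))
    cat("test:", paste(names(x$test_metrics),
                       sprintf("%.4g", unlist(x$test_metrics)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# pooled CV metrics for a fit/predict closure
.cv_metrics <- function(X, y, folds, fit_predict, task) {
  pred <- if (is.factor(y)) factor(rep(NA, length(y)), levels = levels(y))
          else numeric(length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    if (all(hold) || !any(hold)) stop("degenerate cross-validation fold")
    if (is.factor(y) && nlevels(droplevels(y[!hold])) < 2L)
      stop("degenerate cross-validation fold: single-class training part")
    pred[hold] <- fit_predict(X[!hold, , drop = FALSE], y[!hold],
                              X[hold, , drop = FALSE])
  }
  if (task == "classify")
    list(accuracy = mean(pred == y), kappa = cohen_kappa(pred, y))
  else {
    m <- regression_metrics(pred, y)
    list(rmse = m$rmse, r_squared = m$r_squared)
  }
}

#' Grid search for the Gaussian SVM / SVR hyperparameters
#'
#' Evaluates every `(C, sigma)` combination of an exponential grid (default
#' `log2` from -10 to 10 in 0.5 steps, 41 x 41 = 1681 combinations) under
#' k-fold cross-validation. Classification selects the highest CV accuracy,
#' ties broken by smallest C then smallest sigma; regression selects the
#' lowest CV RMSE with the same tie-break. The kernel is
#' `k(x, x') = exp(-sigma * ||x - x'||^2)`.
#'
#' @param train Training `tis_matrix`.
#' @param task `"classify"` or `"regress"`.
#' @param log2_C_grid,log2_sigma_grid Exponent grids for C and sigma.
#' @param epsilon SVR epsilon-tube width (ignored for classification).
#' @param k Number of CV folds.
#' @param seed Seed fixing the fold assignment.
#' @return List `C`, `sigma`, `cv_surface` (data frame log2_C, log2_sigma,
#'   metric), `folds`, `metric_name`.
#' @export
tune_svm <- function(train, task = c("classify", "regress"),
                     log2_C_grid = seq(-10, 10, by = 0.5),
                     log2_sigma_grid = seq(-10, 10, by = 0.5),
                     epsilon = 0.1, k = 5L, seed = 1L) {
  task <- match.arg(task)
  d <- .xy(train, task)
  folds <- make_cv_folds(d$y, k = k, seed = seed)
  grid <- expand.grid(log2_C = log2_C_grid, log2_sigma = log2_sigma_grid)
  metric <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    C <- 2^grid$log2_C[i]; sigma <- 2^grid$log2_sigma[i]
    cm <- .cv_metrics(d$x, d$y, folds, function(xt, yt, xv) {
      m <- .fit_ksvm(xt, yt, task, C, sigma, epsilon)
      kernlab::predict(m, xv)
    }, task)
    metric[i] <- if (task == "classify") cm$accuracy else cm$rmse
  }
  better <- if (task == "classify") order(-metric, grid$log2_C,
                                          grid$log2_sigma)
            else order(metric, grid$log2_C, grid$log2_sigma)
  best <- better[1L]
  list(C = 2^grid$log2_C[best], sigma = 2^grid$log2_sigma[best],
       cv_surface = data.frame(grid, metric = metric),
       folds = folds,
       metric_name = if (task == "classify") "accuracy" else "rmse")
}

.fit_ksvm <- function(X, y, task, C, sigma, epsilon = 0.1) {
  if (task == "classify")
    kernlab::ksvm(X, y, type = "C-svc", kernel = "rbfdot",
                  kpar = list(sigma = sigma), C = C, scaled = FALSE)
  else
    kernlab::ksvm(X, y, type = "eps-svr", kernel = "rbfdot",
                  kpar = list(sigma = sigma), C = C, epsilon = epsilon,
                  scaled = FALSE)
}

#' Train a Gaussian-kernel SVM classifier
#'
#' Fits a C-SVC with kernel `exp(-sigma * ||x - x'||^2)` at the tuned
#' hyperparameters, reporting the support-vector count and (when folds are
#' supplied) pooled k-fold CV accuracy and kappa.
#'
#' @param train Training `tis_matrix`.
#' @param C Cost parameter (> 0).
#' @param sigma Gaussian kernel width parameter (> 0); some software calls
#'   the same quantity gamma.
#' @param folds Optional fold assignment from [make_cv_folds()].
#' @return A `model_result`.
#' @export
train_svm <- function(train, C, sigma, folds = NULL) {
  if (C <= 0 || sigma <= 0) stop("C and sigma must be positive")
  d <- .xy(train, "classify")
  if (nlevels(d$y) < 2L) stop("training data contain a single class")
  model <- .fit_ksvm(d$x, d$y, "classify", C, sigma)
  cv <- if (!is.null(folds))
    .cv_metrics(d$x, d$y, folds, function(xt, yt, xv)
      kernlab::predict(.fit_ksvm(xt, yt, "classify", C, sigma), xv),
      "classify")
  .new_model_result("gaussian_svm", "classify", model,
                    list(C = C, sigma = sigma), cv,
                    extra = list(n_support_vectors = kernlab::nSV(model)),
                    mz_used = as.integer(colnames(d$x)))
}

#' Train a Gaussian-kernel support vector regressor
#'
#' Epsilon-insensitive SVR with the same kernel parameterization as
#' [train_svm()].
#'
#' @inheritParams train_svm
#' @param epsilon Width of the epsilon-insensitive tube.
#' @return A `model_result`.
#' @export
train_svr <- function(train, C, sigma, epsilon = 0.1, folds = NULL) {
  if (C <= 0 || sigma <= 0) stop("C and sigma must be positive")
  d <- .xy(train, "regress")
  model <- .fit_ksvm(d$x, d$y, "regress", C, sigma, epsilon)
  cv <- if (!is.null(folds))
    .cv_metrics(d$x, d$y, folds, function(xt, yt, xv)
      kernlab::predict(.fit_ksvm(xt, yt, "regress", C, sigma, epsilon), xv),
      "regress")
  .new_model_result("gaussian_svr", "regress", model,
                    list(C = C, sigma = sigma, epsilon = epsilon), cv,
                    extra = list(n_support_vectors = kernlab::nSV(model)),
                    mz_used = as.integer(colnames(d$x)))
}

#' Default predictors-per-split for a random forest
#'
#' `sqrt(p)` for classification and `p / 3` for regression, returned before
#' integer truncation (the forest itself uses the floor).
#'
#' @param p Number of predictors.
#' @param task `"classify"` or `"regress"`.
#' @return Numeric mtry value.
#' @export
mtry_default <- function(p, task = c("classify", "regress")) {
  task <- match.arg(task)
  if (task == "classify") sqrt(p) else p / 3
}

#' Random forest classifier / regressor with ntree sweep
#'
#' Fits a random forest at `ntree_final` trees with permutation variable
#' importance (mean decrease in OOB accuracy / increase in MSE, normalized to
#' 0-100%), optionally preceded by a cross-validated sweep of the tree count
#' used to verify that the error has stabilized.
#'
#' @param train Training `tis_matrix`.
#' @param task `"classify"` or `"regress"`.
#' @param mtry Predictors sampled per split; default `floor(sqrt(p))` for
#'   classification, `floor(p / 3)` for regression.
#' @param ntree_final Tree count of the final model.
#' @param ntree_grid Tree counts of the sweep.
#' @param sweep Run the CV sweep over `ntree_grid`.
#' @param folds Optional fold assignment from [make_cv_folds()]; required for
#'   the sweep and the CV metrics.
#' @param seed Seed for the forest's bootstrap.
#' @return A `model_result` with elements `oob_error`, `importances` (named
#'   by m/z, max = 100) and, if swept, `ntree_sweep` (data frame ntree,
#'   metric).
#' @export
rf_fit <- function(train, task = c("classify", "regress"), mtry = NULL,
                   ntree_final = 100L, ntree_grid = seq(2L, 100L, by = 2L),
                   sweep = FALSE, folds = NULL, seed = 1L) {
  task <- match.arg(task)
  d <- .xy(train, task)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- floor(mtry_default(p, task))
  if (mtry > p) stop("mtry cannot exceed the number of predictors")
  fit_rf <- function(xt, yt, ntree)
    with_local_seed(seed,
      randomForest::randomForest(xt, yt, ntree = ntree, mtry = mtry,
                                 importance = TRUE))
  sweep_df <- NULL
  if (sweep) {
    if (is.null(folds)) stop("the ntree sweep needs cross-validation folds")
    metric <- vapply(ntree_grid, function(nt) {
      cm <- .cv_metrics(d$x, d$y, folds, function(xt, yt, xv)
        stats::predict(fit_rf(xt, yt, nt), xv), task)
      if (task == "classify") cm$accuracy else cm$rmse
    }, numeric(1))
    sweep_df <- data.frame(ntree = ntree_grid, metric = metric)
  }
  model <- fit_rf(d$x, d$y, ntree_final)
  cv <- if (!is.null(folds))
    .cv_metrics(d$x, d$y, folds, function(xt, yt, xv)
      stats::predict(fit_rf(xt, yt, ntree_final), xv), task)
  oob <- if (task == "classify") mean(model$predicted != d$y)
         else mean((model$predicted - d$y)^2)
  imp_raw <- randomForest::importance(model, type = 1, scale = TRUE)[, 1]
  rng <- range(imp_raw)
  importances <- if (diff(rng) == 0) stats::setNames(rep(100, p),
                                                     names(imp_raw))
                 else 100 * (imp_raw - rng[1]) / diff(rng)
  .new_model_result("random_forest", task, model,
                    list(mtry = mtry, ntree = ntree_final), cv,
                    extra = list(oob_error = oob, ntree_sweep = sweep_df),
                    importances = importances,
                    mz_used = as.integer(colnames(d$x)))
}

#' Reduce to high-importance m/z channels
#'
#' Channels whose relative importance exceeds the threshold (percent). An
#' empty selection falls back, with a warning, to the `top_k` most important
#' channels.
#'
#' @param result A `model_result` with importances.
#' @param threshold Relative importance cut-off in percent.
#' @param top_k Fallback size if nothing clears the threshold.
#' @return Integer vector of selected m/z channels.
#' @export
importance_reduce <- function(result, threshold = 70, top_k = 8L) {
  stopifnot(inherits(result, "model_result"))
  if (is.null(result$importances)) stop("model result carries no importances")
  imp <- result$importances
  sel <- names(imp)[imp > threshold]
  if (length(sel) == 0L) {
    warning("no channel clears the importance threshold; falling back to top-k")
    sel <- names(sort(imp, decreasing = TRUE))[seq_len(min(top_k,
                                                           length(imp)))]
  }
  sort(as.integer(sel))
}

#' Restrict a TIS matrix to selected channels
#'
#' @param x A `tis_matrix`.
#' @param mz_set Integer m/z channels to keep (must be on the axis).
#' @return A `tis_matrix` over the reduced axis.
#' @export
subset_channels <- function(x, mz_set) {
  stopifnot(inherits(x, "tis_matrix"))
  idx <- match(mz_set, x$mz_axis)
  if (anyNA(idx)) stop("mz_set contains channels outside the matrix axis")
  structure(list(D = x$D[idx, , drop = FALSE], mz_axis = x$mz_axis[idx],
                 metadata = x$metadata),
            class = "tis_matrix")
}

#' Per-channel one-way ANOVA across odor grades
#'
#' Tests each selected m/z channel for mean-intensity differences across the
#' five grades; used to confirm that importance-selected channels carry
#' grade information.
#'
#' @param x A `tis_matrix`.
#' @param mz_set Channels to test.
#' @param alpha Significance level.
#' @return Data frame: mz, f, p, significant.
#' @export
channel_anova <- function(x, mz_set, alpha = 0.05) {
  stopifnot(inherits(x, "tis_matrix"))
  g <- droplevels(x$metadata$grade)
  idx <- match(mz_set, x$mz_axis)
  if (anyNA(idx)) stop("mz_set contains channels outside the matrix axis")
  rows <- lapply(idx, function(i) {
    a <- stats::anova(stats::lm(x$D[i, ] ~ g))
    data.frame(f = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  out <- do.call(rbind, rows)
  data.frame(mz = mz_set, f = out$f, p = out$p,
             significant = out$p < alpha)
}

# ---- PLSR (NIPALS, PLS1) ---------------------------------------------------

# NIPALS partial least squares for a single response; returns per-component
# weights/loadings and the coefficient path.
.nipals_pls1 <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  q <- numeric(ncomp)
  ssy <- sum(yc^2)
  ssx <- sum(Xc^2)
  var_y <- var_x <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { ncomp <- h - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(Xd, t)) / tt
    qh <- sum(yd * t) / tt
    W[, h] <- w; P[, h] <- pvec; Tm[, h] <- t; q[h] <- qh
    var_x[h] <- tt * sum(pvec^2) / ssx
    var_y[h] <- qh^2 * tt / ssy
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - t * qh
  }
  ncomp <- max(ncomp, 1L)
  # coefficient vector for every component count 1..ncomp
  coefs <- matrix(0, p, ncomp)
  for (h in seq_len(ncomp)) {
    Wh <- W[, 1:h, drop = FALSE]; Ph <- P[, 1:h, drop = FALSE]
    R <- Wh %*% solve(crossprod(Ph, Wh))
    coefs[, h] <- R %*% q[1:h]
  }
  list(ncomp = ncomp, x_mean = xm, y_mean = ym, weights = W[, 1:ncomp,
       drop = FALSE], loadings = P[, 1:ncomp, drop = FALSE],
       scores = Tm[, 1:ncomp, drop = FALSE], q = q[1:ncomp],
       coefs = coefs, var_x = var_x[1:ncomp], var_y = var_y[1:ncomp])
}

.predict_pls <- function(pls, X, ncomp)
  drop(sweep(as.matrix(X), 2, pls$x_mean) %*% pls$coefs[, ncomp]) + pls$y_mean

#' Partial least squares regression with CV component selection
#'
#' NIPALS PLS1 on mean-centered data. The component count minimizing the
#' k-fold CV RMSE is selected; variable importances are weighted sums of the
#' absolute regression coefficients over components, weighted by the
#' response variance each component explains, scaled so the top channel is
#' 100%.
#'
#' @param train Training `tis_matrix`.
#' @param max_components Largest component count considered.
#' @param folds Optional fold assignment (default: built from the response
#'   with `seed`).
#' @param k,seed Fold construction parameters when `folds` is NULL.
#' @return A `model_result` with `ncomp`, `rmse_curve` (CV RMSE per component
#'   count), `variance_explained` (`x`, `y` cumulative percentages) and
#'   `importances`.
#' @export
pls_fit <- function(train, max_components = 10L, folds = NULL, k = 5L,
                    seed = 1L) {
  if (max_components < 1L) stop("max_components must be >= 1")
  d <- .xy(train, "regress")
  max_components <- min(max_components, nrow(d$x) - 2L, ncol(d$x))
  if (is.null(folds)) folds <- make_cv_folds(d$y, k = k, seed = seed)
  preds <- matrix(NA_real_, length(d$y), max_components)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    pf <- .nipals_pls1(d$x[!hold, , drop = FALSE], d$y[!hold],
                       max_components)
    for (h in seq_len(pf$ncomp))
      preds[hold, h] <- .predict_pls(pf, d$x[hold, , drop = FALSE], h)
  }
  rmse_curve <- apply(preds, 2, function(p) sqrt(mean((p - d$y)^2)))
  ncomp <- which.min(rmse_curve)
  final <- .nipals_pls1(d$x, d$y, max_components)
  ncomp <- min(ncomp, final$ncomp)
  cvm <- regression_metrics(preds[, ncomp], d$y)
  # importance: sum_h w_h |B^(h)_j|, w_h = response variance explained by h
  w <- final$var_y[1:ncomp]
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / ncomp, ncomp)
  imp <- drop(abs(final$coefs[, 1:ncomp, drop = FALSE]) %*% w)
  imp <- 100 * imp / max(imp)
  names(imp) <- colnames(d$x)
  .new_model_result("plsr", "regress", c(final, list(ncomp_used = ncomp)),
                    list(ncomp = ncomp),
                    list(rmse = cvm$rmse, r_squared = cvm$r_squared),
                    extra = list(
                      rmse_curve = data.frame(ncomp = seq_along(rmse_curve),
                                              cv_rmse = rmse_curve),
                      variance_explained = list(
                        x = 100 * cumsum(final$var_x)[ncomp],
                        y = 100 * cumsum(final$var_y)[ncomp])),
                    importances = imp,
                    mz_used = as.integer(colnames(d$x)))
}

#' Predict from a fitted model result
#'
#' @param object A `model_result`.
#' @param newdata A `tis_matrix` on the same channel set.
#' @param ... Unused.
#' @return Predicted grades (factor) or blend percentages (numeric).
#' @export
predict.model_result <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "tis_matrix"))
  X <- t(newdata$D)
  if (!is.null(object$mz_used)) {
    idx <- match(object$mz_used, as.integer(colnames(X)))
    if (anyNA(idx)) stop("newdata lacks channels the model was trained on")
    X <- X[, idx, drop = FALSE]
  }
  switch(object$algorithm,
         gaussian_svm = ,
         gaussian_svr = kernlab::predict(object$model, X),
         random_forest = stats::predict(object$model, X),
         plsr = .predict_pls(object$model, X, object$model$ncomp_used),
         stop("unknown algorithm: ", object$algorithm))
}

#' Evaluate a model on a held-out test set
#'
#' @param result A `model_result`.
#' @param test Test `tis_matrix`.
#' @return The `model_result` with `test_metrics` filled in (accuracy +
#'   kappa, or RMSE + R-squared).
#' @export
assess_model <- function(result, test) {
  stopifnot(inherits(result, "model_result"))
  pred <- predict(result, test)
  result$test_metrics <- if (result$task == "classify") {
    actual <- droplevels(test$metadata$grade)
    list(accuracy = mean(pred == actual), kappa = cohen_kappa(pred, actual))
  } else {
    m <- regression_metrics(pred, test$metadata$blend_pct)
    list(rmse = m$rmse, r_squared = m$r_squared)
  }
  result
}

#' Mean spectralprint of each odor grade
#'
#' Per-grade mean of the base-peak-normalized intensities at the selected
#' marker channels, re-normalized to each grade's maximum for display - the
#' reduced bar-chart fingerprint that lets grades be told apart by eye.
#'
#' @param x A `tis_matrix` (normalized columns).
#' @param mz_set Marker channels.
#' @param grade_labels Factor of grade labels (default: from the metadata).
#' @return An object of class `spectralprint`: `mz_set`, `means` (raw
#'   per-grade means) and `display` (per-grade max-normalized), both channels
#'   x grades.
#' @export
extract_spectralprint <- function(x, mz_set, grade_labels = NULL) {
  stopifnot(inherits(x, "tis_matrix"))
  if (is.null(grade_labels)) grade_labels <- x$metadata$grade
  if (anyNA(grade_labels) || !all(grade_labels %in% grade_levels))
    stop("grade labels must all be one of: ",
         paste(grade_levels, collapse = ", "))
  grade_labels <- factor(grade_labels, levels = grade_levels)
  idx <- match(mz_set, x$mz_axis)
  if (anyNA(idx)) stop("mz_set contains channels outside the matrix axis")
  grades <- levels(droplevels(grade_labels))
  means <- vapply(grades, function(g)
    rowMeans(x$D[idx, grade_labels == g, drop = FALSE]),
    numeric(length(idx)))
  means <- matrix(means, nrow = length(idx),
                  dimnames = list(mz_set, grades))
  display <- sweep(means, 2, apply(means, 2, max), "/")
  structure(list(mz_set = as.integer(mz_set), means = means,
                 display = display),
            class = "spectralprint")
}

#' @export
print.spectralprint <- function(x, ...) {
  cat(sprintf("<spectralprint> %d marker channels x %d grades\n",
              nrow(x$display), ncol(x$display)))
  print(round(x$display, 3))
  invisible(x)
}
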