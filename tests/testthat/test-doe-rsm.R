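# Box-Behnken design, quadratic fit, pure-error ANOVA, lack of fit,
# standardized effects, surface optimization, kinetic ANOVA, precision CV.

test_that("the 3-factor Box-Behnken design has the canonical structure", {
  study <- bbd_design(headspace_factors(), n_center = 6L)
  d <- as.matrix(study$design[, c("x1", "x2", "x3")])
  expect_equal(nrow(d), 18L)
  expect_equal(colSums(d), c(x1 = 0, x2 = 0, x3 = 0))
  for (j in 1:3) expect_equal(sum(abs(d[, j]) == 1), 8L)
  # edge set equals the brute-force enumeration of pairs (+-1,+-1) x {0}
  edges <- d[rowSums(abs(d)) > 0, ]
  enum <- NULL
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    for (a in c(-1, 1)) for (b in c(-1, 1)) {
      row <- c(0, 0, 0); row[pair] <- c(a, b)
      enum <- rbind(enum, row)
    }
  key <- function(m) unname(sort(apply(m, 1, paste, collapse = ",")))
  expect_equal(key(edges), key(enum))
  expect_equal(sum(rowSums(abs(d)) == 0), 6L)
  expect_equal(nrow(bbd_design(n_center = 3L)$design), 15L)
  expect_error(bbd_design(headspace_factors()[1:2]), "3-factor")
  # randomized run order permutes the order column only
  r <- bbd_design(seed = 42L)
  expect_equal(r$design[, 1:3], study$design[, 1:3])
  expect_equal(sort(r$design$run_order), 1:18)
})

test_that("coding maps natural units affinely onto [-1, 1]", {
  temp <- headspace_factors()[[1]]
  expect_equal(code_level(temp, 140), 1)
  expect_equal(code_level(temp, 100), -1)
  for (f in headspace_factors()) expect_equal(code_level(f, f$mid), 0)
  set.seed(4)
  for (f in headspace_factors()) {
    x <- runif(25, f$low, f$high)
    expect_equal(uncode_level(f, code_level(f, x)), x)
  }
  out <- code_level(temp, 200)
  expect_true(isTRUE(attr(out, "extrapolated")))
  expect_error(factor_def("bad", 1, 3, mid = 2.5), "midpoint")
})

test_that("the quadratic fit reproduces the published model", {
  fit <- fit_quadratic(example_bbd_study())
  b <- fit$coefficients
  expect_equal(signif(unname(b["b0"]), 3), 0.0831)
  expect_equal(signif(unname(b["b1"]), 3), 0.0245)
  expect_equal(signif(unname(b["b3"]), 3), 0.0109)
  expect_equal(fit$predicted[1], 0.0495423, tolerance = 1e-5)
  expect_equal(100 * fit$r_squared, 88.75, tolerance = 1e-3)
  expect_equal(fit$predicted + fit$residuals, example_bbd_study()$responses)
  expect_error(fit_quadratic(bbd_design()), "no responses")
})

test_that("ANOVA uses type-III term SS against pure error", {
  fit <- fit_quadratic(example_bbd_study())
  tab <- anova_table(fit)
  # linear term SS = 8 b^2 for this design (orthogonality)
  expect_equal(tab$ss[tab$term == "X1"], 8 * fit$coefficients[["b1"]]^2)
  expect_equal(tab$ss[tab$term == "X1"], 0.00480448, tolerance = 1e-5)
  expect_equal(tab$f[tab$term == "X1"], 45.18, tolerance = 1e-3)
  expect_equal(tab$p[tab$term == "X1"], 0.0011, tolerance = 0.05)
  expect_equal(tab$f[tab$term == "X3"], 8.91, tolerance = 1e-3)
  expect_equal(tab$p[tab$term == "X3"], 0.0306, tolerance = 1e-2)
  expect_true(all(tab$ms == tab$ss / tab$df))
  # pure-error MS equals the sample variance of the six center responses
  centers <- example_bbd_study()$responses[13:18]
  expect_equal(fit$ss_pure_error / fit$df_pure_error, var(centers))
  # linear-term estimates equal sum(x_i * y) / 8 (BBD orthogonality)
  d <- example_bbd_study()
  for (j in 1:3)
    expect_equal(unname(fit$coefficients[1 + j]),
                 sum(d$design[[j]] * d$responses) / 8)
  # a constant response gives zero SS for every term
  const <- fit_quadratic(set_responses(bbd_design(), rep(0.5, 18)))
  expect_true(all(abs(const$coefficients[-1]) < 1e-12))
  # no replicates: pure error undefined
  nc <- set_responses(bbd_design(n_center = 1L), runif(13))
  expect_error(anova_table(fit_quadratic(nc)), "center points")
})

test_that("lack of fit partitions the residual SS against pure error", {
  fit <- fit_quadratic(example_bbd_study())
  lof <- lack_of_fit(fit)
  expect_equal(lof$p, 0.436, tolerance = 2e-3)
  expect_equal(lof$df_lof, 3L)
  set.seed(6)
  rfit <- fit_quadratic(set_responses(bbd_design(), runif(18)))
  rlof <- lack_of_fit(rfit)
  expect_equal(rlof$ss_lof + rlof$ss_pe, rfit$ss_residual)
  # responses exactly quadratic except center noise: the model absorbs the
  # center mean, so lack of fit is exactly zero
  s <- surrogate_surface()
  study <- bbd_design()
  y <- apply(study$design[, 1:3], 1, function(pt) surrogate_response(s, pt))
  y[13:18] <- y[13:18] + c(-0.003, 0.001, 0.002, -0.001, 0.0005, 0.0005)
  clof <- lack_of_fit(fit_quadratic(set_responses(study, y)))
  expect_lt(abs(clof$f), 1e-6)
})

test_that("standardized effects are t statistics consistent with the ANOVA", {
  fit <- fit_quadratic(example_bbd_study())
  eff <- standardized_effects(fit)
  tab <- anova_table(fit)
  for (i in seq_len(nrow(eff))) {
    f_row <- tab$f[tab$term == eff$term[i]]
    expect_equal(eff$t[i]^2, f_row, tolerance = 1e-10)
  }
  expect_equal(eff$term[1], "X1")
  expect_equal(sort(eff$term[eff$significant]), c("X1", "X3"))
  expect_true(all(diff(abs(eff$t)) <= 1e-12))
  # symmetric center noise around the edge level: all effects exactly zero
  y0 <- c(rep(0.5, 12), 0.5 + c(-0.01, 0.01, -0.02, 0.02, -0.005, 0.005))
  eff0 <- standardized_effects(fit_quadratic(set_responses(bbd_design(), y0)))
  expect_true(all(abs(eff0$t) < 1e-9))
})

test_that("surface optimization finds the constrained maximum", {
  bowl <- set_responses(bbd_design(), apply(
    bbd_design()$design[, 1:3], 1, function(x) -sum(x^2)))
  opt0 <- optimize_surface(fit_quadratic(bowl))
  expect_equal(unname(opt0$coded), c(0, 0, 0), tolerance = 1e-6)
  fit <- fit_quadratic(example_bbd_study())
  opt <- optimize_surface(fit)
  expect_equal(unname(opt$coded["x1"]), 1, tolerance = 1e-6)
  expect_equal(unname(opt$natural["temperature"]), 140, tolerance = 1e-3)
  # grid oracle: no cube point beats the optimizer
  g <- seq(-1, 1, by = 0.05)
  pts <- as.matrix(expand.grid(g, g, g))
  vals <- apply(pts, 1, function(x)
    sum(fit$coefficients * c(1, x[1], x[2], x[3], x[1]^2, x[1] * x[2],
                             x[1] * x[3], x[2]^2, x[2] * x[3], x[3]^2)))
  expect_gte(opt$predicted + 1e-9, max(vals))
})

test_that("kinetic ANOVA behaves like classical one-way ANOVA", {
  same <- list(`5` = c(1, 1), `10` = c(1, 1), `15` = c(1, 1))
  res <- kinetic_anova(same)
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)
  set.seed(7)
  g1 <- rnorm(6); g2 <- rnorm(6, 0.5)
  two <- kinetic_anova(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(two$f, unname(tt$statistic^2))
  expect_equal(two$p, tt$p.value)
  expect_equal(two$summary$mean, c(mean(g1), mean(g2)))
  expect_error(kinetic_anova(list(a = 1:3)), "two groups")
  expect_error(kinetic_anova(list(a = 1, b = 2)), "two replicates")
  df <- data.frame(time = rep(c(5, 10), each = 3), distance = rnorm(6))
  expect_length(kinetic_anova(df)$summary$group, 2L)
})

test_that("precision CV is 100 sd / mean with a 10% acceptance limit", {
  expect_equal(precision_cv(c(2, 2, 2))$cv_percent, 0)
  res <- precision_cv(c(9, 10, 11))
  expect_equal(res$cv_percent, 10, tolerance = 1e-12)
  expect_true(res$pass)
  expect_equal(res$limit, 10)
  expect_false(precision_cv(c(5, 10, 15))$pass)
  expect_error(precision_cv(c(0)), "two replicate")
  expect_error(precision_cv(c(-1, 1)), "mean distance is zero")
})
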