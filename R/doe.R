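# Box-Behnken design, second-order response-surface fit, pure-error ANOVA,
# lack-of-fit, surface optimization, kinetic ANOVA and precision CV%.

#' Define a design factor
#'
#' @param name Factor label.
#' @param low,high Low / high natural-unit levels.
#' @param mid Center level; defaults to the midpoint and must equal it (a
#'   Box-Behnken factor is symmetric).
#' @return An object of class `factor_def`.
#' @export
factor_def <- function(name, low, high, mid = (low + high) / 2) {
  if (!(low < mid && mid < high)) stop("need low < mid < high")
  if (abs(mid - (low + high) / 2) > 1e-8 * (high - low))
    stop("mid must be the midpoint of low and high")
  structure(list(name = name, low = low, mid = mid, high = high),
            class = "factor_def")
}

#' The headspace-generation factors
#'
#' Incubation temperature (100-140 degC), agitation (250-750 rpm) and sample
#' quantity (0.2-0.6 g), the three variables screened for headspace
#' optimization.
#'
#' @return List of three [factor_def()].
#' @export
headspace_factors <- function() {
  list(factor_def("temperature", 100, 140),
       factor_def("agitation", 250, 750),
       factor_def("sample_quantity", 0.2, 0.6))
}

#' Code / uncode a factor level
#'
#' Affine map between natural units and coded units: low -> -1, mid -> 0,
#' high -> +1. Values outside `[-1, 1]` are allowed (extrapolation) and
#' flagged with an `"extrapolated"` attribute.
#'
#' @param f A [factor_def()].
#' @param value Numeric value(s) in natural (for `code_level`) or coded
#'   (for `uncode_level`) units.
#' @return Numeric value(s) in the other unit system.
#' @export
code_level <- function(f, value) {
  stopifnot(inherits(f, "factor_def"))
  x <- (value - f$mid) / ((f$high - f$low) / 2)
  if (any(abs(x) > 1 + 1e-9)) attr(x, "extrapolated") <- TRUE
  x
}

#' @rdname code_level
#' @export
uncode_level <- function(f, value) {
  stopifnot(inherits(f, "factor_def"))
  x <- f$mid + value * (f$high - f$low) / 2
  if (any(abs(value) > 1 + 1e-9)) attr(x, "extrapolated") <- TRUE
  x
}

#' Build a three-factor Box-Behnken design
#'
#' Twelve edge runs (each factor pair at the four `(+-1, +-1)` combinations
#' with the third factor at its center) plus replicated center points. Run
#' order can be randomized under a seed; randomization adds an order column
#' only and never changes the fit.
#'
#' @param factors List of exactly three [factor_def()].
#' @param n_center Number of center-point replicates (>= 1).
#' @param seed Optional seed to randomize the run order.
#' @return An object of class `bbd_study`: `factors`, `design` (coded
#'   data.frame `x1, x2, x3` plus `run_order`), `responses` (NULL until
#'   measured).
#' @export
bbd_design <- function(factors = headspace_factors(), n_center = 6L,
                       seed = NULL) {
  if (length(factors) != 3L)
    stop("only the 3-factor Box-Behnken design is supported")
  stopifnot(all(vapply(factors, inherits, logical(1), "factor_def")))
  if (n_center < 1L) stop("n_center must be >= 1")
  pm <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  edges <- rbind(
    cbind(pm$a, pm$b, 0),   # (x1, x2) varied, x3 center
    cbind(pm$a, 0, pm$b),   # (x1, x3)
    cbind(0, pm$a, pm$b))   # (x2, x3)
  design <- rbind(edges, matrix(0, n_center, 3))
  colnames(design) <- c("x1", "x2", "x3")
  design <- as.data.frame(design)
  design$run_order <- if (is.null(seed)) seq_len(nrow(design)) else
    with_local_seed(seed, sample.int(nrow(design)))
  structure(list(factors = factors, design = design, responses = NULL),
            class = "bbd_study")
}

#' Attach measured responses to a design
#'
#' @param study A `bbd_study`.
#' @param responses Numeric vector, one response (Euclidean distance between
#'   the normalized TIS of the two reference grades) per design row.
#' @return The study with responses set.
#' @export
set_responses <- function(study, responses) {
  stopifnot(inherits(study, "bbd_study"))
  if (length(responses) != nrow(study$design))
    stop("need one response per design run")
  study$responses <- as.numeric(responses)
  study
}

#' The published headspace-optimization experiment
#'
#' The 18-run Box-Behnken design (12 edge runs + 6 center replicates) over
#' incubation temperature, agitation and sample quantity, with the measured
#' responses - the Euclidean distance between the normalized TIS of a Slight
#' (25%) and a Very Strong (100%) sample - from the published optimization of
#' headspace conditions for paraffin-wax odor analysis. Bundled as reference
#' data for the response-surface machinery.
#'
#' @return A `bbd_study` with responses attached.
#' @export
example_bbd_study <- function() {
  design <- data.frame(
    x1 = c(-1, 1, -1, 1, 1, 1, 0, -1, 0, 0, -1, 0, 0, 0, 0, 0, 0, 0),
    x2 = c(0, -1, -1, 0, 1, 0, -1, 1, -1, 1, 0, 1, 0, 0, 0, 0, 0, 0),
    x3 = c(1, 0, 0, -1, 0, 1, -1, 0, 1, 1, -1, -1, 0, 0, 0, 0, 0, 0))
  design$run_order <- seq_len(nrow(design))
  responses <- c(0.056794, 0.111667, 0.0546288, 0.0695383, 0.105074,
                 0.1244, 0.0580481, 0.0492514, 0.0918902, 0.0831786,
                 0.0539537, 0.0876625, 0.0808236, 0.0825085, 0.0898495,
                 0.0641407, 0.0892545, 0.0922287)
  structure(list(factors = headspace_factors(), design = design,
                 responses = responses),
            class = "bbd_study")
}

term_names <- c("b0", "b1", "b2", "b3", "b11", "b12", "b13", "b22", "b23",
                "b33")
term_labels <- c("(Intercept)", "X1", "X2", "X3", "X1:X1", "X1:X2", "X1:X3",
                 "X2:X2", "X2:X3", "X3:X3")

# rows of the design that are center points
.center_rows <- function(study)
  which(rowSums(abs(as.matrix(study$design[, c("x1", "x2", "x3")]))) == 0)

#' Fit the full second-order polynomial by ordinary least squares
#'
#' Fits `Y = b0 + sum bi xi + sum bii xi^2 + sum bij xi xj` in coded units to
#' the design responses.
#'
#' @param study A `bbd_study` with responses.
#' @return An object of class `quadratic_fit`: `coefficients` (named
#'   b0...b33), `predicted`, `residuals`, `r_squared`, plus the pieces the
#'   ANOVA needs (inverse cross-product diagonal, pure-error df and SS).
#' @export
fit_quadratic <- function(study) {
  stopifnot(inherits(study, "bbd_study"))
  if (is.null(study$responses)) stop("study has no responses")
  y <- study$responses
  X <- quad_terms(as.matrix(study$design[, c("x1", "x2", "x3")]))
  colnames(X) <- term_names
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design is rank deficient for the 10-term model")
  b <- qr.coef(qrX, y)
  predicted <- drop(X %*% b)
  residuals <- y - predicted
  ss_res <- sum(residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  centers <- .center_rows(study)
  ss_pe <- if (length(centers) >= 2L)
    sum((y[centers] - mean(y[centers]))^2) else NA_real_
  structure(list(
    coefficients = b, predicted = predicted, residuals = residuals,
    r_squared = 1 - ss_res / ss_tot,
    ss_residual = ss_res, ss_total = ss_tot,
    ss_pure_error = ss_pe, df_pure_error = length(centers) - 1L,
    xtx_inv_diag = diag(chol2inv(qr.R(qrX))),
    n = length(y), p = ncol(X), study = study),
    class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat("<quadratic_fit> coded second-order model\n")
  print(round(x$coefficients, 6))
  cat(sprintf("R-squared: %.2f%%\n", 100 * x$r_squared))
  invisible(x)
}

pure_error_ms <- function(fit) {
  if (is.na(fit$ss_pure_error) || fit$df_pure_error < 1L)
    stop("pure error undefined: the design has no replicated center points")
  fit$ss_pure_error / fit$df_pure_error
}

#' Term-wise ANOVA of the quadratic model
#'
#' One single-degree-of-freedom row per model term (partial, type-III sum of
#' squares `b^2 / C_jj`; for a linear term of this design that reduces to
#' `8 b^2`). Each F statistic tests the term mean square against the
#' pure-error mean square estimated from the replicated center points - the
#' convention of classical DOE software, which a residual-MS denominator does
#' not reproduce.
#'
#' @param fit A [fit_quadratic()] result.
#' @return Data frame: term, ss, df, ms, f, p.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  ms_pe <- pure_error_ms(fit)
  idx <- 2:fit$p  # all terms except the intercept
  ss <- fit$coefficients[idx]^2 / fit$xtx_inv_diag[idx]
  f <- ss / ms_pe
  data.frame(term = term_labels[idx], ss = unname(ss), df = 1L,
             ms = unname(ss), f = unname(f),
             p = stats::pf(unname(f), 1, fit$df_pure_error,
                           lower.tail = FALSE),
             row.names = NULL)
}

#' Lack-of-fit test against pure error
#'
#' Partitions the residual SS into pure error (center-point replication) and
#' lack of fit; a small F / large p says the quadratic form is adequate.
#'
#' @param fit A [fit_quadratic()] result.
#' @return List `f`, `p`, `df_lof`, `df_pe`, `ss_lof`, `ss_pe`.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  ms_pe <- pure_error_ms(fit)
  df_lof <- fit$n - fit$p - fit$df_pure_error
  if (df_lof <= 0L) stop("no degrees of freedom left for lack of fit")
  ss_lof <- fit$ss_residual - fit$ss_pure_error
  f <- (ss_lof / df_lof) / ms_pe
  list(f = f, p = stats::pf(f, df_lof, fit$df_pure_error, lower.tail = FALSE),
       df_lof = df_lof, df_pe = fit$df_pure_error,
       ss_lof = ss_lof, ss_pe = fit$ss_pure_error)
}

#' Standardized effects (Pareto chart data)
#'
#' t statistic of every non-intercept term against its pure-error-based
#' standard error, ordered by decreasing magnitude, with the two-sided 5%
#' significance threshold at the pure-error degrees of freedom. For these
#' single-df terms `t^2` equals the ANOVA F.
#'
#' @param fit A [fit_quadratic()] result.
#' @param alpha Significance level of the reference line.
#' @return Data frame: term, coefficient, t, significant; attribute
#'   `"t_critical"`.
#' @export
standardized_effects <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "quadratic_fit"))
  ms_pe <- pure_error_ms(fit)
  idx <- 2:fit$p
  se <- sqrt(ms_pe * fit$xtx_inv_diag[idx])
  t <- fit$coefficients[idx] / se
  t_crit <- stats::qt(1 - alpha / 2, fit$df_pure_error)
  out <- data.frame(term = term_labels[idx],
                    coefficient = unname(fit$coefficients[idx]),
                    t = unname(t), significant = abs(unname(t)) > t_crit,
                    row.names = NULL)
  out <- out[order(-abs(out$t)), ]
  rownames(out) <- NULL
  attr(out, "t_critical") <- t_crit
  out
}

#' Maximize the fitted surface over the coded cube
#'
#' Multi-start L-BFGS-B maximization of the fitted polynomial over
#' `[-1, 1]^3`, cross-checked against (and refined by) a grid scan.
#'
#' @param fit A [fit_quadratic()] result.
#' @param n_starts Number of random starts.
#' @param grid_step Step of the confirming grid scan.
#' @param seed Seed for the random starts.
#' @return List `coded` (x1, x2, x3), `natural` (named by factor),
#'   `predicted` (fitted response at the optimum).
#' @export
optimize_surface <- function(fit, n_starts = 25L, grid_step = 0.001,
                             seed = 1L) {
  stopifnot(inherits(fit, "quadratic_fit"))
  b <- fit$coefficients
  fn <- function(x) drop(quad_terms(x) %*% b)
  gr <- function(x) c(
    b[2] + 2 * b[5] * x[1] + b[6] * x[2] + b[7] * x[3],
    b[3] + b[6] * x[1] + 2 * b[8] * x[2] + b[9] * x[3],
    b[4] + b[7] * x[1] + b[9] * x[2] + 2 * b[10] * x[3])
  starts <- rbind(c(0, 0, 0),
                  with_local_seed(seed,
                    matrix(stats::runif(3 * (n_starts - 1), -1, 1),
                           ncol = 3)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                      lower = -1, upper = 1,
                      control = list(fnscale = -1, factr = 1e4))
    if (is.null(best) || o$value > best$value) best <- o
  }
  # coarse-to-fine grid confirmation
  g <- seq(-1, 1, by = 0.05)
  gpts <- as.matrix(expand.grid(x1 = g, x2 = g, x3 = g))
  gv <- quad_terms(gpts) %*% b
  gbest <- gpts[which.max(gv), ]
  lo <- pmax(gbest - 0.05, -1); hi <- pmin(gbest + 0.05, 1)
  gf <- as.matrix(expand.grid(x1 = seq(lo[1], hi[1], by = grid_step),
                              x2 = seq(lo[2], hi[2], by = grid_step),
                              x3 = seq(lo[3], hi[3], by = grid_step)))
  gfv <- quad_terms(gf) %*% b
  if (max(gfv) > best$value + 1e-12) {
    coded <- gf[which.max(gfv), ]
    value <- max(gfv)
  } else {
    coded <- best$par
    value <- best$value
  }
  names(coded) <- c("x1", "x2", "x3")
  natural <- mapply(uncode_level, fit$study$factors, coded)
  names(natural) <- vapply(fit$study$factors, function(f) f$name, character(1))
  list(coded = coded, natural = natural, predicted = value)
}

#' One-way ANOVA for the incubation-time kinetic study
#'
#' Classical one-way ANOVA of replicate Euclidean distances grouped by
#' incubation time, reporting per-time mean and s.d. A non-significant result
#' (fail to reject at `alpha`) means the headspace has equilibrated and the
#' shortest time can be adopted.
#'
#' @param groups Named list of numeric replicate vectors (one per time), or a
#'   data frame with columns `time` and `distance`.
#' @param alpha Significance level.
#' @return List `f`, `p`, `df_between`, `df_within`, `significant`,
#'   `summary` (data frame: group, n, mean, sd).
#' @export
kinetic_anova <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups))
    groups <- split(groups$distance, groups$time)
  if (length(groups) < 2L) stop("need at least two groups")
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs at least two replicates")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), n_i), levels = names(groups))
  means <- tapply(y, g, mean)
  ssb <- sum(n_i * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  df_b <- length(groups) - 1L
  df_w <- length(y) - length(groups)
  if (ssb <= .Machine$double.eps * sum(y^2)) {
    f <- 0; p <- 1  # identical group means: nothing to reject
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(f = f, p = p, df_between = df_b, df_within = df_w,
       significant = p < alpha,
       summary = data.frame(group = names(groups), n = as.integer(n_i),
                            mean = as.numeric(means),
                            sd = as.numeric(tapply(y, g, stats::sd)),
                            row.names = NULL))
}

#' Coefficient of variation of replicate distances
#'
#' Precision statistic for repeatability / intermediate precision:
#' `100 * sd / mean` of replicate Euclidean distances, checked against an
#' acceptance limit.
#'
#' @param distances Numeric vector of replicate distances (>= 2 values).
#' @param limit Acceptance limit in percent.
#' @return List `distances`, `cv_percent`, `limit`, `pass`.
#' @export
precision_cv <- function(distances, limit = 10) {
  if (length(distances) < 2L) stop("need at least two replicate distances")
  m <- mean(distances)
  if (m == 0) stop("mean distance is zero; CV undefined")
  cv <- 100 * stats::sd(distances) / m
  list(distances = distances, cv_percent = cv, limit = limit,
       pass = cv <= limit)
}
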