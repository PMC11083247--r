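# Synthetic GC/MS generator: stands in for the HS-GC/MS instrument so the
# whole analysis is reproducible offline. Runs carry grade-dependent marker
# ions on top of an odor-independent alkane-fragment baseline.

#' Default marker-ion table
#'
#' Expected base-peak-normalized TIS intensity of each marker ion for the five
#' odor grades (columns None ... Very Strong). The values encode the
#' qualitative structure of real wax spectra:
#' * grades None and Slight peak at m/z 97 (alkane series), the higher grades
#'   at m/z 92 (toluene-related);
#' * m/z 92, 118 and 157 sit at or above 0.75 for Slight but below 0.5 for
#'   None;
#' * m/z 79, 95, 97, 118, 157, 188 and 221 decrease monotonically from
#'   Moderate to Very Strong;
#' * m/z 91 (tropylium, alkylbenzenes) rises steeply and monotonically with
#'   blend percentage, so it dominates the first principal component and the
#'   regression models.
#'
#' Bar heights at this level of detail are not tabulated anywhere, so the
#' numbers are the package's own calibration satisfying those inequalities;
#' the table is an ordinary matrix and can be edited freely.
#'
#' @return Numeric matrix, marker ions (rownames = m/z) x 5 grades.
#' @export
default_marker_table <- function() {
  m <- rbind(
    `79`  = c(0.45, 0.60, 0.65, 0.50, 0.35),
    `91`  = c(0.10, 0.30, 0.55, 0.80, 0.98),
    `92`  = c(0.40, 0.90, 1.00, 1.00, 1.00),
    `95`  = c(0.50, 0.70, 0.72, 0.58, 0.42),
    `97`  = c(1.00, 1.00, 0.85, 0.70, 0.55),
    `118` = c(0.35, 0.80, 0.75, 0.60, 0.45),
    `157` = c(0.30, 0.78, 0.70, 0.55, 0.40),
    `188` = c(0.25, 0.45, 0.50, 0.38, 0.26),
    `221` = c(0.20, 0.35, 0.40, 0.28, 0.18))
  colnames(m) <- grade_levels
  m
}

#' Default odor-independent baseline ions
#'
#' Alkane fragment ions present in every wax regardless of grade, kept below
#' the grade-dependent base peak.
#'
#' @return Data frame with columns `mz` and `intensity`.
#' @export
default_baseline_ions <- function() {
  data.frame(mz = c(57L, 71L, 85L, 99L, 111L, 125L),
             intensity = c(0.45, 0.35, 0.30, 0.20, 0.12, 0.08))
}

#' Generator parameters
#'
#' @param marker_table Marker m/z x grade matrix of expected normalized
#'   intensities (see [default_marker_table()]).
#' @param baseline_ions Data frame `(mz, intensity)` of odor-independent ions.
#' @param peak_width Chromatographic peak s.d. in scan units (cosmetic: the
#'   TIS depends only on time-integrated intensity).
#' @param noise_sd Additive intensity noise s.d. on the normalized scale.
#' @param lot_sd S.d. of the per-(lot, ion) multiplicative log-normal lot
#'   effect.
#' @param seed Integer seed governing the lot effects (replicate noise is
#'   controlled by the per-run seed).
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(marker_table = default_marker_table(),
                             baseline_ions = default_baseline_ions(),
                             peak_width = 1.5, noise_sd = 0.02,
                             lot_sd = 0.05, seed = 101L) {
  marker_table <- as.matrix(marker_table)
  if (any(marker_table < 0) || any(baseline_ions$intensity < 0))
    stop("all intensities must be non-negative")
  if (ncol(marker_table) != 5L)
    stop("marker_table needs one column per odor grade (5)")
  if (is.null(rownames(marker_table)) ||
      anyNA(suppressWarnings(as.integer(rownames(marker_table)))))
    stop("marker_table rownames must be integer m/z values")
  if (peak_width <= 0) stop("peak_width must be positive")
  if (noise_sd < 0 || lot_sd < 0) stop("noise_sd and lot_sd must be >= 0")
  structure(list(marker_table = marker_table,
                 baseline_ions = baseline_ions,
                 peak_width = peak_width, noise_sd = noise_sd,
                 lot_sd = lot_sd, seed = as.integer(seed)),
            class = "generator_params")
}

# Evaluate a deterministic function of the RNG under a local seed without
# disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Small deterministic string hash, kept below 2^31.
.str_seed <- function(s, base) {
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(base) %% 1000003) * 1009 + h) %% 2147483647L
}

# Per-(lot, ion) multiplicative log-normal factors, deterministic in
# (params$seed, lot_id); identical for every run of the lot.
.lot_factors <- function(params, lot_id, n_ions) {
  if (params$lot_sd == 0) return(rep(1, n_ions))
  z <- with_local_seed(.str_seed(lot_id, params$seed), stats::rnorm(n_ions))
  exp(params$lot_sd * z)
}

#' Simulate one GC/MS run
#'
#' Emits each marker and baseline ion as a single Gaussian-in-time
#' chromatographic peak whose time-integrated area equals the ion's expected
#' normalized intensity (times an instrument scale), multiplied by the lot
#' effect; adds truncated Gaussian intensity noise. With `noise_sd = 0` and
#' `lot_sd = 0` the collapsed, base-peak-normalized TIS reproduces the
#' marker table exactly.
#'
#' @param blend_pct Percentage of non-hydrogenated wax; one of 0, 25, 50, 75,
#'   100 (maps to grades None ... Very Strong).
#' @param lot_id Lot label (e.g. `"A"`).
#' @param replicate Replicate label (e.g. `"R1"`).
#' @param params A [generator_params()].
#' @param seed Integer seed for this run's noise.
#' @param n_scans Number of scans across the 15.83 min program.
#' @param mz_hi Upper end of the acquired m/z axis (the instrument scans
#'   wider than the 50-550 fingerprint window).
#' @return A [gcms_run()].
#' @export
make_run <- function(blend_pct, lot_id, replicate, params = generator_params(),
                     seed = 1L, n_scans = 120L, mz_hi = 600L) {
  if (!(length(blend_pct) == 1L && blend_pct %in% c(0, 25, 50, 75, 100)))
    stop("blend_pct must be one of 0, 25, 50, 75, 100")
  stopifnot(inherits(params, "generator_params"))
  grade <- as.integer(blend_pct / 25) + 1L
  mz_axis <- 50:mz_hi
  scan_times <- seq(0.05, 15.83, length.out = n_scans)
  scale <- 1e6  # arbitrary instrument counts for one normalized unit

  marker_mz <- as.integer(rownames(params$marker_table))
  ion_mz <- c(marker_mz, params$baseline_ions$mz)
  areas <- c(params$marker_table[, grade], params$baseline_ions$intensity) *
    scale
  areas <- areas * .lot_factors(params, lot_id, length(areas))

  # fixed, well-spread retention times per ion (cosmetic; TIS integrates them
  # out)
  rt_centers <- 10 + ((seq_along(ion_mz) * 37) %% (n_scans - 20L))

  X <- matrix(0, n_scans, length(mz_axis))
  col_of <- match(ion_mz, mz_axis)
  for (j in seq_along(ion_mz)) {
    w <- stats::dnorm(seq_len(n_scans), rt_centers[j], params$peak_width)
    X[, col_of[j]] <- X[, col_of[j]] + areas[j] * w / sum(w)
  }
  if (params$noise_sd > 0) {
    # per-cell noise scaled so the collapsed TIS channel noise has s.d.
    # noise_sd on the normalized (base peak = 1) scale
    cell_sd <- params$noise_sd * scale / sqrt(n_scans)
    X <- X + with_local_seed(seed,
      matrix(stats::rnorm(length(X), 0, cell_sd), nrow(X)))
    X[X < 0] <- 0  # physical non-negativity
  }
  gcms_run(scan_times, mz_axis, X,
           sample_id = sprintf("%d%%_%s_%s", as.integer(blend_pct), lot_id,
                               replicate),
           lot = lot_id, blend_pct = blend_pct, replicate = replicate)
}

#' Simulate the full 75-run study
#'
#' Five independent lots (A-E) x five blend percentages (0, 25, 50, 75, 100)
#' x three replicates (R1-R3), labelled `"<pct>%_<lot>_<rep>"`.
#'
#' @param params A [generator_params()].
#' @param seed Master seed; each run's noise seed is derived from it.
#' @param ... Passed on to [make_run()] (`n_scans`, `mz_hi`).
#' @return List with `runs` (list of 75 [gcms_run()]) and `metadata`
#'   (data frame: sample_id, lot, blend_pct, replicate, grade).
#' @export
make_study <- function(params = generator_params(), seed = 1L, ...) {
  lots <- LETTERS[1:5]
  blends <- c(0, 25, 50, 75, 100)
  reps <- paste0("R", 1:3)
  grid <- expand.grid(replicate = reps, lot = lots, blend_pct = blends,
                      stringsAsFactors = FALSE)[, c("blend_pct", "lot",
                                                    "replicate")]
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    run_seed <- (as.integer(seed) %% 1000003L) * 1000L + i
    runs[[i]] <- make_run(grid$blend_pct[i], grid$lot[i], grid$replicate[i],
                          params = params, seed = run_seed, ...)
  }
  metadata <- data.frame(
    sample_id = vapply(runs, function(r) r$sample_id, character(1)),
    lot = grid$lot, blend_pct = grid$blend_pct, replicate = grid$replicate,
    grade = grade_from_blend(grid$blend_pct),
    stringsAsFactors = FALSE)
  list(runs = runs, metadata = metadata)
}

#' Collapse a simulated study to its normalized TIS matrix
#'
#' Convenience wrapper: collapse every run, base-peak normalize, assemble.
#'
#' @param study Output of [make_study()].
#' @param mz_lo,mz_hi TIS window bounds, as in [collapse_to_tis()].
#' @return A `tis_matrix`.
#' @export
study_tis_matrix <- function(study, mz_lo = 50L, mz_hi = 550L) {
  assemble_matrix(lapply(study$runs, function(r)
    base_peak_normalize(collapse_to_tis(r, mz_lo, mz_hi))))
}

#' Surrogate response surface for design-of-experiments testing
#'
#' A known second-order polynomial in the three coded headspace factors,
#' used as a ground-truth oracle for the response-surface fitting machinery.
#' The default coefficients are those of the published full quadratic model
#' for the wax headspace optimization (see [example_bbd_study()]).
#'
#' @param coefficients Named numeric vector of the 10 model terms, names
#'   `b0, b1, b2, b3, b11, b12, b13, b22, b23, b33`.
#' @param noise_sd Gaussian response noise s.d.; 0 gives the exact polynomial.
#' @return An object of class `surrogate_surface`.
#' @export
surrogate_surface <- function(coefficients = c(
                                b0 = 0.0831, b1 = 0.0245, b2 = 0.00111,
                                b3 = 0.0109, b11 = -0.00350, b12 = -0.000304,
                                b13 = 0.0130, b22 = 0.000522, b23 = -0.00958,
                                b33 = -0.00346),
                              noise_sd = 0) {
  nm <- c("b0", "b1", "b2", "b3", "b11", "b12", "b13", "b22", "b23", "b33")
  if (!setequal(names(coefficients), nm))
    stop("coefficients must be named b0, b1, b2, b3, b11, b12, b13, b22, b23, b33")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(coefficients = coefficients[nm], noise_sd = noise_sd),
            class = "surrogate_surface")
}

# Evaluate the 10-term quadratic at coded points (rows of a matrix or a
# length-3 vector).
quad_terms <- function(x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  cbind(1, x[, 1], x[, 2], x[, 3], x[, 1]^2, x[, 1] * x[, 2], x[, 1] * x[, 3],
        x[, 2]^2, x[, 2] * x[, 3], x[, 3]^2)
}

#' Evaluate the surrogate response at a coded design point
#'
#' @param surface A [surrogate_surface()].
#' @param coded_point Numeric triple inside the coded cube `[-1, 1]^3`.
#' @param seed Seed for the response noise.
#' @return Scalar response (a Euclidean-distance analogue).
#' @export
surrogate_response <- function(surface, coded_point, seed = 1L) {
  stopifnot(inherits(surface, "surrogate_surface"))
  if (length(coded_point) != 3L || any(abs(coded_point) > 1 + 1e-12))
    stop("coded_point must be a triple inside the coded cube [-1, 1]^3")
  y <- drop(quad_terms(coded_point) %*% surface$coefficients)
  if (surface$noise_sd > 0)
    y <- y + with_local_seed(seed, stats::rnorm(1, 0, surface$noise_sd))
  y
}
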