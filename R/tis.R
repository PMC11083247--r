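#' Construct a GC/MS run object
#'
#' A run is a retention-time-by-m/z intensity map at unit (nominal) mass
#' resolution, the second-order data structure produced by a scanning
#' quadrupole instrument.
#'
#' @param scan_times Strictly increasing numeric vector of scan times (minutes).
#' @param mz_axis Sorted vector of unique integer m/z channels (Th).
#' @param intensities Non-negative numeric matrix, scans x channels.
#' @param sample_id Sample label, e.g. `"25%_A_R1"`.
#' @param lot,blend_pct,replicate Optional sample metadata carried through to
#'   the TIS.
#' @return An object of class `gcms_run`.
#' @export
gcms_run <- function(scan_times, mz_axis, intensities, sample_id,
                     lot = NA_character_, blend_pct = NA_real_,
                     replicate = NA_character_) {
  scan_times <- as.numeric(scan_times)
  mz_axis <- as.integer(mz_axis)
  intensities <- as.matrix(intensities)
  if (length(scan_times) == 0L || length(mz_axis) == 0L)
    stop("empty run: need at least one scan and one m/z channel")
  if (any(diff(scan_times) <= 0))
    stop("scan_times must be strictly increasing")
  if (is.unsorted(mz_axis, strictly = TRUE))
    stop("mz_axis must be sorted and unique")
  if (nrow(intensities) != length(scan_times) ||
      ncol(intensities) != length(mz_axis))
    stop("intensities must be a length(scan_times) x length(mz_axis) matrix")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(
    list(scan_times = scan_times, mz_axis = mz_axis,
         intensities = unname(intensities), sample_id = sample_id,
         lot = lot, blend_pct = blend_pct, replicate = replicate),
    class = "gcms_run")
}

#' @export
print.gcms_run <- function(x, ...) {
  cat(sprintf("<gcms_run> %s: %d scans (%.2f-%.2f min), m/z %d-%d\n",
              x$sample_id, length(x$scan_times), min(x$scan_times),
              max(x$scan_times), min(x$mz_axis), max(x$mz_axis)))
  invisible(x)
}

#' Construct a total ion spectrum object
#'
#' @param mz_axis Integer m/z channels.
#' @param values Non-negative intensities, one per channel.
#' @param normalized Logical; `TRUE` once base-peak normalized (max = 1).
#' @param sample_id,lot,blend_pct,replicate Sample metadata.
#' @return An object of class `tis`.
#' @export
tis <- function(mz_axis, values, normalized = FALSE, sample_id = NA_character_,
                lot = NA_character_, blend_pct = NA_real_,
                replicate = NA_character_) {
  mz_axis <- as.integer(mz_axis)
  values <- as.numeric(values)
  if (length(mz_axis) != length(values))
    stop("mz_axis and values must have equal length")
  if (any(values < 0)) stop("TIS values must be non-negative")
  if (normalized && length(values) &&
      abs(max(values) - 1) > 1e-12)
    stop("normalized TIS must have maximum exactly 1")
  structure(
    list(mz_axis = mz_axis, values = values, normalized = normalized,
         sample_id = sample_id, lot = lot, blend_pct = blend_pct,
         replicate = replicate),
    class = "tis")
}

#' @export
print.tis <- function(x, ...) {
  cat(sprintf("<tis> %s: %d channels (m/z %d-%d), %s; base peak m/z %d\n",
              x$sample_id, length(x$mz_axis), min(x$mz_axis), max(x$mz_axis),
              if (x$normalized) "normalized" else "raw",
              x$mz_axis[which.max(x$values)]))
  invisible(x)
}

#' Collapse a GC/MS run to its total ion spectrum
#'
#' Sums the intensity of every m/z channel over the full chromatographic run,
#' discarding retention time entirely. Channels of the output axis not covered
#' by the run are zero. The result is *not* yet normalized.
#'
#' @param run A [gcms_run()].
#' @param mz_lo,mz_hi Integer bounds of the retained m/z window. The defaults
#'   give the standard 501-channel fingerprint (m/z 50-550); instruments often
#'   acquire a wider scan range, which is truncated here.
#' @return A raw [tis()] of length `mz_hi - mz_lo + 1`.
#' @export
collapse_to_tis <- function(run, mz_lo = 50L, mz_hi = 550L) {
  stopifnot(inherits(run, "gcms_run"))
  if (mz_hi < mz_lo) stop("mz_hi must be >= mz_lo")
  axis <- seq.int(mz_lo, mz_hi)
  keep <- run$mz_axis >= mz_lo & run$mz_axis <= mz_hi
  if (!any(keep))
    stop(sprintf("run %s covers no m/z channel in [%d, %d]",
                 run$sample_id, mz_lo, mz_hi))
  sums <- colSums(run$intensities[, keep, drop = FALSE])
  values <- numeric(length(axis))
  values[match(run$mz_axis[keep], axis)] <- sums
  tis(axis, values, normalized = FALSE, sample_id = run$sample_id,
      lot = run$lot, blend_pct = run$blend_pct, replicate = run$replicate)
}

#' Base-peak normalize a TIS
#'
#' Divides every channel by the intensity of the base peak (the sample's own
#' maximum), so the largest channel equals exactly 1. Normalization is always
#' per sample, never global.
#'
#' @param x A [tis()].
#' @return The normalized [tis()].
#' @export
base_peak_normalize <- function(x) {
  stopifnot(inherits(x, "tis"))
  bp <- max(x$values)
  if (bp <= 0)
    stop(sprintf("cannot normalize all-zero spectrum (sample %s)", x$sample_id))
  x$values <- x$values / bp
  x$normalized <- TRUE
  x
}

#' Assemble normalized spectra into the data matrix
#'
#' Stacks normalized TIS column-wise into the channels x samples matrix used
#' by every downstream chemometric step, together with its sample metadata
#' table.
#'
#' @param tis_list List of normalized [tis()] objects sharing one m/z axis.
#' @return An object of class `tis_matrix` with elements `D` (channels x
#'   samples matrix, rownames = m/z, colnames = sample ids), `mz_axis`, and
#'   `metadata` (data frame: sample_id, lot, blend_pct, replicate, grade).
#' @export
assemble_matrix <- function(tis_list) {
  if (length(tis_list) == 0L) stop("need at least one TIS")
  stopifnot(all(vapply(tis_list, inherits, logical(1), "tis")))
  axis <- tis_list[[1L]]$mz_axis
  for (t in tis_list) {
    if (!identical(t$mz_axis, axis))
      stop("all TIS must share the same m/z axis")
    if (!t$normalized)
      stop(sprintf("TIS %s is not base-peak normalized", t$sample_id))
  }
  D <- vapply(tis_list, function(t) t$values, numeric(length(axis)))
  D <- matrix(D, nrow = length(axis),
              dimnames = list(axis, vapply(tis_list, function(t)
                as.character(t$sample_id), character(1))))
  metadata <- data.frame(
    sample_id = vapply(tis_list, function(t) as.character(t$sample_id),
                       character(1)),
    lot = vapply(tis_list, function(t) as.character(t$lot), character(1)),
    blend_pct = vapply(tis_list, function(t) as.numeric(t$blend_pct),
                       numeric(1)),
    replicate = vapply(tis_list, function(t) as.character(t$replicate),
                       character(1)),
    stringsAsFactors = FALSE)
  metadata$grade <- grade_from_blend(metadata$blend_pct)
  structure(list(D = D, mz_axis = axis, metadata = metadata),
            class = "tis_matrix")
}

#' @export
print.tis_matrix <- function(x, ...) {
  cat(sprintf("<tis_matrix> %d m/z channels x %d samples\n",
              nrow(x$D), ncol(x$D)))
  invisible(x)
}

#' Euclidean distance between two normalized spectra
#'
#' The response statistic of the headspace optimization: the plain Euclidean
#' distance between two base-peak-normalized TIS, large when the two odor
#' grades are well separated.
#'
#' @param a,b Normalized [tis()] objects on the same axis.
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "tis"), inherits(b, "tis"))
  if (!a$normalized || !b$normalized)
    stop("euclidean_distance is defined on base-peak-normalized TIS")
  if (!identical(a$mz_axis, b$mz_axis))
    stop("TIS must share the same m/z axis")
  sqrt(sum((a$values - b$values)^2))
}

# ASTM D1833-style grade labels from the blend percentage of
# non-hydrogenated wax (0/25/50/75/100 -> grades 0-4).
grade_levels <- c("None", "Slight", "Moderate", "Strong", "Very Strong")

#' Map blend percentage to odor grade label
#'
#' @param blend_pct Numeric vector with values in `c(0, 25, 50, 75, 100)`
#'   (NA allowed).
#' @return Factor with levels None, Slight, Moderate, Strong, Very Strong.
#' @export
grade_from_blend <- function(blend_pct) {
  ok <- is.na(blend_pct) | blend_pct %in% c(0, 25, 50, 75, 100)
  if (!all(ok))
    stop("blend_pct must be one of 0, 25, 50, 75, 100")
  factor(grade_levels[blend_pct / 25 + 1], levels = grade_levels)
}

#' Write / read a TIS matrix as wide CSV
#'
#' The canonical interchange format: one row per m/z channel (first column
#' `mz`), one column per sample. Values are written with full double
#' precision so a round trip is bit-identical. Metadata travels in a sibling
#' CSV.
#'
#' @param x A `tis_matrix`.
#' @param path Output CSV path for the matrix.
#' @param metadata_path Optional path for the metadata CSV (default: same path
#'   with `_metadata.csv` suffix).
#' @return `path`, invisibly.
#' @export
write_tis_matrix <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "tis_matrix"))
  if (is.null(metadata_path))
    metadata_path <- sub("\\.csv$", "_metadata.csv", path)
  body <- cbind(mz = as.character(x$mz_axis),
                matrix(sprintf("%.17g", x$D), nrow = nrow(x$D)))
  colnames(body) <- c("mz", colnames(x$D))
  utils::write.csv(body, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(x$metadata, metadata_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tis_matrix
#' @export
read_tis_matrix <- function(path, metadata_path = NULL) {
  if (is.null(metadata_path))
    metadata_path <- sub("\\.csv$", "_metadata.csv", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  axis <- as.integer(raw$mz)
  D <- vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  D <- matrix(D, nrow = length(axis),
              dimnames = list(axis, colnames(raw)[-1L]))
  metadata <- if (file.exists(metadata_path)) {
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    md$grade <- grade_from_blend(md$blend_pct)
    md
  } else {
    data.frame(sample_id = colnames(D), lot = NA_character_,
               blend_pct = NA_real_, replicate = NA_character_,
               grade = grade_from_blend(rep(NA_real_, ncol(D))))
  }
  structure(list(D = D, mz_axis = axis, metadata = metadata),
            class = "tis_matrix")
}

# Subset a tis_matrix by sample index, keeping metadata aligned.
subset_samples <- function(x, idx) {
  stopifnot(inherits(x, "tis_matrix"))
  structure(list(D = x$D[, idx, drop = FALSE], mz_axis = x$mz_axis,
                 metadata = x$metadata[idx, , drop = FALSE]),
            class = "tis_matrix")
}
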