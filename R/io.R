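# Format readers/writers. Canonical interchange is long CSV
# (scan_time, mz, intensity); mzML is supported through mzR.

#' Write a GC/MS run to long-format CSV
#'
#' Columns `scan_time` (minutes), `mz` (integer Th), `intensity`. Zero cells
#' are omitted; values carry full double precision so the read-back run is
#' identical at unit-mass resolution.
#'
#' @param run A [gcms_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "gcms_run"))
  nz <- which(run$intensities > 0, arr.ind = TRUE)
  df <- data.frame(
    scan_time = sprintf("%.17g", run$scan_times[nz[, 1]]),
    mz = run$mz_axis[nz[, 2]],
    intensity = sprintf("%.17g", run$intensities[nz]))
  df <- df[order(as.numeric(df$scan_time), df$mz), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GC/MS run from CSV or mzML
#'
#' CSV must carry columns `scan_time`, `mz`, `intensity`. mzML (read via
#' mzR) may be profile-mode; m/z values are binned to nominal mass by
#' rounding to the nearest integer (ties to even, the IEC default of R's
#' `round`), summing intensities within a bin.
#'
#' @param path Input file.
#' @param format `"csv"` or `"mzml"` (default: guessed from the extension).
#' @param sample_id Sample label for the run (default: file name).
#' @return A [gcms_run()].
#' @export
read_run <- function(path, format = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "csv"
  format <- match.arg(format, c("csv", "mzml"))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") .read_run_csv(path, sample_id)
  else .read_run_mzml(path, sample_id)
}

.read_run_csv <- function(path, sample_id) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed CSV run file '", path,
                                          "': ", conditionMessage(e)))
  need <- c("scan_time", "mz", "intensity")
  if (!all(need %in% names(df)))
    stop("run CSV '", path, "' must have columns scan_time, mz, intensity ",
         "(found: ", paste(names(df), collapse = ", "), ")")
  if (nrow(df) == 0L) stop("run CSV '", path, "' contains no records")
  .bin_points(df$scan_time, df$mz, df$intensity, sample_id)
}

.read_run_mzml <- function(path, sample_id) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  if (nrow(hdr) == 0L) stop("mzML file '", path, "' contains no spectra")
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  times <- hdr$retentionTime / 60  # mzML stores seconds
  sc <- rep(times, vapply(pk, nrow, integer(1)))
  all <- do.call(rbind, pk)
  .bin_points(sc, all[, 1], all[, 2], sample_id)
}

# Bin (scan_time, mz, intensity) triples to a scans x unit-mass matrix.
.bin_points <- function(scan_time, mz, intensity, sample_id) {
  mz <- round(as.numeric(mz))  # nominal mass, ties to even
  times <- sort(unique(as.numeric(scan_time)))
  channels <- sort(unique(mz))
  X <- matrix(0, length(times), length(channels))
  i <- match(as.numeric(scan_time), times)
  j <- match(mz, channels)
  for (k in seq_along(i)) X[i[k], j[k]] <- X[i[k], j[k]] + intensity[k]
  gcms_run(times, channels, X, sample_id = sample_id)
}

#' Write a GC/MS run as centroided mzML
#'
#' Unit-mass centroid spectra, one per scan, written through mzR.
#'
#' @param run A [gcms_run()].
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  stopifnot(inherits(run, "gcms_run"))
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  n <- length(run$scan_times)
  pks <- lapply(seq_len(n), function(i) {
    nz <- run$intensities[i, ] > 0
    cbind(mz = as.numeric(run$mz_axis[nz]),
          intensity = run$intensities[i, nz])
  })
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = rowSums(run$intensities),
    retentionTime = run$scan_times * 60,
    basePeakMZ = run$mz_axis[max.col(run$intensities)],
    basePeakIntensity = apply(run$intensities, 1, max),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(run$mz_axis), highMZ = max(run$mz_axis),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(run$mz_axis),
    scanWindowUpperLimit = max(run$mz_axis))
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}
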