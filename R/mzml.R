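# mzML input/output, delegated to mzR (proteowizard backend).

#' Read a centroided MS1 run from mzML
#'
#' Only MS1 spectra are used. Files whose spectra are flagged profile mode
#' are rejected (this package consumes centroided data only); an unflagged
#' file is accepted with a warning. Scans are sorted by retention time
#' regardless of on-disk order.
#'
#' @param path path to an mzML file.
#' @param run_id run identifier; default the file name without extension.
#' @return an [ms_run()].
#' @export
read_mzml <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop_isotopt("no such file: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop_isotopt("cannot read ", path, ": ",
                                                  conditionMessage(e),
                                                  class = "isotopt_format_error"))
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1))
    stop_isotopt(path, ": no MS1 spectra", class = "isotopt_empty_input_error")
  cent <- hdr$centroided[ms1]
  if (any(!is.na(cent) & !cent))
    stop_isotopt(path, ": spectra are profile mode; centroided data required",
                 class = "isotopt_format_error")
  if (all(is.na(cent)))
    warning(path, ": centroided flag absent; assuming centroided data")
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(fh, i)
    ord <- order(pk[, 1])
    list(rt = hdr$retentionTime[i], mz = pk[ord, 1], intensity = pk[ord, 2])
  })
  ms_run(run_id %||% sub("\\.[^.]*$", "", basename(path)), scans)
}

#' Write a run to mzML
#'
#' Spectra are written as centroided MS1 scans.
#'
#' @param run an [ms_run()].
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- length(run$scans)
  if (n == 0L) stop_isotopt("cannot write a run with zero scans")
  pks <- lapply(run$scans, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(pks, nrow, 0L),
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), 0),
    retentionTime = scan_times(run),
    basePeakMZ = 0, basePeakIntensity = 0,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s) if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(run$scans, function(s) if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

#' Read / write a whole run set
#'
#' `write_runset` writes one `<run_id>.mzML` per injection into `dir`;
#' `read_runset` reads a set of mzML paths in the given order.
#'
#' @param runset an [ms_runset()].
#' @param dir output directory (created if needed).
#' @param paths character vector of mzML paths.
#' @return `write_runset` the file paths; `read_runset` an [ms_runset()].
#' @export
write_runset <- function(runset, dir) {
  stopifnot(inherits(runset, "ms_runset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(run_ids(runset), ".mzML"))
  for (k in seq_along(runset$runs)) write_mzml(runset$runs[[k]], paths[k])
  invisible(paths)
}

#' @rdname write_runset
#' @export
read_runset <- function(paths) {
  ms_runset(lapply(paths, read_mzml))
}
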