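# Peak table container and its CSV dialect.
#
# A peak table is a plain data.frame with exactly the columns
#   run_id, mz, mzmin, mzmax, rt, rtmin, rtmax, intensity
# (RT in seconds, m/z in Da, intensity = apex height of the chromatographic
# peak). This fixed dialect lets the scoring functions run on third-party
# peak tables without raw mzML.

PEAK_COLUMNS <- c("run_id", "mz", "mzmin", "mzmax", "rt", "rtmin", "rtmax",
                  "intensity")

#' Validate a peak table
#'
#' Checks the column schema and the per-row invariants
#' `mzmin <= mz <= mzmax`, `rtmin <= rt <= rtmax`, `intensity > 0`.
#' Violations raise an error naming the offending rows.
#'
#' @param peaks a data frame.
#' @return the peak table with columns in canonical order.
#' @export
validate_peaks <- function(peaks) {
  if (!is.data.frame(peaks)) stop_isotopt("peaks must be a data.frame")
  missing <- setdiff(PEAK_COLUMNS, names(peaks))
  if (length(missing))
    stop_isotopt("peak table is missing column(s): ",
                 paste(missing, collapse = ", "), class = "isotopt_schema_error")
  peaks <- peaks[, PEAK_COLUMNS]
  peaks$run_id <- as.character(peaks$run_id)
  num <- setdiff(PEAK_COLUMNS, "run_id")
  for (cl in num) {
    if (!is.numeric(peaks[[cl]]))
      stop_isotopt("peak column ", cl, " must be numeric",
                   class = "isotopt_schema_error")
  }
  if (nrow(peaks)) {
    bad <- !(peaks$mzmin <= peaks$mz & peaks$mz <= peaks$mzmax) |
           !(peaks$rtmin <= peaks$rt & peaks$rt <= peaks$rtmax) |
           !(peaks$intensity > 0) |
           !stats::complete.cases(peaks[num])
    if (any(bad))
      stop_isotopt("invalid peak row(s): ",
                   paste(utils::head(which(bad), 10), collapse = ", "),
                   " (require mzmin <= mz <= mzmax, rtmin <= rt <= rtmax, ",
                   "intensity > 0)", class = "isotopt_validation_error")
  }
  rownames(peaks) <- NULL
  peaks
}

#' Write / read the peak-table CSV dialect
#'
#' Column order and names are fixed (`run_id, mz, mzmin, mzmax, rt, rtmin,
#' rtmax, intensity`); numbers are written with full double precision so that
#' read(write(x)) is the identity up to float round-trip.
#'
#' @param peaks a valid peak table.
#' @param path file path.
#' @return `read_peaks_csv` returns the validated peak table.
#' @export
write_peaks_csv <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  num <- setdiff(PEAK_COLUMNS, "run_id")
  out <- peaks
  for (cl in num) out[[cl]] <- sprintf("%.17g", peaks[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  if (!file.exists(path)) stop_isotopt("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$run_id <- as.character(df$run_id)
  num <- intersect(setdiff(PEAK_COLUMNS, "run_id"), names(df))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  missing <- setdiff(PEAK_COLUMNS, names(df))
  if (length(missing))
    stop_isotopt(path, ": missing column(s): ",
                 paste(missing, collapse = ", "), class = "isotopt_schema_error")
  validate_peaks(df)
}

#' Choose the reference run for retention time alignment
#'
#' The center run is the one whose picked peaks have the highest mean
#' intensity; ties go to the first such run in input order.
#'
#' @param peaklists named list of per-run peak tables (names = run ids, in
#'   acquisition order).
#' @return the run id of the center run.
#' @export
select_center_run <- function(peaklists) {
  stopifnot(is.list(peaklists), length(peaklists) >= 1L)
  ids <- names(peaklists) %||% as.character(seq_along(peaklists))
  means <- vapply(peaklists, function(pk) {
    if (is.null(pk) || nrow(pk) == 0L) -Inf else mean(pk$intensity)
  }, 0)
  if (all(!is.finite(means)))
    stop_isotopt("all runs are peakless; cannot choose a center run")
  ids[which.max(means)]
}
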