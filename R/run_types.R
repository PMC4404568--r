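# In-memory containers for centroided LC-MS data: one scan is a stick
# spectrum (rt, mz[], intensity[]), one run is an injection, a run set is the
# repeated injections of one pooled sample.

#' Construct a centroided run
#'
#' @param run_id character scalar.
#' @param scans list of scans; each scan is a list with `rt` (seconds), `mz`
#'   (strictly increasing, Da) and `intensity` (nonnegative, same length).
#'   Scans are sorted by RT; duplicate scan RTs are an error.
#' @param meta free-form named list.
#' @return an object of class `ms_run`.
#' @export
ms_run <- function(run_id, scans, meta = list()) {
  stopifnot(is.character(run_id), length(run_id) == 1L, is.list(scans))
  rts <- vapply(scans, function(s) as.numeric(s$rt[1]), 0)
  if (anyNA(rts)) stop_isotopt("every scan needs a finite rt")
  for (k in seq_along(scans)) {
    s <- scans[[k]]
    mz <- as.numeric(s$mz); int <- as.numeric(s$intensity)
    if (length(mz) != length(int))
      stop_isotopt("scan ", k, ": mz and intensity lengths differ")
    if (length(mz) > 1L && any(diff(mz) <= 0))
      stop_isotopt("scan ", k, ": mz values must be strictly increasing")
    if (any(int < 0) || anyNA(int) || anyNA(mz))
      stop_isotopt("scan ", k, ": intensities must be finite and >= 0")
    scans[[k]] <- list(rt = rts[k], mz = mz, intensity = int)
  }
  ord <- order(rts)
  scans <- scans[ord]
  if (length(scans) > 1L && any(diff(rts[ord]) <= 0))
    stop_isotopt("scan retention times must be strictly increasing")
  structure(list(run_id = run_id, scans = scans, meta = meta),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  n <- length(x$scans)
  cat("<ms_run> ", x$run_id, ": ", n, " scans",
      if (n) sprintf(", rt %.1f-%.1f s", x$scans[[1]]$rt, x$scans[[n]]$rt),
      "\n", sep = "")
  invisible(x)
}

#' Construct a run set (repeated injections of one pooled sample)
#'
#' @param runs list of [ms_run()] objects with distinct run ids, in
#'   acquisition order.
#' @return an object of class `ms_runset`.
#' @export
ms_runset <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  ok <- vapply(runs, inherits, TRUE, "ms_run")
  if (!all(ok)) stop_isotopt("runs must all be ms_run objects")
  ids <- vapply(runs, `[[`, "", "run_id")
  if (anyDuplicated(ids)) stop_isotopt("duplicate run ids: ",
                                       paste(ids[duplicated(ids)], collapse = ", "))
  names(runs) <- ids
  structure(list(runs = runs), class = "ms_runset")
}

#' @export
print.ms_runset <- function(x, ...) {
  cat("<ms_runset> ", length(x$runs), " runs: ",
      paste(names(x$runs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

run_ids <- function(runset) names(runset$runs)

#' Flatten a run to a centroid table
#'
#' @param run an [ms_run()].
#' @return data frame with columns `scan` (index), `rt`, `mz`, `intensity`.
#' @export
run_centroids <- function(run) {
  stopifnot(inherits(run, "ms_run"))
  ns <- vapply(run$scans, function(s) length(s$mz), 0L)
  data.frame(scan = rep(seq_along(run$scans), ns),
             rt = rep(vapply(run$scans, `[[`, 0, "rt"), ns),
             mz = unlist(lapply(run$scans, `[[`, "mz"), use.names = FALSE) %||% numeric(),
             intensity = unlist(lapply(run$scans, `[[`, "intensity"), use.names = FALSE) %||% numeric())
}

scan_times <- function(run) vapply(run$scans, `[[`, 0, "rt")

# median scan spacing in seconds
scan_interval_of <- function(run) {
  rt <- scan_times(run)
  if (length(rt) < 2L) return(1)
  stats::median(diff(rt))
}
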