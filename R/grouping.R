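# Density-based feature grouping: peaks are partitioned into overlapping m/z
# slices; within a slice, a Gaussian kernel density over retention time
# defines candidate groups as the regions under each density maximum
# (delimited by the surrounding minima). Candidates are resolved greedily in
# descending peak-count order so every peak joins at most one group, and
# groups are kept only when enough distinct runs are represented.

#' Grouping parameters
#'
#' @param bw Gaussian kernel density bandwidth over retention time (seconds).
#' @param mzwid width of the m/z slices (Da); slices overlap by 50%.
#' @param minfrac minimum fraction of runs that must be represented (by
#'   distinct run ids, not peak counts) for a group to be kept.
#' @return an object of class `group_params`.
#' @export
group_params <- function(bw = 30, mzwid = 0.025, minfrac = 0.5) {
  assert_scalar_num(bw, "bw", 0, strict = TRUE)
  assert_scalar_num(mzwid, "mzwid", 0, strict = TRUE)
  assert_scalar_num(minfrac, "minfrac", 0, strict = TRUE)
  if (minfrac > 1) stop_isotopt("minfrac must be in (0, 1]")
  structure(list(bw = bw, mzwid = mzwid, minfrac = minfrac),
            class = "group_params")
}

#' Group peaks across runs into features
#'
#' @param peaks a peak table pooling all runs (column `run_id` distinguishes
#'   them), or a named list of per-run peak tables.
#' @param params a [group_params()].
#' @param n_runs the number of runs in the experiment (needed because a run
#'   may contribute no peaks).
#' @return an object of class `feature_groups`: list with `peaks` (the pooled
#'   validated peak table) and `groups` (list of integer row-index vectors,
#'   one per kept group). `as.data.frame()` yields the group summary table.
#' @export
group_density <- function(peaks, params = group_params(), n_runs) {
  stopifnot(inherits(params, "group_params"))
  if (is.list(peaks) && !is.data.frame(peaks))
    peaks <- do.call(rbind, peaks)
  peaks <- validate_peaks(peaks)
  n <- nrow(peaks)
  if (missing(n_runs)) n_runs <- length(unique(peaks$run_id))
  out <- structure(list(peaks = peaks, groups = list(), params = params,
                        n_runs = n_runs), class = "feature_groups")
  if (n == 0L) return(out)

  half <- params$mzwid / 2
  mz0 <- min(peaks$mz)
  k_hi <- floor((peaks$mz - mz0) / half)          # slice starting at k*half
  slice_ids <- sort(unique(c(k_hi, pmax(k_hi - 1L, 0))))
  cands <- list()
  for (k in slice_ids) {
    lo <- mz0 + k * half
    idx <- which(peaks$mz >= lo & peaks$mz < lo + params$mzwid)
    if (!length(idx)) next
    regions <- .density_regions(peaks$rt[idx], params$bw)
    for (r in regions) {
      mem <- idx[peaks$rt[idx] >= r[1] & peaks$rt[idx] < r[2]]
      if (length(mem))
        cands[[length(cands) + 1L]] <- mem
    }
  }
  if (!length(cands)) return(out)
  counts <- lengths(cands)
  mzc <- vapply(cands, function(i) mean(peaks$mz[i]), 0)
  rtc <- vapply(cands, function(i) stats::median(peaks$rt[i]), 0)
  ord <- order(-counts, mzc, rtc)
  assigned <- logical(n)
  groups <- list()
  for (ci in ord) {
    mem <- cands[[ci]][!assigned[cands[[ci]]]]
    if (!length(mem)) next
    n_rep <- length(unique(peaks$run_id[mem]))
    if (n_rep + 1e-9 < params$minfrac * n_runs) next
    assigned[mem] <- TRUE
    groups[[length(groups) + 1L]] <- sort(mem)
  }
  out$groups <- groups
  out
}

# candidate RT regions of one slice: each local density maximum, delimited by
# the surrounding local minima (-Inf / +Inf at the ends)
.density_regions <- function(rt, bw) {
  if (length(rt) == 1L) return(list(c(-Inf, Inf)))
  d <- stats::density(rt, bw = bw, from = min(rt) - 3 * bw,
                      to = max(rt) + 3 * bw, n = 512)
  y <- d$y
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  peaks_at <- which(is_max & y > 0)
  if (length(peaks_at) <= 1L) return(list(c(-Inf, Inf)))
  bounds <- numeric(length(peaks_at) - 1L)
  for (i in seq_along(bounds)) {
    seg <- peaks_at[i]:peaks_at[i + 1L]
    bounds[i] <- d$x[seg[which.min(y[seg])]]
  }
  edges <- c(-Inf, bounds, Inf)
  lapply(seq_along(peaks_at), function(i) c(edges[i], edges[i + 1L]))
}

#' @export
as.data.frame.feature_groups <- function(x, ...) {
  if (!length(x$groups))
    return(data.frame(group_id = integer(), mz_center = numeric(),
                      median_rt = numeric(), n_members = integer(),
                      n_runs = integer()))
  data.frame(
    group_id = seq_along(x$groups),
    mz_center = vapply(x$groups, function(i) mean(x$peaks$mz[i]), 0),
    median_rt = vapply(x$groups, function(i) stats::median(x$peaks$rt[i]), 0),
    n_members = lengths(x$groups),
    n_runs = vapply(x$groups, function(i) length(unique(x$peaks$run_id[i])), 0L))
}

#' @export
print.feature_groups <- function(x, ...) {
  cat("<feature_groups> ", length(x$groups), " groups over ",
      nrow(x$peaks), " peaks from ", x$n_runs, " runs\n", sep = "")
  invisible(x)
}

#' Write / read grouped features as CSV
#'
#' Long format: one row per member peak with its group's id and summary
#' columns (`group_id`, `mz_center`, `median_rt`) followed by the peak
#' columns.
#'
#' @param groups a `feature_groups` object.
#' @param path file path.
#' @param n_runs number of runs for the reconstructed object (default: the
#'   distinct run ids in the file).
#' @return `read_groups_csv` returns a `feature_groups` object.
#' @export
write_groups_csv <- function(groups, path) {
  stopifnot(inherits(groups, "feature_groups"))
  summ <- as.data.frame(groups)
  rows <- lapply(seq_along(groups$groups), function(g) {
    cbind(group_id = g, mz_center = summ$mz_center[g],
          median_rt = summ$median_rt[g],
          groups$peaks[groups$groups[[g]], , drop = FALSE])
  })
  long <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(group_id = integer(), mz_center = numeric(),
                     median_rt = numeric()), .empty_peak_df(), run_id = character())
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_groups_csv
#' @export
read_groups_csv <- function(path, n_runs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$run_id <- as.character(df$run_id)
  for (cl in intersect(setdiff(PEAK_COLUMNS, "run_id"), names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  need <- c("group_id", PEAK_COLUMNS)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_isotopt(path, ": missing column(s): ", paste(missing, collapse = ", "),
                 class = "isotopt_schema_error")
  peaks <- validate_peaks(df[, PEAK_COLUMNS])
  groups <- split(seq_len(nrow(df)), df$group_id)
  names(groups) <- NULL
  structure(list(peaks = peaks, groups = groups, params = NULL,
                 n_runs = n_runs %||% length(unique(peaks$run_id))),
            class = "feature_groups")
}
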