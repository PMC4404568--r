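# Parameterized centWave-style peak picking: ROI detection by chaining
# centroids within a ppm tolerance of the ROI's running mean m/z, then
# chromatographic peak detection inside each ROI with a Mexican-hat
# continuous wavelet transform whose scales span the expected peak width
# range. This is a simplified detector, not an xcms port: the contract is
# that ppm, min/max peakwidth and mzdiff control detection in the documented
# directions.

#' Peak picking parameters
#'
#' @param ppm m/z tolerance for chaining centroids into regions of interest
#'   (parts per million of the ROI's running mean).
#' @param min_peakwidth,max_peakwidth expected chromatographic peak width
#'   range (FWHM, seconds); sets the wavelet scales and the width filter.
#' @param mzdiff minimum m/z difference (Da) for peaks with overlapping
#'   retention times; closer peaks are merged, keeping the more intense.
#'   Values <= 0 disable merging.
#' @param noise intensity floor: a peak's apex must exceed it.
#' @param prefilter_k,prefilter_I ROI prefilter: an ROI is kept only if it
#'   contains at least `prefilter_k` centroids with intensity >=
#'   `prefilter_I`.
#' @return an object of class `pick_params`.
#' @export
pick_params <- function(ppm = 25, min_peakwidth = 20, max_peakwidth = 50,
                        mzdiff = 0.01, noise = 100,
                        prefilter_k = 3, prefilter_I = 100) {
  p <- list(ppm = ppm, min_peakwidth = min_peakwidth,
            max_peakwidth = max_peakwidth, mzdiff = mzdiff, noise = noise,
            prefilter_k = prefilter_k, prefilter_I = prefilter_I)
  problems <- validate_pick_params(p)
  if (length(problems))
    stop_isotopt("invalid peak picking parameters: ",
                 paste(problems, collapse = "; "),
                 class = "isotopt_validation_error")
  structure(p, class = "pick_params")
}

validate_pick_params <- function(p) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(p$ppm) && p$ppm > 0, "ppm must be > 0")
  chk(is.numeric(p$min_peakwidth) && p$min_peakwidth > 0,
      "min_peakwidth must be > 0")
  chk(is.numeric(p$max_peakwidth) && p$min_peakwidth < p$max_peakwidth,
      "min_peakwidth must be < max_peakwidth")
  chk(is.numeric(p$noise) && p$noise >= 0, "noise must be >= 0")
  chk(is.numeric(p$prefilter_k) && p$prefilter_k >= 0,
      "prefilter_k must be >= 0")
  chk(is.numeric(p$prefilter_I) && p$prefilter_I >= 0,
      "prefilter_I must be >= 0")
  problems
}

#' Find regions of interest (ROIs)
#'
#' Chains centroids of consecutive scans whose m/z deviates from the ROI's
#' running mean by at most `ppm`. Within a scan each centroid joins at most
#' one ROI and each ROI accepts at most one centroid (nearest m/z wins); an
#' ROI survives a single scan without a matching centroid. ROIs failing the
#' prefilter (fewer than `prefilter_k` members with intensity >=
#' `prefilter_I`) are dropped.
#'
#' @param run an [ms_run()].
#' @param params a [pick_params()].
#' @return list of ROIs, each a list with `scans` (scan indices), `mz`,
#'   `intensity` (members) and `mz_mean`.
#' @export
find_rois <- function(run, params) {
  stopifnot(inherits(run, "ms_run"), inherits(params, "pick_params"))
  n_scans <- length(run$scans)
  act <- list()      # open ROIs
  done <- list()
  for (s in seq_len(n_scans)) {
    # retire ROIs that missed more than one scan
    if (length(act)) {
      last <- vapply(act, function(r) r$last, 0L)
      retire <- s - last > 2L
      done <- c(done, act[retire])
      act <- act[!retire]
    }
    mz <- run$scans[[s]]$mz
    int <- run$scans[[s]]$intensity
    if (!length(mz)) next
    taken_c <- rep(FALSE, length(mz))
    if (length(act)) {
      means <- vapply(act, function(r) r$mean, 0)
      d <- abs(outer(mz, means, "-"))
      tol <- matrix(params$ppm * 1e-6 * rep(means, each = length(mz)),
                    nrow = length(mz))
      qual <- which(d <= tol, arr.ind = TRUE)
      if (nrow(qual)) {
        qual <- qual[order(d[qual]), , drop = FALSE]
        taken_r <- rep(FALSE, length(act))
        for (q in seq_len(nrow(qual))) {
          ci <- qual[q, 1]; ri <- qual[q, 2]
          if (taken_c[ci] || taken_r[ri]) next
          taken_c[ci] <- TRUE; taken_r[ri] <- TRUE
          r <- act[[ri]]
          r$scans <- c(r$scans, s); r$mz <- c(r$mz, mz[ci])
          r$intensity <- c(r$intensity, int[ci])
          r$mean <- mean(r$mz); r$last <- s
          act[[ri]] <- r
        }
      }
    }
    for (ci in which(!taken_c)) {
      act[[length(act) + 1L]] <- list(scans = s, mz = mz[ci],
                                      intensity = int[ci],
                                      mean = mz[ci], last = s)
    }
  }
  done <- c(done, act)
  keep <- vapply(done, function(r)
    sum(r$intensity >= params$prefilter_I) >= params$prefilter_k, TRUE)
  lapply(done[keep], function(r)
    list(scans = r$scans, mz = r$mz, intensity = r$intensity,
         mz_mean = r$mean, scan_range = range(r$scans)))
}

# Mexican-hat (Ricker) kernel at scale a (in scans), unit L2 norm
.ricker <- function(a) {
  t <- seq(-ceiling(5 * a), ceiling(5 * a))
  k <- (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
  k / sqrt(sum(k^2))
}

.cwt_scales <- function(params, si) {
  fwhm_to_sigma <- 2 * sqrt(2 * log(2))
  sec <- exp(seq(log(params$min_peakwidth), log(params$max_peakwidth),
                 length.out = 10))
  pmax(sec / fwhm_to_sigma / si, 1)
}

#' Detect chromatographic peaks within one ROI
#'
#' The ROI's intensity trace is transformed with Mexican-hat wavelets over 10
#' logarithmically spaced scales spanning the peak width range; local maxima
#' of the scale-maximized transform with apex intensity above `noise` become
#' peaks. Peak boundaries come from intensity descent to the surrounding
#' minima; a peak is rejected when its measured FWHM falls outside
#' `[min_peakwidth, max_peakwidth]`.
#'
#' @param roi one ROI from [find_rois()].
#' @param run the [ms_run()] the ROI came from.
#' @param params a [pick_params()].
#' @return a peak data frame (without `run_id`).
#' @export
detect_peaks_in_roi <- function(roi, run, params) {
  st <- scan_times(run)
  si <- scan_interval_of(run)
  s0 <- roi$scan_range[1]; s1 <- roi$scan_range[2]
  len <- s1 - s0 + 1L
  trace <- numeric(len)
  trace[roi$scans - s0 + 1L] <- roi$intensity
  if (all(trace <= 0)) return(.empty_peak_df())
  scales <- .cwt_scales(params, si)
  pad <- as.integer(ceiling(5 * max(scales))) + 1L
  x <- c(numeric(pad), trace, numeric(pad))
  env <- rep(-Inf, len)
  best_scale <- numeric(len)
  for (a in scales) {
    k <- .ricker(a)
    h <- (length(k) - 1L) %/% 2L
    cw <- stats::filter(x, k, method = "convolution", sides = 2)
    cw <- as.numeric(cw[(pad + 1L):(pad + len)])
    upd <- !is.na(cw) & cw > env
    env[upd] <- cw[upd]
    best_scale[upd] <- a
  }
  w <- max(1L, as.integer(round(min(scales))))
  cand <- integer(0)
  for (i in seq_len(len)) {
    if (!is.finite(env[i]) || env[i] <= 0) next
    lo <- max(1L, i - w); hi <- min(len, i + w)
    if (env[i] == max(env[lo:hi])) cand <- c(cand, i)
  }
  if (!length(cand)) return(.empty_peak_df())
  peaks <- list()
  used_apex <- integer(0)
  for (i in cand) {
    r <- max(1L, as.integer(round(best_scale[i])))
    lo <- max(1L, i - r); hi <- min(len, i + r)
    apex <- lo + which.max(trace[lo:hi]) - 1L
    if (apex %in% used_apex) next
    if (trace[apex] <= params$noise) next
    used_apex <- c(used_apex, apex)
    # descend to boundaries
    lb <- apex
    while (lb > 1L && trace[lb - 1L] < trace[lb] && trace[lb - 1L] > 0) lb <- lb - 1L
    ub <- apex
    while (ub < len && trace[ub + 1L] < trace[ub] && trace[ub + 1L] > 0) ub <- ub + 1L
    fw <- .measured_fwhm(trace, apex, lb, ub, st, s0, si)
    if (fw < params$min_peakwidth || fw > params$max_peakwidth) next
    in_rt <- roi$scans >= s0 + lb - 1L & roi$scans <= s0 + ub - 1L
    if (!any(in_rt)) next
    mzs <- roi$mz[in_rt]; wts <- roi$intensity[in_rt]
    mz_apex <- clamp(stats::weighted.mean(mzs, wts), min(mzs), max(mzs))
    peaks[[length(peaks) + 1L]] <- data.frame(
      mz = mz_apex, mzmin = min(mzs), mzmax = max(mzs),
      rt = st[s0 + apex - 1L], rtmin = st[s0 + lb - 1L],
      rtmax = st[s0 + ub - 1L], intensity = trace[apex])
  }
  if (!length(peaks)) return(.empty_peak_df())
  do.call(rbind, peaks)
}

# FWHM measured from the trace by interpolated half-maximum crossings;
# falls back to 60% of the boundary extent when a flank never crosses.
.measured_fwhm <- function(trace, apex, lb, ub, st, s0, si) {
  half <- trace[apex] / 2
  left <- NA_real_
  if (lb < apex) {
    below <- which(trace[lb:apex] < half)
    if (length(below)) {
      j <- lb + max(below) - 1L          # last point below half on the left
      frac <- (half - trace[j]) / (trace[j + 1L] - trace[j])
      left <- st[s0 + j - 1L] + frac * si
    }
  }
  right <- NA_real_
  if (ub > apex) {
    below <- which(trace[apex:ub] < half)
    if (length(below)) {
      j <- apex + min(below) - 1L        # first point below half on the right
      frac <- (trace[j - 1L] - half) / (trace[j - 1L] - trace[j])
      right <- st[s0 + j - 2L] + frac * si
    }
  }
  if (is.na(left) || is.na(right))
    return((st[s0 + ub - 1L] - st[s0 + lb - 1L]) * 0.6)
  right - left
}

.empty_peak_df <- function() {
  data.frame(mz = numeric(), mzmin = numeric(), mzmax = numeric(),
             rt = numeric(), rtmin = numeric(), rtmax = numeric(),
             intensity = numeric())
}

#' Pick chromatographic peaks in a run
#'
#' ROI detection, in-ROI wavelet peak detection, and an mzdiff post-filter:
#' among peaks with overlapping RT extents whose m/z differ by less than
#' `mzdiff`, only the most intense survives. Deterministic for fixed input.
#'
#' @param run an [ms_run()].
#' @param params a [pick_params()], or a named list of parameter values.
#' @return a validated peak table with `run_id` taken from the run.
#' @export
pick_peaks <- function(run, params = pick_params()) {
  stopifnot(inherits(run, "ms_run"))
  if (!inherits(params, "pick_params")) params <- do.call(pick_params, params)
  rois <- find_rois(run, params)
  pk <- do.call(rbind, c(list(.empty_peak_df()),
                         lapply(rois, detect_peaks_in_roi, run = run,
                                params = params)))
  if (nrow(pk) && params$mzdiff > 0) {
    ord <- order(-pk$intensity, pk$mz, pk$rt)
    pk <- pk[ord, , drop = FALSE]
    keep <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      ks <- which(keep)
      clash <- length(ks) && any(
        pk$rtmin[ks] <= pk$rtmax[i] & pk$rtmax[ks] >= pk$rtmin[i] &
          abs(pk$mz[ks] - pk$mz[i]) < params$mzdiff)
      keep[i] <- !clash
    }
    pk <- pk[keep, , drop = FALSE]
  }
  pk <- pk[order(pk$mz, pk$rt), , drop = FALSE]
  pk <- cbind(run_id = rep(run$run_id, nrow(pk)), pk)
  validate_peaks(pk)
}
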