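# Synthetic pooled-sample LC-MS generator with known ground truth.
#
# Emulates what the scoring framework exploits in real data: every compound
# elutes as a Gaussian chromatographic peak and carries a 13C M+1
# isotopologue trace at +1.0033548 Da whose intensity is n_carbons * IA times
# the parent trace (first-order binomial at natural abundance). Injections of
# the same pooled sample differ by a smooth RT drift (linear + sinusoid) and
# optional dropouts; centroid m/z values carry ppm-scale jitter and random
# noise centroids are sprinkled over the scans.

#' Configuration of the synthetic run-set generator
#'
#' Defaults describe a small pooled-sample series: 4 injections of 30
#' compounds over a 7-minute gradient, chromatographic FWHM 20 s (+-25%),
#' 30 s retention time drift, 2 ppm centroid jitter and 2 noise centroids per
#' scan.
#'
#' @param n_compounds number of compounds.
#' @param mz_range,rt_range,fwhm_range,log10_intensity_range closed intervals
#'   for compound m/z (Da), base retention time (s), chromatographic FWHM (s)
#'   and log10 apex intensity.
#' @param carbon_model function mapping a compound m/z to its carbon count;
#'   the default is the hydrocarbon-like heuristic
#'   `round(mz * 0.7 / 14)` clamped to `[1, max_carbons(mz)]`.
#' @param isotope_abundance natural 13C abundance (fraction).
#' @param scan_interval spacing of the scan grid (s).
#' @param mz_jitter_ppm standard deviation of centroid m/z jitter (ppm).
#' @param noise_peak_rate expected number of random noise centroids per scan
#'   (Poisson).
#' @param n_injections number of injections of the pooled sample.
#' @param rt_drift_amplitude maximal per-injection RT drift (s).
#' @param dropout_prob probability that a compound is absent from one
#'   injection.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 30,
                             mz_range = c(100, 600),
                             rt_range = c(0, 420),
                             fwhm_range = c(15, 25),
                             log10_intensity_range = c(5, 6.5),
                             carbon_model = NULL,
                             isotope_abundance = 0.01108,
                             scan_interval = 1,
                             mz_jitter_ppm = 2,
                             noise_peak_rate = 2,
                             n_injections = 4,
                             rt_drift_amplitude = 30,
                             dropout_prob = 0,
                             seed = 42) {
  cfg <- list(n_compounds = n_compounds, mz_range = mz_range,
              rt_range = rt_range, fwhm_range = fwhm_range,
              log10_intensity_range = log10_intensity_range,
              carbon_model = carbon_model %||% default_carbon_model,
              isotope_abundance = isotope_abundance,
              scan_interval = scan_interval, mz_jitter_ppm = mz_jitter_ppm,
              noise_peak_rate = noise_peak_rate, n_injections = n_injections,
              rt_drift_amplitude = rt_drift_amplitude,
              dropout_prob = dropout_prob, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

default_carbon_model <- function(mz) {
  pmax(1L, pmin(max_carbons(mz), as.integer(round(mz * 0.7 / 14.015650))))
}

validate_synthetic_config <- function(cfg) {
  for (rng in c("mz_range", "rt_range", "fwhm_range", "log10_intensity_range")) {
    v <- cfg[[rng]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v) || v[1] > v[2])
      stop_isotopt(rng, " must be a nonempty interval c(lo, hi)")
  }
  assert_scalar_num(cfg$n_compounds, "n_compounds", 0)
  assert_scalar_num(cfg$n_injections, "n_injections", 1)
  assert_scalar_num(cfg$isotope_abundance, "isotope_abundance", 0)
  if (cfg$isotope_abundance >= 1) stop_isotopt("isotope_abundance must be < 1")
  assert_scalar_num(cfg$scan_interval, "scan_interval", 0, strict = TRUE)
  assert_scalar_num(cfg$mz_jitter_ppm, "mz_jitter_ppm", 0)
  assert_scalar_num(cfg$noise_peak_rate, "noise_peak_rate", 0)
  assert_scalar_num(cfg$rt_drift_amplitude, "rt_drift_amplitude", 0)
  assert_scalar_num(cfg$dropout_prob, "dropout_prob", 0)
  if (cfg$dropout_prob >= 1) stop_isotopt("dropout_prob must be < 1")
  if (!is.function(cfg$carbon_model)) stop_isotopt("carbon_model must be a function")
  invisible(cfg)
}

#' Generate a synthetic pooled-sample run set with ground truth
#'
#' Each compound yields a Gaussian elution profile sampled on the scan grid,
#' a parent ion trace and an M+1 trace offset by +1.0033548 Da with relative
#' intensity `n_carbons * IA` (exact in the noiseless limit). Injections
#' share the compound set but apply a per-run smooth drift to all retention
#' times. Compounds are drawn with a minimum separation (either resolved in
#' RT or > 0.3 Da apart, isotopologue positions included) so that the ground
#' truth stays unambiguous.
#'
#' @param config a [synthetic_config()].
#' @return list with `runset` (an [ms_runset()]) and `truth`, a data frame
#'   with one row per compound and injection: `compound`, `injection`,
#'   `run_id`, `mz`, `n_carbons`, `rt_true` (drifted apex), `fwhm`,
#'   `parent_intensity`, `iso_intensity`, `dropout`.
#' @export
generate_runset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  with_seed(config$seed, .generate_runset(config))
}

.generate_runset <- function(cfg) {
  si <- cfg$scan_interval
  scan_rt <- seq(cfg$rt_range[1], cfg$rt_range[2], by = si)
  n_scans <- length(scan_rt)
  sigma_max <- max(cfg$fwhm_range) / (2 * sqrt(2 * log(2)))
  margin <- cfg$rt_drift_amplitude + 4 * sigma_max
  rt_lo <- cfg$rt_range[1] + margin
  rt_hi <- cfg$rt_range[2] - margin
  if (cfg$n_compounds > 0 && rt_lo >= rt_hi)
    stop_isotopt("rt_range too narrow for the drift amplitude and peak width ",
                 "(usable window is empty)")

  # --- draw compounds with minimum separation -------------------------------
  n <- cfg$n_compounds
  mz <- rt0 <- fwhm <- inten <- numeric(0)
  nc <- integer(0)
  tries <- 0L
  while (length(mz) < n) {
    tries <- tries + 1L
    if (tries > 1000L * max(n, 1L))
      stop_isotopt("could not place ", n, " separated compounds; ",
                   "widen mz_range/rt_range or lower n_compounds")
    m <- stats::runif(1, cfg$mz_range[1], cfg$mz_range[2])
    r <- stats::runif(1, rt_lo, rt_hi)
    f <- stats::runif(1, cfg$fwhm_range[1], cfg$fwhm_range[2])
    sep_rt <- abs(r - rt0) > 2 * max(cfg$fwhm_range)
    dmz <- c(abs(m - mz), abs(m - (mz + .C13_C12_DELTA)),
             abs((m + .C13_C12_DELTA) - mz))
    sep_mz <- if (length(mz)) {
      apply(matrix(dmz, nrow = length(mz)), 1, min) > 0.3
    } else logical(0)
    if (all(sep_rt | sep_mz)) {
      k <- cfg$carbon_model(m)
      if (is.na(k) || k < 1)
        stop_isotopt("carbon_model returned an invalid count for mz ", m)
      if (k > max_carbons(m))
        stop_isotopt("carbon_model gives ", k, " carbons at mz ",
                     signif(m, 8), " but at most ", max_carbons(m),
                     " fit a hydrocarbon of that mass")
      mz <- c(mz, m); rt0 <- c(rt0, r); fwhm <- c(fwhm, f)
      inten <- c(inten, 10^stats::runif(1, cfg$log10_intensity_range[1],
                                        cfg$log10_intensity_range[2]))
      nc <- c(nc, as.integer(k))
    }
  }

  # --- per-injection drift, dropout, signal synthesis -----------------------
  span <- diff(cfg$rt_range)
  runs <- vector("list", cfg$n_injections)
  truth <- vector("list", cfg$n_injections)
  for (j in seq_len(cfg$n_injections)) {
    a <- stats::runif(1, -1, 1)
    b <- stats::runif(1, -1, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- function(t) {
      u <- (t - cfg$rt_range[1]) / max(span, 1e-9)
      cfg$rt_drift_amplitude * 0.5 * (a * u + b * sin(pi * u + phase))
    }
    dropout <- if (n > 0) stats::runif(n) < cfg$dropout_prob else logical(0)
    rt_true <- rt0 + drift(rt0)
    run_id <- sprintf("injection_%02d", j)

    cmz <- cint <- numeric(0)
    cscan <- integer(0)
    sqrt2l2 <- 2 * sqrt(2 * log(2))
    for (c in seq_len(n)) {
      if (dropout[c]) next
      sigma <- fwhm[c] / sqrt2l2
      win <- which(abs(scan_rt - rt_true[c]) <= 4.5 * sigma)
      if (!length(win)) next
      prof <- inten[c] * exp(-(scan_rt[win] - rt_true[c])^2 / (2 * sigma^2))
      keep <- prof >= 1
      if (!any(keep)) next
      win <- win[keep]; prof <- prof[keep]
      iso <- prof * nc[c] * cfg$isotope_abundance
      cscan <- c(cscan, win, win)
      cmz <- c(cmz, rep(mz[c], length(win)),
               rep(mz[c] + .C13_C12_DELTA, length(win)))
      cint <- c(cint, prof, iso)
    }
    # noise centroids
    if (cfg$noise_peak_rate > 0 && n_scans > 0) {
      n_noise <- stats::rpois(n_scans, cfg$noise_peak_rate)
      tot <- sum(n_noise)
      if (tot > 0) {
        cscan <- c(cscan, rep(seq_len(n_scans), n_noise))
        cmz <- c(cmz, stats::runif(tot, cfg$mz_range[1], cfg$mz_range[2]))
        cint <- c(cint, 10^stats::runif(tot, 3, 4.7))
      }
    }
    # m/z jitter (applied to every centroid, ppm scale)
    if (cfg$mz_jitter_ppm > 0 && length(cmz)) {
      cmz <- cmz * (1 + stats::rnorm(length(cmz), 0, cfg$mz_jitter_ppm * 1e-6))
    }
    scans <- .assemble_scans(scan_rt, cscan, cmz, cint)
    runs[[j]] <- ms_run(run_id, scans)
    truth[[j]] <- data.frame(
      compound = seq_len(n), injection = rep(j, n),
      run_id = rep(run_id, n), mz = mz, n_carbons = nc, rt_true = rt_true,
      fwhm = fwhm, parent_intensity = inten,
      iso_intensity = inten * nc * cfg$isotope_abundance, dropout = dropout)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(runset = ms_runset(runs), truth = truth)
}

.assemble_scans <- function(scan_rt, cscan, cmz, cint) {
  lapply(seq_along(scan_rt), function(s) {
    sel <- cscan == s
    m <- cmz[sel]; i <- cint[sel]
    if (length(m)) {
      ord <- order(m); m <- m[ord]; i <- i[ord]
      if (length(m) > 1L && any(diff(m) == 0)) {   # coincident sticks merge
        grp <- cumsum(c(1, diff(m) != 0))
        i <- as.numeric(rowsum(i, grp))
        m <- m[!duplicated(grp)]
      }
    }
    list(rt = scan_rt[s], mz = m, intensity = i)
  })
}

#' Count the ion traces expected detectable at an intensity floor
#'
#' A trace is one (compound, parent-or-isotopologue) ion chromatogram. With
#' `per_injection = TRUE`, counts for each injection the traces present
#' (not dropped) whose apex intensity is at least `floor`. The default scalar
#' counts the traces detectable in every injection — the expected number of
#' complete ("reliable") feature groups.
#'
#' @param truth the truth table from [generate_runset()].
#' @param floor intensity floor (apex counts).
#' @param per_injection return a per-injection vector instead of the scalar.
#' @return integer count, or named integer vector.
#' @export
truth_feature_count <- function(truth, floor = 0, per_injection = FALSE) {
  stopifnot(is.data.frame(truth))
  if (per_injection) {
    counts <- vapply(split(truth, truth$injection), function(tr) {
      sum(!tr$dropout & tr$parent_intensity >= floor) +
        sum(!tr$dropout & tr$iso_intensity >= floor)
    }, 0L)
    return(counts)
  }
  by_cmp <- split(truth, truth$compound)
  sum(vapply(by_cmp, function(tr) {
    if (any(tr$dropout)) return(0L)
    sum(min(tr$parent_intensity) >= floor, min(tr$iso_intensity) >= floor)
  }, 0L))
}
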