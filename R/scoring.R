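# Target values for the optimization: PPS (peak picking), RCS (retention time
# correction), GS (grouping) and their per-round combination RGTV.

# exact masses (Da)
.C13_C12_DELTA <- 1.0033548
.CH2_MASS <- 14.015650
.CH3_MASS <- 15.023475
.C13_ABUNDANCE <- 0.01108

#' Maximum number of carbon atoms compatible with an m/z
#'
#' Upper bound on the carbon count of a singly charged ion of mass-to-charge
#' ratio `mz`, assuming a saturated hydrocarbon chain: the two terminal CH3
#' groups are subtracted, the remainder is divided into CH2 units, and the two
#' terminal carbons are added back:
#' `maxC = floor((mz - 2*CH3) / CH2) + 2`.
#' Used to bound the intensity window of a candidate 13C isotopologue peak.
#'
#' @param mz numeric vector of mass-to-charge ratios (Da, charge 1).
#' @return integer vector; 0 where `mz` is below the mass of two CH3 groups
#'   (no hydrocarbon of that mass exists).
#' @examples
#' max_carbons(c(100, 200))
#' @export
max_carbons <- function(mz) {
  if (!is.numeric(mz)) stop_isotopt("mz must be numeric")
  out <- integer(length(mz))
  ok <- is.finite(mz) & mz >= 2 * .CH3_MASS
  out[ok] <- as.integer(floor((mz[ok] - 2 * .CH3_MASS) / .CH2_MASS)) + 2L
  out[!is.finite(mz)] <- NA_integer_
  out
}

#' Criteria for recognizing a 13C isotopologue pair
#'
#' A candidate peak q is accepted as the M+1 isotopologue of a parent peak p
#' when all three criteria hold:
#' \enumerate{
#'   \item mass: `|q.mz - (p.mz + iso_mass_delta)| <= mass_tol_ppm * p.mz * 1e-6`;
#'   \item co-elution: the RT extents of p and q overlap and
#'     `|q.rt - p.rt| <= rt_window_frac * (p.rtmax - p.rtmin)`;
#'   \item intensity: `q.intensity` lies in
#'     `[IA * p.intensity / (1 + slack), maxC(p.mz) * IA * p.intensity * (1 + slack)]`,
#'     i.e. between the expectation for one carbon and for the maximum
#'     hydrocarbon carbon count.
#' }
#'
#' @param iso_mass_delta mass difference 13C - 12C in Da.
#' @param mass_tol_ppm tolerance on the isotopologue position, ppm of the
#'   parent m/z.
#' @param rt_window_frac co-elution window as a fraction of the parent peak's
#'   RT extent.
#' @param intensity_slack multiplicative slack on the intensity window
#'   (0 = exact natural-abundance window).
#' @param isotope_abundance natural 13C abundance (fraction).
#' @return an object of class `iso_criteria`.
#' @export
iso_criteria <- function(iso_mass_delta = .C13_C12_DELTA,
                         mass_tol_ppm = 10,
                         rt_window_frac = 0.5,
                         intensity_slack = 0,
                         isotope_abundance = .C13_ABUNDANCE) {
  assert_scalar_num(iso_mass_delta, "iso_mass_delta", 0, strict = TRUE)
  assert_scalar_num(mass_tol_ppm, "mass_tol_ppm", 0, strict = TRUE)
  assert_scalar_num(rt_window_frac, "rt_window_frac", 0, strict = TRUE)
  assert_scalar_num(intensity_slack, "intensity_slack", 0)
  assert_scalar_num(isotope_abundance, "isotope_abundance", 0, strict = TRUE)
  if (isotope_abundance >= 1) stop_isotopt("isotope_abundance must be < 1")
  structure(list(iso_mass_delta = iso_mass_delta,
                 mass_tol_ppm = mass_tol_ppm,
                 rt_window_frac = rt_window_frac,
                 intensity_slack = intensity_slack,
                 isotope_abundance = isotope_abundance),
            class = "iso_criteria")
}

#' Label reliable peaks (RPs) by isotopologue detection
#'
#' Scans a one-run peak table for parent/M+1 pairs satisfying all three
#' criteria of [iso_criteria()]. Both members of every passing pair are
#' labeled `"RP"` (a reliable peak is one that belongs to an isotopologue).
#'
#' @param peaks a peak data frame (see [validate_peaks()]), one run.
#' @param criteria an [iso_criteria()] object.
#' @return an object of class `peak_classification`: list with `label`
#'   (character, one of `"RP"`, `"LIP"`, `"UNRELIABLE"` per peak — `"LIP"`
#'   only after [classify_lip()]) and `partners` (list of integer vectors:
#'   for each RP, the row indices of its isotopologue partners).
#' @export
find_isotopologues <- function(peaks, criteria = iso_criteria()) {
  stopifnot(inherits(criteria, "iso_criteria"))
  peaks <- validate_peaks(peaks)
  n <- nrow(peaks)
  label <- rep("UNRELIABLE", n)
  partners <- vector("list", n)
  if (n >= 2L) {
    ord <- order(peaks$mz)
    mz_sorted <- peaks$mz[ord]
    for (i in seq_len(n)) {
      target <- peaks$mz[i] + criteria$iso_mass_delta
      tol <- criteria$mass_tol_ppm * peaks$mz[i] * 1e-6
      lo <- findInterval(target - tol, mz_sorted) + 1L
      hi <- findInterval(target + tol, mz_sorted)
      if (hi < lo) next
      js <- ord[lo:hi]
      js <- js[js != i]
      if (!length(js)) next
      ok <- .iso_pair_ok(peaks, i, js, criteria)
      js <- js[ok]
      if (length(js)) {
        label[i] <- "RP"
        label[js] <- "RP"
        partners[[i]] <- sort(unique(c(partners[[i]], js)))
        for (j in js) partners[[j]] <- sort(unique(c(partners[[j]], i)))
      }
    }
  }
  structure(list(label = label, partners = partners), class = "peak_classification")
}

# vectorized evaluation of criteria 2 and 3 for parent i against candidates js
.iso_pair_ok <- function(peaks, i, js, criteria) {
  p_rt <- peaks$rt[i]; p_lo <- peaks$rtmin[i]; p_hi <- peaks$rtmax[i]
  width <- p_hi - p_lo
  overlap <- peaks$rtmax[js] >= p_lo & peaks$rtmin[js] <= p_hi
  close_rt <- abs(peaks$rt[js] - p_rt) <= criteria$rt_window_frac * width
  ia <- criteria$isotope_abundance
  slack <- criteria$intensity_slack
  lo_i <- ia * peaks$intensity[i] / (1 + slack)
  hi_i <- max_carbons(peaks$mz[i]) * ia * peaks$intensity[i] * (1 + slack)
  in_window <- peaks$intensity[js] >= lo_i & peaks$intensity[js] <= hi_i
  overlap & close_rt & in_window
}

#' Label low intensity peaks (LIPs)
#'
#' Peaks whose best-case isotopologue signal would fall below the estimated
#' instrument sensitivity are neither reliable nor unreliable: they are
#' excluded from the PPS denominator. The sensitivity cut-off is the mean of
#' the lowest 3 percent of all peak intensities (at least one value). A
#' non-RP peak becomes LIP when `intensity * maxC(mz) * IA` is strictly below
#' that cut-off; RPs are never relabeled.
#'
#' @inheritParams find_isotopologues
#' @param classification result of [find_isotopologues()].
#' @return the updated `peak_classification`, with the cut-off stored as
#'   attribute `"lip_cutoff"`.
#' @export
classify_lip <- function(peaks, classification, criteria = iso_criteria()) {
  stopifnot(inherits(classification, "peak_classification"))
  peaks <- validate_peaks(peaks)
  n <- nrow(peaks)
  if (n != length(classification$label))
    stop_isotopt("classification does not match the peak table (",
                 length(classification$label), " labels vs ", n, " peaks)")
  if (n == 0L) return(classification)
  k <- max(1L, ceiling(0.03 * n))
  cutoff <- mean(sort(peaks$intensity)[seq_len(k)])
  predicted <- peaks$intensity * max_carbons(peaks$mz) * criteria$isotope_abundance
  lip <- classification$label != "RP" & predicted < cutoff
  classification$label[lip] <- "LIP"
  attr(classification, "lip_cutoff") <- cutoff
  classification
}

#' Peak picking score (PPS)
#'
#' `PPS = RP^2 / (n_peaks - LIP)`: the squared number of reliable peaks over
#' the number of all peaks diminished by the low intensity peaks. Squaring RP
#' creates an optimization force towards recall: if RP and the total count
#' grow by the same amount, PPS increases. Degenerate cases (no RPs, or a
#' non-positive denominator) score 0.
#'
#' @param x either a `peak_classification` (or a list of them, whose counts
#'   are pooled) or the RP count.
#' @param n_peaks,n_lip total and LIP counts when `x` is given as a count.
#' @return a single nonnegative number.
#' @examples
#' compute_pps(4, 10, 2) # 2
#' @export
compute_pps <- function(x, n_peaks = NULL, n_lip = NULL) {
  if (inherits(x, "peak_classification")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "peak_classification"))) {
    labs <- unlist(lapply(x, `[[`, "label"))
    n_rp <- sum(labs == "RP")
    n_peaks <- length(labs)
    n_lip <- sum(labs == "LIP")
  } else {
    n_rp <- x
    stopifnot(is.numeric(n_rp), is.numeric(n_peaks), is.numeric(n_lip))
  }
  n_rp <- as.numeric(n_rp)
  denom <- as.numeric(n_peaks) - as.numeric(n_lip)
  if (n_rp <= 0 || denom <= 0) return(0)
  n_rp^2 / denom
}

#' Score the peak picking of a run set
#'
#' Runs isotopologue detection and LIP classification per run, pools the
#' counts over runs, and applies the PPS formula once to the pooled counts.
#'
#' @param peaklists named list of per-run peak data frames.
#' @param criteria an [iso_criteria()] object.
#' @return list with `n_peaks`, `n_rp`, `n_lip`, `pps` and a `per_run` data
#'   frame of the same counts.
#' @export
score_peak_picking <- function(peaklists, criteria = iso_criteria()) {
  stopifnot(is.list(peaklists), length(peaklists) >= 1L)
  per <- lapply(peaklists, function(pk) {
    cl <- classify_lip(pk, find_isotopologues(pk, criteria), criteria)
    c(n_peaks = length(cl$label),
      n_rp = sum(cl$label == "RP"),
      n_lip = sum(cl$label == "LIP"))
  })
  per_run <- as.data.frame(do.call(rbind, per))
  per_run$run_id <- names(peaklists) %||% as.character(seq_along(peaklists))
  tot <- colSums(per_run[, c("n_peaks", "n_rp", "n_lip")])
  list(n_peaks = unname(tot["n_peaks"]), n_rp = unname(tot["n_rp"]),
       n_lip = unname(tot["n_lip"]),
       pps = compute_pps(tot["n_rp"], tot["n_peaks"], tot["n_lip"]),
       per_run = per_run)
}

#' Group retention time shift (GRTS)
#'
#' Mean absolute deviation of the member retention times of one feature group
#' from their median.
#'
#' @param rts numeric vector of member retention times (seconds).
#' @return GRTS in seconds.
#' @examples
#' compute_grts(c(9, 10, 11)) # 2/3
#' @export
compute_grts <- function(rts) {
  if (!is.numeric(rts) || length(rts) == 0L)
    stop_isotopt("a group must contain at least one retention time")
  mean(abs(stats::median(rts) - rts))
}

#' Retention time correction score (RCS)
#'
#' ARTS is the mean of the per-group GRTS values; RCS is its inverse, so that
#' better-aligned data score higher. Perfect alignment (ARTS = 0) yields
#' `RCS = Inf`, a sentinel that [compute_rgtv()] maps to the round's maximum.
#' Zero groups yield RCS 0 with a warning.
#'
#' @param grts numeric vector of per-group GRTS values (seconds).
#' @return list with `arts` (seconds) and `rcs` (1/seconds).
#' @export
compute_rcs <- function(grts) {
  if (length(grts) == 0L) {
    warning("no feature groups: RCS undefined, reporting 0")
    return(list(arts = NA_real_, rcs = 0))
  }
  arts <- mean(grts)
  list(arts = arts, rcs = if (arts == 0) Inf else 1 / arts)
}

#' Classify feature groups as reliable or non-reliable
#'
#' A reliable group shows exactly one peak from each injection of the pooled
#' sample: exactly `n_runs` members and each run represented exactly once.
#' Every other group is non-reliable.
#'
#' @param groups a `feature_groups` object (see [group_density()]) or a list
#'   of character vectors of member run ids.
#' @param n_runs number of injections in the run set.
#' @return list with `n_reliable`, `n_nonreliable` and logical `reliable` per
#'   group.
#' @export
classify_groups <- function(groups, n_runs) {
  run_sets <- if (inherits(groups, "feature_groups")) {
    lapply(groups$groups, function(idx) groups$peaks$run_id[idx])
  } else groups
  stopifnot(is.list(run_sets))
  reliable <- vapply(run_sets, function(r) {
    length(r) == n_runs && !anyDuplicated(r) && length(unique(r)) == n_runs
  }, TRUE)
  list(n_reliable = sum(reliable), n_nonreliable = sum(!reliable),
       reliable = reliable)
}

#' Grouping score (GS)
#'
#' `GS = n_reliable^2 / n_nonreliable`. When no non-reliable group exists the
#' denominator is treated as 1, so a perfect grouping scores `n_reliable^2`.
#'
#' @param n_reliable,n_nonreliable nonnegative counts.
#' @return a single nonnegative number.
#' @examples
#' compute_gs(10, 4) # 25
#' @export
compute_gs <- function(n_reliable, n_nonreliable) {
  stopifnot(n_reliable >= 0, n_nonreliable >= 0)
  if (n_reliable == 0) return(0)
  n_reliable^2 / max(n_nonreliable, 1)
}

# unity-based normalization over the experiments of one DoE round;
# Inf sentinels (perfect alignment) are pinned to the round's maximum,
# a constant score normalizes to 0.5 everywhere.
unity_normalize <- function(v) {
  stopifnot(is.numeric(v))
  out <- v
  fin <- is.finite(v)
  if (!any(fin)) return(rep(0.5, length(v)))
  out[!fin & v > 0] <- max(v[fin])
  out[!fin & v < 0] <- min(v[fin])
  rng <- range(out)
  if (diff(rng) == 0) return(rep(0.5, length(v)))
  (out - rng[1]) / diff(rng)
}

#' Combined retention time correction and grouping target value (RGTV)
#'
#' Per experiment of one DoE round, `RGTV = norm(RCS) + norm(GS)` where
#' `norm` is the unity-based normalization over all experiments of the round
#' (values scaled to \[0, 1\]). RGTV is therefore only comparable within one
#' round. A score that is constant across the round contributes 0.5
#' everywhere; `Inf` RCS sentinels are mapped to the round maximum before
#' normalizing.
#'
#' @param rcs_values,gs_values numeric vectors of equal length (>= 2), one
#'   value per experiment of the round.
#' @return numeric vector of RGTV values in \[0, 2\].
#' @examples
#' compute_rgtv(c(1, 2, 3), c(30, 10, 20)) # 1.0 0.5 1.5
#' @export
compute_rgtv <- function(rcs_values, gs_values) {
  if (length(rcs_values) != length(gs_values))
    stop_isotopt("rcs_values and gs_values must have the same length (got ",
                 length(rcs_values), " and ", length(gs_values), ")")
  if (length(rcs_values) < 2L)
    stop_isotopt("RGTV normalization needs at least 2 experiments per round")
  unity_normalize(rcs_values) + unity_normalize(gs_values)
}

#' Score alignment and grouping of a run set
#'
#' Computes per-group GRTS, ARTS, RCS, the reliable/non-reliable counts and
#' GS for one grouping result.
#'
#' @param groups a `feature_groups` object.
#' @param n_runs number of injections.
#' @return list with `grts`, `arts`, `rcs`, `n_reliable`, `n_nonreliable`,
#'   `gs`, `n_groups`.
#' @export
score_alignment <- function(groups, n_runs) {
  stopifnot(inherits(groups, "feature_groups"))
  grts <- vapply(groups$groups,
                 function(idx) compute_grts(groups$peaks$rt[idx]), 0)
  rc <- compute_rcs(grts)
  cl <- classify_groups(groups, n_runs)
  list(grts = grts, arts = rc$arts, rcs = rc$rcs,
       n_reliable = cl$n_reliable, n_nonreliable = cl$n_nonreliable,
       gs = compute_gs(cl$n_reliable, cl$n_nonreliable),
       n_groups = length(grts))
}
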