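# Retention time alignment in the spirit of obiwarp: runs are binned into
# m/z profiles, scan-by-scan Pearson similarities are computed between a run
# and the center run, and an affine-gap dynamic program extracts the optimal
# monotone correspondence of scans. The resulting warp rewrites peak
# retention times onto the center run's time axis.

#' Alignment parameters
#'
#' @param profStep width of the m/z profile bins (Da).
#' @param gapInit,gapExtend nonnegative penalties for opening and extending
#'   an off-diagonal (gap) move in the alignment path.
#' @return an object of class `align_params`.
#' @export
align_params <- function(profStep = 1, gapInit = 0.3, gapExtend = 2.4) {
  assert_scalar_num(profStep, "profStep", 0, strict = TRUE)
  assert_scalar_num(gapInit, "gapInit", 0)
  assert_scalar_num(gapExtend, "gapExtend", 0)
  structure(list(profStep = profStep, gapInit = gapInit,
                 gapExtend = gapExtend), class = "align_params")
}

#' Profile matrix of a run
#'
#' Bins centroid intensities into m/z rows of width `profStep` (bin b covers
#' `[mz0 + b*profStep, mz0 + (b+1)*profStep)`) by scan columns, summing
#' intensities per cell. Total intensity is conserved for centroids inside
#' `mz_range`.
#'
#' @param run an [ms_run()].
#' @param profStep bin width in Da.
#' @param mz_range optional m/z interval defining a common bin grid across
#'   runs; defaults to the run's own centroid range.
#' @return a dense matrix (bins x scans) with attributes `mz0`, `profStep`
#'   and `rt` (scan times).
#' @export
profile_matrix <- function(run, profStep, mz_range = NULL) {
  stopifnot(inherits(run, "ms_run"))
  assert_scalar_num(profStep, "profStep", 0, strict = TRUE)
  cent <- run_centroids(run)
  rt <- scan_times(run)
  if (is.null(mz_range)) {
    mz_range <- if (nrow(cent)) range(cent$mz) else c(0, profStep)
  }
  mz0 <- floor(mz_range[1] / profStep) * profStep
  nbins <- max(1L, floor((mz_range[2] - mz0) / profStep) + 1L)
  if (nbins > 2e5)
    stop_isotopt("profStep ", profStep, " yields ", nbins,
                 " m/z bins over this mass range; choose a coarser step")
  keep <- cent$mz >= mz0 & cent$mz < mz0 + nbins * profStep
  cent <- cent[keep, , drop = FALSE]
  b <- pmin(nbins, floor((cent$mz - mz0) / profStep) + 1L)
  m <- as.matrix(Matrix::sparseMatrix(i = b, j = cent$scan, x = cent$intensity,
                                      dims = c(nbins, length(rt))))
  attr(m, "mz0") <- mz0
  attr(m, "profStep") <- profStep
  attr(m, "rt") <- rt
  m
}

# profiles of a whole run set on one common m/z grid
profile_matrices <- function(runset, profStep) {
  rngs <- lapply(runset$runs, function(r) {
    cent <- run_centroids(r)
    if (nrow(cent)) range(cent$mz) else c(0, profStep)
  })
  mz_range <- c(min(vapply(rngs, `[`, 0, 1)), max(vapply(rngs, `[`, 0, 2)))
  lapply(runset$runs, profile_matrix, profStep = profStep, mz_range = mz_range)
}

#' Align a run's profile to a center profile
#'
#' Scan-pair similarity is the Pearson correlation of the two binned columns
#' (zero-variance columns score 0); an affine-gap dynamic program then finds
#' the monotone path of maximal summed similarity, penalizing off-diagonal
#' moves by `gapInit`/`gapExtend`. The result is a monotone nondecreasing
#' mapping of the run's scan times onto the center run's time axis.
#'
#' @param run_profile,center_profile matrices from [profile_matrix()] on the
#'   same bin grid.
#' @param params an [align_params()] (only the gap penalties are used here;
#'   `profStep` acted when the profiles were built).
#' @return an object of class `rt_warp`: list with `from` (run scan times)
#'   and `to` (mapped center times), both sorted nondecreasing.
#' @export
align_run <- function(run_profile, center_profile, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  if (nrow(run_profile) != nrow(center_profile) ||
      !isTRUE(all.equal(attr(run_profile, "mz0"), attr(center_profile, "mz0"))) ||
      !isTRUE(all.equal(attr(run_profile, "profStep"),
                        attr(center_profile, "profStep"))))
    stop_isotopt("profiles are on incompatible m/z bin grids")
  S <- .column_correlation(run_profile, center_profile)
  .warp_from_similarity(S, attr(run_profile, "rt"),
                        attr(center_profile, "rt"), params)
}

# the DP + interpolation part of align_run, reusable with a cached
# similarity matrix
.warp_from_similarity <- function(S, rt_run, rt_cen, params) {
  matches <- .dp_align(S, params$gapInit, params$gapExtend)
  if (nrow(matches) < 2L) {
    warning("alignment found fewer than 2 matched scans; identity warp used")
    return(structure(list(from = rt_run, to = rt_run), class = "rt_warp"))
  }
  mapped <- stats::approx(rt_run[matches[, 1]], rt_cen[matches[, 2]],
                          xout = rt_run, rule = 2, ties = "ordered")$y
  mapped <- cummax(mapped)   # guard against numeric non-monotonicity
  structure(list(from = rt_run, to = mapped), class = "rt_warp")
}

# Pearson correlation of every column pair; zero-variance columns give 0
.column_correlation <- function(a, b) {
  za <- .zscore_cols(a)
  zb <- .zscore_cols(b)
  crossprod(za, zb) / max(1L, nrow(a) - 1L)
}

.zscore_cols <- function(m) {
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  sd <- sqrt(colSums(ctr^2) / max(1L, nrow(m) - 1L))
  sd[sd == 0] <- Inf          # zero-variance column -> all-zero z-scores
  sweep(ctr, 2L, sd, "/")
}

#' Apply a retention time warp to a peak table
#'
#' Peak `rt`, `rtmin` and `rtmax` are mapped by piecewise-linear
#' interpolation between the warp's anchor scans; times outside the scan
#' range clamp to the boundary mapping.
#'
#' @param peaks a peak table.
#' @param warp an `rt_warp` from [align_run()].
#' @return the peak table with rewritten retention times.
#' @export
apply_warp <- function(peaks, warp) {
  stopifnot(inherits(warp, "rt_warp"))
  peaks <- validate_peaks(peaks)
  f <- function(x) stats::approx(warp$from, warp$to, xout = x, rule = 2,
                                 ties = "ordered")$y
  peaks$rt <- f(peaks$rt)
  peaks$rtmin <- f(peaks$rtmin)
  peaks$rtmax <- f(peaks$rtmax)
  validate_peaks(peaks)
}

#' Align all runs of a run set to a center run
#'
#' Builds profile matrices on a common m/z grid, aligns every non-center run
#' to the center, and rewrites the peak retention times. The center run's
#' peaks are returned unchanged.
#'
#' @param runset an [ms_runset()].
#' @param peaklists named list of per-run peak tables.
#' @param center_id run id of the reference run (see [select_center_run()]).
#' @param params an [align_params()].
#' @param profiles optional precomputed result of an internal profile pass
#'   (used by the optimizer to cache per-`profStep` work).
#' @param sims optional precomputed per-run similarity matrices (see
#'   [runset_similarities()]); the similarity depends only on `profStep`, so
#'   the optimizer caches it across gap-penalty settings.
#' @return named list of warped peak tables, same order as `peaklists`.
#' @export
align_runset <- function(runset, peaklists, center_id,
                         params = align_params(), profiles = NULL,
                         sims = NULL) {
  stopifnot(inherits(runset, "ms_runset"))
  if (!center_id %in% run_ids(runset))
    stop_isotopt("center run ", center_id, " not in the run set")
  if (is.null(sims)) {
    if (is.null(profiles)) profiles <- profile_matrices(runset, params$profStep)
    sims <- runset_similarities(profiles, center_id)
  }
  out <- peaklists
  for (id in names(peaklists)) {
    if (id == center_id) next
    warp <- .warp_from_similarity(sims$S[[id]], sims$rt[[id]],
                                  sims$rt_center, params)
    out[[id]] <- apply_warp(peaklists[[id]], warp)
  }
  out
}

#' Precompute scan similarity matrices against a center run
#'
#' @param profiles result of an internal profile pass over the run set (one
#'   [profile_matrix()] per run on a common grid).
#' @param center_id run id of the reference run.
#' @return list with `S` (named list of similarity matrices, run x center
#'   scans), `rt` (run scan times) and `rt_center`.
#' @export
runset_similarities <- function(profiles, center_id) {
  zc <- .zscore_cols(profiles[[center_id]])
  nb <- nrow(profiles[[center_id]])
  S <- list(); rt <- list()
  for (id in names(profiles)) {
    if (id != center_id)
      S[[id]] <- crossprod(.zscore_cols(profiles[[id]]), zc) / max(1L, nb - 1L)
    rt[[id]] <- attr(profiles[[id]], "rt")
  }
  list(S = S, rt = rt, rt_center = attr(profiles[[center_id]], "rt"))
}
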