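# Semi-sequential optimization: peak picking parameters are optimized first
# against PPS; retention time correction and grouping parameters are then
# optimized simultaneously against the per-round RGTV. Rounds continue while
# the respective score increases; the global best over all rounds is
# returned.

#' Default parameter spaces
#'
#' Start ranges are centered on the conventional defaults of the underlying
#' methods: peak width 20-50 s, ppm 25, mzdiff 0.01 Da for picking; profStep
#' 1 Da, bw 30 s, mzwid 0.025 Da, minfrac 0.5 for alignment and grouping.
#'
#' @return a [param_space()].
#' @export
default_pick_space <- function() {
  param_space(optimized = list(min_peakwidth = c(12, 28),
                               max_peakwidth = c(35, 65),
                               ppm = c(15, 35),
                               mzdiff = c(0.002, 0.018)),
              fixed = list(noise = 100, prefilter_k = 3, prefilter_I = 100))
}

#' @rdname default_pick_space
#' @export
default_align_space <- function() {
  param_space(optimized = list(profStep = c(0.5, 1.5),
                               gapInit = c(0, 0.6),
                               gapExtend = c(0, 0.5),
                               bw = c(15, 45),
                               mzwid = c(0.015, 0.035),
                               minfrac = c(0.3, 0.7)))
}

new_optimization_result <- function(rounds, best_settings, best_score,
                                    stop_reason, history) {
  structure(list(rounds = rounds, best_settings = best_settings,
                 best_score = best_score, stop_reason = stop_reason,
                 history = history), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> ", length(x$rounds), " round(s), stop: ",
      x$stop_reason, "\n  best score ", format(x$best_score), "\n", sep = "")
  invisible(x)
}

#' Optimize peak picking parameters against PPS
#'
#' Each experiment of a DoE round picks peaks on every run of the pooled
#' sample with the decoded settings, classifies isotopologues and low
#' intensity peaks, and computes one pooled PPS. Rounds proceed by maximum
#' focusing; the loop stops when a round's best PPS no longer exceeds the
#' best seen so far (strict improvement required), or after `max_rounds`.
#'
#' @param runset an [ms_runset()].
#' @param space a [param_space()] over [pick_params()] names.
#' @param criteria an [iso_criteria()].
#' @param max_rounds round limit.
#' @param quiet suppress progress messages.
#' @return an `optimization_result`; `best_settings` are the full decoded
#'   settings of the best experiment over all rounds.
#' @export
optimize_peak_picking <- function(runset, space = default_pick_space(),
                                  criteria = iso_criteria(), max_rounds = 10,
                                  quiet = TRUE) {
  stopifnot(inherits(runset, "ms_runset"), inherits(space, "param_space"))
  evaluate <- function(settings) {
    pl <- lapply(runset$runs, pick_peaks, params = do.call(pick_params, settings))
    sc <- score_peak_picking(pl, criteria)
    c(pps = sc$pps, n_peaks = sc$n_peaks, n_rp = sc$n_rp, n_lip = sc$n_lip)
  }
  rounds <- list()
  best_score <- -Inf
  best_settings <- NULL
  stop_reason <- "max_rounds"
  for (rd in seq_len(max_rounds)) {
    res <- run_doe_round(space, evaluate)
    if (rd == 1L) {
      vals <- do.call(rbind, res$values[res$status == "ok"])
      if (all(vals[, "n_peaks"] == 0))
        stop_isotopt("no peaks picked in any experiment of round 1; ",
                     "check the start ranges and the input data")
    }
    rounds[[rd]] <- res
    round_best <- res$scores[res$best_index]
    if (!quiet)
      message(sprintf("picking round %d: best PPS %.3f", rd, round_best))
    if (round_best <= best_score) { stop_reason <- "no_improvement"; break }
    best_score <- round_best
    best_settings <- res$design$settings[[res$best_index]]
    space <- res$next_space
  }
  new_optimization_result(rounds, best_settings, best_score, stop_reason,
                          history = vapply(rounds, function(r)
                            r$scores[r$best_index], 0))
}

# evaluate one align/group setting; returns the score components
.align_group_eval <- function(settings, runset, peaklists, center_id,
                              profile_cache) {
  ap <- align_params(settings$profStep, settings$gapInit, settings$gapExtend)
  gp <- group_params(settings$bw, settings$mzwid, settings$minfrac)
  key <- sprintf("%.12g", ap$profStep)
  if (!exists(key, envir = profile_cache, inherits = FALSE))
    assign(key,
           runset_similarities(profile_matrices(runset, ap$profStep),
                               center_id),
           envir = profile_cache)
  warped <- align_runset(runset, peaklists, center_id, ap,
                         sims = get(key, envir = profile_cache))
  groups <- group_density(warped, gp, n_runs = length(runset$runs))
  sc <- score_alignment(groups, n_runs = length(runset$runs))
  c(rcs = sc$rcs, gs = sc$gs, arts = sc$arts,
    n_reliable = sc$n_reliable, n_nonreliable = sc$n_nonreliable,
    n_groups = sc$n_groups)
}

#' Optimize retention time correction and grouping against RGTV
#'
#' Each experiment aligns all runs to the center run (chosen by highest mean
#' peak intensity), applies the warps to the picked peaks, groups them, and
#' computes RCS and GS; RGTV is normalized across the experiments of the
#' round. Because RGTV is only comparable within one round, rounds are
#' compared on the (GS, RCS) pair of the round's best experiment: a round
#' improves when it strictly improves GS, or ties GS and improves RCS.
#'
#' @param runset an [ms_runset()].
#' @param peaklists named list of per-run peak tables picked with the best
#'   settings (peak picking is not re-run here).
#' @param space a [param_space()] over [align_params()] and [group_params()]
#'   names.
#' @param max_rounds round limit.
#' @param quiet suppress progress messages.
#' @return an `optimization_result` whose `best_score` is `c(gs, rcs)`.
#' @export
optimize_align_group <- function(runset, peaklists,
                                 space = default_align_space(),
                                 max_rounds = 10, quiet = TRUE) {
  stopifnot(inherits(runset, "ms_runset"), is.list(peaklists))
  if (length(runset$runs) < 2L)
    stop_isotopt("alignment optimization needs at least 2 runs")
  center_id <- select_center_run(peaklists)
  profile_cache <- new.env(parent = emptyenv())
  evaluate <- function(settings)
    .align_group_eval(settings, runset, peaklists, center_id, profile_cache)
  objective <- function(vdf) {
    if (nrow(vdf) < 2L)
      stop_isotopt("RGTV normalization needs at least 2 evaluable experiments")
    compute_rgtv(vdf$rcs, vdf$gs)
  }
  rounds <- list()
  best_gs <- -Inf; best_rcs <- -Inf
  best_settings <- NULL
  stop_reason <- "max_rounds"
  for (rd in seq_len(max_rounds)) {
    res <- run_doe_round(space, evaluate, objective = objective)
    vals <- do.call(rbind, res$values[res$status == "ok"])
    if (rd == 1L && all(vals[, "n_groups"] == 0))
      stop_isotopt("no feature groups in any experiment of round 1; ",
                   "check the grouping start ranges")
    rounds[[rd]] <- res
    bi <- res$best_index
    vi <- match(bi, which(res$status == "ok"))
    rb_gs <- unname(vals[vi, "gs"]); rb_rcs <- unname(vals[vi, "rcs"])
    if (!quiet)
      message(sprintf("align/group round %d: best GS %.3f RCS %.4f", rd,
                      rb_gs, rb_rcs))
    improved <- rb_gs > best_gs || (rb_gs == best_gs && rb_rcs > best_rcs)
    if (!improved) { stop_reason <- "no_improvement"; break }
    best_gs <- rb_gs; best_rcs <- rb_rcs
    best_settings <- res$design$settings[[bi]]
    space <- res$next_space
  }
  new_optimization_result(rounds, best_settings,
                          best_score = c(gs = best_gs, rcs = best_rcs),
                          stop_reason,
                          history = t(vapply(rounds, function(r) {
                            v <- do.call(rbind, r$values[r$status == "ok"])
                            i <- match(r$best_index, which(r$status == "ok"))
                            c(gs = v[i, "gs"], rcs = v[i, "rcs"])
                          }, c(gs = 0, rcs = 0))))
}

#' Full semi-sequential optimization of a pooled-sample run set
#'
#' Stage 1 optimizes the peak picking parameters against PPS; the runs are
#' then re-picked once with the winning settings, and stage 2 optimizes
#' retention time correction and grouping against RGTV on those fixed peak
#' lists (the stated cost saving of the semi-sequential split). The report
#' compares the scores at the default settings (the centers of the start
#' ranges) with the optimized ones. With an empty optimized set in both
#' spaces, only the default scoring is performed.
#'
#' @param runset an [ms_runset()].
#' @param config list with optional entries `pick_space`, `align_space`,
#'   `criteria`, `max_rounds`, `quiet`.
#' @return an object of class `optimization_report`: `picking` and
#'   `align_group` stage results, `best_settings`, and `score_table`
#'   comparing default and optimized PPS, RCS/ARTS and group counts.
#' @export
run_full_optimization <- function(runset, config = list()) {
  stopifnot(inherits(runset, "ms_runset"))
  pick_space <- config$pick_space %||% default_pick_space()
  align_space <- config$align_space %||% default_align_space()
  criteria <- config$criteria %||% iso_criteria()
  max_rounds <- config$max_rounds %||% 10
  quiet <- config$quiet %||% TRUE

  n_runs <- length(runset$runs)
  # --- defaults = centers of the start ranges -------------------------------
  def_pick <- decode_point(pick_space, numeric(length(pick_space$optimized)))
  def_align <- decode_point(align_space, numeric(length(align_space$optimized)))
  def_peaklists <- lapply(runset$runs, pick_peaks,
                          params = do.call(pick_params, def_pick))
  def_pps <- score_peak_picking(def_peaklists, criteria)

  scoring_only <- length(pick_space$optimized) == 0 &&
    length(align_space$optimized) == 0

  if (scoring_only || length(pick_space$optimized) == 0) {
    picking <- NULL
    best_pick <- def_pick
    best_peaklists <- def_peaklists
    opt_pps <- def_pps
  } else {
    picking <- optimize_peak_picking(runset, pick_space, criteria,
                                     max_rounds, quiet)
    best_pick <- picking$best_settings
    best_peaklists <- lapply(runset$runs, pick_peaks,
                             params = do.call(pick_params, best_pick))
    opt_pps <- score_peak_picking(best_peaklists, criteria)
  }

  center_id <- select_center_run(best_peaklists)
  cache <- new.env(parent = emptyenv())
  def_ag <- .align_group_eval(def_align, runset, best_peaklists, center_id,
                              cache)
  if (scoring_only || length(align_space$optimized) == 0) {
    align_group <- NULL
    best_align <- def_align
    opt_ag <- def_ag
  } else {
    align_group <- optimize_align_group(runset, best_peaklists, align_space,
                                        max_rounds, quiet)
    best_align <- align_group$best_settings
    opt_ag <- .align_group_eval(best_align, runset, best_peaklists, center_id,
                                cache)
  }

  score_table <- data.frame(
    metric = c("n_peaks", "n_rp", "n_lip", "pps", "arts", "rcs",
               "n_reliable", "n_nonreliable", "gs"),
    default = c(def_pps$n_peaks, def_pps$n_rp, def_pps$n_lip, def_pps$pps,
                def_ag[["arts"]], def_ag[["rcs"]], def_ag[["n_reliable"]],
                def_ag[["n_nonreliable"]], def_ag[["gs"]]),
    optimized = c(opt_pps$n_peaks, opt_pps$n_rp, opt_pps$n_lip, opt_pps$pps,
                  opt_ag[["arts"]], opt_ag[["rcs"]], opt_ag[["n_reliable"]],
                  opt_ag[["n_nonreliable"]], opt_ag[["gs"]]))

  structure(list(picking = picking, align_group = align_group,
                 best_settings = list(picking = best_pick,
                                      align_group = best_align),
                 center_run = center_id, n_runs = n_runs,
                 score_table = score_table),
            class = "optimization_report")
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("<optimization_report> center run: ", x$center_run, "\n", sep = "")
  print(x$score_table, row.names = FALSE)
  invisible(x)
}
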