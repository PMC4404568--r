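# JSON serialization of results for audit and downstream tooling.

doe_result_to_list <- function(res) {
  stopifnot(inherits(res, "doe_result"))
  list(coded_matrix = unname(res$design$coded),
       parameter_names = colnames(res$design$coded),
       settings = lapply(res$design$settings, function(s) lapply(s, unname)),
       status = res$status,
       scores = res$scores,
       values = lapply(res$values, function(v) if (is.null(v)) NULL else as.list(v)),
       surface = list(coefficients = as.list(res$surface$coefficients),
                      r_squared = res$surface$r_squared),
       best_coded = as.list(res$best_coded),
       best_decoded = lapply(res$best_decoded, unname),
       actions = as.list(res$actions))
}

optimization_result_to_list <- function(opt) {
  stopifnot(inherits(opt, "optimization_result"))
  list(n_rounds = length(opt$rounds),
       stop_reason = opt$stop_reason,
       best_score = as.list(opt$best_score),
       best_settings = lapply(opt$best_settings, unname),
       rounds = lapply(opt$rounds, doe_result_to_list))
}

#' Serialize an optimization report to JSON
#'
#' Writes the full audit trail: per-round coded designs, decoded settings,
#' per-experiment score components, response-surface coefficients, located
#' maxima and range actions, plus the default-vs-optimized score table and
#' the resolved best settings.
#'
#' @param report an `optimization_report` from [run_full_optimization()].
#' @param path output path; `NULL` returns the list without writing.
#' @param config optional resolved configuration to echo for reproducibility.
#' @return the report list, invisibly.
#' @export
write_report_json <- function(report, path = NULL, config = NULL) {
  stopifnot(inherits(report, "optimization_report"))
  out <- list(
    center_run = report$center_run,
    n_runs = report$n_runs,
    best_settings = lapply(report$best_settings, function(s)
      lapply(s, unname)),
    score_table = report$score_table,
    picking = if (!is.null(report$picking))
      optimization_result_to_list(report$picking),
    align_group = if (!is.null(report$align_group))
      optimization_result_to_list(report$align_group),
    config = config)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(out)
}

score_report_to_list <- function(sc) {
  list(n_peaks = sc$n_peaks, n_rp = sc$n_rp, n_lip = sc$n_lip, pps = sc$pps,
       per_run = sc$per_run)
}

align_score_to_list <- function(sc) {
  list(n_groups = sc$n_groups, arts = sc$arts, rcs = sc$rcs,
       n_reliable = sc$n_reliable, n_nonreliable = sc$n_nonreliable,
       gs = sc$gs)
}
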