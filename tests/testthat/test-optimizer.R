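# The semi-sequential optimization loop on small synthetic fixtures.

small_pick_space <- function()
  param_space(list(min_peakwidth = c(12, 28), max_peakwidth = c(35, 65)),
              fixed = list(ppm = 25, mzdiff = 0.01, noise = 100,
                           prefilter_k = 3, prefilter_I = 100))

small_align_space <- function()
  param_space(list(gapInit = c(0, 0.6), bw = c(5, 25)),
              fixed = list(profStep = 1, gapExtend = 0.25, mzwid = 0.025,
                           minfrac = 0.5))

test_that("max_rounds = 1 stops after exactly one round", {
  sim <- generate_runset(small_config())
  opt <- optimize_peak_picking(sim$runset, small_pick_space(), max_rounds = 1)
  expect_length(opt$rounds, 1)
  expect_equal(opt$stop_reason, "max_rounds")
  expect_false(is.null(opt$best_settings))
})

test_that("picking optimization improves PPS over the start center and stops on a plateau", {
  sim <- generate_runset(small_config())
  opt <- optimize_peak_picking(sim$runset, small_pick_space(), max_rounds = 5)
  ctr <- decode_point(small_pick_space(),
                      numeric(2))
  pl <- lapply(sim$runset$runs, pick_peaks, params = do.call(pick_params, ctr))
  pps_center <- score_peak_picking(pl)$pps
  expect_gt(opt$best_score, pps_center)
  # best score equals the recomputed PPS at the returned settings
  pl_best <- lapply(sim$runset$runs, pick_peaks,
                    params = do.call(pick_params, opt$best_settings))
  expect_equal(score_peak_picking(pl_best)$pps, opt$best_score)
  # accepted-round history is nondecreasing up to the stopping round
  h <- opt$history
  if (length(h) > 1) expect_true(all(diff(h[-length(h)]) >= 0))
  if (opt$stop_reason == "no_improvement")
    expect_lte(h[length(h)], max(h[-length(h)]))
})

test_that("a runset yielding no peaks aborts round 1 with a diagnostic", {
  cfg <- small_config(n_compounds = 0, noise_peak_rate = 0)
  sim <- generate_runset(cfg)
  expect_error(optimize_peak_picking(sim$runset, small_pick_space(),
                                     max_rounds = 2),
               "no peaks")
})

test_that("align/group optimization needs two runs and an evaluable round", {
  sim <- generate_runset(small_config(n_injections = 1))
  pl <- lapply(sim$runset$runs, pick_peaks,
               params = pick_params(min_peakwidth = 10, max_peakwidth = 40))
  expect_error(optimize_align_group(sim$runset, pl, small_align_space()),
               "at least 2 runs")
})

test_that("align/group optimization does not degrade an undrifted runset", {
  cfg <- small_config(rt_drift_amplitude = 0, noise_peak_rate = 0,
                      mz_jitter_ppm = 0)
  sim <- generate_runset(cfg)
  pl <- lapply(sim$runset$runs, pick_peaks,
               params = pick_params(min_peakwidth = 10, max_peakwidth = 40))
  opt <- optimize_align_group(sim$runset, pl, small_align_space(),
                              max_rounds = 2)
  # at the optimized settings ARTS stays at least as good as no alignment
  center <- select_center_run(pl)
  s <- opt$best_settings
  warped <- align_runset(sim$runset, pl, center,
                         align_params(s$profStep, s$gapInit, s$gapExtend))
  gp <- group_params(s$bw, s$mzwid, s$minfrac)
  arts_opt <- score_alignment(group_density(warped, gp, 3), 3)$arts
  arts_raw <- score_alignment(group_density(pl, gp, 3), 3)$arts
  expect_lte(arts_opt, arts_raw + 1e-9)
})

test_that("an all-fixed configuration produces a scoring-only report", {
  sim <- generate_runset(small_config())
  cfg <- list(pick_space = param_space(list(),
                                       fixed = list(ppm = 25,
                                                    min_peakwidth = 10,
                                                    max_peakwidth = 40,
                                                    mzdiff = 0.01, noise = 100,
                                                    prefilter_k = 3,
                                                    prefilter_I = 100)),
              align_space = param_space(list(),
                                        fixed = list(profStep = 1,
                                                     gapInit = 0.3,
                                                     gapExtend = 0.25,
                                                     bw = 10, mzwid = 0.025,
                                                     minfrac = 0.5)),
              max_rounds = 2)
  rep <- run_full_optimization(sim$runset, cfg)
  expect_null(rep$picking)
  expect_null(rep$align_group)
  expect_equal(rep$score_table$default, rep$score_table$optimized)
  expect_true(all(c("pps", "gs") %in% rep$score_table$metric))
})
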