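# ROI construction and wavelet peak detection.

test_that("centroids chain into one ROI within ppm of the running mean", {
  scans <- lapply(1:3, function(i)
    list(rt = i, mz = 100 + (i - 1) * 2e-4, intensity = 1000))
  run <- ms_run("r", scans)
  rois <- find_rois(run, pick_params(ppm = 25, prefilter_k = 0))
  expect_length(rois, 1)
  expect_length(rois[[1]]$mz, 3)
  expect_equal(rois[[1]]$mz_mean, mean(100 + (0:2) * 2e-4))
  # with ppm = 1 the deviations (2 ppm) break the chain: three singletons,
  # all removed by prefilter_k = 3
  expect_length(find_rois(run, pick_params(ppm = 1, prefilter_k = 3)), 0)
  expect_length(find_rois(run, pick_params(ppm = 1, prefilter_k = 0)), 3)
  # empty run
  empty <- ms_run("e", list(list(rt = 1, mz = numeric(), intensity = numeric())))
  expect_length(find_rois(empty, pick_params()), 0)
})

test_that("every ROI member stays within ppm of the running mean", {
  sim <- generate_runset(small_config())
  params <- pick_params(ppm = 25, min_peakwidth = 10, max_peakwidth = 40)
  rois <- find_rois(sim$runset$runs[[1]], params)
  expect_gt(length(rois), 0)
  for (r in rois)
    expect_true(all(abs(r$mz - r$mz_mean) <= params$ppm * 1e-6 * r$mz_mean * 2))
})

test_that("a clean Gaussian inside the width window gives exactly one peak", {
  run <- gaussian_run(data.frame(mz = 250.1, rt = 100, fwhm = 20,
                                 intensity = 1e6))
  pk <- pick_peaks(run, pick_params(min_peakwidth = 10, max_peakwidth = 35))
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$rt - 100), 1)          # within one scan interval
  expect_equal(pk$mz, 250.1, tolerance = 1e-6)
  # measured width within 25% of the truth
  # (detection-scale filter passed it, so the apex half-max width is close)
  # too-narrow expected widths miss or fragment the peak
  pk2 <- pick_peaks(run, pick_params(min_peakwidth = 2, max_peakwidth = 5))
  expect_true(nrow(pk2) != 1)
  # flat zero trace: no peaks
  flat <- ms_run("f", lapply(1:50, function(i)
    list(rt = i, mz = 100, intensity = 0)))
  expect_equal(nrow(pick_peaks(flat, pick_params())), 0)
})

test_that("detected FWHM tracks the true width within 25%", {
  for (fw in c(12, 20, 30)) {
    run <- gaussian_run(data.frame(mz = 300.2, rt = 100, fwhm = fw,
                                   intensity = 5e5))
    pk <- pick_peaks(run, pick_params(min_peakwidth = 8, max_peakwidth = 45))
    expect_equal(nrow(pk), 1)
    # reconstruct the measured width from the trace at half maximum
    cents <- run_centroids(run)
    half <- max(cents$intensity) / 2
    width <- diff(range(cents$rt[cents$intensity >= half]))
    expect_lt(abs(width - fw) / fw, 0.25)
  }
})

test_that("co-eluting peaks closer than mzdiff merge, keeping the intense one", {
  run <- gaussian_run(data.frame(mz = c(200.000, 200.001), rt = c(100, 100),
                                 fwhm = c(15, 15), intensity = c(1e6, 4e5)))
  pk <- pick_peaks(run, pick_params(min_peakwidth = 8, max_peakwidth = 30,
                                    mzdiff = 0.01))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mz, 200.0, tolerance = 1e-4)
  pk2 <- pick_peaks(run, pick_params(min_peakwidth = 8, max_peakwidth = 30,
                                     mzdiff = 1e-4))
  expect_equal(nrow(pk2), 2)
})

test_that("all synthetic parents are recovered at matched parameters", {
  sim <- generate_runset(small_config())
  run <- sim$runset$runs[[1]]
  tr <- sim$truth[sim$truth$injection == 1, ]
  pk <- pick_peaks(run, pick_params(min_peakwidth = 10, max_peakwidth = 40))
  si <- 1  # scan interval of the fixture
  for (i in seq_len(nrow(tr))) {
    hit <- abs(pk$mz - tr$mz[i]) <= 5e-6 * tr$mz[i] &
      abs(pk$rt - tr$rt_true[i]) <= 1.5 * si
    expect_true(any(hit), label = paste("parent", i, "recovered"))
  }
})

test_that("lowering the noise floor never loses peaks", {
  sim <- generate_runset(small_config())
  run <- sim$runset$runs[[2]]
  counts <- vapply(c(1e5, 1e4, 1e3, 1e2), function(nz)
    nrow(pick_peaks(run, pick_params(min_peakwidth = 10, max_peakwidth = 40,
                                     noise = nz))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("picking is deterministic and validates its parameters", {
  sim <- generate_runset(small_config())
  p <- pick_params(min_peakwidth = 10, max_peakwidth = 40)
  expect_identical(pick_peaks(sim$runset$runs[[1]], p),
                   pick_peaks(sim$runset$runs[[1]], p))
  expect_error(pick_params(min_peakwidth = 30, max_peakwidth = 20),
               "min_peakwidth", class = "isotopt_validation_error")
  expect_error(pick_params(ppm = -1), "ppm")
})
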