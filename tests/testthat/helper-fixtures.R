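# Fixtures built in code: tiny runs, random peak tables, and independent
# brute-force oracles used to cross-check the vectorized implementations.

# a run with Gaussian elution profiles for given compounds
# compounds: data.frame(mz, rt, fwhm, intensity)
gaussian_run <- function(compounds, rt_range = c(0, 200), scan_interval = 1,
                         run_id = "run1") {
  rts <- seq(rt_range[1], rt_range[2], by = scan_interval)
  scans <- lapply(rts, function(t) {
    mz <- int <- numeric(0)
    for (i in seq_len(nrow(compounds))) {
      sigma <- compounds$fwhm[i] / (2 * sqrt(2 * log(2)))
      v <- compounds$intensity[i] * exp(-(t - compounds$rt[i])^2 / (2 * sigma^2))
      if (v >= 1) { mz <- c(mz, compounds$mz[i]); int <- c(int, v) }
    }
    ord <- order(mz)
    list(rt = t, mz = mz[ord], intensity = int[ord])
  })
  ms_run(run_id, scans)
}

# random valid peak table; plant_pairs adds isotopologue partners that pass
# all three criteria
random_peaks <- function(n, seed, plant_pairs = 0, run_id = "r1") {
  set.seed(seed)
  mz <- runif(n, 100, 500)
  rt <- runif(n, 50, 500)
  w <- runif(n, 5, 15)
  pk <- data.frame(run_id = rep(run_id, n), mz = mz, mzmin = mz - 1e-3,
                   mzmax = mz + 1e-3, rt = rt, rtmin = rt - w,
                   rtmax = rt + w, intensity = 10^runif(n, 4, 6.5))
  if (plant_pairs > 0) {
    idx <- sample(n, plant_pairs)
    iso <- pk[idx, ]
    iso$mz <- iso$mz + 1.0033548
    iso$mzmin <- iso$mz - 1e-3
    iso$mzmax <- iso$mz + 1e-3
    nc <- max_carbons(pk$mz[idx])
    frac <- runif(plant_pairs, 1.05, pmax(1.1, nc * 0.95))
    iso$intensity <- pk$intensity[idx] * 0.01108 * frac
    iso$rt <- pk$rt[idx] + runif(plant_pairs, -1, 1)
    pk <- rbind(pk, iso)
  }
  validate_peaks(pk)
}

# all-pairs brute-force reference for find_isotopologues: every parent i is
# checked against every candidate j directly, no sorted windowing
brute_force_rp <- function(peaks, criteria = iso_criteria()) {
  n <- nrow(peaks)
  label <- rep("UNRELIABLE", n)
  partners <- vector("list", n)
  ia <- criteria$isotope_abundance; sl <- criteria$intensity_slack
  for (i in seq_len(n)) {
    mass_ok <- abs(peaks$mz - (peaks$mz[i] + criteria$iso_mass_delta)) <=
      criteria$mass_tol_ppm * peaks$mz[i] * 1e-6
    overlap <- peaks$rtmax >= peaks$rtmin[i] & peaks$rtmin <= peaks$rtmax[i]
    rt_ok <- abs(peaks$rt - peaks$rt[i]) <=
      criteria$rt_window_frac * (peaks$rtmax[i] - peaks$rtmin[i])
    int_ok <- peaks$intensity >= ia * peaks$intensity[i] / (1 + sl) &
      peaks$intensity <= max_carbons(peaks$mz[i]) * ia * peaks$intensity[i] * (1 + sl)
    js <- setdiff(which(mass_ok & overlap & rt_ok & int_ok), i)
    if (length(js)) {
      label[i] <- "RP"; label[js] <- "RP"
      partners[[i]] <- sort(unique(c(partners[[i]], js)))
      for (j in js) partners[[j]] <- sort(unique(c(partners[[j]], i)))
    }
  }
  list(label = label, partners = partners)
}

# the mzR header skeleton used to write edge-case mzML fixtures directly
mzr_header <- function(n, rt, msLevel = 1L, centroided = TRUE) {
  data.frame(seqNum = 1:n, acquisitionNum = 1:n, msLevel = msLevel,
    polarity = 1L, peaksCount = 1L, totIonCurrent = 1, retentionTime = rt,
    basePeakMZ = 0, basePeakIntensity = 0, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 100, highMZ = 100, precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", 1:n),
    centroided = centroided, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
}

# small fast synthetic config for pipeline-level tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_compounds = 10, rt_range = c(0, 260), rt_drift_amplitude = 15,
         n_injections = 3, noise_peak_rate = 1, seed = 7),
    list(...))
  do.call(synthetic_config, args)
}

# run the CLI quietly (its info logging goes to stderr via message())
run_cli <- function(args) suppressMessages(main(args))
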