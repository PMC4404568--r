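# The score formulas and the isotopologue classifier.

test_that("max_carbons follows the hydrocarbon-chain bound", {
  expect_identical(max_carbons(30.04695), 2L)   # numerator exactly 0
  expect_identical(max_carbons(100), 6L)
  expect_identical(max_carbons(200), 14L)
  expect_identical(max_carbons(10), 0L)         # below two CH3 masses
  # nondecreasing, integer, >= 2 on its domain
  mz <- seq(31, 900, by = 0.37)
  v <- max_carbons(mz)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 2))
})

test_that("isotopologue pairs are recognized by the three criteria", {
  parent <- data.frame(run_id = "a", mz = 200, mzmin = 199.99, mzmax = 200.01,
                       rt = 100, rtmin = 90, rtmax = 110, intensity = 1e6)
  iso <- transform(parent, mz = 201.00335, mzmin = 201, mzmax = 201.01,
                   intensity = 5e4)
  cl <- find_isotopologues(rbind(parent, iso))
  expect_equal(cl$label, c("RP", "RP"))
  expect_equal(cl$partners[[1]], 2L)
  # intensity above the maxC window (14 carbons -> upper bound 155120)
  iso_hot <- transform(iso, intensity = 1e6)
  cl2 <- find_isotopologues(rbind(parent, iso_hot))
  expect_equal(cl2$label, c("UNRELIABLE", "UNRELIABLE"))
  # empty input
  cl3 <- find_isotopologues(random_peaks(0, 1))
  expect_length(cl3$label, 0)
})

test_that("isotopologue detector agrees with the all-pairs brute force", {
  for (seed in 1:12) {
    n <- sample(c(20, 60, 120), 1)
    pk <- random_peaks(n, seed = seed, plant_pairs = sample(0:8, 1))
    got <- find_isotopologues(pk)
    ref <- brute_force_rp(pk)
    expect_identical(got$label, ref$label)
    expect_identical(got$partners, ref$partners)
  }
})

test_that("LIP classification uses the lowest-3%-mean cut-off with strict <", {
  pk <- random_peaks(100, seed = 3)
  pk$intensity <- as.numeric(1:100)
  pk$mz <- rep(100, 100)       # maxC = 6
  pk$mzmin <- pk$mz - 1e-3; pk$mzmax <- pk$mz + 1e-3
  cl <- find_isotopologues(pk)          # ratios 1:1 never in the window
  cl <- classify_lip(pk, cl)
  expect_equal(attr(cl, "lip_cutoff"), 2)       # mean of {1,2,3}
  # predicted iso = I * 6 * 0.01108 < 2  <=>  I < 30.08
  expect_equal(which(cl$label == "LIP"), which(pk$intensity * 6 * 0.01108 < 2))
  # exact boundary is NOT a LIP
  pk2 <- pk
  pk2$intensity[50] <- 2 / (6 * 0.01108)
  cl2 <- classify_lip(pk2, find_isotopologues(pk2))
  expect_false(cl2$label[50] == "LIP")
  # an RP is never relabeled
  cl3 <- find_isotopologues(pk)
  cl3$label[1] <- "RP"
  expect_equal(classify_lip(pk, cl3)$label[1], "RP")
})

test_that("PPS arithmetic and its optimization-force property", {
  expect_equal(compute_pps(4, 10, 2), 2)
  expect_equal(compute_pps(0, 10, 2), 0)
  expect_equal(compute_pps(5, 5, 0), 5)
  expect_equal(compute_pps(3, 3, 3), 0)    # denominator <= 0
  expect_equal(compute_pps(10, 20, 0), 5)
  expect_gt(compute_pps(11, 21, 0), compute_pps(10, 20, 0))
  # equal increments of RP and total always raise PPS
  for (d in c(1, 5, 20))
    expect_gt(compute_pps(10 + d, 30 + d, 2), compute_pps(10, 30, 2))
})

test_that("GRTS, ARTS/RCS and translation invariance", {
  expect_equal(compute_grts(c(10, 10, 10)), 0)
  expect_equal(compute_grts(c(9, 10, 11)), 2 / 3)
  expect_equal(compute_grts(5), 0)               # singleton
  rc <- compute_rcs(c(0.5, 1.5))
  expect_equal(rc$arts, 1); expect_equal(rc$rcs, 1)
  expect_equal(compute_rcs(c(0, 0))$rcs, Inf)    # perfect alignment sentinel
  expect_warning(z <- compute_rcs(numeric(0)), "no feature groups")
  expect_equal(z$rcs, 0)
  # shifting all retention times leaves GRTS (hence RCS) unchanged
  rts <- runif(9, 100, 200)
  expect_equal(compute_grts(rts + 5), compute_grts(rts))
})

test_that("group reliability and GS", {
  g <- list(c("a", "b", "c"), c("a", "a", "b", "c"), c("a", "b"))
  cl <- classify_groups(g, n_runs = 3)
  expect_equal(cl$reliable, c(TRUE, FALSE, FALSE))
  expect_equal(compute_gs(10, 4), 25)
  expect_equal(compute_gs(0, 7), 0)
  expect_equal(compute_gs(10, 0), 100)   # empty denominator treated as 1
})

test_that("RGTV normalizes per round and handles degenerate rounds", {
  expect_equal(compute_rgtv(c(1, 2, 3), c(30, 10, 20)), c(1.0, 0.5, 1.5))
  # constant RCS contributes 0.5 everywhere: ranking decided by GS alone
  r <- compute_rgtv(c(2, 2, 2), c(1, 3, 2))
  expect_equal(r, c(0.5, 1.5, 1.0))
  # Inf sentinel pinned to the round maximum
  r2 <- compute_rgtv(c(Inf, 1, 3), c(0, 0, 0))
  expect_equal(r2, c(1.5, 0.5, 1.5))
  expect_error(compute_rgtv(1:3, 1:2), "same length")
  expect_error(compute_rgtv(1, 1), "at least 2")
  # always within [0, 2]
  for (s in 1:5) {
    set.seed(s)
    r3 <- compute_rgtv(runif(7), runif(7))
    expect_true(all(r3 >= 0 & r3 <= 2))
  }
})

test_that("PPS and GS are invariant under intensity rescaling", {
  pk <- random_peaks(80, seed = 11, plant_pairs = 10)
  score1 <- score_peak_picking(list(r1 = pk))
  pk2 <- pk; pk2$intensity <- pk2$intensity * 7.3
  score2 <- score_peak_picking(list(r1 = pk2))
  expect_equal(score2$pps, score1$pps)
  expect_equal(score2$n_rp, score1$n_rp)
  expect_equal(score2$n_lip, score1$n_lip)
})
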