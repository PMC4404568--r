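# Design generation, response-surface fitting, maximization, range focusing.

space3 <- function() param_space(list(a = c(-2, 2), b = c(0, 10), cc = c(1, 3)))

test_that("designs have the documented shapes per k", {
  d1 <- build_design(param_space(list(a = c(10, 30))))
  expect_equal(unname(d1$coded[, 1]), c(-1, 0, 1))
  expect_equal(vapply(d1$settings, `[[`, 0, "a"), c(10, 20, 30))
  d2 <- build_design(param_space(list(a = c(0, 1), b = c(0, 1))))
  expect_equal(nrow(d2$coded), 9)              # full 3-level factorial
  expect_equal(nrow(unique(d2$coded)), 9)
  d3 <- build_design(space3())
  expect_equal(nrow(d3$coded), 13)             # 3 pairs x 4 signs + center
  noncenter <- d3$coded[rowSums(abs(d3$coded)) > 0, ]
  expect_true(all(rowSums(noncenter != 0) == 2))
  expect_true(all(noncenter %in% c(-1, 0, 1)))
  d4 <- build_design(param_space(list(a = c(0, 1), b = c(0, 1), c = c(0, 1),
                                      d = c(0, 1))))
  expect_equal(nrow(d4$coded), 25)             # 4C2 x 4 + center
  expect_error(build_design(param_space(setNames(list(), character()))),
               "empty")
})

test_that("decode/encode round-trips and stays within bounds", {
  sp <- space3()
  d <- build_design(sp)
  for (r in seq_len(nrow(d$coded))) {
    st <- d$settings[[r]]
    expect_equal(unname(isotopt:::encode_point(sp, st)),
                 unname(d$coded[r, ]))
    for (nm in names(sp$optimized)) {
      expect_gte(st[[nm]], sp$optimized[[nm]][1])
      expect_lte(st[[nm]], sp$optimized[[nm]][2])
    }
  }
})

test_that("an exact quadratic is recovered to 1e-8 and maximized exactly", {
  sp <- space3()
  d <- build_design(sp)
  f <- function(x) 2 + x[1] - x[2]^2
  scores <- apply(d$coded, 1, f)
  surf <- fit_response_surface(d, scores)
  co <- surf$coefficients
  expect_equal(unname(co["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(co["a"]), 1, tolerance = 1e-8)
  expect_equal(unname(co["b^2"]), -1, tolerance = 1e-8)
  others <- setdiff(names(co), c("(Intercept)", "a", "b^2"))
  expect_true(all(abs(co[others]) < 1e-8))
  # monotone term maximized on its bound, flat terms at the center
  m <- locate_maximum(surf)
  expect_equal(unname(m), c(1, 0, 0), tolerance = 1e-6)
})

test_that("locate_maximum finds interior, boundary and degenerate optima", {
  sp <- space3()
  d <- build_design(sp)
  fit <- function(f) fit_response_surface(d, apply(d$coded, 1, f))
  m1 <- locate_maximum(fit(function(x) 1 - (x[1] - 0.2)^2 - x[2]^2 - x[3]^2))
  expect_equal(unname(m1), c(0.2, 0, 0), tolerance = 1e-6)
  m2 <- locate_maximum(fit(function(x) x[1]))
  expect_equal(unname(m2[1]), 1)
  m3 <- locate_maximum(fit(function(x) 5))     # constant -> center tie rule
  expect_equal(unname(m3), c(0, 0, 0))
  # saddle with maximum on a face
  m4 <- locate_maximum(fit(function(x) x[1]^2 - x[2]^2))
  expect_equal(abs(unname(m4[1])), 1)
  expect_equal(unname(m4[2]), 0)
})

test_that("constant scores yield an intercept-only surface", {
  d <- build_design(space3())
  surf <- fit_response_surface(d, rep(3.5, nrow(d$coded)))
  expect_equal(unname(surf$coefficients["(Intercept)"]), 3.5, tolerance = 1e-8)
  expect_true(all(abs(surf$coefficients[-1]) < 1e-8))
  expect_error(fit_response_surface(d, c(NaN, rep(1, nrow(d$coded) - 1))),
               "experiment")
})

test_that("zoom rules move and resize ranges as documented", {
  sp <- param_space(list(p = c(20, 50)))
  # maximum on the upper bound: zoom out, width 30 -> 36, center 50
  adj <- adjust_ranges(sp, list(p = 50), c(p = 1))
  expect_equal(unname(adj$space$optimized$p), c(32, 68))
  expect_equal(unname(adj$actions), "zoom_out")
  # maximum at the center: zoom in, width 30 -> 24, center 35
  adj2 <- adjust_ranges(sp, list(p = 35), c(p = 0))
  expect_equal(unname(adj2$space$optimized$p), c(23, 47))
  expect_equal(unname(adj2$actions), "zoom_in")
  # maximum at coded 0.5: recenter only
  adj3 <- adjust_ranges(sp, list(p = 42.5), c(p = 0.5))
  expect_equal(unname(adj3$space$optimized$p), c(27.5, 57.5))
  expect_equal(unname(adj3$actions), "keep")
})

test_that("zoomed ranges contain the best point and respect floors", {
  sp <- param_space(list(ppm = c(15, 35), bw = c(15, 45)))
  for (coded in list(c(1, -1), c(0.1, 0.6), c(-1, 0))) {
    names(coded) <- c("ppm", "bw")
    best <- decode_point(sp, coded)
    adj <- adjust_ranges(sp, best, coded)
    for (nm in c("ppm", "bw")) {
      b <- adj$space$optimized[[nm]]
      expect_gte(best[[nm]], b[1]); expect_lte(best[[nm]], b[2])
      w0 <- diff(sp$optimized[[nm]]); w1 <- diff(b)
      if (adj$actions[nm] == "zoom_out") expect_gt(w1, w0)
      if (adj$actions[nm] == "zoom_in") expect_lt(w1, w0)
      if (adj$actions[nm] == "keep") expect_equal(w1, w0)
    }
  }
  # clamping at a floor keeps the interval valid (possibly asymmetric)
  spf <- param_space(list(mzwid = c(0.015, 0.035)))
  adj <- adjust_ranges(spf, list(mzwid = 0.015), c(mzwid = -1))
  expect_gte(adj$space$optimized$mzwid[1], 1e-4)
  expect_lt(adj$space$optimized$mzwid[1], adj$space$optimized$mzwid[2])
})

test_that("a full round on an exact quadratic finds the analytic optimum", {
  sp <- space3()
  f <- function(s) 10 - (s$a - 0.5)^2 - (s$b - 5)^2 / 4 - (s$cc - 2)^2
  res <- run_doe_round(sp, f)
  expect_equal(res$best_decoded$a, 0.5, tolerance = 1e-6)
  expect_equal(res$best_decoded$b, 5, tolerance = 1e-6)
  expect_equal(res$best_decoded$cc, 2, tolerance = 1e-6)
  expect_s3_class(res$next_space, "param_space")
})

test_that("a failing experiment is excluded with a warning, fit proceeds", {
  sp <- param_space(list(a = c(0, 1), b = c(0, 1), cc = c(0, 1)))
  f <- function(s) {
    if (abs(s$a - 0) < 1e-12 && abs(s$b - 1) < 1e-12) stop("boom")
    s$a + s$b + s$cc
  }
  expect_warning(res <- run_doe_round(sp, f), "failed")
  expect_equal(sum(res$status == "error"), 1)
  expect_true(is.na(res$scores[res$status == "error"]))
  expect_s3_class(res$surface, "response_surface")
})

test_that("infeasible decoded settings score 0 instead of evaluating", {
  sp <- param_space(list(min_peakwidth = c(10, 40), max_peakwidth = c(20, 50)))
  seen <- new.env(); seen$bad <- 0
  f <- function(s) {
    if (s$min_peakwidth >= s$max_peakwidth) seen$bad <- seen$bad + 1
    s$max_peakwidth - s$min_peakwidth
  }
  res <- run_doe_round(sp, f)
  expect_gt(sum(res$status == "infeasible"), 0)
  expect_equal(seen$bad, 0)   # evaluator never saw an infeasible setting
  expect_true(all(res$scores[res$status == "infeasible"] == 0))
})

test_that("repeated rounds on an exact quadratic shrink onto the optimum", {
  sp <- param_space(list(a = c(-2, 2), b = c(-2, 2), cc = c(-2, 2)))
  f <- function(s) 3 - (s$a - 0.3)^2 - (s$b + 0.4)^2 - s$cc^2
  for (i in 1:6) {
    res <- run_doe_round(sp, f)
    sp <- res$next_space
  }
  ctr <- vapply(sp$optimized, mean, 0)
  expect_equal(unname(ctr), c(0.3, -0.4, 0), tolerance = 0.02)
  expect_true(all(vapply(sp$optimized, diff, 0) < 4))
})
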