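# Design-of-experiments engine: three-level designs over a parameter space
# (Box-Behnken for k >= 3, full 3-level factorial for k = 2, a sweep for
# k = 1), second-order response-surface fitting in coded units, exact
# maximization of the fitted quadratic over the coded cube, and the
# maximum-focusing range adjustment (zoom out 20% at a bound, zoom in 10%
# per bound near the center).

# hard lower limits (and upper limits where a parameter is a fraction)
.DEFAULT_FLOORS <- c(ppm = 1e-3, min_peakwidth = 0.5, max_peakwidth = 1,
                     mzdiff = 0, noise = 0, profStep = 0.1, bw = 0.1,
                     mzwid = 1e-4, minfrac = 0.05, gapInit = 0, gapExtend = 0)
.DEFAULT_CEILINGS <- c(minfrac = 1)
.DEFAULT_CONSTRAINTS <- list(c("min_peakwidth", "max_peakwidth"))

#' Parameter space for optimization
#'
#' Holds the parameters to optimize with their current bounds, the fixed
#' parameters, per-parameter hard floors (and ceilings for fractions), and
#' pairwise ordering constraints such as `min_peakwidth < max_peakwidth`.
#'
#' @param optimized named list of `c(low, high)` bounds, `low < high`.
#' @param fixed named list of fixed parameter values.
#' @param constraints list of 2-element character vectors `c(a, b)` requiring
#'   `a < b` in any decoded setting; defaults to the peak width ordering when
#'   both names are present.
#' @param floors,ceilings named numeric overrides of the built-in hard
#'   limits.
#' @return an object of class `param_space`.
#' @export
param_space <- function(optimized, fixed = list(), constraints = NULL,
                        floors = NULL, ceilings = NULL) {
  if (!is.list(optimized))
    stop_isotopt("optimized must be a named list of c(low, high) bounds")
  if (length(optimized) && is.null(names(optimized)))
    stop_isotopt("optimized parameters must be named")
  fl <- .DEFAULT_FLOORS
  fl[names(floors)] <- floors
  ce <- .DEFAULT_CEILINGS
  ce[names(ceilings)] <- ceilings
  for (nm in names(optimized)) {
    v <- optimized[[nm]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v) || v[1] >= v[2])
      stop_isotopt("bounds of ", nm, " must be c(low, high) with low < high")
    if (nm %in% names(fl) && v[1] < fl[nm])
      stop_isotopt(nm, " lower bound ", v[1], " is below its floor ", fl[nm])
    if (nm %in% names(ce) && v[2] > ce[nm])
      stop_isotopt(nm, " upper bound ", v[2], " is above its ceiling ", ce[nm])
  }
  if (is.null(constraints)) {
    nms <- c(names(optimized), names(fixed))
    constraints <- Filter(function(cn) all(cn %in% nms), .DEFAULT_CONSTRAINTS)
  }
  structure(list(optimized = optimized, fixed = fixed,
                 constraints = constraints, floors = fl, ceilings = ce),
            class = "param_space")
}

space_centers <- function(space)
  vapply(space$optimized, function(b) mean(b), 0)

space_widths <- function(space)
  vapply(space$optimized, function(b) diff(b), 0)

#' Decode a coded design point into parameter settings
#'
#' Coded coordinate x in \[-1, 1\] maps to `center + x * half_width`; fixed
#' parameters are appended unchanged.
#'
#' @param space a [param_space()].
#' @param coded numeric vector of length k (order of `space$optimized`).
#' @return named list of settings.
#' @export
decode_point <- function(space, coded) {
  ctr <- space_centers(space)
  hw <- space_widths(space) / 2
  vals <- as.list(ctr + coded * hw)
  names(vals) <- names(space$optimized)
  c(vals, space$fixed)
}

encode_point <- function(space, settings) {
  ctr <- space_centers(space)
  hw <- space_widths(space) / 2
  (unlist(settings[names(space$optimized)]) - ctr) / hw
}

# do the decoded settings satisfy floors and ordering constraints?
settings_feasible <- function(space, settings) {
  for (nm in names(settings)) {
    v <- settings[[nm]]
    if (nm %in% names(space$floors) && v < space$floors[nm] - 1e-12) return(FALSE)
    if (nm %in% names(space$ceilings) && v > space$ceilings[nm] + 1e-12) return(FALSE)
  }
  for (cn in space$constraints) {
    if (all(cn %in% names(settings)) &&
        !(settings[[cn[1]]] < settings[[cn[2]]])) return(FALSE)
  }
  TRUE
}

#' Build the three-level design for a parameter space
#'
#' For k >= 3 parameters a Box-Behnken design: every pair of parameters at
#' the four (+-1, +-1) combinations with all others at 0, plus one center
#' point (`4 * choose(k, 2) + 1` rows). For k = 2 a full 3-level factorial
#' (9 rows); for k = 1 a sweep over the three levels.
#'
#' @param space a [param_space()] with at least one optimized parameter.
#' @return an object of class `doe_design`: list with `coded` (rows x k
#'   matrix), `settings` (list of decoded settings per row) and `n_center`.
#' @export
build_design <- function(space) {
  stopifnot(inherits(space, "param_space"))
  k <- length(space$optimized)
  if (k == 0L) stop_isotopt("no parameters to optimize: empty space")
  if (k == 1L) {
    coded <- matrix(c(-1, 0, 1), ncol = 1)
  } else if (k == 2L) {
    g <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
    coded <- rbind(g[rowSums(abs(g)) > 0, ], c(0, 0))  # center point last
  } else {
    pairs <- utils::combn(k, 2)
    rows <- list()
    signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
    for (p in seq_len(ncol(pairs))) {
      for (s in seq_len(nrow(signs))) {
        r <- numeric(k)
        r[pairs[, p]] <- signs[s, ]
        rows[[length(rows) + 1L]] <- r
      }
    }
    coded <- rbind(do.call(rbind, rows), numeric(k))
  }
  dimnames(coded) <- list(NULL, names(space$optimized))
  settings <- apply(coded, 1, decode_point, space = space, simplify = FALSE)
  structure(list(coded = coded, settings = settings, n_center = 1L,
                 space = space), class = "doe_design")
}

# model matrix of the full quadratic in coded coordinates
rs_model_matrix <- function(coded) {
  k <- ncol(coded)
  cols <- list("(Intercept)" = rep(1, nrow(coded)))
  for (i in seq_len(k)) cols[[colnames(coded)[i]]] <- coded[, i]
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      cols[[paste0(colnames(coded)[i], ":", colnames(coded)[j])]] <-
        coded[, i] * coded[, j]
  }
  for (i in seq_len(k))
    cols[[paste0(colnames(coded)[i], "^2")]] <- coded[, i]^2
  do.call(cbind, cols)
}

#' Fit a second-order response surface in coded units
#'
#' Least-squares fit of the full quadratic (intercept, k linear, k(k-1)/2
#' interaction, k quadratic terms) to the per-experiment scores. Exact
#' quadratics are interpolated exactly; a rank-deficient system is fitted on
#' the estimable terms with a warning (inestimable coefficients set to 0).
#'
#' @param design a `doe_design` (or a coded matrix).
#' @param scores numeric vector, one finite score per design row.
#' @return an object of class `response_surface`: coefficients, `k` and
#'   `r_squared`.
#' @export
fit_response_surface <- function(design, scores) {
  coded <- if (inherits(design, "doe_design")) design$coded else design
  if (length(scores) != nrow(coded))
    stop_isotopt("need one score per design row (", nrow(coded), " rows, ",
                 length(scores), " scores)")
  bad <- !is.finite(scores)
  if (any(bad))
    stop_isotopt("non-finite score for experiment(s) ",
                 paste(which(bad), collapse = ", "))
  X <- rs_model_matrix(coded)
  fit <- stats::lm.fit(X, scores)
  coef <- fit$coefficients
  if (anyNA(coef)) {
    warning("rank-deficient response surface fit; ",
            sum(is.na(coef)), " coefficient(s) set to 0")
    coef[is.na(coef)] <- 0
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((scores - mean(scores))^2)
  structure(list(coefficients = coef, k = ncol(coded),
                 names = colnames(coded),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "response_surface")
}

#' Evaluate a fitted response surface at coded points
#'
#' @param surface a `response_surface`.
#' @param coded matrix of coded points (rows) or a single point vector.
#' @return numeric vector of predicted scores.
#' @export
surface_value <- function(surface, coded) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  colnames(coded) <- surface$names
  as.numeric(rs_model_matrix(coded) %*% surface$coefficients)
}

# quadratic form pieces: f(x) = c0 + g'x + x' Q x  (Q symmetric)
.surface_qform <- function(surface) {
  k <- surface$k
  co <- surface$coefficients
  g <- co[2:(k + 1)]
  Q <- diag(co[(length(co) - k + 1):length(co)], k)
  if (k >= 2) {
    idx <- k + 2L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- co[idx] / 2
      idx <- idx + 1L
    }
  }
  list(c0 = co[1], g = as.numeric(g), Q = Q)
}

#' Maximize the fitted quadratic over the coded cube
#'
#' Enumerates the 3^k bound-activity patterns of the box-constrained
#' quadratic: for each subset of coordinates fixed at -1 or +1, the
#' stationary point of the remaining free block is solved (minimum-norm
#' solution for flat directions) and kept when it lies inside the cube. The
#' best candidate wins; ties are broken towards the center (smallest
#' Euclidean norm, then lexicographic order), so a constant surface yields
#' the center point.
#'
#' @param surface a `response_surface`.
#' @param k number of parameters (must match the surface).
#' @return coded coordinates of the maximizer, in `[-1, 1]^k`.
#' @export
locate_maximum <- function(surface, k = surface$k) {
  stopifnot(inherits(surface, "response_surface"), k == surface$k)
  qf <- .surface_qform(surface)
  cand <- list()
  patterns <- expand.grid(rep(list(c(-1, 0, 1)), k))  # 0 marks a free coord
  for (r in seq_len(nrow(patterns))) {
    pat <- as.numeric(patterns[r, ])
    free <- pat == 0
    x <- pat
    if (any(free)) {
      # stationary point of the free block: 2 Q_ff x_f = -(g_f + 2 Q_fb x_b)
      Qff <- qf$Q[free, free, drop = FALSE]
      rhs <- -(qf$g[free] + 2 * qf$Q[free, !free, drop = FALSE] %*%
                 pat[!free]) / 2
      xf <- tryCatch(MASS::ginv(Qff) %*% rhs, error = function(e) NULL)
      if (is.null(xf)) next
      if (max(abs(Qff %*% xf - rhs)) > 1e-8 * (1 + max(abs(rhs)))) next
      if (any(abs(xf) > 1 + 1e-9)) next
      x[free] <- clamp(as.numeric(xf), -1, 1)
    }
    cand[[length(cand) + 1L]] <- x
  }
  cand[[length(cand) + 1L]] <- numeric(k)   # the center is always a candidate
  pts <- do.call(rbind, cand)
  vals <- vapply(seq_len(nrow(pts)), function(i)
    qf$c0 + sum(qf$g * pts[i, ]) + drop(pts[i, ] %*% qf$Q %*% pts[i, ]), 0)
  top <- which(vals >= max(vals) - 1e-9 * max(1, abs(max(vals))))
  if (length(top) > 1L) {
    nrm <- rowSums(pts[top, , drop = FALSE]^2)
    top <- top[nrm <= min(nrm) + 1e-12]
    if (length(top) > 1L) {
      o <- do.call(order, as.data.frame(pts[top, , drop = FALSE]))
      top <- top[o[1]]
    }
  }
  out <- pts[top[1], ]
  names(out) <- surface$names
  out
}

#' Maximum-focusing range adjustment
#'
#' The best decoded point becomes the next round's center. Per parameter: if
#' the maximum sits on a bound of the current range (|coded| = 1) the range
#' is widened by 20% (zoom out); if it lies within 25% of the center the
#' range is narrowed by 10% at each bound (zoom in, width x 0.8); otherwise
#' the width is kept. Bounds are then clamped to the parameter floors and
#' ceilings (which may leave the range asymmetric around the center), and
#' ordering constraints are re-checked on the new centers.
#'
#' @param space the current [param_space()].
#' @param best_decoded named list of the best settings (decoded).
#' @param best_coded coded coordinates of the best point.
#' @return list with `space` (the next [param_space()]) and `actions`
#'   (character per parameter: `"zoom_out"`, `"zoom_in"` or `"keep"`).
#' @export
adjust_ranges <- function(space, best_decoded, best_coded) {
  stopifnot(inherits(space, "param_space"))
  nms <- names(space$optimized)
  widths <- space_widths(space)
  actions <- character(length(nms))
  names(actions) <- nms
  new_opt <- space$optimized
  for (i in seq_along(nms)) {
    nm <- nms[i]
    ctr <- best_decoded[[nm]]
    w <- widths[i]
    if (abs(best_coded[i]) >= 1 - 1e-9) {
      w <- w * 1.2; actions[i] <- "zoom_out"
    } else if (abs(best_coded[i]) < 0.25) {
      w <- w * 0.8; actions[i] <- "zoom_in"
    } else actions[i] <- "keep"
    lo <- ctr - w / 2; hi <- ctr + w / 2
    if (nm %in% names(space$floors)) lo <- max(lo, unname(space$floors[nm]))
    if (nm %in% names(space$ceilings)) hi <- min(hi, unname(space$ceilings[nm]))
    if (!(lo < hi))
      stop_isotopt("adjusted range of ", nm, " collapsed to [", lo, ", ", hi,
                   "]; raise its floor/ceiling or fix the parameter")
    new_opt[[nm]] <- c(unname(lo), unname(hi))
  }
  new_space <- param_space(new_opt, fixed = space$fixed,
                           constraints = space$constraints,
                           floors = space$floors, ceilings = space$ceilings)
  ctrs <- space_centers(new_space)
  all_vals <- c(as.list(ctrs), space$fixed)
  for (cn in space$constraints) {
    if (all(cn %in% names(all_vals)) &&
        !(all_vals[[cn[1]]] < all_vals[[cn[2]]]))
      stop_isotopt("adjusted ranges violate ", cn[1], " < ", cn[2],
                   " at the new centers; consider widening the start range ",
                   "of ", cn[2], " or fixing ", cn[1])
  }
  list(space = new_space, actions = actions)
}

#' Run one DoE round
#'
#' Builds the design, evaluates every experiment, fits the response surface
#' on the objective scores, locates the maximum and adjusts the parameter
#' ranges. Decoded settings that violate floors or ordering constraints are
#' not evaluated; they are scored `infeasible_score` (default 0), penalizing
#' that region of the surface. An evaluator error excludes the row from the
#' fit (with a warning); the fit proceeds while at least as many rows as
#' coefficients remain.
#'
#' @param space a [param_space()].
#' @param evaluate function(settings) returning either a single score or a
#'   named numeric vector of score components; must be a pure function of
#'   the settings.
#' @param objective optional function mapping the data frame of evaluated
#'   score components to one numeric score per row (used for the per-round
#'   RGTV normalization); default: first component.
#' @param infeasible_score score assigned to infeasible settings.
#' @return an object of class `doe_result`: the design, per-experiment
#'   `values` (components), `scores`, `status`, the fitted `surface`,
#'   `best_coded`, `best_decoded`, `best_index` (best evaluated experiment),
#'   range `actions` and the `next_space`.
#' @export
run_doe_round <- function(space, evaluate, objective = NULL,
                          infeasible_score = 0) {
  design <- build_design(space)
  n <- nrow(design$coded)
  status <- character(n)
  values <- vector("list", n)
  for (r in seq_len(n)) {
    st <- design$settings[[r]]
    if (!settings_feasible(space, st)) {
      status[r] <- "infeasible"
      next
    }
    v <- tryCatch(evaluate(st), error = function(e) e)
    if (inherits(v, "error")) {
      warning("experiment ", r, " failed: ", conditionMessage(v))
      status[r] <- "error"
    } else {
      status[r] <- "ok"
      values[[r]] <- v
    }
  }
  ok <- status == "ok"
  if (!any(ok)) stop_isotopt("all experiments of the round failed")
  vdf <- as.data.frame(do.call(rbind, values[ok]))
  scores <- rep(NA_real_, n)
  scores[ok] <- if (is.null(objective)) vdf[[1]] else objective(vdf)
  scores[status == "infeasible"] <- infeasible_score
  fit_rows <- !is.na(scores)
  ncoef <- 1 + 2 * ncol(design$coded) + choose(ncol(design$coded), 2)
  if (sum(fit_rows) < ncoef)
    stop_isotopt("only ", sum(fit_rows), " evaluable experiments but the ",
                 "quadratic needs ", ncoef)
  surface <- fit_response_surface(design$coded[fit_rows, , drop = FALSE],
                                  scores[fit_rows])
  best_coded <- locate_maximum(surface)
  best_decoded <- decode_point(space, best_coded)
  adj <- adjust_ranges(space, best_decoded, best_coded)
  best_index <- which(ok)[which.max(scores[ok])]
  structure(list(design = design, values = values, scores = scores,
                 status = status, surface = surface,
                 best_coded = best_coded, best_decoded = best_decoded,
                 best_index = best_index, actions = adj$actions,
                 next_space = adj$space), class = "doe_result")
}
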