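---
title: "Isotopologue-scored optimization of LC-HRMS preprocessing parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopologue-scored optimization of LC-HRMS preprocessing parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotopt)
```

## The problem

Untargeted LC-HRMS preprocessing — peak picking, retention time correction,
feature grouping — is controlled by numeric parameters whose poor settings
silently bias every downstream analysis. `isotopt` optimizes these parameters
without isotope labeling or dilution series, exploiting a signal that is free
in every biological sample: natural ^13^C isotopologues. About 1.1% of carbon
is ^13^C, so every sufficiently intense compound peak must be accompanied by
an M+1 partner at +1.0033548 Da whose intensity is predictable from the
carbon count. A parameter setting that recovers many such parent/partner
pairs is, demonstrably, picking real chromatographic peaks.

## Scores

**Peak picking (PPS).** A peak is a *reliable peak* (RP) when it belongs to
a detected isotopologue pair. A candidate partner must satisfy three
criteria relative to its parent: (1) its m/z lies within `mass_tol_ppm`
(default 10 ppm) of parent m/z + 1.0033548; (2) it co-elutes — the RT
extents overlap and the apex distance is at most `rt_window_frac` (default
0.5) of the parent's RT extent; (3) its intensity lies in
\[IA·I, maxC·IA·I\], where I is the parent intensity, IA = 0.01108 the
natural ^13^C abundance, and maxC the largest carbon count a hydrocarbon ion
of that mass could carry,

$$maxC = \left\lfloor \frac{m/z - 2\,CH_3}{CH_2} \right\rfloor + 2 .$$

Peaks too weak for their isotopologue to clear the instrument's sensitivity
floor should not count against a setting. The floor is estimated as the mean
of the lowest 3% of peak intensities; a non-RP peak whose best-case
isotopologue signal (I · maxC · IA) falls strictly below it is a *low
intensity peak* (LIP). The score is

$$PPS = \frac{RP^2}{\mathrm{all\ peaks} - LIP} .$$

The squared numerator is the optimization force: growing RP and the total
count by the same amount raises PPS, so the optimizer prefers settings that
recover more verifiable peaks rather than merely fewer peaks.

**Retention time correction (RCS).** For each feature group, GRTS is the
mean absolute deviation of member RTs from the group median; ARTS averages
GRTS over groups; RCS = 1/ARTS, so tighter alignment scores higher. A
perfectly aligned round yields ARTS = 0; the resulting infinite RCS is a
sentinel that the per-round normalization pins to the round maximum rather
than propagating into the surface fit.

**Grouping (GS).** Injections of one pooled sample are chemically
identical, so an ideal feature group shows *exactly one peak from each
injection* ("reliable group"). With `GS = reliable^2 / nonreliable`
(denominator treated as 1 when no group is non-reliable), grouping quality is
rewarded quadratically, mirroring PPS.

**Combination (RGTV).** RCS and GS live on unrelated scales, so within one
design round each is unity-normalized over the round's experiments and
summed: `RGTV = norm(RCS) + norm(GS)` in \[0, 2\]. A score constant across
a round normalizes to 0.5 everywhere — it then contributes no ranking
information, which is the intended semantics. Because the normalization is
per-round, RGTV is *not* comparable across rounds; rounds are compared on
the (GS, RCS) pair of their best experiment, lexicographically (GS first,
as the more discrete and more interpretable quantity). This cross-round rule
is a design choice of this package.

## The optimization loop

Parameters are optimized semi-sequentially: picking first (PPS), then
retention time correction and grouping simultaneously (RGTV) on the peak
lists picked once with the winning settings. The simultaneous second stage
is forced by the scores themselves — RCS needs groups, and grouping depends
on corrected RTs; the split saves re-picking inside every alignment
experiment.

Each round is a three-level design over the current parameter box: a
Box-Behnken design for k ≥ 3 (all pairs at (±1, ±1), others at center, plus
one center point — 4·C(k,2)+1 rows), a full 3-level factorial for k = 2, a
sweep for k = 1. One center point suffices because the evaluator is
deterministic; replicated centers would only re-measure the same number. A
full second-order polynomial is least-squares fitted to the scores in coded
units and maximized over the coded cube. The maximizer becomes the next
center ("maximum focusing"), and per parameter: a maximum on a bound widens
the range by 20% (zoom out); a maximum within 25% of the center narrows it
by 10% at each bound (zoom in); otherwise the width is kept. Rounds continue
while the score strictly improves; the global best over all rounds is
returned, guarding against a final degraded round.

### Numerical choices

- **Quadratic maximization.** The fitted quadratic is maximized exactly by
  enumerating the 3^k bound-activity patterns of the box constraint: each
  coordinate is free or pinned at ±1, the stationary point of the free block
  is solved (minimum-norm via pseudo-inverse for flat directions) and kept
  when inside the cube. Ties are broken towards the center (smallest norm,
  then lexicographic), so a constant surface returns the center.
- **Infeasible settings** (e.g. a decoded `min_peakwidth` ≥
  `max_peakwidth`) are not evaluated; they enter the fit with score 0,
  penalizing that region of the surface instead of silently shrinking the
  design.
- **Failed experiments** are excluded from the fit with a warning; the fit
  proceeds while at least as many rows as coefficients remain.
- **Floors and ceilings.** Zooming out is clamped at hard per-parameter
  limits (possibly leaving a range asymmetric around its center): widths and
  tolerances stay positive, `minfrac` stays in (0, 1], and `profStep` has a
  floor of 0.1 Da — below that the dense m/z-by-scan profile matrices grow
  quadratically without improving the scan correlation signal.
- **Rank deficiency** in the surface fit (after dropped rows) sets the
  inestimable coefficients to 0 with a warning rather than aborting.

## Processing backends

The package carries its own parameterized backends so the optimizer has real
machinery to steer; both are deliberately simplified re-implementations of
the standard algorithms, not ports.

**Peak picking** chains centroids of consecutive scans into regions of
interest within `ppm` of the ROI's running mean m/z (an ROI survives one
empty scan; a prefilter requires `prefilter_k` members above `prefilter_I`),
then detects chromatographic peaks with a Mexican-hat CWT over 10
log-spaced scales spanning \[`min_peakwidth`, `max_peakwidth`\]. A detected
peak must exceed the `noise` floor at its apex and show a measured FWHM
inside the peak width window; co-eluting peaks closer than `mzdiff` in m/z
merge, keeping the more intense. Gaussian fitting, m/z-dependent ROI
extension and in-ROI baseline estimation are omitted: the contract is only
that the four public parameters steer detection in the documented
directions, which is what the optimizer exercises. Peak `intensity` is the
apex height, not the integrated area; the same convention feeds the
isotopologue intensity window.

**Alignment** bins each run into an m/z profile (`profStep`), computes
Pearson correlations between scan columns (zero-variance columns score 0),
and extracts a monotone scan correspondence with an affine-gap dynamic
program (`gapInit`/`gapExtend`; ties prefer the diagonal, so self-alignment
is the identity). Peak RTs are rewritten by piecewise-linear interpolation
between matched scans, clamped at the ends. There is no m/z warping and no
alternative similarity family.

**Grouping** slices peaks by m/z (`mzwid`-wide slices, 50% overlap), runs a
Gaussian kernel density over RT (`bw`) per slice, and takes the peaks under
each density maximum (delimited by the surrounding minima) as a candidate
group. Candidates are resolved greedily in descending size so each peak
joins at most one group; a group is kept when at least `minfrac` of the
`n_runs` injections contribute a *distinct* run id — duplicate peaks from
one run never satisfy the fraction, which keeps the reliable-group
definition meaningful.

## The synthetic pooled-sample generator

`generate_runset()` emulates exactly the structure the scores exploit:
Gaussian elution profiles on a regular scan grid, an M+1 trace at
+1.0033548 Da with relative intensity `n_carbons × IA` (exact in the
noiseless limit — the invariant the tests assert), a smooth per-injection RT
drift (linear plus one sinusoid, bounded by `rt_drift_amplitude`; smooth and
invertible like real LC drift), ppm-scale centroid jitter, Poisson noise
centroids, and optional per-injection dropouts. Compounds are drawn with a
minimum separation (resolved in RT or > 0.3 Da apart, isotopologue
positions included) so the ground truth stays unambiguous. The carbon count
defaults to the hydrocarbon-like heuristic `round(mz·0.7/14)` clamped to
\[1, maxC\].

Defaults describe a small but realistic pooled-sample series: 4 injections,
30 compounds over a 7-minute scan range at 1 Hz, apex intensities
10^5–10^6.5, FWHM 20 s ± 25% (real chromatography never produces a single
exact width; the dispersion also gives the peak width parameters a genuine
optimum to find), 30 s drift, 2 ppm jitter, 2 noise centroids per scan.
These sizes keep a full two-stage optimization within a couple of minutes
on one core while leaving every score a non-trivial landscape.

What the generator does *not* emulate: adducts and in-source fragments,
charge states above 1, M+2 and heavier isotopologues (negligible at these
carbon counts, and the detection criteria address single ^13^C partners
only), intensity-dependent mass error, baseline drift and detector
saturation. Tests passing on this generator therefore demonstrate the
correctness and the steering behavior of the machinery, not instrument-grade
performance on real data.

## Worked example

```{r example, eval = FALSE}
sim <- generate_runset(synthetic_config(seed = 1))
report <- run_full_optimization(sim$runset, list(max_rounds = 5))
report$score_table
report$best_settings$picking[c("min_peakwidth", "max_peakwidth", "ppm")]
```

On this fixture the start-center settings (peak width 20–50 s) truncate the
narrower peaks and PPS roughly triples after optimization, with the
optimized peak width bracket containing the true 20 s; after alignment and
grouping optimization every true ion trace forms one complete group
(non-reliable count 0) and ARTS drops well below the uncorrected value.
`scripts/acceptance.R` reproduces these numbers from scratch.

## Limitations

- The backends are intentionally minimal; absolute peak counts and scores
  are not comparable to any specific external software, only the parameter
  *response* is meant to be faithful.
- PPS pools RP/LIP counts over all runs before applying the formula (one
  scalar per experiment); per-file PPS combination is a plausible
  alternative the package does not implement.
- Charge 1 is assumed throughout the isotopologue criteria.
- RGTV's cross-round comparison is defined here lexicographically on
  (GS, RCS); other monotone combinations are defensible.
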