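---
title: "Methods: receptive-field statistics and tuning stability in the L2/3 whisker map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptive-field statistics and tuning stability in the L2/3 whisker map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Layer 2/3 of mouse whisker somatosensory cortex carries a *salt-and-pepper*
somatotopic map: neurons tuned to different whiskers are spatially
intermixed within each anatomical (barrel) column. Quantifying that map
from two-photon calcium imaging raises a chain of statistical questions —
which cells respond at all, which whisker each cell prefers, how tuning is
laid out relative to column anatomy, whether co-tuned cells cluster at the
micrometre scale, and whether single-cell tuning is stable across days.
whiskermap implements that chain as a tidy, testable pipeline, together
with a synthetic-data generator so that every stage can be validated
against known ground truth.

The experimental design assumed throughout: on each trial one of nine
whiskers (rows C–E, arcs 1–3, a 3×3 grid centred on D2) is deflected, or an
all-whisker stimulus, a tone, or nothing (a blank). The per-trial activity
measure is the evoked ΔF/F — the mean over a 0–1000 ms post-stimulus window
minus the mean over a 0–500 ms pre-stimulus baseline — and trials with
licking are excluded before any analysis.

## Responsiveness: permutation test with FDR control

For each cell and each single whisker, the test statistic is the
difference between the mean single-trial evoked ΔF/F on that whisker's
trials and on blank trials. The null distribution is built by shuffling
trials between the two sets (`n_permutations`, default 10,000) and
recomputing the difference. Monte-Carlo p-values use the add-one
convention $p = (1+k)/(1+N)$, which cannot return zero and is slightly
conservative. Positive and negative responses are two one-sided tests;
they are pooled into one two-sided decision per stimulus
($p = \min(1, 2\min(p_+, p_-))$, sign recorded) so that each stimulus
yields a single call, and Benjamini–Hochberg correction at $q = 0.05$ is
applied across the nine single whiskers within each cell. The raw
one-sided p-values are kept in the profile for analyses that need them.
A cell is *responsive* if at least one whisker has a significant positive
response; cells with only significant negative responses are classed
`negative_only` and excluded downstream, as are non-significant cells.
The BH family is the nine single whiskers only — tone and all-whisker
stimuli are carried through filtering but take no part in receptive-field
statistics (a documented choice; the set of stimuli entering the
correction is a genuine free parameter of designs like this one).

A note on the permutation engine (`src/perm.cpp`): summation order differs
between permutations, so statistics that are exact ties of the observed
value can drift by a few machine epsilons. Ties are counted with a
tolerance of $10^{-9}(1+|t_{obs}|)$, which is conservative and is required
for the engine to agree with exhaustive enumeration on small inputs (an
invariant the test suite enforces on every fixture with ≤ 10 trials).

## Tuning metrics

With $R_w$ the mean evoked ΔF/F to whisker $w$:

* **BW / eBW.** The best whisker is the significant-positive whisker with
  the largest mean (ties: smaller p, then fixed grid order). Equivalent
  best whiskers are significant whiskers whose trials are not
  distinguishable from the BW's by a two-sided permutation test at
  $\alpha = 0.05$, uncorrected across the ≤ 8 candidates ($\alpha$ and
  multiplicity here are unstated in the field's descriptions; uncorrected
  testing at 0.05 is the more conservative choice *against* broad tuning
  and is exposed in code). Cells with $|eBW| > 1$ are broadly tuned; the
  nominal BW used by ensemble and stability analyses is always the
  max-mean whisker, a deterministic rule.
* **Sharpness.** $(R_{BW} - \bar R_W)/(R_{BW} + \bar R_W)$ with negative
  per-whisker means zeroed inside $\bar R_W$ (the mean over the other
  eight whiskers); lives in $[0, 1]$.
* **CW preference.** Same formula centred on the columnar whisker.
* **CWDI.** $(R_{CW} - R_{SW^*})/|R_{CW} + R_{SW^*}|$ on *raw* means,
  where $SW^*$ is the strongest surround whisker. Raw (un-zeroed) means
  are used deliberately: values above 1 (negative strongest surround) and
  below 0 (negative CW response) are informative and expected.
* **Tuning CoM.** Response-weighted centroid on the 3×3 grid (arc → x,
  row → y, C = 0/D = 1/E = 2, unit spacing), negatives zeroed.
* **Columnar class.** A columnar cell is `nonCW_tuned` only when its BW
  differs from the CW *and* the BW's trials beat the CW's trials in a
  one-sided permutation test at $\alpha$; otherwise `CW_tuned`. The rule
  is conservative by design — ambiguous cells count as columnar.

Negative responses are therefore retained in rank-ordered tuning curves
and CWDI, and zeroed in sharpness, CW preference, CoM, and signal
correlation. This split is applied consistently everywhere.

## The normalized column frame

Cells from different imaging fields are pooled in a polar frame per
reference column: radius is the centroid-to-cell distance divided by the
centroid-to-boundary distance *along the same ray* (so radius 1 is the
boundary in every direction, whatever the boundary's shape), and angle is
mapped piecewise-linearly so the eight centroid-to-neighbour-centroid
vectors land on the canonical 45° sectors. Radius is invariant to global
translation and rotation of the map. Column membership is
point-in-polygon; cells outside all polygons but within 1.25 radii of some
column are septal; farther cells are excluded. Where a concave
histological boundary is crossed twice by a ray, the nearest intersection
is used. The absolute rotation of the angular frame is a convention (the
synthetic maps define the lattice axes explicitly).

## Cluster analysis

Tuning similarity of co-columnar responsive pairs is measured three ways —
signal correlation (Pearson on zero-negative 9-vectors), ΔCoM distance,
and shared-BW identity — plus BW-magnitude similarity
$|R_a - R_b| / |R_a + R_b|$. Profiles are binned by inter-soma distance in
half-open 10 µm bins ($[k\cdot 10, (k+1)\cdot 10)$; a pair at exactly
10.0 µm is in the second bin). Two null models:

* **Spatial shuffle.** Cell positions are permuted within each column
  (10,000 iterations), preserving the multiset of positions and of tuning
  vectors; per-bin percentile CIs describe a map with random intermixing.
* **Regression extrapolation.** An OLS line fitted to pair-level points
  over 30–200 µm is extrapolated to the centres of the bins at ≤ 20 µm;
  each bin's mean is bootstrapped (resampling pairs with replacement) and
  the one-sided p is the add-one fraction of bootstrap means on the
  expected side of the line, BH-corrected across tested bins. The fit is
  on pair-level points rather than bin means to avoid weighting sparse
  bins equally with dense ones (bin-mean fitting is available via
  `fit_on = "bins"`). The expected side is `"greater"` for correlation-type
  metrics and `"less"` for ΔCoM, where clustering lowers the metric.

The per-cell **cluster index** is the mean signal correlation with
responsive neighbours closer than 20 µm, `NA` when no such neighbour
exists. Pairs are never formed across imaging fields. The two sub-20 µm
bins are tested separately (two p-values per metric), not pooled.

## Longitudinal stability

For a cell responsive in both sessions of a pair:

1. **ΔBW test.** The BW has changed when some whisker's session-$j$
   trials are significantly stronger than the prior BW's session-$j$
   trials (one-sided permutation test at $\alpha$) — equivalently, the
   prior BW is no longer an eBW. Candidates are tested uncorrected by
   default (the conservative direction is genuinely unclear: correction
   misses true changes, no correction inflates them slightly; both are
   exposed, and the within-session control below shows the default is
   calibrated). The new BW is the session-$j$ max-mean whisker.
2. **ΔCoM test** (only when the BW is stable). The observed statistic is
   the Euclidean distance between the two sessions' CoMs. The null
   shuffles single trials of the same whisker between sessions, preserving
   per-session trial counts, and recomputes ΔCoM (10,000 iterations);
   change is declared above the null's 95th percentile (one-sided; a
   two-sided switch uses the 97.5th). Whiskers sampled in only one
   session are excluded from both CoMs.

A cell is *stable* when neither test fires; `delta_bw` and `delta_com` are
mutually exclusive by construction. Responsiveness transitions
(`stable_nonresponsive` / `gained` / `lost` / `stable_responsive`) come
from the per-session FDR-corrected calls, made independently per session.
Interval classes Δ1/Δ2/Δ3 are session-index differences (calendar dates,
where present, are metadata). Because a cell imaged in four sessions
contributes three Δ1 and two Δ2 records, summary quantities are
subsampled: each of 1000 repetitions draws one record per cell per
interval class and the percentile 95% CI over repetitions is reported.

The **within-session control** splits one session into alternate-trial or
first/second-half pseudo-sessions and runs the same two tests; since both
halves sample the same stationary tuning, the flagged fraction estimates
the false-positive rate and should sit near $\alpha$. The test suite
checks 5% ± 2.5 percentage points at 500 cells, both within-session and
across drift-free simulated sessions.

**Change prediction.** A binomial GLM (logit link) predicts tuning change
from map location (distance from the cell to its session-1 BW column
centre, in column radii), initial sharpness, BW response magnitude, and
cluster index (the last omitted for the responsiveness-change outcome),
with stratified 10-fold cross-validation (per-fold deviance and rank-based
AUC). Predictors are standardized so coefficient magnitudes are
comparable. Cells without a cluster index receive the population median
plus a missingness indicator — imputation keeps them in the model without
letting the indicator masquerade as the index itself. Quasi-complete
separation aborts with an explicit error rather than returning runaway
coefficients.

## The synthetic generator

`sim_config()` defaults are the study conditions the analyses assume, and
they are fixed rather than tuned per run:

* **Map.** Nine regular hexagonal columns (apothem 125 µm) on a 300 µm
  lattice, D2 at the origin; the gaps are septa. Real barrel boundaries
  are irregular histological polygons — the map readers accept arbitrary
  simple polygons, and all geometry uses the ray-intersection radius, so
  nothing downstream depends on hexagonal symmetry.
* **Cells.** Positions uniform within the 1.25-radius inclusion zone;
  30% responsive; among columnar responsive cells 52% are CW-tuned, the
  rest peak at a grid-adjacent whisker. A radial gradient
  (`gradient_strength`) tilts the CW probability toward the column centre
  and a cluster field (`cluster_scale` = 20 µm) lets cells adopt a near
  neighbour's peak, reproducing sub-columnar gradients and local co-tuned
  clusters.
* **Tuning surfaces.** Single-peak: amplitude lognormal around 0.4 ΔF/F,
  geometric falloff 0.35 per grid step (Chebyshev distance), giving
  sharpness values around 0.6–0.8. A quarter of responsive cells carry
  one suppressed far whisker with a small negative mean (−0.05), so the
  negative-response rules are exercised.
* **Noise.** Evoked ΔF/F = true mean × lognormal trial gain (log-SD 0.5)
  plus additive Gaussian blank noise (SD 0.08); blanks draw the additive
  part only. No distributional form is prescribed by the source
  measurements, so this is a calibration choice: with the default 40
  trials per whisker and 100 blanks per session it yields ≈ 20–30% of
  cells passing the responsiveness test and realistic single-trial
  response fractions. (Real sessions spread ~900–1000 trials over 13
  stimulus types; 40/whisker + 100 blanks matches that budget for the
  trials the analyses actually consume.)
* **Drift.** Per interval, non-CW cells shift their peak with probability
  0.3 and CW cells with 0.05 — the concentration of instability in the
  non-columnar surround. Shifts are one grid step and *bounded*: a cell
  at its base peak moves to a random adjacent whisker; an already-shifted
  cell returns to its base. Every move is adjacent to its predecessor,
  yet the surface never walks away from base, so ΔCoM magnitude does not
  grow with interval length — bounded instability, not unbounded drift.
  Non-shifting cells may receive a bounded BW-preserving perturbation of
  the surround (`com_jitter_prob` = 0.15), producing ΔCoM-class changes.
* **Wavering.** Per-session responsiveness dropout is amplitude gating
  (the cell's surface scaled to zero with probability 0.15), not roster
  removal, so cross-session identity is untouched.

What the generator does *not* emulate: calcium indicator dynamics and
temporal trace shape (trials carry evoked scalars; `compute_evoked()`
handles frame-resolved traces when present), behavioural state
fluctuations, neuropil contamination, registration error, and
multi-whisker combination stimuli. Passing tests on synthetic data
therefore validate the statistical machinery — calibration, power,
geometry, bookkeeping — not the upstream imaging pipeline.

## Numerical and design choices worth knowing

* All stochastic operations accept a seed; the configuration (with seed)
  travels on every result (`result_config()`), and `run_pipeline()` gives
  each stage its own seed stream derived from the master seed, so stages
  can be rerun independently and byte-identically.
* Distance bins and frame windows are half-open; the single-trial
  criterion (evoked > blank mean + 1 SD) is a strict inequality; blank SD
  uses the $n-1$ denominator.
* Degenerate inputs return `NA` (CWDI with zero denominator, sharpness
  with non-positive BW response, CoM with no positive mean, correlation
  of a zero-variance vector) rather than ±Inf.
* Gradient regression reports $p = 1$ for constant outcomes and a
  below-machine-floor p for exact lines instead of dividing by a zero
  standard error.
* Test-suite problem sizes (500 cells for calibration, 1000 for the FDR
  null, 2000-iteration nulls, 200 cluster replicates at 350 cells with
  400 bootstrap draws) were chosen as the smallest sizes at which the
  binomial error bands in the checks are meaningful.

## Known limitations

* Detection power for a one-step BW shift at the default noise level is
  ≈ 0.9, so estimated change fractions sit slightly below the injected
  fraction at high drift rates (false positives no longer compensate).
* The spatial-shuffle null and cluster-excess test assume column
  assignments are correct; mis-registered boundaries would blur, not
  bias, the clustering signal.
* The cluster-field construction (neighbour adoption in one random pass)
  produces local co-tuning but not a literal microcolumn geometry; its
  `cluster_scale` is an effective, not anatomical, parameter.
* `magnitude_similarity` is a *difference* index (0 = identical
  magnitudes); its name follows the field's usage, not its sign.
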