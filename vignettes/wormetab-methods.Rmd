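---
title: "Methods: NMR metabolomics chemometrics in wormetab"
author: "wormetab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR metabolomics chemometrics in wormetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures it implements, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The analysis problem

A 1D ¹H NMR spectrum of a polar tissue extract is a superposition of
metabolite resonances on a chemical-shift axis (ppm). An exposure study
yields tens of such spectra in dosed and control groups; the analytical
question is whether and how the metabolome differs between groups, and
which resonances, metabolites, and pathways carry the difference. The
chain implemented here is the standard chemometric answer: reduce each
spectrum to a bin vector, remove nuisance scale variation, model class
membership multivariately with honest validation, and then read the
result back at the metabolite and pathway level.

## Preprocessing

**Baseline offset.** Spectra are assumed phase- and baseline-corrected
upstream except for a residual constant offset, which
`correct_baseline()` estimates as a low quantile (default: the median) of
each spectrum's intensities — in a 1D spectrum most grid points carry no
peak, so the median sits on the baseline. Interactive baseline polishing
is deliberately out of scope.

**Water exclusion.** `exclude_region(set, 4.70, 5.25)` drops the
residual water signal and its affected neighborhood before any
statistics; excluded intervals are remembered so no later bin can span
them.

**Adaptive binning.** `adaptive_bin()` segments 0.2–8.8 ppm into bins
with a target *average* width of 0.015 ppm. Boundaries are placed at
local minima of the Savitzky–Golay-smoothed (3rd order, window matched to
the target width) mean spectrum, so multiplets are not cut mid-peak;
minima closer than half the target width are merged, and stretches longer
than twice the target width without a minimum are split uniformly. Bin
values are trapezoidal integrals over half-open intervals `[lo, hi)`,
evaluated from an interpolated cumulative integral so the bins are
exactly additive: their sum reproduces the total integral of the binned
range. Published descriptions of adaptive binning leave the algorithm
underdetermined (the cited implementations differ in smoothing and
splitting details, and at least one is wavelet-based); the local-minima
variant here was chosen because every step of it is specifiable and
testable. On a featureless spectrum it degrades gracefully to uniform
0.015-ppm bins (≈537 of them over the default range).

**Probability quotient normalization.** Sample loading and extraction
dilute spectra by per-sample factors. `pqn_normalize()` first scales each
sample to the reference's total integral, then divides by the median of
the bin-wise ratios to the reference. The reference defaults to the
per-bin median spectrum of all samples; a per-group reference or a frozen
numeric reference can be supplied. Two numerical choices matter:

- *Noise floor.* The quotient median runs only over bins whose reference
  value exceeds 5% of the mean positive reference level. Signal-free
  bins integrate arbitrarily close to zero with either sign, so their
  ratios are meaningless and, left in, would dominate the median. For
  the same reason the textbook precondition "reference positive on half
  the bins" is applied to these signal bins rather than to all bins:
  with zero-mean noise roughly half of the *empty* bins are negative in
  any real binned spectrum.
- *Idempotence.* With a frozen reference, re-normalizing the output
  reproduces it exactly (the operation is a fixed point). With a
  data-derived median reference, the reference itself moves after
  normalization, so a second pass is only approximately a no-op; the
  residual factors stay within a few percent under realistic variation
  and are exactly 1 when samples differ by pure scaling. Both properties
  are tested.

The stored quotients (total-area step × median quotient) estimate
relative dilution; on synthetic studies they are checked against the
generator's true dilution factors.

**Centering.** `mean_center()` subtracts column means and keeps them, so
loadings can be back-transformed to the intensity scale.

## Multivariate modelling

**OSC.** `osc_filter()` removes components of the centered bin matrix
orthogonal to class membership. Per component: start from the first
principal-component score, project it onto the orthogonal complement of
the dummy class matrix **Y**, regress **X** on the score for a weight
vector, and iterate to a fixed point (tolerance 1e-8, at most 100
iterations; non-convergence is flagged and reported, not fatal — the
fixed-point iteration converges slowly on weakly structured data). The
final score is re-projected so its orthogonality to **Y** is exact by
construction, then its loading is deflated from **X**. Weights are kept
so the identical correction can be applied to held-out samples. One
component is removed by default; the appropriate number is not derivable
from theory and one is the most conservative choice.

**PLS-DA.** `plsda_fit()` is NIPALS PLS2 with deflation of **X** only,
on the dummy-coded, internally centered class matrix. Successive scores
are mutually orthogonal, R²Y is non-decreasing in the number of
components, and all score/weight vectors carry a deterministic sign
convention (largest-magnitude element positive) so outputs are
reproducible bit for bit. An independent PLS implementation (mixOmics,
regression mode) is used in the test suite as an equivalence oracle;
it is never the implementation.

**Cross-validation.** `cross_validate_q2()` implements repeated
stratified two-fold cross-validation: per repeat, each group is split in
half at random; each half is predicted from a model fit on the other.
PRESS is pooled over all folds and repeats, and
Q²Y = 1 − PRESS/SS_total. Centering and OSC are re-fit inside each
training fold only — applying OSC to the full matrix before CV leaks
label information and inflates Q²Y. Because published workflows are
often silent on this point, the leaky variant can be reproduced by
filtering first and cross-validating with `n_osc = 0`, but the default
is leakage-free. Fifty repeats is the default; the Q²Y > 0.5
significance convention is used throughout.

**Permutation testing.** `permutation_test()` permutes the class labels
`n_perm` times (default 2000) and recomputes the cross-validated Q²Y for
each relabeling; 7 CV repeats are used per permutation — and for the
observed statistic, so the comparison is like-for-like — keeping 2000
permutations tractable on one core. The p-value is
(1 + #{null ≥ observed}) / (n_perm + 1), which cannot be zero and has
floor 1/2001 ≈ 5e-04 at 2000 permutations. Q²Y was chosen as the
permutation statistic because it is the validation quantity the rest of
the workflow emphasizes. Calibration under the null (super-uniformity)
is part of the acceptance suite.

**Variable influence.** `splot()` reports per-bin covariance and
correlation with the first predictive score; `correlation_loadings()`
renders the covariance as a pseudo-spectrum colored by |r| with a
significance cutoff from inverting the t distribution
(r = t / √(t² + df), df = n − 2), restricted to display windows
(default 0.4–4.3 and 5.7–9.4 ppm) that skip the water gap. Score plots
draw a 95% Hotelling T² ellipse; this is a rendering convention, not an
inferential claim, and a bivariate-normal ellipse would be equally
defensible.

## STOCSY

`stocsy_1d()` correlates a driver bin's intensities with every bin
across samples, on the normalized, *uncentered* matrix — Pearson
correlation centers internally, and keeping the matrix uncentered leaves
the covariances on the intensity scale. Resonances of one molecule share
a concentration and correlate near 1; the 2D variant returns the full
correlation matrix (with a feature-count guard against accidental huge
allocations). Drivers resolve to the half-open bin containing them, so
ties are impossible.

## Univariate layer

Metabolite integrals sum the bins whose midpoints fall into the
assignment windows of each metabolite (windows are consumed from a CSV
or derived from the synthetic library). Fold change is the ratio of
group means (dosed/control); the test is the pooled two-sided Student t
(Welch is available but the pooled form is the stated convention);
q-values are Benjamini–Hochberg, adjusted *within* one treated-vs-control
comparison across metabolites, matching the per-column reading of a
fold-change table. Significance stars follow the raw p thresholds
0.05/0.01/0.001 — star legends conventionally refer to raw p — while q
is always reported alongside; both choices are flags.

## Pathway analysis

For a set of affected metabolites, each pathway graph (undirected,
unweighted compound graph; KEGG edge direction is deliberately not
modeled) yields (i) a hypergeometric upper-tail p-value for
over-representation against the compound universe and (ii) a topology
impact: the sum over hit compounds of relative betweenness centrality,
i.e. node betweenness normalized to sum to 1 across the pathway. When
every node has zero betweenness (complete graphs, isolated pairs) the
importance falls back to uniform, so impact remains defined. The
normalization denominator is the *sum* of centralities rather than the
maximum; summing makes impact = 1 exactly when all compounds are hit.
The universe defaults to the union of library compounds and can be set
to the detected-metabolite list, mirroring the reference-metabolome
option of pathway-analysis tools. Holm and BH adjustments across the
library are included. A bundled toy library (chain, cycle, star, tree,
clique, two-component graphs over common metabolites) supports tests and
demos; real libraries are read from edge-list CSVs.

## Bioaccumulation

BAF = tissue metal concentration (mg/kg dry weight) / soil metal
concentration (mg/kg); tables are reported to 3 decimals, matching the
precision of the published values the test suite checks against.
Survival is 1 − deaths/initial. Group-mean concentrations are consumed
directly (per-worm replicates can be averaged upstream); the bundled
`metal_exposure_means()` table carries the published group means used by
the acceptance checks.

## The synthetic-data generator

`simulate_study()` renders each sample as

intensity(δ) = dilution × Σ_m conc_m × Σ_lines area × Lorentzian(δ; center + jitter_m, γ) + baseline + noise

with, per sample: log-normal concentrations around base × fold(group),
a log-normal global dilution factor, per-metabolite (not per-line)
chemical-shift jitter so multiplet structure is preserved, a constant
baseline offset, and additive Gaussian noise. The Lorentzian is the
natural NMR line shape; `linewidth_ppm` is the full width at half
maximum (default 0.002 ppm, γ = 0.001). A single master seed spawns
named substreams (concentrations, dilutions, jitter, baseline, noise) so
switching one noise source on or off does not perturb the others.

Defaults were fixed once as the package's study conditions:
σ_log(concentration) = 0.15 (positive, multiplicative within-group
biological variation — the studies this emulates do not report a value,
and 15% is a typical metabolomics figure), σ_log(dilution) = 0.1,
jitter sd = 0.001 ppm, noise sd = 0.5 intensity units (signal-to-noise
of a few hundred against typical simulated peak heights, consistent with
modern 500 MHz extract spectra), baseline offset sd = 0.2. The default
grid is 0.0–10.0 ppm at 2¹⁴ points.

What the generator does *not* emulate: true J-coupling physics (multiplet
splittings are fixed input values, not field-dependent), peak overlap
beyond what the chosen shift table produces, water and solvent signals,
phase errors, baseline curvature, and vendor FID formats. Consequently,
passing tests demonstrate correctness of the statistical machinery under
a faithful statistical model of binned NMR data — not robustness to
acquisition artifacts that upstream processing is assumed to have
handled. One consequence is visible in the tests: where the library
places genuinely overlapping multiplets (the 0.94–1.04 ppm
leucine/isoleucine/valine region), metabolite integrals cross-talk and
their correlation with true concentrations drops — exactly as in real
crowded spectra — so the per-metabolite recovery checks assert tightly
only for resolved resonances.

## Problem sizes and determinism

The statistical acceptance checks run, per claim: 2000 permutations of a
30 × 120 two-class matrix; 200 null datasets (n = 16, p = 60) at 199
permutations each; and 20-seed suites of full generator studies
(10 samples/group, 30-metabolite library) for the Q²Y threshold,
parameter recovery, dilution recovery, and STOCSY claims. These sizes
are the package's chosen compromise between statistical resolution and a
desk-scale run; all seeds are fixed in code, and every pipeline artifact
is hashed so a config snapshot plus the package version reproduces a run
exactly.

## Known limitations

- PQN absorbs part of a large, asymmetric treatment effect into the
  normalization (the classic normalization/effect confound): with few
  metabolites and strong folds, unaffected metabolites show small
  apparent counter-changes and estimated folds shrink toward 1. With a
  realistic library size the bias is small, but fold values near the
  significance boundary should be read with this in mind.
- The adaptive-binning boundary rule is one defensible member of a
  family; bin counts (not totals) depend on the smoothing window.
- OSC-then-PLS is not O-PLS: the orthogonal filter and the predictive
  model are estimated sequentially, not jointly.
- Pathway impact treats compound graphs as undirected and unweighted;
  reaction directionality and stoichiometry are out of scope.
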