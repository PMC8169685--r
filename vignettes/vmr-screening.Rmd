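---
title: "Methods: scotopic VMR drug-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scotopic VMR drug-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmrscreen)
```

## The assay and its readout

Larval zebrafish startle when the light goes out: the scotopic visual motor
response (VMR) is a burst of locomotion in the seconds after light offset,
measured as per-second displacement (cm) of one larva per well of a 96-well
plate. In a rod-degeneration model (a truncating rhodopsin mutation, Q344X,
expressed in rods), dim-light vision is lost and the light-off burst under a
0.01 lx stimulus collapses — wild-type larvae move about 0.281 cm in the first
second after offset, mutants about 0.127 cm. A drug that restores the mutant
light-off VMR is a candidate vision-restoring treatment; that is the screen
this package implements, together with the statistics used around it.

The stimulus protocol is 30 min dark acclimation, 60 min scotopic light at
0.01 lx, then light off for 5 min, with the single light-off event as the
analysis anchor. The scotopic intensity comes from stacking neutral-density
filters: each transmits ~40%, so seven filters attenuate the 3.2 µW cm⁻²
source to `3.2 * 0.4^7 ≈ 0.005` µW cm⁻² (`attenuated_intensity()`). The two
analysis windows are the first post-offset second (immediate response,
dimension p = 1) and seconds 1–30 after offset (sustained response, p = 30);
offsets are 1-based inclusive, so "1 to 30 s" is exactly 30 columns, matching
the F-test degrees of freedom the screen quotes.

## The generative model

`simulate_plate()` draws per-second displacement as

d(w, t) = max(0, b_w + β_batch + γ_well + A_w · exp(−(t − t_off − 1)/τ) · 1[t > t_off] + ε)

* b_w — per-larva dark baseline, Normal(`baseline_rate` = 0.05 cm/s,
  `baseline_dispersion` = 0.02);
* β_batch — additive batch (biological replicate) effect, Normal(0,
  `batch_sd` = 0.01);
* γ_well — additive well-position effect, linear in plate column and centred
  (a lamp-inhomogeneity proxy), scale `well_sd` = 0.02;
* A_w — per-larva startle amplitude, Normal(mean amplitude, `startle_sd`),
  drawn once per larva; τ — exponential decay constant, default 1.5 s;
* ε — per-second measurement noise, Normal(0, `noise_sd` = 0.02);
* dead larvae (drug lethality) emit near-zero displacement throughout.

Everything is clipped at zero, as a tracking camera reports no negative
displacement. The clipping matters for calibration: the `"WT"` and `"Q344X"`
presets solve the truncated-Gaussian mean identity
E[max(0, N(µ, σ))] = µΦ(µ/σ) + σφ(µ/σ) for the amplitude so that the
*clipped* expected displacement at offset+1 s equals the published group
means (0.281 / 0.127 cm) exactly, rather than undershooting by the truncation
bias. The startle heterogeneity defaults (`startle_sd` 0.150 for WT, 0.128
for Q344X) are sized so an 18-larva sample has a standard error near the
published 0.036 / 0.031 cm. The published mean ± s.e.m. is the only variance
information available, and it is larva-level: we read the N = 18 with its
Welch df ≈ 33 as two groups of ~18 individuals, and keep the batch effect a
separate, smaller term (0.01 cm). Treating the published s.e.m. as the spread
of 18 *batch means* would instead force a batch sd near 0.15 cm, under which
no 864-larva simulation could pin the grand mean to ±0.02 cm — the
calibration the package (and its acceptance checks) rely on.

A drug effect is two multipliers and a lethality: the amplitude multiplier
scales the *mean* amplitude (heterogeneity stays a property of the larvae),
the τ multiplier stretches the decay — a sustained response, the signature of
the screen's positive control, is τ × 3–5 — and lethality is the per-larva
death probability used for planted toxic compounds (default 0.9 at screening
dose). `simulate_screen()` assembles a whole screen: vehicle (DMSO) batches
of 48 larvae, each drug at 24 larvae in two replicate batches that share the
batch effects with their vehicle controls, plus a ground-truth table.

What the generator does *not* emulate: light-onset startles, habituation and
circadian drift, non-Gaussian burst kinematics, within-well tracking
artifacts, and any correlation between baseline activity and startle
amplitude. Passing tests therefore certify the analysis machinery on data
with the assumed additive structure, not the idiosyncrasies of real tracking
exports.

## Normalization

Raw traces are normalized for baseline activity, per-well light-intensity
variation and batch effect, then shifted by one global offset so nothing is
negative. `fit_normalization()` regresses baseline-window displacement (the
full dark-acclimation segment — never post-stimulus seconds, so treatment
effects cannot be absorbed) on additive batch and well-position factors by
OLS; the per-larva baseline is the larva's mean residual. Because both
factors are constant within a larva and all larvae share one balanced time
grid, fitting on per-larva baseline means is algebraically identical to
row-level OLS (the tests assert this against a raw normal-equations solve)
and far cheaper. Subtracting fitted batch + well + larva baseline and adding
`offset = max(0, −min(adjusted))` yields activity that is exactly zero at its
binding minimum and non-negative everywhere on the data the model saw.
Rank-deficient designs (a single batch, aliased levels) drop the
non-estimable term with a warning. Unseen batch, well or larva levels are an
error rather than a silent extrapolation.

The reference describing the original regression design is not reproduced in
detail anywhere we can check, so this module fixes the smallest model with
the three stated corrections and documents it; exact numeric parity with the
original scripts is out of scope.

## The two-sample tests

**Hotelling's T²** (`hotelling_t2()`) compares mean displacement vectors over
a window using the pooled covariance, converted as
F = (n₁+n₂−p−1) / (p(n₁+n₂−2)) · T² ~ F(p, n₁+n₂−p−1). It requires
p ≤ n₁+n₂−2; the 30-s window with 24-larva groups satisfies this against
48-larva controls. A singular pooled covariance is an explicit error (an
optional ridge is available and recorded in the result); a zero mean
difference short-circuits to T² = 0, p = 1, which is the correct value of the
quadratic form however ill-conditioned the covariance. At p = 1 the statistic
collapses to the squared pooled-variance t — the suite checks this identity,
a brute-force oracle with explicit inverses, and affine invariance.

**The high-dimensional test** (`hd_two_sample_test()`) covers p > n, where
the pooled covariance cannot be inverted: the statistic is the largest
studentized coordinate-wise mean difference,
T_HD = max_j |x̄_j − ȳ_j| / √(s²₁ⱼ/n₁ + s²₂ⱼ/n₂). Its null distribution is
calibrated by resampling with a mandatory seed. Two schemes are provided:

* **permutation** (default): group labels are randomly reassigned and the
  full studentized statistic recomputed, B = 1000 times; the p-value is
  (1 + #{T* ≥ T}) / (B + 1). Under the null the two groups are exchangeable,
  so this is exact up to resampling granularity.
* **multiplier**: a Gaussian multiplier bootstrap of the group-centred data
  with the scale correction √(n(n−1)), the classical
  high-dimensional-CLT construction.

Permutation is the default because of how the screen *uses* this test. The
replicate-consistency criterion reads a LARGE p-value (> 0.9) as evidence of
similarity, which leans on the entire null distribution of p, not just the
rejection tail. At the screen's operating point (n = 24 per group, p = 30)
the multiplier bootstrap is visibly miscalibrated — in our null simulations
its type-I error is ~0.10 at α = 0.05 in the plain form, and its
P(p > 0.9) is ~0.05 after scale correction — while the permutation scheme
gives type-I ≈ 0.05 and P(p > 0.9) ≈ 0.10 as a uniform null requires. With
24+24 observations there are ~1.6 × 10¹³ distinct label assignments, so
B = 1000 random permutations carry no meaningful discreteness penalty.

Supporting tests are thin, explicit wrappers over base R: Welch's t
(`welch_t()`), Pearson's χ² without continuity correction
(`pearson_chi2_2x2()` — only the uncorrected statistic reproduces both
published rod-phenotype values 4.09 and 5.33, and the three-level
Strong/Intermediate/Weak tables collapse to the two observed categories,
hence df = 1), and one-way ANOVA with pooled-variance pairwise t-tests
adjusted by Benjamini–Hochberg (`anova_pairwise_fdr()`).

## Hit calling

`run_screen()` applies the funnel per drug and window:

1. **Toxicity** (raw traces): a larva is dead if its total recording
   displacement is below 5% of the vehicle-median total; a drug is toxic if
   more than half its larvae are dead in *any* replicate. The underlying
   study states only the toxic count, not the rule; this one is concrete,
   configurable, and flags a 60%-lethal drug in ≈ 96% of realizations
   (per-replicate OR), where a pooled-replicate rule would sit near 88%.
2. **Replicate consistency** (normalized windows): `hd_two_sample_test()` on
   replicate 1 vs replicate 2; pass iff p > 0.9, strictly — a p of exactly
   0.9 fails. Consistency is evaluated per window.
3. **Significance vs vehicle**: Hotelling's T² against same-batch DMSO
   controls; by default each replicate must reject at α = 0.05 (strict),
   mirroring the per-replicate statistics the original analysis quotes; a
   pooled mode is available. Whether consistency should use raw or
   normalized vectors is not documented in the source analysis; we use
   normalized (the same data the significance test sees) and expose
   `normalize = FALSE`.

A hit is non-toxic ∧ consistent ∧ significant. `summarize_screen()` returns
the funnel counts (starting ≥ non-toxic ≥ consistent ≥ hits per window),
which is monotone by construction.

**A calibrated caveat.** The consistency criterion is a similarity lottery:
for any drug whose two replicates genuinely follow the same distribution — in
particular every well-behaved true hit — the consistency p-value is uniform
on (0, 1), so the pass probability is ~0.10 no matter how strong or
reproducible the drug's effect is. The published funnel itself shows the
pattern (4–5 of 68 non-toxic drugs "consistent" ≈ 6–7%, about the uniform
rate). A calibrated implementation cannot make a planted hit pass this filter
9 times out of 10; it passes ~1 in 10, and conditional on passing it is
essentially always significant. The end-to-end expectations in our acceptance
suite state the stronger recovery property and are left failing with this
analysis on record, because the alternative — a test whose null p-values pile
up near 1 — would be a broken test, not a better screen. Users who want a
reproducibility filter with power should test *each replicate against
vehicle* and require concordant rejections, rather than thresholding a
similarity p-value.

## Dose-response

`normalize_luminescence()` divides every reading by its experiment's maximum
per-dose mean (the best dose level averages to 1; the operation is
idempotent; vehicle/zero-dose wells take part in normalization only).
`fit_logistic()` fits response = bottom + (top − bottom) / (1 + 10^((pXC50 +
log₁₀dose)·h·s)) on log dose, s = −1 for agonist and +1 for antagonist
curves. The default is the three-parameter model with the hill slope fixed at
1 — following the named three-parameter convention of the original analysis —
with a variable-slope mode opt-in. Starting values are deterministic (min /
max per-dose mean, dose nearest half-max, h = 1), and the optimizer is
Levenberg–Marquardt on the explicit residual function: the textbook `nls()`
machinery fails on exactly-recoverable (noise-free) curves, which our
round-trip checks require to 10⁻⁶. Standard errors come from the asymptotic
covariance σ²(JᵀJ)⁻¹ with a central-difference Jacobian. Whether a published
potency ± value is a fit SE or an across-experiment spread is often
ambiguous, so `fit_dose_response()` reports both, labelled.

## Numerical and scale choices

* Seeds are mandatory for every stochastic stage; one master seed expands
  into per-batch / per-drug / per-test streams via a fixed affine map modulo
  2³¹ − 1, so any stage can be re-run in isolation and all derived seeds stay
  valid 32-bit integers.
* Test and demonstration runs use shortened protocols (e.g. 300 s dark /
  300 s light / 60 s off) — the baseline window and both analysis windows are
  structurally identical to the full assay, and a 300-s baseline estimates a
  larva's baseline mean to ±0.002 cm. Generator *parameters* are never
  shortened. The calibration checks for the published group means use the
  full 5700-s protocol at the published scale (18 batches × 48 larvae).
* The Monte-Carlo problem sizes in the suite (200-simulation power checks,
  1000-replicate null calibrations at B = 1000) were chosen so binomial error
  on the checked rates is well inside the asserted bands.
* CSV round-trips write sorted rows (plate, well, second) so identical traces
  give byte-identical files; the normalization model serializes to YAML at
  15 significant digits.

## Known limitations

* The generator's variance structure beyond the published mean ± s.e.m. is
  an assumption; power numbers quoted here transfer to real data only insofar
  as the additive-Gaussian, exponential-decay burst model holds.
* The published real-data statistics (T = 378.0/456.0, T_HD = 1.78, the
  Welch T = 13.2, the imaging ANOVAs) require the archived raw dataset and
  are deliberately not asserted anywhere; property-based checks stand in.
* Hotelling's test needs p ≤ n₁+n₂−2 and a well-conditioned pooled
  covariance; for the 1-s window this is trivial, for 30 s it holds at the
  default group sizes but users shrinking groups should shrink windows too
  (the error message says so).
* The consistency criterion's low pass rate for true hits is a property of
  the published screening design, discussed above, not of this
  implementation.
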