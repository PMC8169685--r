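# vmrscreen

Analysis toolkit for scotopic **visual motor response (VMR)** drug screens in
larval zebrafish models of retinal degeneration.

When the light goes out, a zebrafish larva startles — a burst of swimming
measured as per-second displacement in a 96-well tracking box. In a
rod-degeneration model (rhodopsin Q344X), dim-light (0.01 lx) vision is lost
and the light-off burst collapses: wild-type larvae travel ≈ 0.281 cm in the
first second after light offset, mutants ≈ 0.127 cm. A compound that restores
the mutant response is a candidate vision-preserving drug. `vmrscreen`
implements the full analysis for that screen — and, because real tracking
data are bulky and archived elsewhere, a calibrated generative model so every
stage is testable from scratch.

## What it does

* **Simulation** (`simulate_plate()`, `simulate_screen()`,
  `simulate_dose_response()`): per-second displacement traces with per-larva
  baselines, a light-off startle burst decaying exponentially, batch and
  well-position effects, toxic (immobile) wells, and planted drug effects;
  whole screens come with a ground-truth table. Presets reproduce the
  published WT/Q344X group means exactly (truncation-corrected calibration).
* **Normalization** (`fit_normalization()`, `apply_normalization()`): additive
  OLS removal of baseline activity, per-well light-intensity variation and
  batch effect, fitted on dark-acclimation data only, plus a global offset
  keeping activity non-negative.
* **Hypothesis tests** (`hotelling_t2()`, `hd_two_sample_test()`,
  `welch_t()`, `pearson_chi2_2x2()`, `anova_pairwise_fdr()`): two-sample
  Hotelling's T² with the F conversion
  `F = (n1+n2−p−1)/(p(n1+n2−2)) · T² ~ F(p, n1+n2−p−1)`, and a
  high-dimensional studentized max-type mean test
  `T_HD = max_j |x̄_j − ȳ_j| / se_j` with permutation (default) or Gaussian
  multiplier-bootstrap calibration, for the p > n windows where Hotelling is
  unavailable.
* **Hit calling** (`run_screen()`): the screening funnel — toxicity filter,
  replicate-consistency criterion (high-dimensional test, pass iff p > 0.9),
  significance vs DMSO vehicle (Hotelling, p < 0.05), over the 1-s and
  1–30-s post-offset windows — with funnel summaries shaped like the
  published drug-count table.
* **Dose-response** (`normalize_luminescence()`, `fit_logistic()`):
  GloSensor-style cAMP curves normalized to the maximum per-dose mean and fit
  with a 3-parameter logistic (hill fixed at 1, variable-slope opt-in),
  reporting pEC50/pIC50 with fit and across-experiment uncertainties.
* **Pipeline** (`cmd_simulate()`, `cmd_screen()`, `cmd_fitdr()`, plus the
  `inst/cli/vmrscreen.R` Rscript): YAML-configured simulate → screen → report
  stages with deterministic seeds and run manifests.

## Worked example

```r
library(vmrscreen)

# a small screen: 12 drugs, 2 planted toxics, 1 planted sustained-response hit
proto <- vmr_protocol(data.frame(label = c("dark", "light", "dark"),
                                 duration_s = c(300, 300, 60),
                                 lux = c(0, 0.01, 0)))
design <- screen_design(n_drugs = 12, control_replicates = 4, seed = 2026)
library_tbl <- screen_library(12, n_toxic = 2, hit_drugs = 9)
sim <- simulate_screen(design, library_tbl, protocol = proto)
screen <- run_screen(sim$trace, seed = 11)
print(screen)
#> Drug-screening funnel
#>   starting drugs:   12
#>   non-toxic drugs:  10
#>   window 1-1 s     consistent: 0, hits: 0
#>   window 1-30 s    consistent: 2, hits: 0
```

Both planted toxics are caught (12 → 10). The planted hit is *significant*
against vehicle in the 30-s window but fails the consistency lottery this
time:

```r
subset(screen$records, drug == "drug_009")
#>        drug window toxic consistency_p consistent significance_p significant   hit
#> 17 drug_009  1-1 s FALSE    0.23576424      FALSE      0.8623885       FALSE FALSE
#> 18 drug_009 1-30 s FALSE    0.04795205      FALSE      0.0171447        TRUE FALSE
```

That is not a bug: the consistency criterion passes a drug only when the
high-dimensional test comparing its two replicates lands above p = 0.9, and
for replicates drawn from the same distribution that p-value is uniform — a
~10% lottery whatever the effect size. The vignette discusses why, and what a
higher-power reproducibility filter would look like.

Dose-response and contingency statistics:

```r
d <- simulate_dose_response(list(bottom = 0, top = 1, pXC50 = 7.49, hill = 1),
                            noise_sd = 0.05, seed = 3)
fit_logistic(d$dose_M, d$luminescence, "agonist")
#> Logistic dose-response fit (agonist, hill fixed at 1)
#>   pEC50 = 7.462 +/- 0.037  (bottom -0.005, top 1.005, hill 1.00)
#>   n = 36 readings over 9 doses, RSS = 0.057, converged: TRUE

pearson_chi2_2x2(rbind(c(9, 15), c(16, 8)))
#>  Pearson chi-square test (no continuity correction)
#> X-squared = 4.0904, df = 1, p-value = 0.04313
```

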