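---
title: "Methods: OPLS-DA profiling of longitudinal urinary NMR cohorts"
author: "nmropls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OPLS-DA profiling of longitudinal urinary NMR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmropls)
```

# The problem

Urinary ^1^H NMR metabolomics compares groups of subjects — here a
six-group rat design (untreated control NC, treated healthy control HLD,
two cholestasis models TAA and BDL, and their treated counterparts THC and
BHD) sampled over eight urine collection windows (T1 = 0–8 h through
T8 = 120–144 h). Each spectrum is a superposition of metabolite multiplets
on a chemical-shift (ppm) axis, confounded by strongly varying urine
dilution, small pH-driven peak shifts, baseline drift and noise. The
package implements the full analysis chain from raw spectral matrices to
validated discriminant models and reference-normalized metabolite tables.

# Preprocessing model

The stage order is fixed and enforced through provenance flags:
**align → exclude → bin → PQN → center/pareto**.

- **Alignment** splits the axis into segments (default 0.2 ppm) and shifts
  each segment of each spectrum by the integer lag (≤ 0.02 ppm) maximizing
  cross-correlation with the median spectrum, filling vacated points by
  edge-value extension. This is the segment-wise correlation shifting
  commonly used for urine spectra; it corrects jitter smaller than the
  segment length and leaves genuine lineshape differences alone.
- **Exclusion** removes the residual water/urea region, by default the
  closed interval 4.2–5.9 ppm. Closed endpoints err on the side of
  removing water shoulders.
- **Binning** tiles 0.5–9.8 ppm with half-open fixed-width buckets
  (default 0.04 ppm — the field-standard bucket; a trailing partial bin is
  dropped, giving 232 bins before exclusion). The bin statistic is the
  **sum**, so integrals are conserved and bin values remain "integrations
  of area". Bins whose center falls in an excluded region are dropped.
- **PQN** (probabilistic quotient normalization) first divides each sample
  by its total integral, then by the median quotient against the
  element-wise median reference spectrum. This removes multiplicative
  dilution; the estimated factors are retained so simulations can verify
  recovery of planted dilution.
- **Pareto scaling** mean-centers each bin and divides by the square root
  of its standard deviation — the usual NMR compromise between preserving
  magnitude information and letting small peaks contribute. Original SDs
  are stored for back-scaling covariances in loadings/S-plots.

Whether normalization precedes or follows binning is a genuine design
choice; we bin first (binning a normalized spectrum would be equivalent up
to the bin statistic, but binning first makes PQN cheaper and less
sensitive to sharp noise).

# OPLS-DA

For a two-class response encoded +1/−1 and mean-centered, each orthogonal
round computes the PLS weight `w ∝ X'y` (unit norm), scores `t = Xw`,
loading `p = X't/(t't)`, and the orthogonal weight
`w_o ∝ p − (w'p)w`, scores `t_o = X w_o`, loading `p_o`, deflating
`X ← X − t_o p_o'`. After `n_ortho` rounds the predictive component is
computed on the filtered matrix. With `n_ortho = 0` this is exactly
one-component NIPALS PLS1, which the test suite checks against an
independent textbook implementation.

The default `n_ortho` is 1: a single orthogonal component absorbs the
dominant class-unrelated variation (in this design, e.g. time-of-collection
physiology) and is what the two-dimensional score and trajectory plots
display. Interpretive outputs follow chemometric convention: loadings are
drawn as the back-scaled covariance `cov(t, X_j)` colored by
`|corr(t, X_j)|`, and the S-plot pairs covariance (magnitude, on the
original intensity scale) with correlation (reliability). Multi-group
score planes are produced by fitting the two extreme groups and passively
projecting the others through the fitted weights.

# Validation

- **Cross-validation**: repeated stratified 2-fold (default 50 repeats).
  `Q² = 1 − PRESS/(repeats × SS(y))`; out-of-fold predictions are averaged
  per sample across repeats. Stratification matters because plain 2-fold
  on small groups frequently drops a class. Q² quality labels follow the
  usual chemometric reading: > 0.40 good, > 0.70 robust (strict
  inequalities).
- **Permutation test**: class labels are shuffled (protocol scale
  n = 2000; the package default is 200, configurable), the model refitted
  with the same `n_ortho`, and R²/Q² recorded against the |correlation| of
  permuted with original labels. OLS lines through these points (including
  the unpermuted model at correlation 1) give intercepts at correlation 0;
  a model is declared valid when the Q² intercept is below 0.05 and every
  permuted Q² lies below the actual Q². The empirical p-value is
  `(1 + #{Q²_perm ≥ Q²}) / (n_perm + 1)`.
- **ROC/AUROC**: computed from the averaged out-of-fold predictions, not
  training scores — training scores would push AUROC optimistically toward
  1. AUROC is the Mann–Whitney pair-counting statistic (ties count ½),
  which equals the trapezoidal area under the threshold-swept curve; the
  suite asserts that identity to 1e−10 and cross-checks against pROC.

Inside the permutation loop the per-permutation Q² uses fewer CV repeats
(default 10): the permutation null needs many models more than it needs a
low-variance Q² per model.

A caveat the test suite documents: under 2-fold CV a chance feature–label
alignment present in a given null dataset persists across repeats, so a
minority (~25%) of null datasets yield slightly positive Q². The mean null
Q² is clearly negative, and the permutation verdict — which compares
permuted to actual Q² rather than to zero — is unaffected.

# Univariate stage

Metabolite levels are the normalized average integration of area: the sum
of PQN-normalized (never pareto-scaled) bin values whose centers fall in
the metabolite's windows, divided by the number of contributing bins. Our
sum/bin-count reading of "normalized average integration" is a declared
choice. Relative levels and z-scores against a reference group are
computed per period and pooled over the experiment
(`mean_target/mean_ref` and `(mean_target − mean_ref)/SD_ref`), with the
study's reference scheme built in: all groups against NC, and the treated
groups THC/BHD additionally against HLD to subtract the treatment's effect
on healthy animals.

Significance uses a Shapiro–Wilk gate per group (α = 0.05, both groups
must conform) choosing a Welch t-test or a rank test, at p < 0.05 without
multiple-testing correction by default (a BH-FDR adjustment can be applied
downstream via `p.adjust`). Between groups of different animals the
unpaired rank-sum test is the defensible nonparametric choice; a paired
signed-rank mode exists for matched designs. Significance is assessed per
period by default; pooling is a parameter.

# STOCSY

Statistical total correlation spectroscopy correlates a driver variable
against all variables across samples; multiplets of one molecule vary in
fixed proportion and correlate near 1. It runs on normalized, unscaled
data (correlation is scale-free; the covariance trace keeps spectral
shape). The connection threshold defaults to |r| ≥ 0.8 — a declared
default, as no universal cutoff exists.

# The synthetic cohort generator

Because no real spectra ship with the package, a generator produces
urine-like cohorts with known ground truth. Each spectrum is

```
dilution × Σ_m conc_m × Lorentzian multiplets(m) + baseline + noise
```

with per-sample log-normal dilution (log-SD 0.3), per-sample log-normal
biological variation of concentrations (log-SD 0.2, ≈20% CV — a
mid-range choice for urinary metabolites), per-sample-per-metabolite
chemical-shift jitter (SD 0.002 ppm; whole multiplets move together, as
pH shifts do), a smooth two-cosine baseline (amplitude 0.2) and additive
Gaussian noise (SD 0.05 against peak heights of order 1–40). Lorentzian
lines are the standard solution-state model; the default grid is 0.001 ppm
(9301 points), at least ten points per typical 0.01-ppm linewidth. The
default design is the full 6 groups × 12 subjects × 8 periods; tests and
examples use scaled-down cohorts (e.g. 6×6×8 or 2×3×8) and sometimes
coarser grids, which changes problem size, not the generative conditions.

The default metabolite library holds 28 urinary metabolites at
literature-typical shifts, including urea and allantoin inside the
excluded 4.2–5.9 ppm window — deliberately, so exclusion has real signal
to remove. The library reproduces a real nuisance: neighboring multiplets
overlap (hippurate/benzoate aromatics, taurine/TMAO/betaine around
3.26 ppm). Planted fold-changes on such metabolites bleed into neighbors'
windows, which is faithful to real spectra; fixtures that need exact
arithmetic therefore plant effects on spectrally isolated metabolites
(citrate, alanine, acetate, glycine, formate) or use isolated
mini-libraries.

What the generator does **not** emulate: J-coupling physics (multiplet
patterns are fixed templates), water-suppression artifacts, correlated
baseline distortions, peak-shape changes with ionic strength, or
inter-metabolite concentration correlations beyond the planted effects.
Passing tests therefore demonstrate correctness of the statistical
machinery under a controlled generative model, not performance on any
particular real cohort.

# Numerical choices and degenerate inputs

- Alignment ties between lags break toward the smaller |lag|; a trailing
  axis remainder shorter than one segment merges into the last segment.
- PQN errors on non-positive sample totals (naming the sample) and is
  idempotent to 1e−10.
- Zero-variance bins are centered but not scaled, carry covariance /
  correlation 0 and a degenerate flag in S-plots.
- `n_ortho` must stay below the rank of X; a degenerate orthogonal
  component (no orthogonal variation left) raises an error rather than
  returning a zero vector.
- Stratified fold construction retries (cap 10) before erroring if a fold
  ever lacks a class.
- All-tied univariate input returns p = 1 with a degenerate flag; constant
  groups fail the normality gate and route to the rank test.
- All randomness flows from one global seed through a deterministic
  seed-derivation function; identical configuration and seed reproduce
  every numeric output bit-for-bit.

# Worked example

```{r example, eval = FALSE}
design <- cohort_design(groups = c("NC", "TAA"), n_subjects = 6,
                        periods = paste0("T", 1:8))
lib <- build_default_library(seed = 1)
effects <- rbind(effect_spec("citrate", "TAA", 2),
                 effect_spec("glycine", "TAA", 1.8))
cohort <- generate_cohort(design, lib, effects, noise_model(), seed = 1)

B  <- preprocess_spectra(cohort$spectra)               # scaled, for models
Bn <- preprocess_spectra(cohort$spectra, scale = FALSE) # for univariate/STOCSY

y <- encode_classes(cohort$metadata$group, positive = "TAA")
model <- fit_oplsda(B, y, n_ortho = 1)
report <- validate_model(B, y, n_perm = 200, seed = 1)
report

levels <- integrate_metabolites(Bn, metabolite_windows(lib))
rel <- relative_levels(levels$levels, cohort$metadata, "TAA", "NC")
zscore_table(rel)$z[1:5, 1:4]
run_stocsy(Bn, driver_ppm = 2.54)
```

The full pipeline (`run_pipeline()` on an `analysis_config()`) strings
these stages together for a list of group contrasts and writes all tables,
JSON reports and figures under one output directory.

# Known limitations

- Two-class OPLS-DA only; multi-group figures come from two-group fits
  with passive projection, not a multi-class algorithm.
- One predictive component (the two-class case needs no more), `n_ortho`
  chosen by the user or by the default of 1 — no automatic component
  selection.
- The univariate stage tests each (metabolite, period) cell independently;
  the longitudinal correlation within subject is not modeled.
- Windows-based integration cannot separate overlapping metabolites; that
  is what STOCSY and, in practice, 2D NMR are for.
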