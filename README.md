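# nmropls

OPLS-DA metabolic profiling of longitudinal 1D ^1^H NMR urine spectra.

`nmropls` is for metabolomics analysts who have a matrix of 1D NMR urine
spectra, a sample sheet (group, subject, collection period) and a
metabolite window table, and want the standard discriminant workflow with
honest validation: preprocessing (segment-wise alignment, water/urea
exclusion at 4.2–5.9 ppm, 0.04-ppm sum binning, probabilistic quotient
normalization, mean-centering and pareto scaling), two-class OPLS-DA,
repeated stratified 2-fold cross-validation, label-permutation testing
with R²/Q² regression intercepts, ROC/AUROC from out-of-fold predictions,
STOCSY for multiplet assignment, and reference-group normalized univariate
z-score tables over collection periods. A synthetic cohort generator with
planted ground truth makes the whole chain testable without any external
data.

## The model in brief

For a centered, pareto-scaled matrix `X` and the mean-centered ±1 class
response `y`, each orthogonal round of the OPLS filter computes

```
w ∝ X'y (‖w‖ = 1),  t = Xw,  p = X't/(t't)
w_o ∝ p − (w'p)w,   t_o = X w_o,  p_o = X't_o/(t_o't_o)
X ← X − t_o p_o'
```

and the final predictive component is fitted on the filtered matrix
(`n_ortho = 0` reduces to one-component NIPALS PLS1). Validation reports
`R²Y = 1 − SS(y−ŷ)/SS(y)` on training data,
`Q² = 1 − PRESS/(repeats · SS(y))` from repeated stratified 2-fold CV
(Q² > 0.40 good, > 0.70 robust), permutation intercepts from OLS regression
of R²/Q² on the label correlation, and the pair-counting AUROC
(ties ½; 1.000 = perfect discrimination, 0.500 = random).

Univariate metabolite levels are normalized average integrations of area
(sum of PQN-normalized bins in a window ÷ bin count), compared between a
target and a reference group as `mean_t/mean_r` with
`z = (mean_t − mean_r)/SD_r`, using a Shapiro–Wilk-gated Welch t-test or
rank test at p < 0.05.

## Worked example

```r
library(nmropls)

design  <- cohort_design(groups = c("NC", "TAA"), n_subjects = 6,
                         periods = paste0("T", 1:8))
lib     <- build_default_library(seed = 1)
effects <- rbind(effect_spec("citrate", "TAA", 2),
                 effect_spec("glycine", "TAA", 1.8))
cohort  <- generate_cohort(design, lib, effects, noise_model(), seed = 1)

B  <- preprocess_spectra(cohort$spectra)                # for modelling
Bn <- preprocess_spectra(cohort$spectra, scale = FALSE) # for univariate

y      <- encode_classes(cohort$metadata$group, positive = "TAA")
report <- validate_model(B, y, n_perm = 200, seed = 1)
report
#> <validation_report> R2 = 0.804, Q2 = 0.754 (robust), AUROC = 1.000
#>   permutation: Q2 intercept -0.332, p = 0.004975, valid
```

The planted 2-fold citrate increase separates TAA from NC cleanly: the
training R² of 0.80 is backed by a cross-validated Q² of 0.75 ("robust",
i.e. > 0.70), the AUROC of 1.000 means every out-of-fold TAA prediction
scored above every NC prediction, and the permutation test (200 label
shuffles) finds no shuffled model approaching the real one (empirical
p = 1/201) with a clearly negative Q² intercept — the model is not an
overfitting artifact.

```r
levels <- integrate_metabolites(Bn, metabolite_windows(lib))
rel <- relative_levels(levels$levels, cohort$metadata, "TAA", "NC",
                       periods = "all")
head(rel[order(-abs(rel$z)), c("metabolite", "relative_level", "z", "p_value")], 3)
#>       metabolite relative_level         z      p_value
#> 3        citrate       1.834683 4.0095255 1.485255e-22
#> 10       glycine       1.513078 2.7026635 3.928054e-13
#> 20 dimethylamine       1.071144 0.3599363 9.634438e-02
```

Citrate and glycine show the planted fold-changes (relative levels 1.83
and 1.51 — glycine's window recovers less than its nominal 1.8 because
taurine/TMAO neighbors and baseline dilute it; z = 4.0 and 2.7 reference
SDs above the NC mean), while the first unplanted metabolite sits at
z = 0.36, an order of magnitude below. A full multi-group
study runs through `analysis_config()` + `run_pipeline()`, or the thin
CLI at `inst/exec/nmropls` (`simulate`, `preprocess`, `run` verbs).

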