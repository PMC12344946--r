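# gliodwi

Multi-b-value diffusion MRI modelling for glioma genotype prediction.

Adult diffuse gliomas are stratified by two molecular markers — IDH mutation
and 1p/19q codeletion — that normally require tissue. Quantitative
diffusion-weighted imaging (DWI) offers a non-invasive surrogate: the decay
of the signal `S(b)/S(0)` over diffusion weighting `b` carries microstructural
information that differs by genotype. `gliodwi` is for imaging scientists who
want that full analysis chain in R: voxelwise fitting of four diffusion
signal models to multi-b-value data, VOI-level parameter extraction, the
group-comparison statistics, and ROC diagnostics — plus a synthetic glioma
cohort generator so every stage can be exercised and validated without
patient data.

The four models, fitted to the direction-averaged normalized signal over a
13-b-value scheme (0–2000 s/mm², 30 directions):

| Model | Signal equation | Parameters |
|---|---|---|
| Mono-exponential | `exp(-b·ADC)` | ADC |
| IVIM | `f·exp(-b·D*) + (1-f)·exp(-b·D)` | D, D\*, f |
| Stretched exponential | `exp(-(b·DDC)^α)` | DDC, α |
| CTRW | `E_α(-(b·Dm)^β)` | Dm, α, β |

The continuous-time random walk (CTRW) model is the centerpiece: its kernel
is the one-parameter Mittag-Leffler function `E_α`, evaluated here by a
certified power series with a fixed-Talbot Laplace-inversion fallback
(accurate to ~1e-11; see the methods vignette for why the naive series
fails). Its temporal heterogeneity index `α` is the best-performing
genotype marker in the study this package models.

Diffusivities are stored and reported in `1e-3 mm²/s`, the scale clinical
tables print.

## Worked example

Round-trip a noiseless CTRW curve, then run a small synthetic cohort through
the fitting → extraction → ROC pipeline:

```r
library(gliodwi)

sc  <- bvalue_scheme()   # 13 b-values 0..2000 s/mm^2, 30 directions
sig <- dwi_signal(sc, ctrw_signal(sc$b_values,
                                  ctrw_params(dm = 1.218, alpha = 0.825,
                                              beta = 0.938)))
round(fit_ctrw(sig)$params, 4)
#>    dm alpha  beta
#> 1.218 0.825 0.938

gs <- paper_cohort_groups(voxels_per_voi = c(10L, 15L))
gs[[1]]$n_subjects <- 12L; gs[[2]]$n_subjects <- 5L; gs[[3]]$n_subjects <- 8L
coh <- generate_cohort(synthetic_cohort_config(gs, snr = 50, seed = 11))
tab <- run_cohort_pipeline(coh, models = c("mono", "ctrw"))
roc_analysis(tab$CTRW_alpha, tab$idh_status, positive = "mutant")
#> AUC 0.744 (95% CI 0.538-0.949), threshold 0.881 (higher),
#> sens 0.769 spec 0.750 acc 0.760
```

The fit recovers the generating parameters exactly on noiseless data; on
the noisy 25-subject cohort, the fitted VOI-mean `CTRW_α` separates
IDH-mutant from wild-type subjects with AUC 0.744 at a Youden-optimal
cut-off of 0.881 (mutants above the threshold). Published operating points
can be checked arithmetically from their printed rates:

```r
accuracy_from_rates(0.651, 0.846, n_pos = 43, n_neg = 52)$accuracy
#> 0.758   (TP = 28 of 43 mutants, TN = 44 of 52 wild-type)
```

The numbered scripts under `analysis/` run the full study-scale workflow
(95 subjects) in order — simulate, fit, group statistics, ROC, stratified
re-evaluation — writing their tables under `results/`.

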