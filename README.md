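# fibrostage

Quantitative diffusion-weighted MRI (DWI) analysis for staging liver
fibrosis. The package is aimed at imaging scientists who want to compare how
well three per-voxel signal representations of diffusion separate METAVIR
fibrosis stages F0 (no fibrosis) through F4 (cirrhosis):

- **monoexponential**: `S(b) = S0 · exp(−b·ADC)` — the conventional
  apparent diffusion coefficient;
- **diffusion kurtosis imaging (DKI)**:
  `ln S(b) = ln S0 − b·D_app + (1/6)(b·D_app)²·K_app` — a non-Gaussian
  correction `D_app` plus a dimensionless excess-kurtosis term `K_app`;
- **stretched exponential (SEM)**: `ln S(b) = ln S0 − (b·DDC)^α` — a
  distributed diffusion coefficient `DDC` and a heterogeneity index
  `α ∈ (0, 1]` (α near 1 = nearly monoexponential decay).

Around those models the package provides a complete, reproducible pipeline:

1. **phantom generator** — simulates a METAVIR-staged cohort (default: 80
   subjects, stage counts 16/16/16/17/15) whose per-stage parameter
   distributions follow the package's reference stage table, imaged at
   b = 0, 800 s/mm² (monoexponential protocol) and b = 0, 700, 1400,
   2100 s/mm² (DKI/SEM protocol) under averaged Rician noise;
2. **voxel-wise fitting** — weighted Levenberg–Marquardt least squares in
   the log-signal domain, producing ADC / D_app / K_app / DDC / α maps;
3. **ROI summarization** — five small (3–4 mm²) seeded regions of interest
   per subject, pooled into per-subject parameter means;
4. **staging statistics** — one-way ANOVA with Fisher's LSD post hoc tests,
   Spearman/Pearson correlations with Fisher-z confidence intervals, and
   ROC analysis (empirical AUC, DeLong CI, Youden-index cutoffs) over the
   four stage splits F0 vs F1–4, F0–1 vs F2–4, F0–2 vs F3–4, F0–3 vs F4.

Volumes round-trip through NIfTI plus plain-text b-value/averages files;
reports are written as CSV/JSON tables.

## Worked example

Fit the stretched exponential model to a noiseless four-point decay:

```r
library(fibrostage)
scheme <- multib_scheme()
signal <- predict_sem(sem_params(100, 0.76e-3, 0.68), scheme$b_values)
round(signal, 2)
#> [1] 100.00  52.15  35.24  25.30
fit_sem(dwi_series(scheme, signal))
#> <dwi_fit> converged | residual_norm = 3.944305e-31
#>  $ S0   : num 100
#>  $ DDC  : num 0.00076
#>  $ alpha: num 0.68
```

The fitter recovers the generating parameters (DDC = 0.76×10⁻³ mm²/s,
α = 0.68) exactly. Run the full simulate → fit → summarize → analyze
pipeline on the default 80-subject cohort (a minute or two of CPU):

```r
res <- run_pipeline(read_pipeline_config(), seed = 1)
print(res$report)
#> <staging_report> 80 subjects, stages F0/F1/F2/F3/F4
#>
#> Stage correlations (Spearman):
#>  parameter coefficient ci_low ci_high  p_value  n
#>        ADC      -0.712 -0.806  -0.584 1.33e-13 80
#>      D_app      -0.755 -0.836  -0.642 5.68e-16 80
#>      K_app       0.532  0.354   0.673 3.79e-07 80
#>        DDC      -0.765 -0.843  -0.656 1.36e-16 80
#>      alpha       0.379  0.174   0.553 5.25e-04 80
#>
#> ROC (Youden cutoffs):
#>               split parameter   auc ci_low ci_high cutoff direction ...
#>  F0 versus F1-2-3-4       ADC 0.959  0.910   1.000  1.139        <=
#>  F0 versus F1-2-3-4     D_app 0.960  0.909   1.000  1.272        <=
#>  ...
```

The diffusion coefficients (ADC, D_app, DDC) fall with advancing fibrosis
(negative stage correlations; "positive when ≤ cutoff" ROC orientation),
while K_app and α rise; discrimination is strongest for detecting any
fibrosis (F0 vs F1–4) and weakest for isolating cirrhosis (F0–3 vs F4).
Cutoffs are reported in 10⁻³ mm²/s.

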