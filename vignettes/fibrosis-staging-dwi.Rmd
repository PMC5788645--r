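---
title: "Staging liver fibrosis with multi-model diffusion-weighted MRI"
author: "fibrostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging liver fibrosis with multi-model diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrostage)
```

## The problem

Progressive liver fibrosis deposits extracellular matrix that restricts the
random motion of water, so diffusion-weighted MRI is a natural candidate for
a non-invasive staging biomarker. The conventional readout is the apparent
diffusion coefficient (ADC) of a monoexponential decay, but hepatic water
diffusion is not Gaussian: membranes, septa and collagen create a spectrum
of local diffusion environments. Two non-Gaussian representations capture
this with one extra degree of freedom each — diffusion kurtosis imaging
(DKI) and the stretched exponential model (SEM). This package implements
all three per-voxel models, a synthetic cohort phantom, and the statistics
used to compare the resulting parameters as staging markers across METAVIR
stages F0–F4.

## Signal models

For diffusion weighting $b$ (s/mm²) and baseline signal $S_0$:

* monoexponential: $S(b) = S_0\,e^{-b\,\mathrm{ADC}}$;
* kurtosis: $\ln S(b) = \ln S_0 - b\,D_{app} +
  \tfrac{1}{6}(b\,D_{app})^2 K_{app}$, with $D_{app}$ the corrected
  diffusion coefficient and $K_{app} \ge 0$ the dimensionless apparent
  kurtosis;
* stretched exponential: $\ln S(b) = \ln S_0 - (b\,\mathrm{DDC})^\alpha$,
  with the distributed diffusion coefficient DDC and the heterogeneity
  index $\alpha \in (0, 1]$ ($\alpha \to 1$ means a single dominant
  diffusion environment).

Both non-Gaussian models reduce exactly to the monoexponential one
($K_{app} = 0$, $\alpha = 1$); the test suite verifies these identities to
machine precision. The kurtosis expansion is a truncated cumulant series
and is only monotone decreasing for $b < 3/(D_{app} K_{app})$;
`predict_dki()` warns beyond that range but still evaluates the closed
form, since the fitter's parameter bounds prevent estimates from
exploiting the upturn.

All coefficients are stored internally in mm²/s so that $b \cdot D$ stays
of order one; reporting layers (CSV tables, printed reports) use the
conventional $10^{-3}$ mm²/s.

## Acquisition model

Two protocols are modelled, mirroring routine small-animal liver DWI: a
two-point scheme ($b = 0, 800$ s/mm², 1 and 3 signal averages) for the
monoexponential fit, and a four-point scheme ($b = 0, 700, 1400, 2100$
s/mm², 1–4 averages) shared by DKI and SEM. The number of signal averages
(NSA) matters twice: it scales the noise variance of each measured point
roughly as $1/\mathrm{NSA}$, and it therefore also sets the weights of the
fit.

## Fitting

Fits minimize the NSA-weighted squared residuals of $\ln S$ — the domain
in which the non-Gaussian models are written — by Levenberg–Marquardt
(`minpack.lm::nls.lm`), with:

* $S_0$ a free parameter (never pinned to the measured $b=0$ point);
* bounds $D_{app}, \mathrm{DDC} \in [10^{-5}, 5\times10^{-3}]$ mm²/s,
  $K_{app} \in [0, 3]$, $\alpha \in [0.01, 1]$;
* initialization from the monoexponential fit ($D_{app}$ or DDC from the
  ADC; $K_{app} = 1$, $\alpha = 0.8$), with fallback multi-starts
  ($K_{app} \in \{0.5, 1, 2\}$, $\alpha \in \{0.5, 0.7, 0.9\}$) tried only
  when the first start fails; ties across starts resolve to the lowest
  residual, then the smaller $K_{app}$ / larger $\alpha$;
* tolerances $10^{-12}$ on relative parameter and residual change, at most
  200 iterations. For exactly-solvable (noiseless) data the minimizer
  reports "at numerical limits" rather than "tolerance met"; both are
  treated as convergence, since a residual at machine zero *is* the
  solution. Failures (iteration cap, invalid input) flag the voxel, which
  is excluded from maps and ROI means and counted.

The two-point monoexponential fit is the closed form
$\mathrm{ADC} = \ln(S_{b_0}/S_{b_1})/(b_1 - b_0)$ (clamped at zero, since
a negative diffusivity is unphysical and can only arise from noise); with
more points it is the weighted log-linear least-squares solution. Any
non-positive signal makes the log-domain fit undefined and flags the
voxel.

No Rician bias correction is applied anywhere: the phantom exists partly
to quantify how much the noise floor biases each parameter at a given SNR.
Exact noiseless recovery (relative error $\le 10^{-6}$), independence
from neighbouring voxels, determinism, and local optimality of the
returned minimum are all asserted by the test suite, with brute-force
profiled grid searches as independent oracles.

## The synthetic cohort

The phantom emulates an 80-subject rat cohort with stage counts
16/16/16/17/15. Each subject draws its five true parameters independently
from its stage's normal distribution in the reference table
(`default_stage_table()`); only marginal distributions are specified, so
no cross-parameter correlation is imposed. Draws are clipped to the
fitters' bounds. Each subject's liver is a 32×32-pixel disc at 50/64 mm
pixels; the truth is constant over the liver by default (a configurable
within-subject jitter exists, default 0, because subject-level ROI means
are the unit of analysis).

Signals are generated by the monoexponential model (two-point volume) and,
for the four-point volume, by the stretched exponential with the subject's
DDC/α (configurable to DKI). Noise follows the magnitude-MRI model: each
acquisition records $\sqrt{(S+g_1)^2 + g_2^2}$ with
$g_{1,2} \sim N(0, \sigma)$, and the stored value is the mean over the
scheme's NSA. The default $\sigma$ is 2 % of $S_0$ (SNR 50 at $b = 0$),
chosen once as a realistic scanner operating point that neither
trivializes nor destroys stage separation. An optional collagen-area
fraction (per-stage means 2/6/12/20/30 %, SD 5 %, clipped to [0, 60])
exercises the Pearson-correlation path; it is a plausibility covariate,
not a calibrated quantity.

What the phantom deliberately does **not** emulate: anatomical liver
shape, vessels and bile ducts; respiratory motion and eddy-current
artifacts; perfusion (IVIM) contamination of the low-$b$ regime; spatial
noise correlation; and any coupling between the five parameters beyond
their shared stage. Passing tests therefore demonstrate correctness of the
estimation and statistics machinery under the stated generative model, not
performance on real scanner data.

## ROIs and subject summaries

Five roughly circular ROIs of 3–4 mm² (5–6 pixels at the default pixel
size) are placed at seeded random locations at least one pixel inside the
liver boundary (1-pixel 8-neighbourhood erosion — a minimal proxy for the
radiologist's instruction to avoid the margin and vessels), pairwise
disjoint and 4-connected. A subject's summary value per parameter is the
mean over the *union* of ROI pixels. Pooling pixels rather than averaging
per-ROI means was an open choice; the two coincide for equal-sized ROIs,
and the tested identity `pooled mean = size-weighted mean of ROI means`
makes the alternative reading available by re-weighting.

## Statistics

* **Group comparison**: classical one-way ANOVA per parameter, then
  Fisher's LSD — pairwise t tests sharing the pooled within-group mean
  square and its degrees of freedom, deliberately unadjusted for
  multiplicity (that is the definition of LSD; the output tags it).
  Degenerate zero-variance layouts are resolved explicitly ($F = 0$ when
  all group means coincide, $F = \infty$ when separation is exact).
* **Correlations**: Spearman's ρ computed as the Pearson correlation of
  mid-ranks (stages enter as scores 0–4, so ties are ubiquitous and the
  large-sample p approximation is used), and Pearson's r for the collagen
  covariate. Both report 95 % CIs via the Fisher z transform with
  SE $1/\sqrt{n-3}$ — the standard choice where the upstream software's
  method is unknowable.
* **ROC**: the AUC is the empirical pairwise concordance (ties ½),
  identical to Mann–Whitney $U/(n_1 n_0)$ — an equivalence the tests
  assert against `wilcox.test`. With `direction = "auto"` the orientation
  makes AUC ≥ 0.5, so diffusion coefficients come out "positive when
  ≤ cutoff". CIs use DeLong's placement-value variance (cross-checked
  against pROC). The reported cutoff maximizes the Youden index over
  midpoints between consecutive sorted unique values; ties break toward
  higher specificity, then the smaller cutoff — fixed tie-breaks chosen
  for bit-reproducibility.
* **Normality**: a Kolmogorov–Smirnov screen of pooled within-stage
  z-scores is included as advisory metadata only; nothing is gated on it.
* The four stage splits (F0 vs F1–4, F0–1 vs F2–4, F0–2 vs F3–4, F0–3 vs
  F4) correspond to detecting any, significant, or advanced fibrosis and
  cirrhosis. ROC rows default to the three diffusion coefficients;
  $K_{app}$ and α rows are available on request.

A closed-form oracle accompanies the simulation: for normal
stage-conditional classes the expected concordance is the class-size
weighted mean over (negative, positive) stage pairs of
$\Phi(\Delta\mu/\sqrt{\sigma_-^2+\sigma_+^2})$
(`auc_binormal_mixture()`). Replicate-averaged empirical AUCs are required
to agree with it, which pins the whole simulate–dichotomize–rank chain.

## Reproducibility and problem sizes

Every stochastic step takes a seed, and replicate $r$ of a Monte-Carlo run
uses `seed + r - 1`; cohorts, volumes, maps and tables are bit-identical
under a fixed seed. The test suite runs the voxel-level pipeline on
reduced geometries (10–16 pixel grids, two subjects per stage) and the
subject-level statistics at full cohort size with 120–200 replicates;
noise-consistency checks use 500 simulated voxels per noise level. These
sizes were chosen as the smallest at which each property is
non-trivially exercised. The packaged default configuration
(`inst/extdata/default_config.yaml`) is generated from
`default_pipeline_config()` so the two cannot drift.

## Known limitations

* Stage labels are inputs; nothing about histology is modelled.
* The generator draws parameters independently per subject; real livers
  correlate ADC, DDC and $D_{app}$ strongly, so joint statistics across
  parameters (e.g. comparing two AUCs on the same cohort) should not be
  read off the phantom.
* Model mismatch is intrinsic: the four-point volume is generated by one
  non-Gaussian model, and fitting the other to it estimates that model's
  projection, not a ground truth.
* ROC cutoffs, sensitivities and specificities are single-realization
  quantities with large sampling variability at $n = 80$; only AUCs and
  correlations are stable enough to average meaningfully.
* No perfusion compartment is simulated or fitted; the IVIM biexponential
  model is out of scope.
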