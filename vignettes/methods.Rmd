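---
title: "Quantitative-CT lung water, ECBF correction, and agreement statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-CT lung water, ECBF correction, and agreement statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungwater)
```

## The problem

In severe ARDS on veno-venous ECMO, fluid management is guided by the
extravascular lung water index (EVLWI, ml of edema fluid per kg of ideal
body weight). The bedside standard, transpulmonary thermodilution (TPTD),
is confounded on ECMO: the extracorporeal circuit recirculates the thermal
indicator, inflating the apparent EVLWI roughly in proportion to
extracorporeal blood flow (ECBF, l/min). Quantitative chest CT is immune to
this interference and can serve as the reference. This package implements
the three pieces such a validation needs:

1. **CT densitometry** — EVLWI from an HU volume plus a lung mask;
2. **ECBF correction** — a regression-derived per-litre correction factor
   for bedside TPTD values;
3. **agreement and design statistics** — Bland–Altman with
   limits-of-agreement (LoA) precision, sample-size formulas, gated paired
   tests, Spearman correlation, DICE overlap.

## CT densitometry model

A voxel at $h$ HU has water-equivalent tissue density $1 + h/1000$ g/ml
(air $=-1000$, water $=0$). Over the set $S$ of lung-mask voxels inside the
edema window $[-700, 200]$ HU, with voxel volume $v$ ml:

$$W = \sum_{i \in S} \left(1 + \frac{h_i}{1000}\right) v
    = \left(1 - \frac{\overline{h}}{-1000}\right) |S| v,$$

where the second (mean-HU) form is the algebraic identity the tests verify
against the per-voxel sum. Note a common misprint in this literature writes
the per-voxel factor as $1 - (h - 1000)/1000$, which would assign water a
density of 2 g/ml; we implement the self-consistent form above, which is
the one the mean-HU closed form implies.

The expected (normal) lung weight is height-predicted,
$W_{exp} = -1806.1 + 1633.7 \times \text{height(m)}$ g, valid above
$\approx 1.106$ m (non-positive predictions are an error). Taking 1 g of
excess tissue as 1 ml of water (the g/ml equivalence; "mg" in some sources
is a misprint — it would change the scale by $10^3$),

$$\mathrm{EVLWI_{CT}} = \frac{W - W_{exp}}{\mathrm{IBW}} \;\text{ml/kg}.$$

Negative values (drier-than-expected lungs) are returned, not clipped.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| HU window | $[-700, 200]$, inclusive | HU | edematous tissue; $>200$ HU is contrast agent, $<-700$ hyperaerated |
| integration | windowed voxels only | — | the windowing rule states only these voxels "count"; `integrate = "mask"` is provided for sensitivity analysis |
| IBW rule | sex-specific predicted body weight: male $50 + 0.91(h_{cm} - 152.4)$, female $45.5 + 0.91(h_{cm} - 152.4)$ | kg | the clinical convention is not fixed by the source material; this ARDS-ventilation rule is the default and any function `(height, sex) -> kg` can be substituted |
| voxel volume | $\prod$ spacing $/1000$ | ml | from the NIfTI header; masks must share the grid — a mismatch is an error, never silently resampled |

### Segmentation overlap

`dice_coefficient` computes $2|A \cap B| / (|A| + |B|)$; both masks empty is
an error (0/0). It is exercised by `degrade_mask`, which erodes a mask with
the 6-connectivity structuring element and optionally flips boundary
voxels — a stand-in for comparing automated against manual segmentations.

## ECBF correction

Ordinary least squares of the bedside value on the CT reference and flow:

$$\mathrm{EVLWI_{TPTD}} = \beta_0 + \beta_1\,\mathrm{EVLWI_{CT}}
  + \beta_2\,\mathrm{ECBF} + \varepsilon.$$

$\beta_2$ is the correction factor (ml/kg per l/min). The bedside
correction applies **only** $\beta_2$:
$\mathrm{EVLWI_{TPTDcorr}} = \mathrm{EVLWI_{TPTD}} - \beta_2 \cdot
\mathrm{ECBF}$ — intercept and CT slope are reported but not applied, which
keeps the correction usable without a concurrent CT. Plain OLS is used
(no robust or weighted variants); constant ECBF or constant EVLWI_CT makes
the fit unidentifiable and is an error, as are missing values (no
imputation). The residual SD uses $n-3$ degrees of freedom. Models persist
to a flat key=value file carrying hex-float copies of each coefficient, so
the round-trip is bit exact.

## Agreement and design statistics

Differences are **always** reference − test (CT minus TPTD). This is fixed,
not configurable: one convention prevents silent sign flips, and it makes
the bias of an inflated bedside method negative.

* **Bland–Altman**: bias = mean difference, LoA = bias ± 1.96·SD (sample
  SD, $n-1$); LoA sampling uncertainty uses the classical approximation
  $\mathrm{Var}(\mathrm{LoA}) \approx 3\sigma^2/n$, so the 95% CI
  half-width is $1.96\,\sigma\sqrt{3/n}$.
* **Design formulas** use standard-normal quantiles, not t quantiles:
  $n_{LoA} = \lceil 3 (z_{1-\alpha/2}\,\sigma / \text{halfwidth})^2 \rceil$,
  $n_{paired} = \lceil (z_{1-\alpha/2} + z_{power})^2 \sigma^2/\delta^2 \rceil$,
  and its continuous inverse `detectable_delta`. The z convention is the
  one that jointly reproduces the self-consistent design quadruple
  (45 patients for ±4 ml/kg at SD 7.90; 20 patients for δ = 5; δ = 2.8 and
  CI half-width 3.4 at n = 64); with t quantiles none of these match.
  Sample sizes round up; displayed precisions round half-up to one decimal
  (`round_half_up`), full precision retained internally.
* **Paired comparison** is gated by Shapiro–Wilk on the differences at
  α = 0.05: paired t if normality is not rejected, otherwise Wilcoxon
  signed-rank (exact p for n ≤ 25, normal approximation with continuity
  correction above). All-zero differences are degenerate: p = 1 with a
  warning.
* **Descriptives** are gated the same way: mean ± SD, or median with
  quartiles by the linear-interpolation rule (`quantile` type 7) — the
  quartile rule is fixed here because the convention is otherwise
  unstated.
* **Spearman** uses average ranks for ties and a two-sided p.

## What the synthetic data emulates — and what it does not

### Phantoms

Two ellipsoidal "lungs" inside a soft-tissue body ellipsoid (+40 HU) on an
air background (−1000 HU). Defaults give ≈ 2.1 L of lung — an adult-sized
volume. Lung voxels draw $N(\mu_{HU}, \sigma_{HU})$ clipped to
$(-1000, 200]$; a fraction can be replaced by contrast-like HU in
$(200, 500]$, and an effusion-like shell (+10 HU) can be placed in body
voxels adjacent to the lung. **The ground truth is computed from the
realized (post-noise) voxels**, so quantification must recover it exactly,
not merely in expectation. Phantoms exercise every formula, window bound
and invariance; they do not emulate anatomy, scanner physics
(beam-hardening, kernels), motion, or partial-volume effects — a green
phantom test validates the arithmetic and the windowing logic, not
segmentation quality on real scans.

### Cohorts

Per patient, independently: EVLWI_CT ~ Gamma(shape 2.664175, scale
4.286586) — calibrated by weighted quantile matching (median weighted 4×)
to median 10.2 and IQR 5.8–14.8 ml/kg, giving 6.28/10.03/15.06; ECBF ~
N(3.9, 1.1) truncated to [1.0, 6.5] l/min (inverse-CDF sampling, exact);
height ~ N(1.77, 0.09) m; 23% female; CT-to-TPTD delay lognormal with
median 2 h. Then
$\mathrm{EVLWI_{TPTD}} = 5.054 + 0.4711\,\mathrm{EVLWI_{CT}} +
3.439\,\mathrm{ECBF} + N(0, \sigma_r)$ with $\sigma_r = 8$ ml/kg by
default — chosen so the simulated post-correction LoA width is of the
order of ±17 ml/kg; this is a stated assumption, since residual SDs of the
fitted clinical model are not available. EVLWI_CT and ECBF are drawn
independently; any real correlation between edema burden and prescribed
flow is not modelled. Each generator takes one integer seed and restores
the caller's RNG state.

## Numerical and design choices

* Window bounds inclusive on both ends; contrast exclusion is strictly
  $> 200$ HU.
* NIfTI-1 I/O is a deliberately minimal single-file implementation (there
  is no NIfTI package in this R stack): rank-3 only, both endiannesses,
  `scl_slope`/`scl_inter` honored, float64 written for volumes so HU arrays
  round-trip bit-exactly, uint8 for masks, gzip chosen by file extension.
  Orientation metadata is not interpreted — grids must already agree.
* Erosion/dilation use the 6-connected structuring element with
  out-of-volume treated as background; erosion of a 20³ cube is therefore
  exactly 18³ voxels (DICE $2 \cdot 18^3 / (20^3 + 18^3) \approx 0.8433$).
* The CLI maps condition classes to exit codes (64 usage, 65 format,
  66 validation/alignment, 70 numeric) and never overwrites outputs
  without `--force`.

## Known limitations

* The clinical cohort itself is not reproducible (no deposited data); the
  acceptance suite covers the self-contained design numbers, analytic
  phantom recovery and statistical properties instead.
* No repeated-measures agreement analysis (one scan per patient by
  design), no proportional-bias LoA regression, no robust regression.
* No plot output from the `agree` subcommand; the report is JSON/text.
* The gamma/truncated-normal cohort world is a stated model of the
  published marginals, not a re-identification of patient-level structure.
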