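# lungwater

Quantitative-CT extravascular lung water, an extracorporeal-blood-flow
(ECBF) correction for bedside thermodilution estimates, and the
method-agreement statistics used to validate such corrections.

## Who this is for

In severe ARDS patients supported by veno-venous ECMO, the bedside standard
for quantifying pulmonary edema — the extravascular lung water index
(EVLWI, ml/kg) from transpulmonary thermodilution (TPTD) — is inflated by
the extracorporeal circuit, roughly in proportion to extracorporeal blood
flow. Quantitative chest CT is immune to that interference. This package is
for researchers validating CT-based lung water against thermodilution and
deriving flow-dependent corrections, and it ships ground-truth-known
synthetic phantoms and cohorts so the entire pipeline is testable without
any clinical data.

## The model

From an HU volume and an aligned lung mask, with the edema window
[−700, 200] HU (inclusive; > 200 HU is contrast and excluded):

```
lung weight  W  = Σ over windowed voxels of (1 + HU/1000) · v      [g]
expected     We = −1806.1 + 1633.7 · height(m)                     [g]
EVLWI_CT        = (W − We) / IBW                                   [ml/kg]
```

with IBW the sex-specific predicted body weight. The ECBF correction is the
flow coefficient of the ordinary-least-squares fit

```
EVLWI_TPTD = β0 + β1·EVLWI_CT + β2·ECBF + ε
EVLWI_TPTDcorr = EVLWI_TPTD − β2·ECBF
```

Agreement is assessed Bland–Altman style (differences fixed as
reference − test, i.e. CT − TPTD), with limits of agreement bias ± 1.96·SD
and their precision Var(LoA) ≈ 3σ²/n; design sample sizes use
standard-normal quantiles throughout.

## Worked example

```r
library(lungwater)

anthro <- patient_anthro(height = 1.77, sex = "male")

## a noisy, contrast-contaminated phantom with known ground truth
spec <- phantom_spec(lung_mean_hu = -450, hu_noise_sd = 40,
                     contrast_fraction = 0.05, seed = 11)
ph  <- generate_phantom(spec, anthro = anthro)
res <- quantify_scan(ph$volume, ph$mask, anthro)
res
#> Lung quantification (HU window [-700, 200], window integration, IBW rule pbw)
#>   voxels included : 44090
#>   lung volume     : 1984.0 ml
#>   mean HU         : -450.0
#>   lung weight     : 1091.3 g
#>   expected weight : 1085.5 g
#>   IBW             : 72.39 kg
#>   EVLWI_CT        : 0.08 ml/kg
```

The 5% contrast voxels were excluded by the window; lung weight matches the
analytic truth (`ph$truth$true_lung_weight`) to 1e−6 relative tolerance,
and a mean of −450 HU over ~2 L leaves the lung barely heavier than its
height-predicted 1085.5 g — EVLWI ≈ 0.

```r
## a synthetic cohort drawn from the generative linear model, then re-fitted
cohort <- generate_cohort(cohort_gen_params(n = 64, seed = 11))
model  <- fit_correction_model(cohort)
model
#> ECBF correction model (n = 64)
#>   EVLWI_TPTD = 6.3866 + 0.6764 x EVLWI_CT + 3.2206 x ECBF
#>   correction factor : 3.2206 ml/kg per l/min
#>   residual SD       : 8.592 ml/kg

corrected <- correct_cohort(cohort, model)
bland_altman(corrected$evlwi_ct, corrected$evlwi_tptd)
#> Bland-Altman (differences = reference - test, n = 64)
#>   bias : -16.69 ml/kg   SD of differences : 9.19 ml/kg
#>   limits of agreement : -34.70 to 1.32 ml/kg
#>   LoA 95% CI half-width : 3.90 ml/kg
bland_altman(corrected$evlwi_ct, corrected$evlwi_tptd_corr)
#> Bland-Altman (differences = reference - test, n = 64)
#>   bias : -3.58 ml/kg   SD of differences : 8.61 ml/kg
#>   limits of agreement : -20.44 to 13.29 ml/kg
#>   LoA 95% CI half-width : 3.65 ml/kg
```

At n = 64 the fitted factor (3.22) scatters around the generative 3.439
with SE ≈ 1; applying it pulls the bias from −16.7 to −3.6 ml/kg. Design
helpers: `min_n_for_loa_precision(7.90, 4.0)` → 45,
`paired_n(5, 7.90)` → 20, `detectable_delta(64, 7.90)` → 2.77 ml/kg.

## Command line

```sh
Rscript inst/cli/lungwater simulate phantom --out v.nii.gz --mask-out m.nii.gz \
    --truth truth.json --seed 3 --noise-sd 20
Rscript inst/cli/lungwater quantify --volume v.nii.gz --mask m.nii.gz \
    --height 1.77 --sex male
Rscript inst/cli/lungwater simulate cohort --n 64 --seed 2 --out cohort.csv
Rscript inst/cli/lungwater fit-correction --cohort cohort.csv --model model.txt
Rscript inst/cli/lungwater correct --cohort cohort.csv --model model.txt --out corr.csv
Rscript inst/cli/lungwater agree --cohort corr.csv --corrected --out report.json
```

Volumes and masks are single-file NIfTI-1 (`.nii`/`.nii.gz`); cohorts are
CSV (`patient_id, evlwi_ct, evlwi_tptd, ecbf, height_m, sex[,
time_offset_h]`); models are flat key=value text with bit-exact
coefficients. Exit codes: 0 ok, 64 usage, 65 format, 66 validation,
70 numeric.

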