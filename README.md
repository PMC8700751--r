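# dopplerperf

Quantitative analysis of color-Doppler cine loops for differentiating
malignant from inflammatory focal lesions, built around two complementary
measurement routes:

- **Dynamic tissue perfusion measurement (DTPM)** — decode every colored pixel
  of the Doppler overlay into a signed velocity, pool all flow inside a
  region of interest (ROI), and summarize it per cardiac cycle as

  - tissue flow velocity `TFV [cm/s]` — time average of the per-frame mean
    speed over perfused pixels,
  - tissue resistive index `TRI = (v_max − v_min) / v_max` per cycle,
    averaged across cycles (TRI = 1 ⇔ diastolic no-flow, the hallmark of
    high-impedance malignant vasculature),
  - tissue perfusion intensity
    `TPI [cm/s] = (mean velocity × vascular area) / ROI area`.

- **Single-vessel flow measurement (SVFM)** — segment the largest vessel with
  a consistent flow direction, estimate its axis and the Doppler angle θ to
  the beam, correct the spectral envelope by `1/cos θ` (flagged invalid above
  60°, where the correction falsifies the result), and report

  - flow velocity `FV [cm/s]` — time-averaged corrected peak velocity,
  - resistive index `RI = (PSV − EDV) / PSV`,
  - volume flow `VolF [mL/s] = FV · π (d/2)²` from the vessel diameter `d`.

Cohort-level statistics mirror the clinical analysis: a Shapiro–Wilk
normality gate choosing Welch's t-test (mean ± SD) or the Mann–Whitney U
test (median, Q1–Q3); ROC analysis with the concordance (Mann–Whitney) AUC
estimator, an automatically oriented decision rule and a deterministic
Youden-optimal "nadir" cut-off; and DeLong's paired test for correlated AUCs
to ask whether tissue perfusion discriminates better than single-vessel flow.

Because no patient recordings ship with the package, a calibrated synthetic
generator builds complete cine cases — frames, colorbar LUT, ROI mask,
ground-truth sidecar — whose per-label parameter distributions are matched to
published group summaries for pancreatic lesions (malignant n = 40,
inflammatory n = 29), so the whole pipeline is testable end to end.

## Worked example

Synthesize one lesion recording, decode it, and quantify both routes:

```r
library(dopplerperf)

case <- synthesize_case(seed = 7, label = "inflammatory")
v <- decode_cine(case$cine)
dtpm(v)
#> <dtpm_result> TFV 2.654 cm/s, TRI 0.780, TPI 0.0160 cm/s (3 cycles)
svfm(v)
#> <svfm_result> FV 3.414 cm/s, RI 0.842, VolF 0.0297 mL/s (angle 45.0 deg, 3 cycles)
```

The ground-truth sidecar of this case holds TFV 2.65, TRI 0.778, TPI 0.0159,
FV 3.40, RI 0.843, VolF 0.032 at a 45° Doppler angle: the decoded estimates
recover the truth to within the colorbar quantization for the tissue
parameters, and the vessel diameter estimate (which feeds VolF) to ~10%.

Cohort-level analysis on a calibrated 40/29 cohort:

```r
cohort <- draw_cohort_params(40, 29, seed = 1)
rep <- cohort_report(cohort)
rep$comparisons
#>   parameter         test           malignant        inflammatory            p
#> 1       tfv            t        1.520 ±0.706        2.667 ±0.861 2.781301e-07
#> 2       tri mann-whitney 1.000 (1.000–1.000) 0.703 (0.585–0.866) 1.394208e-08
#> 3       tpi mann-whitney 0.004 (0.002–0.011) 0.015 (0.009–0.031) 2.375739e-05
#> 4        fv mann-whitney 1.524 (1.031–2.954) 3.227 (2.446–4.843) 1.853478e-04
#> 5        ri mann-whitney 1.000 (1.000–1.000) 0.756 (0.618–0.969) 9.654468e-06
#> 6      volf mann-whitney 0.009 (0.005–0.031) 0.029 (0.016–0.066) 1.593906e-03
```

Every parameter separates the groups; flow is uniformly lower and resistance
higher in the malignant label, matching the clinical pattern. The ROC table
(`rep$roc`) adds the oriented AUC, nadir cut-off, sensitivity, specificity
and accuracy per parameter, and `rep$auc_comparisons` holds the paired
DeLong comparisons, e.g. TPI vs FV on this cohort: AUC 0.790 vs 0.766,
p = 0.00034.

`run_pipeline()` drives the full chain — simulate (or load with
`read_cine()`), decode, DTPM, SVFM, statistics — and, given an output
directory, writes `dtpm_results.csv`, `svfm_results.csv`, `table1.csv`,
`table2.csv`, `auc_comparisons.csv`, `roc_curves.json` and an exclusion log
in which every case is accounted for.

Results objects are tidyverse-friendly: `tidy()` / `glance()` methods return
tibbles, and `autoplot()` draws perfusion traces and ROC curves.

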