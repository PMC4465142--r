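# gatedvh

DVH metrics, relative seriality NTCP and paired cohort comparison for
breathing-adapted radiotherapy.

## What this is for

When left-sided breast cancer is irradiated, the heart, the left anterior
descending (LAD) coronary artery and the ipsilateral lung all receive
unwanted dose. Gating the beam to deep inspiration (enhanced inspiration
gating, EIG) moves the heart out of the tangential fields and inflates the
lung, so paired free-breathing (FB) vs gated treatment plans are routinely
compared structure by structure. `gatedvh` is for medical physicists and
methodologists who want that comparison chain as tested, scriptable code:

- **DVH containers and metrics** — differential/cumulative dose-volume
  histograms with exact round-trip conversion, mean dose, near-maximum
  dose D2%, VxGy, and prescription-relative coverage (V93%, V95%, V105%),
  with linear interpolation on the cumulative curve.
- **NTCP** — the relative seriality model with a Poisson dose-response,

  `P(D) = 2^(-exp(e·γ·(1 - D/D50)))`,
  `NTCP = {1 - Π_i [1 - P(D_i)^s]^{ΔV_i}}^{1/s}`,

  evaluated in log space so the near-parallel lung parameters
  (s = 0.012) do not underflow. Published parameter sets for excess
  cardiac mortality (s = 1, γ = 1.28, D50 = 52.3 Gy) and radiation
  pneumonitis (s = 0.012; γ = 0.974, D50 = 27.52 Gy tangential;
  γ = 0.966, D50 = 29.23 Gy locoregional) are registered by default.
- **Maximum heart distance (MHD)** — the beam's-eye-view penetration of
  the heart contour past the posterior field edge, computed exactly on a
  polygon scene.
- **Cohort statistics** — per-patient metric extraction, two-sided paired
  Wilcoxon signed-rank tests (exact for ≤ 20 untied differences, corrected
  normal approximation otherwise), unpaired rank-sum tests between plan
  strata, and median [range] comparison tables at a fixed α = 0.01.
- **Synthetic paired cohorts** — a seeded generator of FB/EIG DVH pairs
  and MHD scenes with realistic curve shapes and genuine within-patient
  pairing, so the entire pipeline runs and is testable without
  planning-system exports.

## Worked example

```r
library(gatedvh)

cohort <- generate_cohort(cohort_config(n_patients = 16,
                                        plan_type = "tangential", seed = 1))
report <- build_cohort_report(cohort)
print(report)
```

```
Tangential treatment (n = 16 pairs; paired Wilcoxon, alpha = 0.01)
 Metric                         FB                    EIG                    p      sig
 V_PTV (cm3)                    981.5 [335.6-2845.3]  985.1 [354.9-2792.7]   0.404
 V_93%,PTV (%)                  98.4 [97.6-99.1]      98.6 [97.7-99.1]       0.083
 ...
 D_mean,heart (Gy)              2.3 [1.7-5.1]         1.7 [1.4-2.1]          <0.001 *
 V_25Gy,heart (%)               1.8 [0.4-8.2]         0.2 [0.0-0.6]          <0.001 *
 MHD (cm)                       1.3 [0.7-2.4]         0.6 [0.0-1.6]          <0.001 *
 V_25Gy,LAD (%)                 33.7 [19.0-79.7]      3.4 [1.7-6.4]          <0.001 *
 NTCP cardiac mortality (%)     0.29 [0.07-2.38]      0.04 [0.01-0.17]       <0.001 *
 NTCP radiation pneumonitis (%) 0.47 [0.09-2.03]      0.38 [0.07-3.17]       0.597
```

Each row is one metric: the cohort median with the [min–max] range under
free breathing and under gating, and the paired signed-rank p-value
(`*` = significant at α = 0.01). In this simulated tangential cohort
gating cuts the median heart V25Gy from 1.8% to 0.2% and the median
cardiac-mortality NTCP from 0.29% to 0.04%, while lung dose and
pneumonitis risk are unchanged — the expected pattern for tangential
fields. A single patient's numbers come straight from the same objects:

```r
params <- lookup_endpoint("cardiac_mortality", "tangential")
100 * ntcp_relative_seriality(cohort[[1]]$fb$heart$dvh, params)   # 0.5799 %
100 * ntcp_relative_seriality(cohort[[1]]$eig$heart$dvh, params)  # 0.0860 %
max_heart_distance(cohort[[1]]$scenes$FB)                         # 1.379 cm
```

The same operations are available from a shell via the thin entry script
`inst/scripts/gatedvh` (`simulate`, `metrics`, `ntcp`, `mhd`, `compare`,
`report`), which reads and writes documented plain-text CSV formats for
DVHs, scenes and cohort manifests.

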