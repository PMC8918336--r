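# kmindex

Early prediction of midline shift after middle-cerebral-artery (MCA)
infarction from an acute CT perfusion study.

When a large MCA infarction swells, midline brain structures are displaced
(midline shift, MLS) and decompressive hemicraniectomy (DHC) can become
life-saving — but the decision is usually made only after neurological
worsening is visible. The **KM index** condenses the initial perfusion
volumetry and the chosen therapy into one number available on day 0:

```
KM = (n · (m_ratio · v_core + v_penumbra) + v_MTT) / v_MIP
```

where `v_core`, `v_penumbra`, `v_MTT` (perfused parenchyma) and `v_MIP`
(scanned intracranial volume) are in cm³, `n` weights the penumbra by the
reperfusion result (mTICI grade; ×λ for intravenous lysis) and
`m_ratio · n` weights the swelling core. Values above 1 mean the predicted
space-occupying burden exceeds the intracranial capacity — herniation risk.
A time-weighted variant (KMT) raises `n` to a factor `t` for the
onset-to-groin interval. The index discretizes to a 0–20 score and four
risk classes (low / moderate / high / severe).

The package is aimed at stroke-imaging researchers who want to compute the
index for patients or cohorts, recalibrate its parameters for their own
perfusion software (core-volume estimates are vendor-dependent), and
evaluate its discrimination — plus a seeded synthetic cohort generator so
the whole pipeline is testable without clinical data.

## Worked example

A patient with cohort-average volumes, treated by thrombectomy with full
reperfusion (mTICI 3), no lysis, groin puncture 3 h after onset:

```r
library(kmindex)

v  <- perfusion_volumes(v_core = 53.81, v_penumbra = 87.77,
                        v_mip = 1086.26, v_mtt = 950.27)
tr <- treatment_record(thrombectomy = TRUE, mtici = "3", rtpa = FALSE,
                       onset_to_groin_hours = 3)
km_index(v, tr)
#> KM index: 0.9846  (score 0, low risk)
#>   I = 0.0495  P = 0.0808  B = 0.8748  n = 0.500  m_eff = 1.400
kmt_index(v, tr)
#> KMT index: 0.9022  (score 0, low risk)
#>   I = 0.0495  P = 0.0808  B = 0.8748  n = 0.500  m_eff = 0.350  t = 3
```

The successful early thrombectomy halves the penumbra weight (n = 0.5) and
keeps the index below 1: no shift expected. With a failed recanalization
(mTICI 0) the same volumes give an index of 1.0943 — score 9, high risk.

Cohort-level analysis on a synthetic cohort:

```r
co  <- generate_cohort(generator_config(n = 186, seed = 1))
tbl <- cohort_indices(co)                  # adds n, index, score, risk_class
outcome <- tbl$mls_max_mm > 0
confusion_at_threshold(tbl$index, outcome, threshold = 1.021)
#> Threshold 1.021: TP 19  FP 60  TN 103  FN 4
#>   sensitivity 82.6% (19/23)  specificity 63.2% (103/163)
auc_mann_whitney(tbl$index, outcome)$auc
#> [1] 0.795
risk_table(co)
#> # A tibble: 4 × 8
#>   risk_class     n   mls mls_rate   dhc dhc_rate death death_rate
#> 1 low          116     6   0.0517     1  0.00862     1    0.00862
#> 2 moderate      37     6   0.162      2  0.0541      0    0
#> 3 high          20     6   0.3        4  0.2         0    0
#> 4 severe        13     5   0.385      3  0.231       2    0.154
```

Outcome risk climbs monotonically with the risk class. Calibration against
measured shift — `calibrate_index(co)` — recovers the index parameters by
maximizing the Pearson correlation between index and maximum MLS over a
deterministic grid/refinement search.

Volumetry from a NIfTI label map (0 = outside, 1 = MIP, 2 = MTT,
3 = penumbra, 4 = core):

```r
vols <- extract_volumes(read_label_map("labels.nii.gz"))
km_index(vols, tr)
```

## Command line

A thin Rscript wrapper exposes the same operations:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "kmindex", package = "kmindex"))')
Rscript $CLI simulate --seed 1 --n 186 --out run
Rscript $CLI compute  --cohort run/cohort.csv --out run
Rscript $CLI evaluate --cohort run/cohort.csv --threshold 1.021 --out run
Rscript $CLI compute  --core 53.81 --penumbra 87.77 --mtt 950.27 \
                      --mip 1086.26 --mtici 3
```

Every run writes a machine-readable provenance record (parameters,
package version, seed); data files are byte-identical across reruns of the
same configuration.

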