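---
title: "The KM index: model, calibration and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The KM index: model, calibration and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmindex)
```

## The model

After occlusion of the middle cerebral artery, infarcted tissue swells. If
the swollen volume exceeds the free intracranial capacity, midline
structures are displaced — a midline shift (MLS) — and decompressive
hemicraniectomy (DHC) may become necessary. The KM index condenses an
acute-phase CT perfusion study and the chosen therapy into a single number
that predicts that risk *before* any shift is visible.

The index relates the predicted space-occupying burden to the scanned
intracranial volume:

$$\mathrm{KM} \;=\; \frac{n\,(m_\mathrm{ratio}\, v_\mathrm{core} + v_\mathrm{penumbra}) + v_\mathrm{MTT}}{v_\mathrm{MIP}}$$

with the four volumes in cm³ taken from perfusion post-processing:

* `v_core` — irreversibly infarcted tissue (CBV-based core estimate);
* `v_penumbra` — hypoperfused but salvageable tissue;
* `v_MTT` — perfused brain parenchyma in the scanned slab (mean-transit-time
  map), the *brain term* B = v_MTT / v_MIP;
* `v_MIP` — the scanned partial intracranial volume
  (maximum-intensity-projection), serving as the intracranial-volume proxy.

Working with ratios rather than absolute volumes lets protective brain
atrophy enter the score: an atrophic brain has a smaller B and tolerates
more swelling. A healthy brain (no core, no penumbra) has KM = B < 1;
values above 1 mean the predicted burden exceeds capacity.

Two treatment-dependent weights modulate the lesion terms:

* **n** — the probability that the penumbra proceeds to infarction. Without
  thrombectomy n = 1. After thrombectomy, n falls linearly with the mTICI
  reperfusion grade: 1.0, 0.9, 0.8, 0.7, 0.6, 0.5 for grades 0, 1, 2a, 2b,
  2c, 3. The linear interpolation deliberately ignores that mTICI grades
  are not quantitatively equidistant; grade 1, absent from some summary
  tables, takes its interpolated value 0.9. Intravenous thrombolysis
  (rtPA) multiplies n by a lysis weight λ (default 0.70). We apply λ
  whenever rtPA was given — also in patients without thrombectomy —
  because lysis is modelled as a multiplicative penumbra-salvage factor
  independent of the mechanical intervention.
* **m = m_ratio · n** — the swelling weight of the core relative to the
  penumbra weight. The default m_ratio = 2.8 was fitted on Syngo.via
  volumes; core-volume estimates are software-dependent, so recalibration
  (below) is expected for other post-processing pipelines.

### The time-weighted variant

The KMT index raises n to a time factor t reflecting the onset-to-groin
interval (3 for ≤ 4.5 h, 2 for 4.5–8 h, 1 beyond 8 h), so an early,
successful thrombectomy shrinks the predicted burden more strongly:

$$\mathrm{KMT} \;=\; \frac{m_\mathrm{ratio}\, n^t v_\mathrm{core} + n^t v_\mathrm{penumbra} + v_\mathrm{MTT}}{v_\mathrm{MIP}}$$

The core keeps its *relative* weight: mᵗ = m_ratio · nᵗ, i.e. m is the t-th
root of m_ratio times n. An alternative printed rendering scales
(v_core + v_penumbra) jointly by m_ratio · nᵗ; that contradicts the root
relation and inflates the penumbra term, so it is available only behind
`literal_grouping = TRUE`. Under the KMT variant the lysis weight takes its
refitted value λₜ (default 0.87). An **unknown onset** (wake-up stroke,
unclear history) maps to t = 1: the most conservative assumption the table
permits, since t = 1 leaves n unshrunk and therefore never understates the
index. With t = 1 the KMT index coincides exactly (floating-point
identically) with the KM index at λₜ.

### Score and risk classes

For bedside use the index is discretized to the 0–20 KM score: 0 below an
index of 1.005, 20 at or above 1.195, otherwise 100·(index − 1) rounded
*half away from zero* — chosen over R's round-half-even so that .5
boundaries always move up, matching the convention that an index of 1.14
scores 14. Scores bin into risk classes low (0–2), moderate (3–7), high
(8–13) and severe (14–20). The class keys off the integer score rather
than the raw index because index-scale bin edges would leave gaps between
published bins (1.07 vs 1.08); the score bins are gap-free.

## Volumetry

`extract_volumes()` turns a 3-D integer label map (NIfTI-1; spacing from
the header) into the four volumes under a label-at-least coverage
convention: MIP = labels ≥ 1, MTT = labels ≥ 2, penumbra = label 3, core =
label 4. A single nested label map is canonical because it makes the
nesting invariant (core ⊆ lesion ⊆ MTT ⊆ MIP) checkable in one pass;
separate binary masks are accepted by `merge_masks()` with strict nesting
validation. Volumes are voxel counts times the voxel volume — no
partial-volume weighting, mirroring how clinical perfusion software
counts voxels. Penumbra and core are disjoint compartments here; pipelines
that report a core-inclusive penumbra should subtract the core first (the
sum is always available as `v_core + v_penumbra`). Orientation metadata is
ignored: volumes are orientation-invariant.

The conceptual ratio form B = 1 − (v_subarachnoid + v_ventricle)/iv on true
anatomical volumes is retained in `conceptual_ratios()`; the index itself
proxies these by the scanned partial volumes, matching the vendor
volumetry setting in which it was derived.

## Cohort tables and inclusion filtering

Cohorts travel as a versioned UTF-8 CSV (`# km-cohort v1`) with one row per
patient; blank fields are missing values, never zeros — an absent MLS
measurement is distinct from a measured 0 mm shift. Exclusion criteria are
explicit per-row flags (large hemorrhage, iatrogenic bleed > 20 ml,
non-diagnostic perfusion, no follow-up imaging). `apply_inclusion_filters()`
removes flagged patients and tallies exclusions; a patient with several
flags counts once under the first flagged reason in that fixed order, so
the tally is disjoint by construction and counts are conserved.

## Calibration

`calibrate_index()` recovers the index parameters from a cohort with
measured maximum MLS by maximizing the Pearson correlation between index
and shift. The search is deliberately plain and fully deterministic:

* m_ratio on a fixed grid 0.1 … 5.0 in steps of 0.1 (a core swelling
  potential of up to 500%), ties broken toward the smaller value;
* λ by bracketed successive grid refinement (21 points per bracket) on
  (0, 1] to a bracket width of 10⁻³, ties toward the larger value (the
  weaker lysis effect); the midpoint of the final bracket is returned;
* alternating (m, λ) sweeps — two by default — then optionally λₜ under
  the KMT index by the same refinement.

Reproducibility over cleverness: every objective evaluation is recorded in
a trace that is serialized with the result, and the reported correlation
always equals a recomputation of the objective at the returned parameters.

Patients without a recorded MLS contribute 0 mm by default (`mls_missing =
"zero"`): the outcome is the *maximum* shift over follow-up, and a patient
in whom no shift was ever observed genuinely contributes zero. The
alternative `"drop"` policy restricts to patients with a recorded value.
Calibration runs on the full included cohort by default rather than the
MLS-positive subgroup; both choices are exposed.

λ is identifiable only if the cohort contains both rtPA and non-rtPA
patients; λₜ additionally needs patients with known onset time. Both
conditions are validated eagerly with explicit errors.

The brain term's contribution can be assessed by
`km_mls_correlation(..., brain_term = FALSE)`; on synthetic cohorts
generated with the term active, dropping it lowers the achieved
correlation — the atrophy contribution is measurable but small.

## Threshold and discrimination analysis

Thresholding uses strict `>` throughout (an index "above x" is exclusive),
switchable to `≥`. Sensitivity and specificity come from raw confusion
counts with explicit denominators; empty denominators are flagged, never
silent NaN. The AUC is computed by the Mann–Whitney construction
U/(n₁n₂) with ties counted ½, whose p value uses the normal approximation
with tie and continuity correction — adequate at cohort sizes in the
hundreds; exact small-sample p values are out of scope. The ROC staircase
draws diagonal segments through tied values, so its trapezoidal area
equals the Mann–Whitney AUC exactly (to 10⁻¹²), which the tests enforce on
every input.

Because the criterion behind a published "optimal" cut-off is rarely
stated, `select_threshold()` offers two labelled selectors: Youden's J,
and a sensitivity-first rule (smallest threshold keeping sensitivity above
a floor, then best specificity) that matches screening-test logic.
`risk_table()` reports per-class event counts and rates with explicit
denominators — it never reproduces denominator typos from summary tables.

## The synthetic cohort generator

No patient-level data are distributable, so `generate_cohort()` produces
cohorts with the statistical structure of a realistic MCA-infarction
population; all calibration and evaluation machinery is exercised on these.

* **Volumes.** MIP is drawn from a truncated normal (1086.26 ± 105.59 cm³);
  the perfused fraction (occupancy) is drawn separately and multiplied on,
  so v_MTT ≤ v_MIP holds always and the two share a head-size factor. The
  occupancy variance is set so the marginal v_MTT SD matches 105.69 cm³.
  Core (53.81 ± 49.71) and penumbra (87.77 ± 37.15) are zero-truncated
  normals whose *locations* are moment-matched (via the truncated-normal
  mean formula) so the post-truncation means equal the stated means; pairs
  violating core + penumbra ≤ v_MTT are resampled. Core and penumbra are
  independent given head size — a documented simplification; no joint
  distribution is published.
* **Treatment.** Thrombectomy with probability 132/186; mTICI drawn with
  weights 12 : 2 : 10 : 33 : 9 : 66; rtPA with probability 0.5053;
  onset-to-groin gamma-distributed (mean 5 h) and unknown with probability
  51/186.
* **Outcome.** The maximum MLS follows a zero-inflated *saturating* hinge
  of the true index Z (computed at the generating parameters m* = 2.8,
  λ* = 0.70): with probability 0.28 a latent shift
  12·tanh((100·(Z − 1) + ε)/12) mm (ε ~ N(0, 6 mm)) is realized, floored
  at 0; otherwise the shift is 0. The hinge sits at Z = 1 because that is
  where burden exceeds capacity; the 12 mm saturation reflects anatomical
  limits and intervening surgery (published DHC decision thresholds sit at
  6–9 mm); the zero-inflation stands for severity-independent rescue
  factors (collateral recruitment, compliance reserve) invisible to the
  perfusion study. At the defaults roughly 14% of patients develop a
  shift, positive shifts average ≈ 6.5 mm, and the generated index
  distribution (≈ 1.01 ± 0.10) emerges from the volume and treatment
  models without any direct tuning.

  The saturating form is a deliberate choice: with a sharp hinge placed
  high in the index range, the Pearson correlation between index and
  shift is *monotone* in m_ratio up to the grid bound, so
  correlation-based calibration cannot recover the generating value — the
  convex response rewards ever-stronger core weighting. Keeping the
  conditional mean of MLS near-linear in Z (low knee, saturation, noise)
  makes the calibration consistent. Even so, a modest upward spread
  remains: over 20 cohorts of n = 500 the median recovered m_ratio lies
  near 3.1 (true 2.8) while λ recovers to ≈ 0.67–0.74. Users should read
  single-cohort calibrated values as order-of-magnitude estimates; the
  published m_ratio was likewise fitted once, on one cohort.
* **Secondary outcomes.** DHC is triggered above a 5 mm shift with
  probability 0.8; 7-day death risk is 1% at baseline, +25 points after
  DHC, +10 points for an untreated large shift.
* **Demographics** (age 73.7 ± 17.9, 58.6% female, NIHSS 9.5 ± 2.1, vessel
  distribution) are sampled but inert by default. An optional
  age–occupancy coupling induces the small negative atrophy correlation
  seen in real cohorts; it is off by default and used only in a
  qualitative sign test.
* **Reproducibility.** Each patient consumes an RNG substream derived from
  (seed, patient index), so cohorts are byte-identical across runs and
  growing a cohort does not perturb existing patients. The caller's RNG
  state is saved and restored.

What passing tests on these cohorts show — and what they do not: the
machinery is exercised end-to-end under realistic marginals, but the
generator's outcome model is idealized (no vessel-site effects, no
infarct-growth dynamics, no measurement error in the volumes themselves),
so observed-cohort statistics such as the published correlation of 0.61 or
an AUC of 0.91 are not reproduced and are not targets.

## Numerical choices

* Score rounding: half away from zero on 100·(index − 1); exact decimal
  boundaries (e.g. 1.005) are not representable in binary and fall on the
  lower side consistently in both the guard and the rounding path.
* Grid/refinement tie-breaks are fixed (smaller m, larger λ) and recorded
  in the result notes.
* Volume invariants are validated with a 10⁻⁹ cm³ slack to absorb
  rounding in CSV round trips.
* Degenerate inputs (constant series, one-class outcomes, empty
  denominators) raise classed errors or explicit markers, never silent
  NA/NaN propagation.

## Problem sizes in the test suite

The packaged tests run cohorts of 186–500 patients (20 seeds for the
recovery checks, 50 for positivity), 5000 for distributional moments, and
100 seeded samples for the AUC/ROC oracle identities; the full suite
completes in about two minutes on a single CPU. These sizes were chosen to
keep Monte-Carlo error well below the asserted tolerances.

## Known limitations

* The index is calibrated to one vendor's perfusion volumetry; the core
  weighting in particular does not transfer across software without
  recalibration.
* Calibration assumes a linear-in-index mean response of the maximum MLS;
  strongly nonlinear outcome processes bias the fitted core weighting
  upward (see the generator discussion).
* The Mann–Whitney p value is asymptotic; below ~20 patients per class it
  should not be trusted.
* No multivariable modelling: NIHSS, diabetes, anticoagulation and other
  clinical covariates are deliberately outside the index.
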