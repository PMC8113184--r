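---
title: "Methods: semi-quantitative capillary pathology scoring"
author: "capmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative capillary pathology scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scoring model

Skeletal-muscle capillary pathology in systemic sclerosis and the
inflammatory myopathies is graded here with a per-capillary ordinal rubric
of five categories, each scored 0 / 1 / 2: basement-membrane (BM)
thickening, BM reduplication, endothelial activation, ensheathment by
pericyte/endothelial processes, and tubuloreticular inclusions (TRI). The
first four categories sum to a per-capillary score in 0–8; averaging that
sum over the `N` capillaries of a biopsy gives the case's **AS score**
(Average Sum), and averaging one category gives its **ACS score** (Average
Category Sum). By construction the four ACS values of a case sum exactly
to its AS; the package asserts this identity to 1e-12 in its test suite.
TRI is scored per capillary but kept out of the sum — it instead drives a
per-case presence flag alongside the manually recorded flags
(myophagocytosis, nuclear inclusions).

Underlying assumptions: capillaries are scored independently; every
annotated capillary contributes equally to AS regardless of size; and the
sampling rule caps annotation at 100 capillaries per case (cases with
fewer are used in full), so AS is a mean over at most 100 exchangeable
units.

### Band conventions

Three of the five categories have printed numeric anchors; `capmorph`
fixes their boundary conventions as follows (all in `ScoringConfig`):

* **Thickness bands are half-open**: `[100, 200)` nm scores 1 and
  `[200, Inf)` scores 2, reading "200+" as ≥ 200. This makes the scorer a
  monotone step function with no ambiguous inputs. Whether original
  readers graded an exactly-200-nm capillary up or down is not knowable
  from a visual consensus procedure; either convention changes AS by at
  most one capillary increment.
* **Sub-50 nm BM scores 0.** The 50–100 nm band describes the normal
  range; a thinner-than-normal BM is not pathological *thickening*.
* **Ensheathment size qualifiers demote, never promote.** The count rule
  (0–4 / 5–6 / 7+ processes) is primary; the qualifier `focal_small`
  (encoding "not only focal and small" / "also depending on size")
  demotes the count-derived score by exactly one level, floored at 0. A
  missing qualifier defaults to `prominent`, i.e. the pure count rule.
* **A single small TRI scores 0**: the level-1 clause starts at "2 small
  or 1 medium", so one small inclusion falls below the bar. Mixed TRI
  lists take the maximum applicable clause.

Two categories are defined only qualitatively and therefore carry
package-defined, config-exposed conventions rather than recovered values:

* **Endothelial activation** accepts either an explicit consensus grade
  (none/mild/marked) or a raw pair (endothelial cross-sectional area,
  organelle prominence). The raw route bands the area ratio relative to a
  reference area `areaRefUm2` (default 10 µm², a typical endothelial ring
  of a normal ~8 µm muscle capillary): < 1.5× none-eligible, 1.5–3×
  mild-eligible, > 3× marked-eligible, combined with the organelle level
  (none/increased/marked = 0/1/2) by a **max rule**, implementing
  "increased area **and/or** organelles".
* **TRI size classes** are assigned by maximum diameter: small < 300 nm,
  medium 300–800 nm, large > 800 nm. These cuts are conventions chosen to
  bracket commonly reported TRI dimensions; they are not recovered from
  the emulated study and are flagged as such in the documentation.

### Missing data (degraded capillaries)

Severely degraded capillaries — e.g. an almost empty BM "sack" with the
endothelium lost — are scored on whatever is measurable. A category that
cannot be assessed is NA; in the four-category sum missing categories
count as 0 (with a warning), so a capillary never gains score from
missingness; only a capillary with **all four** categories missing drops
out of `N` entirely. This keeps AS well defined on real material while
biasing it, if at all, downward for degraded vessels.

## Morphometry

The rubric was designed for visual assessment; the morphometry module
gives its features explicit measurement semantics on polygonal
annotations (coordinates in nm, image convention: origin top-left, y
down). BM layers are annular bands (inner + outer contour); processes are
simple polygons; TRI marks are points with a diameter.

* **BM thickness** is measured by casting `nRays` (default 36) equally
  spaced rays from the lumen's area centroid and summing, per ray, the
  length inside the union of the BM bands (crossing-parity interval
  arithmetic, robust to rays through polygon vertices); the reported
  value is a summary over rays that hit the BM. The default summary is
  the **median** — robust to focal bulges — with mean and max selectable,
  because it is unknown whether original readers graded the typical or
  the thickest point; the choice is reported alongside the value. For
  non-star-shaped lumina whose centroid falls outside the contour, the
  ray origin falls back to an interior point of maximal boundary
  clearance (grid-refined pole of inaccessibility), with a message.
* **Layer count** is the number of annotated BM bands after a nesting
  check (non-nested overlapping bands are an annotation error).
* **Processes** are counted if they touch the peri-capillary annulus of
  width 1000 nm (convention; config-exposed) outside the outermost BM.
  Prominence is graded from the union of angular arcs the counted
  processes subtend from the capillary center: < 25 % of the perimeter →
  `focal_small`, 25–75 % → `prominent`, > 75 % → `very_prominent`.
* **Endothelial area** is the outer endothelial contour area minus the
  lumen area (shoelace), in µm².

Numerical behaviour: measurements are exactly invariant under
translation; the ray fan is anchored to the centroid but its directions
are fixed in the world frame, so thickness is exactly invariant under
rotations commensurate with the fan (multiples of 360°/`nRays`) and
invariant to within the per-ray sampling density otherwise — areas and
counts are invariant under any rigid motion. Thickness is insensitive to
uniform vertex densification (tested 72 → 288 vertices, < 0.02 %
change). Degenerate inputs fail loudly: zero-width bands and absent BM
raise measurement errors rather than returning 0.

## The synthetic cohort generator

The generator exists so every pipeline stage can be exercised, at study
scale, without any image data. It emulates a 29-case muscle-biopsy cohort:
12 MMCP ("minimal myositis with capillary pathology") + 6 non-MMCP SSc
cases, 8 dermatomyositis + 2 anti-synthetase disease controls, and 1
non-diseased control; 100 capillaries per case except eight randomly
chosen cases with U{40..99} (the emulated study reports eight sub-100
samples without printing their counts).

Per group, category scores are drawn i.i.d. per capillary from per-category
probability triplets `(p0, p1, p2)`. The triplets are **moment-matched**
so the expected AS, `Σ_c (p_c1 + 2 p_c2)`, equals the emulated group
means: MMCP 2.35, non-MMCP 4.20, DM 1.45, anti-synthetase 3.55, control
0.08. Between-case spread comes from a case-level latent severity
`s ~ N(0, caseSd)` applied by exponential tilting
(`p'_k ∝ p_k e^{sk}`); `caseSd` is set per group via the linearisation
`SD(AS) ≈ caseSd · Σ_c Var_c(score)` to approximate the reported group
SDs (e.g. 0.62 for MMCP targeting SD ≈ 1.09). The tilt is mildly
nonlinear, so realised SDs are approximate; group means are second-order
accurate. A correlated mode is deliberately absent: no joint
per-capillary data exist to calibrate one, and independent categories are
the conservative default.

Every drawn score is then **inverted into a raw feature sampled uniformly
inside the matching rubric band** (score 1 thickening → U[100, 200) nm,
score 2 reduplication → 4–6 layers, etc.), which guarantees the score
round-trip is *exact*: re-scoring simulated features reproduces the drawn
scores identically, for any `ScoringConfig` used consistently. TRI is
hierarchical — a case is TRI-positive with a group-level probability, and
only positive cases harbor per-capillary TRI — because per-case TRI
presence, not per-capillary prevalence, is the clinically reported
quantity. VAS is truncated-normal on [0, 10] (low-to-medium for MMCP,
high for non-MMCP); CK is log-normal moment-matched to the reported
mean ± SD values (1325 ± 1791 U/l MMCP, 2536 ± 2068 non-specific,
1752 ± 1923 cohort-wide); ages are truncated-normal around the reported
mean of 54 years.

Geometric phantoms (`synthesizeGeometry`) are perturbed ellipses (axis
ratio ≤ 1.08, 2 % harmonic perturbation) whose boundaries are radial
offsets from a common center; the harmonics keep the area centroid at the
construction center to third order, so radial-ray thickness recovers the
nominal BM width well within the 2 % round-trip tolerance; endothelial
ring width solves the quadratic `πd² + I·d = A` for the target area
(1 % tolerance); process wedges are placed at equal angular spacing with
arc coverage at the midpoint of the target prominence band, making count
and prominence recovery exact.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: spatial heterogeneity within a section,
inter-reader disagreement (scores are generated, not read), correlation
between categories within a capillary, annotation noise on contours, and
any association between the clinical covariates and the capillary scores
beyond group membership. Calibration tests demonstrate that the pipeline
reproduces the *group structure* it was told to draw — they are
self-consistency checks, not an independent reproduction of the emulated
study, whose per-capillary human scores are unpublished.

## Case ordering and reporting

The per-case stacked-bar report lays cases out by VAS (primary), AS
(secondary), case id (tiebreak), all ascending; the published ordering
direction and tie handling are unstated, so ascending-with-deterministic
tiebreak is adopted and a `decreasing` switch provided. Group summaries
use the sample SD (n−1) — the usual reading of "mean ± SD" in clinical
papers, also unstated — and flag single-case groups rather than
reporting NA. No hypothesis testing is implemented: the emulated study
names none, and its group contrasts are descriptive.

## Problem sizes and tolerances used in validation

The test suite validates the AS = Σ ACS identity on 10,000 random cases
(tolerance 1e-12), batch-vs-scalar rubric equivalence on an exhaustive
58,320-combination grid (exact), parameter recovery on 1,000 seeded
100-capillary replicates (within 4 SE in ≥ 99 %), morphometry round-trips
on 500 random phantoms (counts exact; thickness 2 %, area 1 %) plus
analytic annuli from 50–400 nm, profile calibration on 200 replicate
cohorts (group mean AS inside the emulated min–max ranges in ≥ 95 %), and
byte-identical reproduction of a seeded cohort. These sizes were chosen
to bound Monte-Carlo noise well below the tested tolerances while keeping
the default test run fast on a laptop.

## Known limitations

* The activation area bands, TRI diameter classes, annulus width and
  coverage cuts are conventions; studies using different conventions will
  produce shifted ACS values for those categories. All are config-exposed
  and serialized with every run manifest.
* Thickness measurement assumes annotations resolve individual BM bands;
  fused or "fuzzy" reduplication annotated as one thick band will score
  reduplication 0 while thickening scores high.
* The rubric is ordinal; AS averages ordinal scores, inheriting the usual
  caveat that a 0→1 step and a 1→2 step are not guaranteed to represent
  equal pathological increments.
* hType / group labels are inputs throughout: the package never infers a
  histological pattern from scores.
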