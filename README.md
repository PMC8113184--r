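# capmorph

Semi-quantitative scoring of skeletal-muscle **capillary pathology** in
large-scale electron microscopy (EM) datasets, for muscle pathologists and
image analysts working on systemic sclerosis (SSc) and inflammatory
myopathies.

Entire ultrathin sections digitized at ~7.3 nm pixel size make it possible
to annotate and grade every capillary in a biopsy cross-section instead of
a handful of fields. `capmorph` implements the analysis layer of such a
workflow:

* **Rubric.** Each capillary receives five ordinal scores in {0, 1, 2}:

  | category | 0 | 1 | 2 |
  |---|---|---|---|
  | BM thickening | 50–100 nm | 100–200 nm | 200+ nm |
  | BM reduplication | 1 layer | 2–3 layers | 4+ layers |
  | endothelial activation | none | mild (increased area and/or organelles) | marked |
  | ensheathment | 0–4 processes | 5–6 processes (not only focal/small) | 7+ processes |
  | TRI | none | 2 small or 1 medium | 2+ medium or 1+ large |

  (BM = basement membrane; TRI = tubuloreticular inclusion.) Bands are
  half-open: exactly 200 nm scores 2.

* **Case statistics.** For a case with *N* scored capillaries, the
  **AS score** (Average Sum, range 0–8) is
  `AS = (1/N) Σ_i (thickening_i + reduplication_i + activation_i + ensheathment_i)`,
  and the **ACS score** (Average Category Sum, range 0–2) of category *c* is
  `ACS_c = (1/N) Σ_i score_{ic}`; the four ACS values sum exactly to AS.
  TRI never enters the sums but drives a per-case presence flag.
  Group summaries report mean ± SD (n−1) and range of per-case AS; cases
  are ordered by VAS (a 0–10 cm light-microscopy severity score), then AS,
  for the stacked-bar per-case report.

* **Morphometry.** Rubric features are measured from polygonal capillary
  annotations (QuPath-compatible GeoJSON): BM thickness by radial rays
  through the annular BM bands (median over 36 rays by default), layer
  counts from nested bands, ensheathing-process counts and arc-coverage
  prominence in a 1 µm peri-capillary annulus, and endothelial
  cross-sectional area.

* **Synthetic cohorts.** A seeded generator draws study-like cohorts
  (12 MMCP + 6 non-MMCP SSc cases, 8 dermatomyositis + 2 anti-synthetase
  disease controls, 1 normal control; 100 capillaries per case with eight
  sub-100 cases) whose group AS statistics match the emulated study, plus
  geometric phantoms with known ground truth for validating the
  morphometry.

## Worked example

```r
library(capmorph)

sim <- simulateCohort(seed = 1)
sim$cohort
#> CapillaryCohort: 29 cases, 2627 scored capillaries
#>   groups: ASyS=2, control=1, DM=8, MMCP=12, nonMMCP=6
#>   AS score range: 0.05 - 5.69 (mean 2.56)

summarizeGroups(sim$cohort)[, 1:6]
#>   group_label n_cases  as_mean     as_sd   as_min   as_max
#> 1        MMCP      12 2.232184 1.1036956 1.086957 5.296296
#> 2     nonMMCP       6 4.146426 0.9331881 2.850000 5.180000
#> 3          DM       8 1.444506 0.5179975 0.490000 2.130000
#> 4        ASyS       2 5.455000 0.3323402 5.220000 5.690000
#> 5     control       1 0.050000 0.0000000 0.050000 0.050000
```

The MMCP group mean AS of ~2.2 ± 1.1 against ~4.1 ± 0.9 for non-MMCP
myositis reproduces the separation the rubric is designed to show: minimal
myositis with capillary pathology scores markedly lower than the overtly
inflammatory patterns, while the normal control sits near zero.

Scoring a single capillary directly:

```r
scoreCapillary(list(bm_thickness_nm = 250, bm_layer_count = 5,
                    activation_grade = "marked", process_count = 8,
                    process_prominence = "very_prominent", tri_large = 1))
#> $bm_thickening [1] 2 ... $four_category_sum [1] 8
```

Measuring an annotated capillary and scoring the result:

```r
geoms <- readAnnotations("capillaries.geojson")   # QuPath GeoJSON, nm or pixels
feat  <- extractFeatures(geoms[[1]], caseId = "case_01", capillaryId = "cap_001")
scoreCapillaries(feat)
```

Command line (same functions, thin wrapper in `inst/scripts/capmorph`):

```sh
capmorph simulate  --seed 7 --out run/
capmorph score     --in run/features.csv --out run/scores.csv
capmorph summarize --scores run/scores.csv --cases run/cases.csv --out run/summary.csv
capmorph report    --scores run/scores.csv --cases run/cases.csv --out run/report.png
```

Every run writes a JSON manifest with checksums and record counts;
`verifyRunManifest()` detects silently truncated tables.

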