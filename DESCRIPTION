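Package: capmorph
Title: Semi-Quantitative Capillary Pathology Scoring for Large-Scale
    Electron Microscopy of Skeletal Muscle
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a semi-quantitative rubric for scoring capillary
    pathology in large-scale electron microscopy datasets of skeletal
    muscle: per-capillary ordinal scores (0/1/2) for basement-membrane
    thickening, basement-membrane reduplication, endothelial activation,
    ensheathment by pericyte or endothelial processes, and tubuloreticular
    inclusions; per-case Average Sum (AS) and Average Category Sum (ACS)
    statistics with group summaries and severity-ordered case reports; a
    geometry engine that measures rubric features (basement-membrane
    thickness, layer counts, process counts, endothelial area) from
    polygonal capillary cross-section annotations in QuPath-compatible
    GeoJSON; and a seeded synthetic-cohort generator that emulates the
    group structure of a muscle-biopsy study (minimal myositis with
    capillary pathology, non-MMCP myositis, dermatomyositis,
    anti-synthetase syndrome, non-diseased control) for end-to-end
    pipeline validation without any image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    pracma,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
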