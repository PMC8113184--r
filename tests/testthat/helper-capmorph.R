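# Shared fixtures and independent oracles, built in code.

# circle contour (hand-rolled, independent of the package's generator)
circleContour <- function(r, center = c(0, 0), n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# independent shoelace area oracle
shoelace <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

# annulus phantom: circular lumen/endothelium plus one BM band of known width
annulusGeometry <- function(rLumen = 1400, rEndo = 1500, bmWidth = 250,
                            nLayers = 1L, gap = 30, center = c(0, 0),
                            n = 96L) {
  layers <- list()
  off <- rEndo
  w <- bmWidth / nLayers
  for (i in seq_len(nLayers)) {
    layers[[i]] <- list(inner = circleContour(off, center, n),
                        outer = circleContour(off + w, center, n))
    off <- off + w + gap
  }
  CapillaryGeometry(circleContour(rLumen, center, n),
                    circleContour(rEndo, center, n), bmLayers = layers)
}

# fully-specified feature row whose expected category scores are all known
featureRow <- function(case = "c1", cap = "k1", thickness = 75, layers = 1L,
                       grade = "none", area = NA, organelle = NA,
                       procs = 2L, prominence = "prominent",
                       triS = 0L, triM = 0L, triL = 0L) {
  data.frame(case_id = case, capillary_id = cap,
             bm_thickness_nm = thickness, bm_layer_count = layers,
             activation_grade = grade, endothelial_area_um2 = area,
             organelle_prominence = organelle, process_count = procs,
             process_prominence = prominence, tri_small = triS,
             tri_medium = triM, tri_large = triL, degraded = FALSE,
             stringsAsFactors = FALSE)
}

# random valid feature table with non-degenerate coverage of every band
randomFeatures <- function(n, caseIds = "c1") {
  data.frame(
    case_id = sample(caseIds, n, replace = TRUE),
    capillary_id = sprintf("k%04d", seq_len(n)),
    bm_thickness_nm = runif(n, 55, 400),
    bm_layer_count = sample(1:6, n, replace = TRUE),
    activation_grade = sample(c("none", "mild", "marked"), n, replace = TRUE),
    endothelial_area_um2 = NA_real_,
    organelle_prominence = NA_character_,
    process_count = sample(0:10, n, replace = TRUE),
    process_prominence = sample(c("focal_small", "prominent",
                                  "very_prominent"), n, replace = TRUE),
    tri_small = sample(0:3, n, replace = TRUE),
    tri_medium = sample(0:3, n, replace = TRUE),
    tri_large = sample(0:2, n, replace = TRUE),
    degraded = FALSE, stringsAsFactors = FALSE)
}

# minimal valid caseData frame for a set of case ids
makeCaseData <- function(ids, group = "MMCP", vas = NULL) {
  n <- length(ids)
  data.frame(case_id = ids, group_label = rep_len(group, n),
             htype_label = "MMCP",
             vas = if (is.null(vas)) runif(n, 0, 10) else vas,
             lm_capillaries = sample(0:3, n, replace = TRUE),
             lm_muscle_fibers = sample(0:3, n, replace = TRUE),
             lm_endo_perimysium = sample(0:3, n, replace = TRUE),
             myophagocytosis = FALSE, nuclear_inclusions = FALSE,
             stringsAsFactors = FALSE)
}
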