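test_that("BM thickening bands match the printed rubric anchors", {
  expect_identical(scoreBmThickening(c(75, 150, 250)), c(0L, 1L, 2L))
  # half-open boundaries: 100 opens the mild band, 200 the marked band
  expect_identical(scoreBmThickening(c(100, 199.999, 200)), c(1L, 1L, 2L))
  # thinner-than-normal BM is not pathological thickening
  expect_identical(scoreBmThickening(30), 0L)
  expect_error(scoreBmThickening(-5), "positive")
  expect_error(scoreBmThickening(Inf), "positive")
  expect_identical(scoreBmThickening(NA_real_), NA_integer_)
})

test_that("BM reduplication bands match the printed layer counts", {
  expect_identical(scoreBmReduplication(c(1, 2, 3, 4, 5)),
                   c(0L, 1L, 1L, 2L, 2L))
  expect_error(scoreBmReduplication(0), ">= 1")
  expect_error(scoreBmReduplication(2.5), ">= 1")
})

test_that("thickening and reduplication scorers are monotone", {
  th <- sort(runif(200, 1, 500))
  expect_true(all(diff(scoreBmThickening(th)) >= 0))
  expect_true(all(diff(scoreBmReduplication(1:20)) >= 0))
})

test_that("activation grades map directly and the raw route uses the max rule", {
  expect_identical(
    scoreEndothelialActivation(grade = c("none", "mild", "marked")),
    c(0L, 1L, 2L))
  # independent enumeration of the (area band x organelle level) grid:
  # expected score = max(band score, organelle level)
  cfg <- ScoringConfig()
  ratios <- c(1.0, 2.0, 4.0)         # one per band
  bandScore <- c(0L, 1L, 2L)
  orgs <- c("none", "increased", "marked")
  for (i in seq_along(ratios)) for (j in seq_along(orgs)) {
    got <- scoreEndothelialActivation(areaUm2 = ratios[i] * cfg@areaRefUm2,
                                      organelle = orgs[j], config = cfg)
    expect_identical(got, max(bandScore[i], j - 1L),
                     label = sprintf("ratio %g x %s", ratios[i], orgs[j]))
  }
  # band edges: mild band is closed at areaMildRatio, open at areaMarkedRatio
  expect_identical(scoreEndothelialActivation(
    areaUm2 = cfg@areaMildRatio * cfg@areaRefUm2, organelle = "none"), 1L)
  expect_identical(scoreEndothelialActivation(
    areaUm2 = cfg@areaMarkedRatio * cfg@areaRefUm2, organelle = "none"), 1L)
  expect_error(scoreEndothelialActivation(grade = "severe"), "unknown")
  expect_error(scoreEndothelialActivation(grade = NA_character_),
               "grade or the raw")
})

test_that("ensheathment counts band correctly and size demotes one level", {
  expect_identical(scoreEnsheathment(c(0, 3, 4, 5, 6, 7, 8)),
                   c(0L, 0L, 0L, 1L, 1L, 2L, 2L))
  expect_identical(scoreEnsheathment(6, "focal_small"), 0L)
  expect_identical(scoreEnsheathment(8, "focal_small"), 1L)
  expect_identical(scoreEnsheathment(0, "focal_small"), 0L)
  expect_identical(scoreEnsheathment(8, "very_prominent"), 2L)
  # missing qualifier defaults to prominent (no demotion)
  expect_identical(scoreEnsheathment(5, NA_character_), 1L)
  expect_error(scoreEnsheathment(-1), ">= 0")
  expect_error(scoreEnsheathment(5, "huge"), "unknown")
})

test_that("TRI score follows the size/count clauses with a max rule", {
  expect_identical(scoreTri(), 0L)                       # no TRI
  expect_identical(scoreTri(small = 1), 0L)              # one small: below bar
  expect_identical(scoreTri(small = 2), 1L)
  expect_identical(scoreTri(medium = 1), 1L)
  expect_identical(scoreTri(medium = 2), 2L)
  expect_identical(scoreTri(large = 1), 2L)
  # mixed lists take the maximum applicable clause
  expect_identical(scoreTri(small = 3, medium = 1), 1L)
  expect_identical(scoreTri(small = 2, large = 1), 2L)
  expect_error(scoreTri(small = -1), "non-negative")
  expect_identical(
    triCounts(data.frame(size_class = c("small", "medium", "small"),
                         count = c(1L, 2L, 1L))),
    c(small = 2L, medium = 2L, large = 0L))
  expect_error(triCounts(data.frame(size_class = "huge", count = 1L)),
               "unknown TRI size class")
})

test_that("scoreCapillary composes the five clause sets", {
  s2 <- scoreCapillary(featureRow(thickness = 250, layers = 5,
                                  grade = "marked", procs = 8,
                                  prominence = "very_prominent", triL = 1))
  expect_identical(unlist(s2),
                   c(bm_thickening = 2L, bm_reduplication = 2L,
                     endothelial_activation = 2L, ensheathment = 2L,
                     tri = 2L, four_category_sum = 8L))
  s0 <- scoreCapillary(featureRow(thickness = 75, layers = 1, grade = "none",
                                  procs = 2))
  expect_identical(s0$four_category_sum, 0L)
  expect_identical(s0$tri, 0L)
  s1 <- scoreCapillary(featureRow(thickness = 150, layers = 2, grade = "mild",
                                  procs = 5, triM = 1))
  expect_identical(unlist(s1),
                   c(bm_thickening = 1L, bm_reduplication = 1L,
                     endothelial_activation = 1L, ensheathment = 1L,
                     tri = 1L, four_category_sum = 4L))
  expect_error(scoreCapillary(featureRow(thickness = -1)), "BM thickening")
  expect_error(scoreCapillary(featureRow(layers = 0)), "BM reduplication")
})

test_that("degraded capillaries are scored on measurable categories", {
  # BM measurable, the rest missing: sum counts the measurable ones
  f <- featureRow(thickness = 250, layers = NA, grade = NA, procs = NA)
  f$bm_layer_count <- NA_integer_; f$activation_grade <- NA_character_
  f$process_count <- NA_integer_
  f$tri_small <- NA_integer_; f$tri_medium <- NA_integer_
  f$tri_large <- NA_integer_
  s <- scoreCapillary(f)
  expect_identical(s$bm_thickening, 2L)
  expect_identical(s$four_category_sum, 2L)
  expect_identical(s$tri, NA_integer_)
  expect_warning(sb <- scoreCapillaries(f), "missing categories count as 0")
  expect_identical(sb$four_category_sum, 2L)
  # all four missing: the capillary cannot contribute a sum at all
  f$bm_thickness_nm <- NA_real_
  expect_identical(scoreCapillary(f)$four_category_sum, NA_integer_)
  expect_identical(scoreCapillaries(f)$four_category_sum, NA_integer_)
})

test_that("every category score lies in {0,1,2} on an exhaustive grid and the
           batch path agrees exactly with the scalar path", {
  set.seed(42)
  grid <- expand.grid(
    bm_thickness_nm = c(55, 100, 150, 200, 300),
    bm_layer_count = c(1L, 2L, 4L),
    activation_grade = c("none", "mild", "marked"),
    process_count = c(0L, 5L, 8L),
    process_prominence = c("focal_small", "prominent", "very_prominent"),
    tri_medium = 0:2, stringsAsFactors = FALSE)
  grid$case_id <- "c1"
  grid$capillary_id <- sprintf("k%04d", seq_len(nrow(grid)))
  batch <- scoreCapillaries(grid)
  cols <- c("bm_thickening", "bm_reduplication", "endothelial_activation",
            "ensheathment", "tri")
  for (cc in cols) expect_true(all(batch[[cc]] %in% 0:2))
  expect_identical(batch$four_category_sum,
                   as.integer(rowSums(batch[, cols[1:4]])))
  scalar <- lapply(seq_len(nrow(grid)),
                   function(i) scoreCapillary(grid[i, ]))
  for (cc in c(cols, "four_category_sum"))
    expect_identical(batch[[cc]],
                     vapply(scalar, function(s) s[[cc]], integer(1L)),
                     label = cc)
})
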