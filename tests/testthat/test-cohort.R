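scoresFrame <- function(caseIds, sums, tri = 0L) {
  n <- length(sums)
  data.frame(case_id = rep_len(caseIds, n),
             capillary_id = sprintf("k%03d", seq_len(n)),
             bm_thickening = pmin(sums, 2L), bm_reduplication = 0L,
             endothelial_activation = 0L, ensheathment = 0L,
             tri = rep_len(tri, n), four_category_sum = as.integer(sums),
             stringsAsFactors = FALSE)
}

test_that("AS is the per-case mean of the four-category sums", {
  expect_equal(asScore(scoresFrame("c1", c(2L, 6L))), c(c1 = 4))
  expect_equal(asScore(scoresFrame("c1", rep(0L, 5))), c(c1 = 0))
  expect_error(asScore(data.frame(case_id = character(),
                                  capillary_id = character(),
                                  four_category_sum = integer())),
               "no capillary scores")
  # scalar-loop oracle on a 100-capillary random table
  set.seed(7)
  feat <- randomFeatures(100)
  sc <- scoreCapillaries(feat)
  oracle <- 0
  for (i in seq_len(100)) {
    s <- scoreCapillary(feat[i, ])
    oracle <- oracle + s$four_category_sum
  }
  expect_equal(unname(asScore(sc)), oracle / 100)
})

test_that("ACS averages one category and the four ACS values sum to AS", {
  sc <- scoresFrame("c1", c(2L, 2L, 2L))
  sc$bm_thickening <- 2L
  expect_equal(acsScore(sc, "bm_thickening"), c(c1 = 2))
  sc2 <- scoresFrame("c1", c(0L, 1L, 2L))
  sc2$bm_thickening <- 0:2
  expect_equal(acsScore(sc2, "bm_thickening"), c(c1 = 1))
  expect_error(acsScore(sc2, "tri"), "unknown ACS category")
  set.seed(11)
  for (rep in 1:20) {
    feat <- randomFeatures(sample(5:60, 1), caseIds = c("a", "b", "c"))
    sc <- scoreCapillaries(feat)
    acs <- acsScore(sc)
    as <- asScore(sc)
    tot <- rowSums(acs[, c("bm_thickening", "bm_reduplication",
                           "endothelial_activation", "ensheathment")])
    expect_equal(unname(tot), unname(as[acs$case_id]), tolerance = 1e-12)
    expect_true(all(as >= 0 & as <= 8))
    expect_true(all(as.matrix(acs[, -1L]) >= 0 & as.matrix(acs[, -1L]) <= 2))
  }
})

test_that("AS is invariant under permutation of capillaries", {
  set.seed(3)
  feat <- randomFeatures(80, caseIds = c("a", "b"))
  sc <- scoreCapillaries(feat)
  perm <- sc[sample(nrow(sc)), ]
  expect_equal(asScore(sc), asScore(perm))
})

test_that("group summaries use sample SD and flag single-case groups", {
  cd <- makeCaseData(c("c1", "c2"), group = "ASyS", vas = c(5, 6))
  # two cases with AS exactly 2.56 and 4.55 (25 capillaries each)
  s1 <- scoresFrame("c1", rep(c(2L, 3L), c(11, 14)))   # mean 2.56
  s2 <- scoresFrame("c2", rep(c(4L, 5L), c(45, 55)))   # mean 4.55
  s2$capillary_id <- sprintf("m%03d", seq_len(nrow(s2)))
  coh <- CapillaryCohort(cd, rbind(s1, s2))
  g <- summarizeGroups(coh)
  expect_equal(g$as_mean, 3.555)
  expect_equal(g$as_min, 2.56)
  expect_equal(g$as_max, 4.55)
  expect_equal(g$as_sd, sd(c(2.56, 4.55)))
  expect_false(g$single_case)
  coh1 <- CapillaryCohort(cd[1L, ], s1)
  g1 <- summarizeGroups(coh1)
  expect_identical(g1$as_sd, 0)
  expect_true(g1$single_case)
  # mean within [min, max] and two-pass oracle on a random cohort
  set.seed(5)
  ids <- sprintf("c%02d", 1:10)
  cd <- makeCaseData(ids)
  feat <- randomFeatures(400, caseIds = ids)
  coh <- CapillaryCohort(cd, scoreCapillaries(feat))
  g <- summarizeGroups(coh)
  as <- asScore(coh)
  expect_true(g$as_min <= g$as_mean && g$as_mean <= g$as_max)
  expect_equal(g$as_mean, sum(as) / length(as))
  expect_equal(g$as_sd, sqrt(sum((as - mean(as))^2) / (length(as) - 1)))
})

test_that("case ordering is VAS, then AS, then id, and is stable", {
  cd <- makeCaseData(c("b", "a", "c"), vas = c(2, 1, 1))
  sc <- rbind(scoresFrame("b", 4L), scoresFrame("a", 3L), scoresFrame("c", 1L))
  sc$capillary_id <- sprintf("k%03d", seq_len(nrow(sc)))
  coh <- CapillaryCohort(cd, sc)
  expect_identical(orderCases(coh)$case_id, c("c", "a", "b"))
  # all-equal keys: lexicographic id tiebreak gives a deterministic order
  cd2 <- makeCaseData(c("z", "y", "x"), vas = c(5, 5, 5))
  sc2 <- rbind(scoresFrame("z", 2L), scoresFrame("y", 2L),
               scoresFrame("x", 2L))
  sc2$capillary_id <- sprintf("k%03d", seq_len(nrow(sc2)))
  expect_identical(orderCases(CapillaryCohort(cd2, sc2))$case_id,
                   c("x", "y", "z"))
  # brute-force sort oracle on a simulated 29-case cohort
  sim <- simulateCohort(seed = 99)
  ord <- orderCases(sim$cohort)
  as <- asScore(sim$cohort)
  cd <- caseData(sim$cohort)
  oracle <- cd$case_id[order(cd$vas, as[cd$case_id], cd$case_id)]
  expect_identical(ord$case_id, oracle)
  # missing VAS is an error
  cdNA <- makeCaseData("a", vas = NA_real_)
  expect_error(orderCases(CapillaryCohort(cdNA, scoresFrame("a", 1L))),
               "missing VAS")
})

test_that("TRI presence is derived from capillary scores, other flags pass through", {
  cd <- makeCaseData(c("a", "b"))
  cd$myophagocytosis <- c(TRUE, FALSE)
  cd$nuclear_inclusions <- c(FALSE, TRUE)
  scA <- scoresFrame("a", rep(1L, 4))           # tri all 0
  scB <- scoresFrame("b", rep(1L, 4), tri = c(0L, 0L, 2L, 0L))
  scB$capillary_id <- sprintf("m%03d", 1:4)
  fl <- deriveFindingsFlags(CapillaryCohort(cd, rbind(scA, scB)))
  expect_identical(fl$tri_present, c(FALSE, TRUE))
  expect_identical(fl$myophagocytosis, c(TRUE, FALSE))
  expect_identical(fl$nuclear_inclusions, c(FALSE, TRUE))
  # exhaustive-scan oracle on random cases
  set.seed(13)
  for (rep in 1:10) {
    ids <- c("a", "b", "c")
    feat <- randomFeatures(60, caseIds = ids)
    coh <- CapillaryCohort(makeCaseData(ids), scoreCapillaries(feat))
    fl <- deriveFindingsFlags(coh)
    sc <- capillaryScores(coh)
    for (i in seq_along(ids)) {
      any1 <- FALSE
      for (j in which(sc$case_id == ids[i]))
        if (!is.na(sc$tri[j]) && sc$tri[j] >= 1) any1 <- TRUE
      expect_identical(fl$tri_present[fl$case_id == ids[i]], any1)
    }
  }
})

test_that("empirical ACS recovers the generating probabilities", {
  # i.i.d. capillaries (caseSd = 0): ACS_c estimates p1 + 2*p2
  prof <- defaultGroupProfiles()$MMCP
  prof@caseSd <- 0
  p <- prof@probs
  expected <- p[, 2L] + 2 * p[, 3L]
  se <- sqrt((p[, 2L] + 4 * p[, 3L] - expected^2) / 100)
  set.seed(17)
  hits <- 0L; nrep <- 200L
  for (r in seq_len(nrep)) {
    one <- simulateCase(prof, nCapillaries = 100L)
    acs <- acsScore(scoreCapillaries(one$features))
    ok <- TRUE
    for (i in 1:4)
      if (abs(acs[[i + 1L]] - expected[i]) > 4 * se[i]) ok <- FALSE
    hits <- hits + ok
  }
  expect_gte(hits / nrep, 0.99)
})
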