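degenerateProfile <- function(score) {
  p <- defaultGroupProfiles()$control
  row <- c(0, 0, 0); row[score + 1L] <- 1
  p@probs <- matrix(rep(row, 4L), 4L, byrow = TRUE,
                    dimnames = list(rownames(p@probs), NULL))
  p@caseSd <- 0
  p
}

test_that("degenerate profiles pin the AS score to its extremes", {
  set.seed(1)
  lo <- simulateCase(degenerateProfile(0L), nCapillaries = 20L)
  expect_equal(unname(asScore(scoreCapillaries(lo$features))), 0)
  hi <- simulateCase(degenerateProfile(2L), nCapillaries = 20L)
  expect_equal(unname(asScore(scoreCapillaries(hi$features))), 8)
})

test_that("banded inversion makes the score round-trip exact", {
  set.seed(5)
  for (p in defaultGroupProfiles()) {
    one <- simulateCase(p, nCapillaries = 60L)
    resc <- suppressWarnings(scoreCapillaries(one$features))
    for (cc in c("bm_thickening", "bm_reduplication",
                 "endothelial_activation", "ensheathment", "tri"))
      expect_identical(resc[[cc]], as.integer(one$drawnScores[[cc]]),
                       label = paste(p@label, cc))
  }
})

test_that("simulated mean AS matches the analytic expectation", {
  prof <- defaultGroupProfiles()$MMCP
  prof@caseSd <- 0   # i.i.d. capillaries: E[AS] = sum_c (p1 + 2 p2)
  expected <- sum(prof@probs[, 2L] + 2 * prof@probs[, 3L])
  varSum <- sum(prof@probs[, 2L] + 4 * prof@probs[, 3L] -
                  (prof@probs[, 2L] + 2 * prof@probs[, 3L])^2)
  nrep <- 100L
  se <- sqrt(varSum / 100 / nrep)
  set.seed(23)
  asv <- replicate(nrep, {
    one <- simulateCase(prof, nCapillaries = 100L)
    mean(one$drawnScores$bm_thickening + one$drawnScores$bm_reduplication +
           one$drawnScores$endothelial_activation +
           one$drawnScores$ensheathment)
  })
  expect_lt(abs(mean(asv) - expected), 4 * se)
})

test_that("the default cohort has the study composition", {
  sim <- simulateCohort(seed = 4)
  cd <- caseData(sim$cohort)
  expect_identical(nrow(cd), 29L)
  tab <- table(cd$group_label)
  expect_identical(as.integer(tab[c("MMCP", "nonMMCP", "DM", "ASyS",
                                    "control")]),
                   c(12L, 6L, 8L, 2L, 1L))
  # eight cases sampled with fewer than 100 capillaries, the rest exactly 100
  expect_identical(sum(cd$n_capillaries < 100L), 8L)
  expect_true(all(cd$n_capillaries[cd$n_capillaries < 100L] >= 40L))
  expect_true(all(cd$n_capillaries <= 100L))
  expect_identical(sum(cd$n_capillaries), nrow(sim$features))
  expect_true(all(cd$vas >= 0 & cd$vas <= 10))
})

test_that("the control profile yields a near-zero cohort AS", {
  cfg <- defaultCohortConfig(
    profiles = defaultGroupProfiles()["control"], nBelow100 = 0L)
  sim <- simulateCohort(cfg, seed = 8)
  expect_lt(mean(asScore(sim$cohort)), 0.5)
})

test_that("simulation is deterministic given the seed", {
  a <- simulateCohort(seed = 123)
  b <- simulateCohort(seed = 123)
  expect_identical(a$features, b$features)
  expect_identical(caseData(a$cohort), caseData(b$cohort))
  c2 <- simulateCohort(seed = 124)
  expect_false(identical(a$features, c2$features))
})

test_that("invalid profiles are rejected", {
  p <- defaultGroupProfiles()$MMCP
  p@probs[1L, ] <- c(0.5, 0.6, 0.1)   # sums to 1.2
  expect_error(simulateCase(p), "sum to 1")
  expect_error(synthesizeGeometry(list(bm_thickness_nm = -5,
                                       bm_layer_count = 1L)),
               "configuration error")
  expect_error(synthesizeGeometry(list(bm_thickness_nm = 100,
                                       bm_layer_count = 0L)),
               "configuration error")
})
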