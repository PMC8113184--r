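test_that("annulus phantoms measure their analytic thickness and area", {
  g <- annulusGeometry(rLumen = 1400, rEndo = 1500, bmWidth = 250)
  expect_equal(measureBmThickness(g), 250, tolerance = 0.01)
  # closed-form annulus area: pi*(2^2 - 1.5^2) um^2 for r 2000/1500 nm
  g2 <- CapillaryGeometry(circleContour(1500), circleContour(2000),
                          bmLayers = list(list(inner = circleContour(2000),
                                               outer = circleContour(2100))))
  expect_equal(measureEndothelialArea(g2), pi * (4 - 2.25), tolerance = 0.01)
  # shoelace oracle on a random simple polygon (star-convex)
  set.seed(21)
  r <- runif(40, 800, 1200)
  th <- sort(runif(40, 0, 2 * pi))
  poly <- cbind(r * cos(th), r * sin(th))
  inner <- poly * 0.5
  g3 <- CapillaryGeometry(inner, poly,
                          bmLayers = list(list(inner = poly,
                                               outer = poly * 1.1)))
  expect_equal(measureEndothelialArea(g3),
               (shoelace(poly) - shoelace(inner)) / 1e6, tolerance = 1e-9)
  # lumen equal to the outer contour: zero endothelial area
  g4 <- CapillaryGeometry(circleContour(1500), circleContour(1500.0001),
                          bmLayers = list(list(inner = circleContour(1501),
                                               outer = circleContour(1700))))
  expect_lt(measureEndothelialArea(g4), 0.01)
})

test_that("degenerate geometries raise measurement errors", {
  # zero-width BM band: no ray accumulates thickness
  g <- CapillaryGeometry(circleContour(1400), circleContour(1500),
                         bmLayers = list(list(inner = circleContour(1600),
                                              outer = circleContour(1600))))
  expect_error(measureBmThickness(g), "measurement failed")
  g2 <- CapillaryGeometry(circleContour(1400), circleContour(1500))
  expect_error(measureBmThickness(g2), "no BM layer")
  expect_error(countBmLayers(g2), "no BM layer")
})

test_that("layer counting validates nesting", {
  g <- annulusGeometry(bmWidth = 300, nLayers = 4L)
  expect_identical(countBmLayers(g), 4L)
  expect_identical(countBmLayers(annulusGeometry()), 1L)
  # overlapping, non-nested bands are an annotation error
  bad <- CapillaryGeometry(circleContour(1400), circleContour(1500),
    bmLayers = list(list(inner = circleContour(1500),
                         outer = circleContour(1800)),
                    list(inner = circleContour(1600),
                         outer = circleContour(1900))))
  expect_error(countBmLayers(bad), "not nested|overlap")
})

test_that("process counting and prominence grading follow arc coverage", {
  g0 <- annulusGeometry()
  expect_identical(countProcesses(g0)$count, 0L)
  expect_identical(countProcesses(g0)$prominence, "focal_small")
  # generated wedges: 8 processes covering ~85% -> very prominent
  set.seed(31)
  f <- list(bm_thickness_nm = 150, bm_layer_count = 1L,
            endothelial_area_um2 = 8, process_count = 8L,
            process_prominence = "very_prominent")
  g8 <- synthesizeGeometry(f)
  got <- countProcesses(g8)
  expect_identical(got$count, 8L)
  expect_identical(got$prominence, "very_prominent")
  expect_equal(got$coverage, 0.85, tolerance = 0.05)
  # 5 tiny processes covering ~15% -> focal_small
  f$process_count <- 5L; f$process_prominence <- "focal_small"
  g5 <- synthesizeGeometry(f)
  got5 <- countProcesses(g5)
  expect_identical(got5$count, 5L)
  expect_identical(got5$prominence, "focal_small")
  expect_equal(got5$coverage, 0.15, tolerance = 0.05)
})

test_that("feature extraction round-trips generator parameters", {
  set.seed(41)
  for (rep in 1:15) {
    truth <- list(
      bm_thickness_nm = runif(1, 60, 400),
      bm_layer_count = sample(1:5, 1),
      endothelial_area_um2 = runif(1, 4, 30),
      process_count = sample(0:9, 1),
      process_prominence = sample(c("focal_small", "prominent",
                                    "very_prominent"), 1),
      tri_small = sample(0:2, 1), tri_medium = sample(0:2, 1),
      tri_large = sample(0:1, 1))
    g <- synthesizeGeometry(truth)
    f <- extractFeatures(g, caseId = "c", capillaryId = "k")
    expect_equal(f$bm_thickness_nm, truth$bm_thickness_nm, tolerance = 0.02)
    expect_identical(f$bm_layer_count, truth$bm_layer_count)
    expect_identical(f$process_count, truth$process_count)
    expect_equal(f$endothelial_area_um2, truth$endothelial_area_um2,
                 tolerance = 0.01)
    expect_identical(f$tri_small, truth$tri_small)
    expect_identical(f$tri_medium, truth$tri_medium)
    expect_identical(f$tri_large, truth$tri_large)
    if (truth$process_count > 0)
      expect_identical(f$process_prominence, truth$process_prominence)
    expect_false(f$degraded)
  }
})

test_that("measurements are invariant under rigid motion", {
  mkAt <- function(center) annulusGeometry(bmWidth = 220, nLayers = 2L,
                                           center = center)
  base <- mkAt(c(0, 0))
  t0 <- measureBmThickness(base)
  a0 <- measureEndothelialArea(base)
  # translation: the ray fan is anchored to the lumen centroid
  tr <- mkAt(c(123456.7, -98765.4))
  expect_equal(measureBmThickness(tr), t0, tolerance = 1e-9)
  expect_equal(measureEndothelialArea(tr), a0, tolerance = 1e-9)
  expect_identical(countBmLayers(tr), 2L)
  # rotation of every contour about the centroid (fan-commensurate angles
  # give exact equality; the phantom here is circular so any angle works)
  rot <- function(m, a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    m %*% t(R)
  }
  a <- 2 * pi * 5 / 36
  grot <- CapillaryGeometry(rot(base@lumen, a), rot(base@endotheliumOuter, a),
    bmLayers = lapply(base@bmLayers, function(l)
      list(inner = rot(l$inner, a), outer = rot(l$outer, a))))
  expect_equal(measureBmThickness(grot), t0, tolerance = 1e-6 * t0)
  expect_equal(measureEndothelialArea(grot), a0, tolerance = 1e-6 * a0)
})

test_that("thickness is invariant under vertex densification", {
  g1 <- annulusGeometry(n = 72L)
  g2 <- annulusGeometry(n = 288L)
  expect_equal(measureBmThickness(g1), measureBmThickness(g2),
               tolerance = 2e-4)
})

test_that("non-star-shaped lumina fall back to an interior ray origin", {
  # crescent lumen whose area centroid lies in the concavity
  th1 <- seq(0.3, 2 * pi - 0.3, length.out = 60L)
  crescent <- rbind(cbind(2000 * cos(th1), 2000 * sin(th1)),
                    cbind(1500 * cos(rev(th1)), 1500 * sin(rev(th1))))
  g <- CapillaryGeometry(crescent, circleContour(3000),
    bmLayers = list(list(inner = circleContour(3050),
                         outer = circleContour(3250))))
  expect_message(t <- measureBmThickness(g), "pole-of-inaccessibility")
  expect_true(is.finite(t) && t > 0)
})
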