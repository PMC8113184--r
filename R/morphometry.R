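#' Measure basement-membrane thickness by radial rays
#'
#' Casts equally spaced rays from an interior origin of the lumen and
#' measures, along each ray, the total length lying inside the union of the
#' annular BM layer bands; the per-capillary thickness is a summary
#' statistic (default: median, robust to focal bulges) over the rays that
#' intersect the BM. The origin is the lumen's area centroid; for
#' pathological, non-star-shaped lumina whose centroid falls outside the
#' contour, the origin falls back to an interior point of maximal boundary
#' clearance (a pole-of-inaccessibility search), with a message.
#'
#' @param geom a \linkS4class{CapillaryGeometry} with at least one BM layer.
#' @param nRays number of rays (>= 8; default from \code{config}).
#' @param summary per-ray summary: \code{"median"}, \code{"mean"} or
#'   \code{"max"} (default from \code{config}).
#' @param config a \linkS4class{ScoringConfig}.
#' @return thickness in nm (single number).
#' @examples
#' ring <- function(r) .radialContour(c(0, 0), function(th) rep(r, length(th)))
#' g <- CapillaryGeometry(ring(1400), ring(1500),
#'                        bmLayers = list(list(inner = ring(1500),
#'                                             outer = ring(1750))))
#' measureBmThickness(g)  # ~250
#' @export
measureBmThickness <- function(geom, nRays = config@nRays,
                               summary = config@thicknessSummary,
                               config = ScoringConfig()) {
  if (!length(geom@bmLayers))
    stop("measurement failed: no BM layer annotated")
  nRays <- as.integer(nRays)
  if (nRays < 8L) stop("nRays must be >= 8")
  summary <- match.arg(summary, c("median", "mean", "max"))
  origin <- .rayOrigin(geom)
  th <- seq(0, 2 * pi, length.out = nRays + 1L)[-(nRays + 1L)]
  per <- vapply(th, function(a) {
    d <- c(cos(a), sin(a))
    tot <- 0
    for (lay in geom@bmLayers) {
      # origin sits in the lumen, inside both band contours
      lo <- .rayInsideLength(origin, d, lay$outer, insideAtOrigin = TRUE)
      li <- .rayInsideLength(origin, d, lay$inner, insideAtOrigin = TRUE)
      tot <- tot + max(lo - li, 0)
    }
    tot
  }, numeric(1L))
  hit <- per > 1e-9
  if (!any(hit))
    stop("measurement failed: no ray intersects the BM")
  switch(summary,
         median = stats::median(per[hit]),
         mean = mean(per[hit]),
         max = max(per[hit]))
}

.rayOrigin <- function(geom) {
  origin <- .polyCentroid(geom@lumen)
  if (!.pointsInPolygon(origin, geom@lumen)) {
    message("lumen centroid falls outside the contour; ",
            "using pole-of-inaccessibility origin")
    origin <- .poleOfInaccessibility(geom@lumen)
  }
  origin
}

#' Count basement-membrane layers
#'
#' Returns the number of annotated BM layer bands after verifying that they
#' are properly nested (each band's outer contour lies inside the next
#' band's inner contour). A geometry with no annotated reduplication (one
#' band) counts as 1 layer.
#'
#' @param geom a \linkS4class{CapillaryGeometry}.
#' @return integer layer count >= 1.
#' @export
countBmLayers <- function(geom) {
  k <- length(geom@bmLayers)
  if (k == 0L) stop("annotation error: no BM layer annotated")
  if (k > 1L) for (i in seq_len(k - 1L)) {
    outerI <- geom@bmLayers[[i]]$outer
    innerNext <- geom@bmLayers[[i + 1L]]$inner
    if (!all(.pointsInPolygon(outerI, innerNext)))
      stop("annotation error: BM layers ", i, " and ", i + 1L,
           " overlap or are not nested innermost-first")
  }
  k
}

#' Count ensheathing processes and grade their prominence
#'
#' Counts the pericyte/endothelial process polygons that touch the
#' peri-capillary annulus: the band of width \code{annulusWidthNm} just
#' outside the outermost BM contour (outside the endothelium when no BM
#' layer is annotated). Prominence is graded from the fraction of the
#' capillary perimeter covered by the counted processes, measured as the
#' union of the angular arcs they subtend from the capillary center:
#' coverage below \code{coverageFocal} is \code{focal_small}, above
#' \code{coverageProminent} is \code{very_prominent}, \code{prominent}
#' in between.
#'
#' @param geom a \linkS4class{CapillaryGeometry}.
#' @param annulusWidthNm annulus width in nm (default from \code{config}).
#' @param config a \linkS4class{ScoringConfig}.
#' @return list with \code{count} (integer), \code{prominence} (character)
#'   and \code{coverage} (fraction of perimeter, 0--1).
#' @export
countProcesses <- function(geom, annulusWidthNm = config@annulusWidthNm,
                           config = ScoringConfig()) {
  outerRef <- if (length(geom@bmLayers))
    geom@bmLayers[[length(geom@bmLayers)]]$outer else geom@endotheliumOuter
  center <- .rayOrigin(geom)
  spans <- list(); count <- 0L
  for (pr in geom@processes) {
    v <- pr$coords
    insideOuter <- .pointsInPolygon(v, outerRef)
    d <- .distToContour(v, outerRef)
    # touching the annulus: some vertex outside the outermost BM within reach
    if (any(!insideOuter & d <= annulusWidthNm)) {
      count <- count + 1L
      spans[[length(spans) + 1L]] <- .angularSpan(v, center)
    }
  }
  coverage <- .angularUnion(spans) / (2 * pi)
  prominence <- if (coverage > config@coverageProminent) "very_prominent"
    else if (coverage >= config@coverageFocal) "prominent"
    else "focal_small"
  list(count = count, prominence = prominence, coverage = coverage)
}

#' Measure endothelial cross-sectional area
#'
#' The endothelial ring area: area enclosed by the outer endothelial
#' contour minus the lumen area, converted to um^2.
#'
#' @param geom a \linkS4class{CapillaryGeometry}.
#' @return area in um^2.
#' @export
measureEndothelialArea <- function(geom) {
  a <- .polyArea(geom@endotheliumOuter) - .polyArea(geom@lumen)
  if (a < -1e-6)
    stop("annotation error: lumen area exceeds the endothelial outer ",
         "contour area (contours swapped?)")
  max(a, 0) / 1e6
}

#' Extract rubric features from a capillary annotation
#'
#' Runs the four geometric measurements (BM thickness, BM layer count,
#' process count/prominence, endothelial area) and classifies TRI marks by
#' diameter into size classes, assembling a one-row feature table ready for
#' [scoreCapillaries()]. A measurement that fails (e.g. a degraded
#' capillary with no measurable BM) marks the affected features NA and sets
#' \code{degraded = TRUE} instead of aborting.
#'
#' Organelle prominence is not derivable from contours; it is taken from
#' the \code{organelle} argument when the caller has graded it, otherwise
#' left NA (the activation category is then scored only if an explicit
#' grade is supplied downstream).
#'
#' @param geom a \linkS4class{CapillaryGeometry}.
#' @param config a \linkS4class{ScoringConfig}.
#' @param caseId,capillaryId identifiers copied into the output row.
#' @param organelle optional organelle-prominence grade
#'   (\code{none}/\code{increased}/\code{marked}).
#' @return one-row data.frame in the feature-table schema (see
#'   [readFeatureTable()]).
#' @export
extractFeatures <- function(geom, config = ScoringConfig(),
                            caseId = NA_character_,
                            capillaryId = NA_character_,
                            organelle = NA_character_) {
  thick <- tryCatch(measureBmThickness(geom, config = config),
                    error = function(e) NA_real_)
  layers <- tryCatch(countBmLayers(geom), error = function(e) NA_integer_)
  area <- tryCatch(measureEndothelialArea(geom), error = function(e) NA_real_)
  proc <- tryCatch(countProcesses(geom, config = config),
                   error = function(e) list(count = NA_integer_,
                                            prominence = NA_character_))
  tri <- c(small = 0L, medium = 0L, large = 0L)
  if (nrow(geom@triMarks)) {
    d <- geom@triMarks$diameter_nm
    cls <- ifelse(d > config@triMediumMaxNm, "large",
                  ifelse(d >= config@triSmallMaxNm, "medium", "small"))
    tab <- table(factor(cls, levels = names(tri)))
    tri <- tri + as.integer(tab)
  }
  data.frame(
    case_id = caseId, capillary_id = capillaryId,
    bm_thickness_nm = thick,
    bm_layer_count = layers,
    activation_grade = NA_character_,
    endothelial_area_um2 = area,
    organelle_prominence = as.character(organelle),
    process_count = proc$count,
    process_prominence = proc$prominence,
    tri_small = tri[["small"]], tri_medium = tri[["medium"]],
    tri_large = tri[["large"]],
    degraded = is.na(thick) || is.na(layers) || is.na(area) ||
      is.na(proc$count),
    stringsAsFactors = FALSE)
}
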