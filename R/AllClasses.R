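#' @import methods
NULL

#' Scoring configuration for the capillary pathology rubric
#'
#' Holds every numeric convention used by the rubric and the morphometry
#' engine: the basement-membrane (BM) thickness band edges, the BM layer-count
#' cuts, the ensheathment process-count cuts, the endothelial-activation area
#' bands relative to a reference endothelial cross-sectional area, the
#' tubuloreticular-inclusion (TRI) size-class diameter cuts, and the geometric
#' conventions (ray count, peri-capillary annulus width, prominence coverage
#' bands, pixel size).
#'
#' Defaults reproduce the printed rubric cuts: BM thickness bands
#' \eqn{[0,100)}, \eqn{[100,200)}, \eqn{[200,\infty)} nm; reduplication bands
#' 1 layer / 2--3 layers / 4+ layers; ensheathment bands 0--4 / 5--6 / 7+
#' processes. Endothelial-activation area bands and TRI diameter classes are
#' package conventions (the rubric defines those categories qualitatively)
#' and are therefore fully configurable.
#'
#' @slot bmCut1,bmCut2 BM thickness band edges in nm (defaults 100, 200);
#'   thickness in \code{[bmCut1, bmCut2)} scores 1, \code{>= bmCut2} scores 2.
#' @slot layersCut1,layersCut2 BM layer-count cuts (defaults 2, 4).
#' @slot procCut1,procCut2 ensheathment process-count cuts (defaults 5, 7).
#' @slot areaRefUm2 reference endothelial cross-sectional area in um^2
#'   (default 10) against which activation area ratios are formed.
#' @slot areaMildRatio,areaMarkedRatio area/reference ratios opening the
#'   mild-eligible and marked-eligible activation bands (defaults 1.5, 3).
#' @slot triSmallMaxNm,triMediumMaxNm TRI maximum-diameter class cuts in nm
#'   (defaults 300, 800): small < 300, medium 300--800, large > 800.
#' @slot annulusWidthNm width of the peri-capillary annulus, outside the
#'   outermost BM contour, in which ensheathing processes are counted
#'   (default 1000 nm).
#' @slot coverageFocal,coverageProminent perimeter arc-coverage fractions
#'   separating focal_small / prominent / very_prominent process prominence
#'   (defaults 0.25, 0.75).
#' @slot nRays number of equally spaced rays used for BM thickness
#'   measurement (default 36).
#' @slot thicknessSummary per-ray thickness summary statistic: one of
#'   \code{"median"}, \code{"mean"}, \code{"max"}.
#' @slot pixelSizeNm physical pixel size in nm used when importing
#'   pixel-unit annotations (default 7.3).
#'
#' @seealso [ScoringConfig()], [readScoringConfig()]
#' @export
setClass("ScoringConfig",
  representation(
    bmCut1 = "numeric", bmCut2 = "numeric",
    layersCut1 = "numeric", layersCut2 = "numeric",
    procCut1 = "numeric", procCut2 = "numeric",
    areaRefUm2 = "numeric", areaMildRatio = "numeric",
    areaMarkedRatio = "numeric",
    triSmallMaxNm = "numeric", triMediumMaxNm = "numeric",
    annulusWidthNm = "numeric",
    coverageFocal = "numeric", coverageProminent = "numeric",
    nRays = "integer", thicknessSummary = "character",
    pixelSizeNm = "numeric"
  ),
  prototype(
    bmCut1 = 100, bmCut2 = 200,
    layersCut1 = 2, layersCut2 = 4,
    procCut1 = 5, procCut2 = 7,
    areaRefUm2 = 10, areaMildRatio = 1.5, areaMarkedRatio = 3,
    triSmallMaxNm = 300, triMediumMaxNm = 800,
    annulusWidthNm = 1000,
    coverageFocal = 0.25, coverageProminent = 0.75,
    nRays = 36L, thicknessSummary = "median",
    pixelSizeNm = 7.3
  )
)

setValidity("ScoringConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x)) {
      msg <<- c(msg, sprintf("'%s' must be a single finite number", nm))
      FALSE
    } else TRUE
  }
  pairs <- list(
    c("bmCut1", "bmCut2"), c("layersCut1", "layersCut2"),
    c("procCut1", "procCut2"), c("areaMildRatio", "areaMarkedRatio"),
    c("triSmallMaxNm", "triMediumMaxNm"),
    c("coverageFocal", "coverageProminent")
  )
  for (p in pairs) {
    a <- slot(object, p[1L]); b <- slot(object, p[2L])
    if (chk1(a, p[1L]) && chk1(b, p[2L])) {
      if (a <= 0 || b <= 0)
        msg <- c(msg, sprintf("'%s' and '%s' must be positive", p[1L], p[2L]))
      else if (a >= b)
        msg <- c(msg, sprintf("'%s' must be < '%s'", p[1L], p[2L]))
    }
  }
  if (chk1(object@areaRefUm2, "areaRefUm2") && object@areaRefUm2 <= 0)
    msg <- c(msg, "'areaRefUm2' must be positive")
  if (chk1(object@annulusWidthNm, "annulusWidthNm") &&
      object@annulusWidthNm <= 0)
    msg <- c(msg, "'annulusWidthNm' must be positive")
  if (chk1(object@pixelSizeNm, "pixelSizeNm") && object@pixelSizeNm <= 0)
    msg <- c(msg, "'pixelSizeNm' must be positive")
  if (object@coverageProminent >= 1)
    msg <- c(msg, "'coverageProminent' must be < 1")
  if (length(object@nRays) != 1L || object@nRays < 8L)
    msg <- c(msg, "'nRays' must be a single integer >= 8")
  if (!object@thicknessSummary %in% c("median", "mean", "max"))
    msg <- c(msg, "'thicknessSummary' must be one of median/mean/max")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoringConfig
#'
#' @param ... named slot overrides; see \linkS4class{ScoringConfig} for the
#'   slot meanings and defaults.
#' @return a validated \linkS4class{ScoringConfig} object.
#' @examples
#' cfg <- ScoringConfig()
#' cfg2 <- ScoringConfig(bmCut2 = 250)
#' @export
ScoringConfig <- function(...) {
  args <- list(...)
  for (nm in intersect(names(args), c("nRays")))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "ScoringConfig"), args))
}

setMethod("show", "ScoringConfig", function(object) {
  cat("ScoringConfig\n")
  cat(sprintf("  BM thickness bands (nm): [0,%g) / [%g,%g) / [%g,Inf)\n",
              object@bmCut1, object@bmCut1, object@bmCut2, object@bmCut2))
  cat(sprintf("  BM layer bands: 1 / %g-%g / %g+\n",
              object@layersCut1, object@layersCut2 - 1, object@layersCut2))
  cat(sprintf("  process-count bands: 0-%g / %g-%g / %g+\n",
              object@procCut1 - 1, object@procCut1,
              object@procCut2 - 1, object@procCut2))
  cat(sprintf("  activation area bands (x %g um^2): <%g / %g-%g / >%g\n",
              object@areaRefUm2, object@areaMildRatio, object@areaMildRatio,
              object@areaMarkedRatio, object@areaMarkedRatio))
  cat(sprintf("  TRI diameter classes (nm): <%g / %g-%g / >%g\n",
              object@triSmallMaxNm, object@triSmallMaxNm,
              object@triMediumMaxNm, object@triMediumMaxNm))
  cat(sprintf("  thickness: %d rays, %s; process annulus %g nm\n",
              object@nRays, object@thicknessSummary, object@annulusWidthNm))
  invisible(object)
})

#' Polygonal annotation of one capillary cross-section
#'
#' All coordinates are continuous (x, y) positions in nm in the section
#' plane, origin top-left, y increasing downward (image convention). BM
#' layers are annular bands, each held as an inner and an outer closed
#' contour, listed innermost first. Ensheathing pericyte/endothelial
#' processes are simple polygons; TRI marks are points with a diameter.
#'
#' @slot pixelSizeNm physical pixel size of the source dataset in nm
#'   (metadata; coordinates are already in nm).
#' @slot lumen two-column matrix, closed polygon of the capillary lumen.
#' @slot endotheliumOuter two-column matrix, outer contour of the
#'   endothelial ring (lumen lies strictly inside it).
#' @slot bmLayers list of BM layers, innermost first; each element is a
#'   \code{list(inner=, outer=)} of two-column matrices.
#' @slot processes list of process polygons; each element a
#'   \code{list(coords=, size=)} where \code{size} is an optional qualifier
#'   tag in \code{small/medium/large} or \code{NA}.
#' @slot triMarks data.frame with columns \code{x}, \code{y},
#'   \code{diameter_nm} (possibly zero rows).
#'
#' @seealso [CapillaryGeometry()], [extractFeatures()], [synthesizeGeometry()]
#' @export
setClass("CapillaryGeometry",
  representation(
    pixelSizeNm = "numeric",
    lumen = "matrix",
    endotheliumOuter = "matrix",
    bmLayers = "list",
    processes = "list",
    triMarks = "data.frame"
  ),
  prototype(
    pixelSizeNm = 7.3,
    bmLayers = list(), processes = list(),
    triMarks = data.frame(x = numeric(), y = numeric(),
                          diameter_nm = numeric())
  )
)

.isContour <- function(m) {
  is.matrix(m) && ncol(m) == 2L && nrow(m) >= 3L && all(is.finite(m))
}

setValidity("CapillaryGeometry", function(object) {
  msg <- character()
  if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
      object@pixelSizeNm <= 0)
    msg <- c(msg, "'pixelSizeNm' must be a single positive number")
  if (!.isContour(object@lumen))
    msg <- c(msg, "'lumen' must be a finite two-column matrix with >= 3 vertices")
  if (!.isContour(object@endotheliumOuter))
    msg <- c(msg, "'endotheliumOuter' must be a finite two-column matrix")
  for (i in seq_along(object@bmLayers)) {
    lay <- object@bmLayers[[i]]
    if (!is.list(lay) || !all(c("inner", "outer") %in% names(lay)) ||
        !.isContour(lay$inner) || !.isContour(lay$outer))
      msg <- c(msg, sprintf("BM layer %d must be list(inner=, outer=) of contours", i))
  }
  for (i in seq_along(object@processes)) {
    pr <- object@processes[[i]]
    if (!is.list(pr) || is.null(pr$coords) || !.isContour(pr$coords))
      msg <- c(msg, sprintf("process %d must be list(coords=) with a contour", i))
  }
  if (!all(c("x", "y", "diameter_nm") %in% names(object@triMarks)))
    msg <- c(msg, "'triMarks' needs columns x, y, diameter_nm")
  if (length(msg)) return(msg)
  # geometric sanity: every lumen vertex inside the endothelial outer contour
  if (!all(.pointsInPolygon(object@lumen, object@endotheliumOuter)))
    msg <- c(msg, "lumen must lie strictly inside endotheliumOuter")
  if (length(msg)) msg else TRUE
})

#' Construct a CapillaryGeometry
#'
#' @param lumen,endotheliumOuter closed contours (two-column matrices, nm).
#' @param bmLayers list of \code{list(inner=, outer=)} annular BM layers,
#'   innermost first.
#' @param processes list of process polygons; bare matrices are accepted and
#'   wrapped as \code{list(coords=, size=NA)}.
#' @param triMarks data.frame with \code{x}, \code{y}, \code{diameter_nm}.
#' @param pixelSizeNm source pixel size in nm (metadata).
#' @return a validated \linkS4class{CapillaryGeometry}.
#' @export
CapillaryGeometry <- function(lumen, endotheliumOuter, bmLayers = list(),
                              processes = list(),
                              triMarks = data.frame(x = numeric(),
                                                    y = numeric(),
                                                    diameter_nm = numeric()),
                              pixelSizeNm = 7.3) {
  processes <- lapply(processes, function(p) {
    if (is.matrix(p)) list(coords = p, size = NA_character_) else p
  })
  new("CapillaryGeometry", pixelSizeNm = pixelSizeNm,
      lumen = .asContour(lumen), endotheliumOuter = .asContour(endotheliumOuter),
      bmLayers = lapply(bmLayers, function(l)
        list(inner = .asContour(l$inner), outer = .asContour(l$outer))),
      processes = lapply(processes, function(p)
        list(coords = .asContour(p$coords),
             size = if (is.null(p$size)) NA_character_ else p$size)),
      triMarks = triMarks)
}

setMethod("show", "CapillaryGeometry", function(object) {
  cat("CapillaryGeometry (coordinates in nm)\n")
  cat(sprintf("  lumen: %d vertices; endothelium outer: %d vertices\n",
              nrow(object@lumen), nrow(object@endotheliumOuter)))
  cat(sprintf("  BM layers: %d; processes: %d; TRI marks: %d\n",
              length(object@bmLayers), length(object@processes),
              nrow(object@triMarks)))
  invisible(object)
})

#' A scored cohort of muscle-biopsy cases
#'
#' Container pairing one row of case-level metadata per biopsy with the
#' per-capillary ordinal category scores of all its annotated capillaries.
#'
#' \code{caseData} must carry columns \code{case_id}, \code{group_label},
#' \code{htype_label}, \code{vas}, the three light-microscopy subscores
#' (\code{lm_capillaries}, \code{lm_muscle_fibers}, \code{lm_endo_perimysium},
#' each in 0--3), and the manual finding flags \code{myophagocytosis} and
#' \code{nuclear_inclusions}. \code{capillaryScores} must carry
#' \code{case_id}, \code{capillary_id}, the four AS categories
#' (\code{bm_thickening}, \code{bm_reduplication},
#' \code{endothelial_activation}, \code{ensheathment}), \code{tri} and
#' \code{four_category_sum}.
#'
#' @slot caseData data.frame, one row per case.
#' @slot capillaryScores data.frame, one row per scored capillary.
#' @seealso [CapillaryCohort()], [asScore()], [acsScore()],
#'   [summarizeGroups()], [orderCases()]
#' @export
setClass("CapillaryCohort",
  representation(caseData = "data.frame", capillaryScores = "data.frame"))

.SCORE_CATEGORIES <- c("bm_thickening", "bm_reduplication",
                       "endothelial_activation", "ensheathment")
.GROUP_LEVELS <- c("MMCP", "nonMMCP", "DM", "ASyS", "control")

setValidity("CapillaryCohort", function(object) {
  msg <- character()
  needCase <- c("case_id", "group_label", "htype_label", "vas",
                "lm_capillaries", "lm_muscle_fibers", "lm_endo_perimysium",
                "myophagocytosis", "nuclear_inclusions")
  miss <- setdiff(needCase, names(object@caseData))
  if (length(miss))
    msg <- c(msg, paste("caseData lacks columns:", paste(miss, collapse = ", ")))
  needScore <- c("case_id", "capillary_id", .SCORE_CATEGORIES, "tri",
                 "four_category_sum")
  miss <- setdiff(needScore, names(object@capillaryScores))
  if (length(miss))
    msg <- c(msg, paste("capillaryScores lacks columns:",
                        paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(object@caseData$case_id))
      msg <- c(msg, "duplicate case_id in caseData")
    orphan <- setdiff(object@capillaryScores$case_id, object@caseData$case_id)
    if (length(orphan))
      msg <- c(msg, paste("capillaryScores reference unknown case_id:",
                          paste(utils::head(orphan, 3L), collapse = ", ")))
    v <- object@caseData$vas
    if (any(!is.na(v) & (v < 0 | v > 10)))
      msg <- c(msg, "vas must lie in [0, 10]")
    for (sc in c("lm_capillaries", "lm_muscle_fibers", "lm_endo_perimysium")) {
      x <- object@caseData[[sc]]
      if (any(!is.na(x) & !x %in% 0:3))
        msg <- c(msg, sprintf("%s must lie in {0,1,2,3}", sc))
    }
    for (cc in c(.SCORE_CATEGORIES, "tri")) {
      x <- object@capillaryScores[[cc]]
      if (any(!is.na(x) & !x %in% 0:2))
        msg <- c(msg, sprintf("capillary score '%s' must lie in {0,1,2}", cc))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CapillaryCohort
#'
#' @param caseData data.frame of case metadata (see
#'   \linkS4class{CapillaryCohort} for required columns).
#' @param capillaryScores data.frame of per-capillary category scores, e.g.
#'   as produced by [scoreCapillaries()].
#' @return a validated \linkS4class{CapillaryCohort}.
#' @export
CapillaryCohort <- function(caseData, capillaryScores) {
  new("CapillaryCohort", caseData = as.data.frame(caseData),
      capillaryScores = as.data.frame(capillaryScores))
}

setMethod("show", "CapillaryCohort", function(object) {
  cat(sprintf("CapillaryCohort: %d cases, %d scored capillaries\n",
              nrow(object@caseData), nrow(object@capillaryScores)))
  tab <- table(object@caseData$group_label)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  as <- asScore(object)
  if (length(as))
    cat(sprintf("  AS score range: %.2f - %.2f (mean %.2f)\n",
                min(as), max(as), mean(as)))
  invisible(object)
})

#' Generative profile of one study group
#'
#' Describes the distributions from which synthetic cases of one group are
#' drawn: the per-category score probabilities, the case-level severity
#' spread, TRI presence, light-microscopy severity, and clinical covariates.
#'
#' @slot label group label, one of MMCP / nonMMCP / DM / ASyS / control.
#' @slot nCases number of cases drawn for this group by default.
#' @slot htypes character vector of histological-pattern labels sampled for
#'   this group's cases (hType is an input annotation, never inferred).
#' @slot probs 4 x 3 matrix of score probabilities (rows: the four AS
#'   categories; columns: scores 0/1/2); each row sums to 1.
#' @slot caseSd standard deviation of the case-level latent severity that
#'   tilts the category distributions (exponential tilting), creating
#'   realistic between-case AS spread; 0 gives i.i.d. capillaries.
#' @slot triCaseProb probability that a case harbors TRI at all.
#' @slot triProbs length-3 score probabilities of the TRI category within a
#'   TRI-positive case.
#' @slot vasMean,vasSd truncated-normal parameters of the VAS score on [0,10].
#' @slot lmProbs 3 x 4 matrix of light-microscopy subscore probabilities
#'   (rows: capillaries, muscle fibers, endo/perimysium; columns: 0..3).
#' @slot myopProb,nucIncProb probabilities of the per-case manual finding
#'   flags (myophagocytosis, nuclear inclusions).
#' @slot ageMean,ageSd age distribution (normal, truncated to [18, 90]).
#' @slot ckMean,ckSd maximum serum creatine-kinase distribution in U/l
#'   (log-normal, moment-matched to this mean and SD).
#' @seealso [defaultGroupProfiles()], [simulateCase()], [simulateCohort()]
#' @export
setClass("GroupProfile",
  representation(
    label = "character", nCases = "integer", htypes = "character",
    probs = "matrix", caseSd = "numeric",
    triCaseProb = "numeric", triProbs = "numeric",
    vasMean = "numeric", vasSd = "numeric",
    lmProbs = "matrix",
    myopProb = "numeric", nucIncProb = "numeric",
    ageMean = "numeric", ageSd = "numeric",
    ckMean = "numeric", ckSd = "numeric"
  )
)

setValidity("GroupProfile", function(object) {
  msg <- character()
  if (!identical(dim(object@probs), c(4L, 3L)))
    msg <- c(msg, "'probs' must be a 4 x 3 matrix")
  else {
    if (any(object@probs < 0 | object@probs > 1))
      msg <- c(msg, "'probs' entries must lie in [0, 1]")
    if (any(abs(rowSums(object@probs) - 1) > 1e-9))
      msg <- c(msg, "each row of 'probs' must sum to 1 (tolerance 1e-9)")
  }
  if (length(object@triProbs) != 3L || any(object@triProbs < 0) ||
      abs(sum(object@triProbs) - 1) > 1e-9)
    msg <- c(msg, "'triProbs' must be 3 probabilities summing to 1")
  if (!identical(dim(object@lmProbs), c(3L, 4L)) ||
      any(object@lmProbs < 0) ||
      any(abs(rowSums(object@lmProbs) - 1) > 1e-9))
    msg <- c(msg, "'lmProbs' must be a 3 x 4 row-stochastic matrix")
  for (p in c("triCaseProb", "myopProb", "nucIncProb")) {
    x <- slot(object, p)
    if (length(x) != 1L || x < 0 || x > 1)
      msg <- c(msg, sprintf("'%s' must be a probability", p))
  }
  if (object@nCases < 1L) msg <- c(msg, "'nCases' must be >= 1")
  if (object@caseSd < 0) msg <- c(msg, "'caseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroupProfile", function(object) {
  eAS <- sum(object@probs[, 2L] + 2 * object@probs[, 3L])
  cat(sprintf("GroupProfile '%s': %d cases, expected AS %.2f, VAS ~ %.1f\n",
              object@label, object@nCases, eAS, object@vasMean))
  invisible(object)
})
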