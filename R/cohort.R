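#' Average Sum (AS) score per case
#'
#' The AS score of a biopsy is the mean, over its analyzed capillaries, of
#' the four-category sum (BM thickening + BM reduplication + endothelial
#' activation + ensheathment, each 0--2), giving a case severity on a 0--8
#' scale. Capillaries whose four-category sum is NA (fully degraded, no
#' measurable category) are excluded from the denominator.
#'
#' @param x a \linkS4class{CapillaryCohort}, or a per-capillary score
#'   data.frame as produced by [scoreCapillaries()].
#' @param ... unused.
#' @return named numeric vector of per-case AS scores in \[0, 8\].
#' @examples
#' sc <- data.frame(case_id = "c1", capillary_id = c("k1", "k2"),
#'                  four_category_sum = c(2L, 6L))
#' asScore(sc)  # c1 = 4
#' @name asScore
NULL

.asFromScores <- function(scores) {
  if (nrow(scores) == 0L) stop("no capillary scores: AS is undefined")
  ok <- !is.na(scores$four_category_sum)
  if (!any(ok)) stop("all capillaries have missing four-category sums")
  dropped <- tapply(!ok, scores$case_id, all)
  if (any(dropped))
    stop("case(s) with no scorable capillary: ",
         paste(names(dropped)[dropped], collapse = ", "))
  s <- scores[ok, , drop = FALSE]
  out <- tapply(s$four_category_sum, s$case_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' @rdname asScore
#' @export
setMethod("asScore", "CapillaryCohort", function(x, ...)
  .asFromScores(x@capillaryScores))

#' @rdname asScore
#' @export
setMethod("asScore", "data.frame", function(x, ...) .asFromScores(x))

#' Average Category Sum (ACS) score per case
#'
#' The ACS score of one category is the per-case mean of that category's
#' 0--2 scores over the analyzed capillaries: it decomposes the AS score
#' into the contribution of each of the four categories, and the four ACS
#' values of a case sum exactly to its AS. Capillaries excluded from AS
#' (all four categories missing) are excluded here too; within retained
#' capillaries a missing single category counts as 0, consistently with the
#' four-category sum.
#'
#' @param x a \linkS4class{CapillaryCohort} or per-capillary score
#'   data.frame.
#' @param category one of \code{"bm_thickening"}, \code{"bm_reduplication"},
#'   \code{"endothelial_activation"}, \code{"ensheathment"}, or NULL for all
#'   four at once.
#' @param ... unused.
#' @return if \code{category} is given, a named numeric vector of per-case
#'   ACS values in \[0, 2\]; otherwise a data.frame with one row per case
#'   and one column per category.
#' @name acsScore
NULL

.acsFromScores <- function(scores, category = NULL) {
  if (nrow(scores) == 0L) stop("no capillary scores: ACS is undefined")
  if (!is.null(category) && !category %in% .SCORE_CATEGORIES)
    stop("unknown ACS category '", category, "' (must be one of: ",
         paste(.SCORE_CATEGORIES, collapse = ", "), ")")
  ok <- !is.na(scores$four_category_sum)
  s <- scores[ok, , drop = FALSE]
  one <- function(cc) {
    v <- s[[cc]]
    v[is.na(v)] <- 0L  # partial degradation: missing category counts as 0
    out <- tapply(v, s$case_id, mean)
    stats::setNames(as.numeric(out), names(out))
  }
  if (!is.null(category)) return(one(category))
  vals <- lapply(.SCORE_CATEGORIES, one)
  out <- data.frame(case_id = names(vals[[1L]]), stringsAsFactors = FALSE)
  for (i in seq_along(.SCORE_CATEGORIES)) out[[.SCORE_CATEGORIES[i]]] <- vals[[i]]
  rownames(out) <- NULL
  out
}

#' @rdname acsScore
#' @export
setMethod("acsScore", "CapillaryCohort", function(x, category = NULL, ...)
  .acsFromScores(x@capillaryScores, category))

#' @rdname acsScore
#' @export
setMethod("acsScore", "data.frame", function(x, category = NULL, ...)
  .acsFromScores(x, category))

#' Per-group summaries of the AS and ACS scores
#'
#' For each study group, reports the number of cases and the mean, sample
#' standard deviation (n-1 denominator, the usual convention for
#' "mean +/- SD" in clinical reporting), minimum and maximum of the
#' per-case AS scores, plus the group mean of each category's ACS. A
#' single-case group gets SD 0 and \code{single_case = TRUE}.
#'
#' @param x a \linkS4class{CapillaryCohort}.
#' @param ... unused.
#' @return data.frame with one row per group: \code{group_label},
#'   \code{n_cases}, \code{as_mean}, \code{as_sd}, \code{as_min},
#'   \code{as_max}, \code{single_case}, and \code{acs_mean_<category>}.
#' @export
#' @name summarizeGroups
setMethod("summarizeGroups", "CapillaryCohort", function(x, ...) {
  as <- asScore(x)
  acs <- acsScore(x)
  cd <- x@caseData
  if (nrow(cd) == 0L) stop("empty cohort")
  groups <- unique(as.character(cd$group_label))
  rows <- lapply(groups, function(g) {
    ids <- cd$case_id[cd$group_label == g]
    v <- as[as.character(ids)]
    if (!length(v)) stop("group '", g, "' has no scored cases")
    a <- acs[match(as.character(ids), acs$case_id), , drop = FALSE]
    out <- data.frame(group_label = g, n_cases = length(v),
                      as_mean = mean(v),
                      as_sd = if (length(v) > 1L) stats::sd(v) else 0,
                      as_min = min(v), as_max = max(v),
                      single_case = length(v) == 1L,
                      stringsAsFactors = FALSE)
    for (cc in .SCORE_CATEGORIES)
      out[[paste0("acs_mean_", cc)]] <- mean(a[[cc]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Order cases for the severity-sorted report
#'
#' Orders cases the way the per-case stacked-bar report is laid out: by the
#' light-microscopy VAS severity score (primary key, ascending), then the
#' ultrastructural AS score (secondary key, ascending), then the case id
#' (lexicographic tiebreak), so the ordering is total and deterministic.
#'
#' @param x a \linkS4class{CapillaryCohort}.
#' @param decreasing order both score keys descending instead (the tiebreak
#'   stays lexicographic ascending).
#' @param ... unused.
#' @return the \code{caseData} data.frame with an added \code{as} column,
#'   reordered.
#' @export
#' @name orderCases
setMethod("orderCases", "CapillaryCohort", function(x, decreasing = FALSE,
                                                    ...) {
  cd <- x@caseData
  if (any(is.na(cd$vas)))
    stop("cannot order cases: missing VAS for ",
         paste(cd$case_id[is.na(cd$vas)], collapse = ", "))
  as <- asScore(x)
  cd$as <- as.numeric(as[as.character(cd$case_id)])
  sgn <- if (decreasing) -1 else 1
  ord <- order(sgn * cd$vas, sgn * cd$as, as.character(cd$case_id))
  out <- cd[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Derive per-case finding flags
#'
#' TRI presence is derived from the capillary scores: a case is TRI-positive
#' iff any of its capillaries has a TRI score >= 1. Myophagocytosis and
#' nuclear inclusions are manual observations recorded at case level and
#' passed through unchanged (they are not derivable from capillary scores).
#'
#' @param x a \linkS4class{CapillaryCohort}.
#' @param ... unused.
#' @return data.frame with \code{case_id}, \code{tri_present},
#'   \code{myophagocytosis}, \code{nuclear_inclusions}.
#' @export
#' @name deriveFindingsFlags
setMethod("deriveFindingsFlags", "CapillaryCohort", function(x, ...) {
  sc <- x@capillaryScores
  tri <- tapply(!is.na(sc$tri) & sc$tri >= 1L, sc$case_id, any)
  cd <- x@caseData
  out <- data.frame(
    case_id = as.character(cd$case_id),
    tri_present = as.logical(tri[as.character(cd$case_id)]),
    myophagocytosis = as.logical(cd$myophagocytosis),
    nuclear_inclusions = as.logical(cd$nuclear_inclusions),
    stringsAsFactors = FALSE)
  out$tri_present[is.na(out$tri_present)] <- FALSE
  rownames(out) <- NULL
  out
})

#' @rdname caseData
#' @export
setMethod("caseData", "CapillaryCohort", function(x) x@caseData)

#' @rdname capillaryScores
#' @export
setMethod("capillaryScores", "CapillaryCohort", function(x) x@capillaryScores)
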