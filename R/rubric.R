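#' Score basement-membrane thickening
#'
#' Maps a capillary's basement-membrane (BM) thickness to the ordinal
#' thickening score. The bands follow the rubric's printed anchors: the
#' normal range (50--100 nm) scores 0, 100--200 nm scores 1, and 200+ nm
#' scores 2. Bands are half-open, \code{[bmCut1, bmCut2)} scoring 1 and
#' \code{[bmCut2, Inf)} scoring 2, so a thickness of exactly 200 nm scores 2.
#' Thickness below 50 nm (thinner than normal) scores 0: the rubric grades
#' pathological thickening only.
#'
#' @param thicknessNm numeric vector of BM thicknesses in nm; must be
#'   positive and finite (NA is propagated, for degraded capillaries whose
#'   BM could not be measured).
#' @param config a \linkS4class{ScoringConfig}; \code{bmCut1}/\code{bmCut2}
#'   give the band edges (defaults 100 and 200 nm).
#' @return integer vector of scores in \{0, 1, 2\}.
#' @examples
#' scoreBmThickening(c(75, 150, 250))  # 0 1 2
#' @export
scoreBmThickening <- function(thicknessNm, config = ScoringConfig()) {
  bad <- !is.na(thicknessNm) & (!is.finite(thicknessNm) | thicknessNm <= 0)
  if (any(bad))
    stop("invalid BM thickness (must be positive and finite): ",
         paste(utils::head(thicknessNm[bad], 3L), collapse = ", "))
  s <- ifelse(thicknessNm >= config@bmCut2, 2L,
              ifelse(thicknessNm >= config@bmCut1, 1L, 0L))
  as.integer(s)
}

#' Score basement-membrane reduplication
#'
#' Maps the number of concentric BM layers to the ordinal reduplication
#' score: a single lamina (1 layer, no reduplication) scores 0, mild
#' reduplication (2--3 layers) scores 1, marked reduplication (4+ layers)
#' scores 2.
#'
#' @param layerCount integer vector of BM layer counts, each >= 1 (NA is
#'   propagated).
#' @param config a \linkS4class{ScoringConfig};
#'   \code{layersCut1}/\code{layersCut2} give the cuts (defaults 2 and 4).
#' @return integer vector of scores in \{0, 1, 2\}.
#' @examples
#' scoreBmReduplication(c(1, 3, 5))  # 0 1 2
#' @export
scoreBmReduplication <- function(layerCount, config = ScoringConfig()) {
  bad <- !is.na(layerCount) &
    (!is.finite(layerCount) | layerCount < 1 | layerCount %% 1 != 0)
  if (any(bad))
    stop("invalid BM layer count (must be an integer >= 1): ",
         paste(utils::head(layerCount[bad], 3L), collapse = ", "))
  s <- ifelse(layerCount >= config@layersCut2, 2L,
              ifelse(layerCount >= config@layersCut1, 1L, 0L))
  as.integer(s)
}

.ORGANELLE_LEVELS <- c(none = 0L, increased = 1L, marked = 2L)
.GRADE_LEVELS <- c(none = 0L, mild = 1L, marked = 2L)

#' Score endothelial activation
#'
#' Two input routes are supported, mirroring how the category is assessed.
#' An explicit consensus grade (\code{none}/\code{mild}/\code{marked}) maps
#' directly to 0/1/2. Alternatively, a raw pair of endothelial
#' cross-sectional area and organelle prominence is graded through
#' configurable area bands: the area ratio relative to
#' \code{areaRefUm2} falls into none- (< \code{areaMildRatio}), mild-
#' (\code{areaMildRatio}--\code{areaMarkedRatio}) or marked-eligible
#' (> \code{areaMarkedRatio}) bands, and the final score is the maximum of
#' the area-band score and the organelle-prominence level
#' (\code{none}/\code{increased}/\code{marked} = 0/1/2) — "increased area
#' and/or organelles". The area bands are package conventions: the rubric
#' defines this category qualitatively.
#'
#' @param grade character vector of explicit grades, or NA where the raw
#'   pair should be used.
#' @param areaUm2 numeric vector of endothelial cross-sectional areas in
#'   um^2 (raw route).
#' @param organelle character vector of organelle prominence levels
#'   (\code{none}/\code{increased}/\code{marked}; raw route).
#' @param config a \linkS4class{ScoringConfig}.
#' @param onMissing what to do for an element with neither a grade nor a
#'   complete raw pair: \code{"error"} (default) or \code{"na"} (used for
#'   degraded capillaries in batch scoring).
#' @return integer vector of scores in \{0, 1, 2\}.
#' @examples
#' scoreEndothelialActivation(grade = c("none", "marked"))       # 0 2
#' scoreEndothelialActivation(areaUm2 = 20, organelle = "increased")  # 1
#' @export
scoreEndothelialActivation <- function(grade = NULL, areaUm2 = NULL,
                                       organelle = NULL,
                                       config = ScoringConfig(),
                                       onMissing = c("error", "na")) {
  onMissing <- match.arg(onMissing)
  n <- max(length(grade), length(areaUm2), length(organelle))
  if (n == 0L) stop("no activation inputs supplied")
  grade <- rep_len(if (is.null(grade)) NA_character_ else as.character(grade), n)
  areaUm2 <- rep_len(if (is.null(areaUm2)) NA_real_ else as.numeric(areaUm2), n)
  organelle <- rep_len(if (is.null(organelle)) NA_character_
                       else as.character(organelle), n)
  badGrade <- !is.na(grade) & !grade %in% names(.GRADE_LEVELS)
  if (any(badGrade))
    stop("unknown activation grade: ",
         paste(unique(grade[badGrade]), collapse = ", "))
  badOrg <- !is.na(organelle) & !organelle %in% names(.ORGANELLE_LEVELS)
  if (any(badOrg))
    stop("unknown organelle prominence: ",
         paste(unique(organelle[badOrg]), collapse = ", "))
  badArea <- !is.na(areaUm2) & (!is.finite(areaUm2) | areaUm2 < 0)
  if (any(badArea)) stop("endothelial area must be non-negative and finite")

  out <- rep(NA_integer_, n)
  useGrade <- !is.na(grade)
  out[useGrade] <- .GRADE_LEVELS[grade[useGrade]]
  raw <- !useGrade & !is.na(areaUm2) & !is.na(organelle)
  if (any(raw)) {
    ratio <- areaUm2[raw] / config@areaRefUm2
    areaScore <- ifelse(ratio > config@areaMarkedRatio, 2L,
                        ifelse(ratio >= config@areaMildRatio, 1L, 0L))
    out[raw] <- pmax(as.integer(areaScore),
                     .ORGANELLE_LEVELS[organelle[raw]])
  }
  unresolved <- !useGrade & !raw
  if (any(unresolved) && onMissing == "error")
    stop("activation needs either an explicit grade or the raw ",
         "(area, organelle) pair; missing for ", sum(unresolved), " element(s)")
  as.integer(out)
}

.PROMINENCE_LEVELS <- c("focal_small", "prominent", "very_prominent")

#' Score capillary ensheathment
#'
#' Maps the number of pericyte/endothelial processes surrounding the
#' capillary to the ordinal ensheathment score: 0--4 processes score 0
#' (no prominent ensheathment), 5--6 score 1 (prominent ensheathment),
#' 7+ score 2 (very prominent ensheathment). The rubric's size caveats
#' ("not only focal and small", "also depending on size") are encoded as a
#' prominence qualifier: \code{focal_small} demotes the count-derived score
#' by one level (never below 0). A missing qualifier defaults to
#' \code{prominent}, leaving the count rule untouched.
#'
#' @param processCount integer vector of process counts (>= 0; NA is
#'   propagated).
#' @param prominence character vector in \code{focal_small} /
#'   \code{prominent} / \code{very_prominent}; NA treated as
#'   \code{prominent}.
#' @param config a \linkS4class{ScoringConfig};
#'   \code{procCut1}/\code{procCut2} give the cuts (defaults 5 and 7).
#' @return integer vector of scores in \{0, 1, 2\}.
#' @examples
#' scoreEnsheathment(c(3, 6, 8))                       # 0 1 2
#' scoreEnsheathment(8, prominence = "focal_small")    # 1
#' @export
scoreEnsheathment <- function(processCount, prominence = "prominent",
                              config = ScoringConfig()) {
  bad <- !is.na(processCount) &
    (!is.finite(processCount) | processCount < 0 | processCount %% 1 != 0)
  if (any(bad))
    stop("invalid process count (must be an integer >= 0): ",
         paste(utils::head(processCount[bad], 3L), collapse = ", "))
  n <- length(processCount)
  prominence <- rep_len(as.character(prominence), n)
  prominence[is.na(prominence)] <- "prominent"
  badP <- !prominence %in% .PROMINENCE_LEVELS
  if (any(badP))
    stop("unknown process prominence: ",
         paste(unique(prominence[badP]), collapse = ", "))
  s <- ifelse(processCount >= config@procCut2, 2L,
              ifelse(processCount >= config@procCut1, 1L, 0L))
  demote <- prominence == "focal_small"
  s <- ifelse(demote, pmax(s - 1L, 0L), s)
  as.integer(s)
}

#' Score tubuloreticular inclusions
#'
#' Maps counts of small/medium/large tubuloreticular inclusions (TRI) in
#' endothelial cells or pericytes to the ordinal TRI score: no TRI (or a
#' single small one) scores 0; 2 small or 1 medium TRI score 1; 2+ medium or
#' 1+ large TRI score 2. Mixed observation lists take the maximum
#' applicable score. Size classes are assigned by maximum diameter
#' (conventions in \linkS4class{ScoringConfig}: small < 300 nm, medium
#' 300--800 nm, large > 800 nm).
#'
#' @param small,medium,large integer vectors of TRI counts per size class
#'   (recycled to a common length; NA propagates to an NA score).
#' @return integer vector of scores in \{0, 1, 2\}.
#' @examples
#' scoreTri(small = 2)              # 1
#' scoreTri(medium = 1)             # 1
#' scoreTri(large = 1)              # 2
#' scoreTri(small = 1)              # 0 (a single small TRI is below the bar)
#' @export
scoreTri <- function(small = 0L, medium = 0L, large = 0L) {
  n <- max(length(small), length(medium), length(large))
  small <- rep_len(small, n); medium <- rep_len(medium, n)
  large <- rep_len(large, n)
  for (v in list(small, medium, large)) {
    bad <- !is.na(v) & (!is.finite(v) | v < 0 | v %% 1 != 0)
    if (any(bad)) stop("TRI counts must be non-negative integers")
  }
  s <- ifelse(large >= 1 | medium >= 2, 2L,
              ifelse(medium == 1 | small >= 2, 1L, 0L))
  as.integer(s)
}

#' Convert a TRI observation list to per-size-class counts
#'
#' @param observations data.frame with columns \code{size_class}
#'   (\code{small}/\code{medium}/\code{large}) and \code{count} (>= 1), one
#'   row per observation; zero rows mean no TRI.
#' @return named integer vector \code{c(small=, medium=, large=)}.
#' @export
triCounts <- function(observations) {
  out <- c(small = 0L, medium = 0L, large = 0L)
  if (is.null(observations) || nrow(observations) == 0L) return(out)
  if (!all(c("size_class", "count") %in% names(observations)))
    stop("TRI observations need columns 'size_class' and 'count'")
  bad <- !observations$size_class %in% names(out)
  if (any(bad))
    stop("unknown TRI size class: ",
         paste(unique(observations$size_class[bad]), collapse = ", "))
  if (any(observations$count < 1 | observations$count %% 1 != 0))
    stop("TRI observation counts must be integers >= 1")
  agg <- tapply(observations$count, observations$size_class, sum)
  out[names(agg)] <- as.integer(agg)
  out
}

#' Score one capillary (scalar path)
#'
#' Applies the five category scorers to one capillary's raw features and
#' assembles the per-capillary record, including the four-category sum
#' (BM thickening + BM reduplication + endothelial activation +
#' ensheathment; the TRI score is reported but never enters the sum). This
#' scalar path is written independently of the vectorized
#' [scoreCapillaries()] and serves as its cross-check.
#'
#' A degraded capillary (e.g. an almost empty BM sack with the endothelium
#' lost) is scored on whatever features are measurable: unmeasurable
#' categories are recorded as NA, and in the four-category sum missing
#' categories count as 0 — unless all four are missing, in which case the
#' sum itself is NA and the capillary drops out of the per-case average.
#'
#' @param features a list or one-row data.frame with (any of) the fields
#'   \code{bm_thickness_nm}, \code{bm_layer_count}, \code{activation_grade},
#'   \code{endothelial_area_um2}, \code{organelle_prominence},
#'   \code{process_count}, \code{process_prominence}, \code{tri_small},
#'   \code{tri_medium}, \code{tri_large}.
#' @param config a \linkS4class{ScoringConfig}.
#' @return named list with the five category scores and
#'   \code{four_category_sum}.
#' @examples
#' scoreCapillary(list(bm_thickness_nm = 250, bm_layer_count = 5,
#'                     activation_grade = "marked", process_count = 8,
#'                     process_prominence = "very_prominent",
#'                     tri_large = 1))
#' @export
scoreCapillary <- function(features, config = ScoringConfig()) {
  f <- as.list(features)
  g <- function(nm) if (is.null(f[[nm]]) || length(f[[nm]]) == 0L) NA else f[[nm]]

  th <- g("bm_thickness_nm")
  bmThick <- if (is.na(th)) NA_integer_ else {
    if (!is.finite(th) || th <= 0) stop("BM thickening: invalid thickness ", th)
    if (th >= config@bmCut2) 2L else if (th >= config@bmCut1) 1L else 0L
  }

  ly <- g("bm_layer_count")
  bmRedup <- if (is.na(ly)) NA_integer_ else {
    if (!is.finite(ly) || ly < 1 || ly %% 1 != 0)
      stop("BM reduplication: invalid layer count ", ly)
    if (ly >= config@layersCut2) 2L else if (ly >= config@layersCut1) 1L else 0L
  }

  gr <- g("activation_grade"); ar <- g("endothelial_area_um2")
  org <- g("organelle_prominence")
  act <- if (!is.na(gr)) {
    if (!gr %in% names(.GRADE_LEVELS))
      stop("endothelial activation: unknown grade '", gr, "'")
    unname(.GRADE_LEVELS[gr])
  } else if (!is.na(ar) && !is.na(org)) {
    if (!org %in% names(.ORGANELLE_LEVELS))
      stop("endothelial activation: unknown organelle prominence '", org, "'")
    ratio <- ar / config@areaRefUm2
    aSc <- if (ratio > config@areaMarkedRatio) 2L else
      if (ratio >= config@areaMildRatio) 1L else 0L
    max(aSc, unname(.ORGANELLE_LEVELS[org]))
  } else NA_integer_

  pc <- g("process_count")
  ens <- if (is.na(pc)) NA_integer_ else {
    if (!is.finite(pc) || pc < 0 || pc %% 1 != 0)
      stop("ensheathment: invalid process count ", pc)
    pp <- g("process_prominence")
    if (is.na(pp)) pp <- "prominent"
    if (!pp %in% .PROMINENCE_LEVELS)
      stop("ensheathment: unknown prominence '", pp, "'")
    s <- if (pc >= config@procCut2) 2L else if (pc >= config@procCut1) 1L else 0L
    if (pp == "focal_small") s <- max(s - 1L, 0L)
    s
  }

  ts <- g("tri_small"); tm <- g("tri_medium"); tl <- g("tri_large")
  tri <- if (is.na(ts) && is.na(tm) && is.na(tl)) NA_integer_ else {
    ts <- if (is.na(ts)) 0L else ts
    tm <- if (is.na(tm)) 0L else tm
    tl <- if (is.na(tl)) 0L else tl
    if (any(c(ts, tm, tl) < 0) || any(c(ts, tm, tl) %% 1 != 0))
      stop("TRI: counts must be non-negative integers")
    if (tl >= 1 || tm >= 2) 2L else if (tm == 1 || ts >= 2) 1L else 0L
  }

  four <- c(bmThick, bmRedup, act, ens)
  fourSum <- if (all(is.na(four))) NA_integer_ else sum(four, na.rm = TRUE)
  list(bm_thickening = bmThick, bm_reduplication = bmRedup,
       endothelial_activation = act, ensheathment = ens, tri = tri,
       four_category_sum = fourSum)
}

#' Score a table of capillaries (vectorized path)
#'
#' Applies the rubric to every row of a per-capillary feature table, in
#' fully vectorized form, returning one score row per capillary. The
#' activation category prefers an explicit \code{activation_grade} and falls
#' back to the raw (\code{endothelial_area_um2},
#' \code{organelle_prominence}) pair. Partially degraded capillaries (some
#' categories NA) contribute their measurable categories, with missing ones
#' counted as 0 in the four-category sum and a single warning issued;
#' capillaries with all four sum categories missing get an NA sum and are
#' excluded from per-case averages downstream.
#'
#' @param features data.frame with columns \code{case_id},
#'   \code{capillary_id} and the feature columns of [scoreCapillary()]
#'   (missing columns are treated as all-NA).
#' @param config a \linkS4class{ScoringConfig}.
#' @return data.frame with \code{case_id}, \code{capillary_id}, the five
#'   category scores, and \code{four_category_sum}.
#' @seealso [scoreCapillary()] for the scalar path and the missing-data
#'   semantics.
#' @export
scoreCapillaries <- function(features, config = ScoringConfig()) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n == 0L) stop("empty feature table")
  col <- function(nm, default = NA) {
    if (nm %in% names(features)) features[[nm]] else rep(default, n)
  }
  ids <- data.frame(
    case_id = as.character(col("case_id", NA_character_)),
    capillary_id = as.character(col("capillary_id", NA_character_)),
    stringsAsFactors = FALSE)

  bmThick <- scoreBmThickening(as.numeric(col("bm_thickness_nm")), config)
  bmRedup <- scoreBmReduplication(as.numeric(col("bm_layer_count")), config)
  act <- scoreEndothelialActivation(
    grade = col("activation_grade", NA_character_),
    areaUm2 = as.numeric(col("endothelial_area_um2")),
    organelle = col("organelle_prominence", NA_character_),
    config = config, onMissing = "na")
  pc <- as.numeric(col("process_count"))
  ens <- rep(NA_integer_, n)
  okP <- !is.na(pc)
  if (any(okP))
    ens[okP] <- scoreEnsheathment(pc[okP],
                                  col("process_prominence", NA_character_)[okP],
                                  config)
  ts <- as.numeric(col("tri_small")); tm <- as.numeric(col("tri_medium"))
  tl <- as.numeric(col("tri_large"))
  allNaTri <- is.na(ts) & is.na(tm) & is.na(tl)
  tri <- scoreTri(ifelse(is.na(ts), 0L, ts), ifelse(is.na(tm), 0L, tm),
                  ifelse(is.na(tl), 0L, tl))
  tri[allNaTri] <- NA_integer_

  four <- cbind(bmThick, bmRedup, act, ens)
  nMiss <- rowSums(is.na(four))
  fourSum <- as.integer(rowSums(four, na.rm = TRUE))
  fourSum[nMiss == 4L] <- NA_integer_
  partial <- nMiss > 0L & nMiss < 4L
  if (any(partial))
    warning(sum(partial), " capillar",
            if (sum(partial) == 1L) "y has" else "ies have",
            " partially missing categories; missing categories count as 0 ",
            "in the four-category sum")
  out <- data.frame(ids, bm_thickening = bmThick, bm_reduplication = bmRedup,
                    endothelial_activation = act, ensheathment = ens,
                    tri = tri, four_category_sum = fourSum,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
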