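# File formats: delimited feature/case tables (UTF-8, comma-separated with
# a required header; TSV dialect available; missing values are empty
# fields), QuPath-compatible GeoJSON annotations, YAML configuration, and
# JSON run manifests.

.FEATURE_COLUMNS <- c("case_id", "capillary_id", "bm_thickness_nm",
                      "bm_layer_count", "activation_grade",
                      "endothelial_area_um2", "organelle_prominence",
                      "process_count", "process_prominence",
                      "tri_small", "tri_medium", "tri_large", "degraded")

.CASE_COLUMNS <- c("case_id", "group_label", "htype_label", "vas",
                   "lm_capillaries", "lm_muscle_fibers",
                   "lm_endo_perimysium", "myophagocytosis",
                   "nuclear_inclusions", "age", "max_ck_ul",
                   "cutaneous_subtype", "n_capillaries")

.sepFor <- function(path, dialect) {
  dialect <- match.arg(dialect, c("auto", "csv", "tsv"))
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  if (dialect == "tsv") "\t" else ","
}

.writeTable <- function(x, path, dialect) {
  utils::write.table(x, path, sep = .sepFor(path, dialect), na = "",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
}

.readTable <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = .sepFor(path, dialect), header = TRUE,
                    na.strings = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", quote = "\"")
}

#' Write / read a per-capillary feature table
#'
#' The table is UTF-8 delimited text with a header; missing values are
#' empty fields. `readFeatureTable` validates each row (positive finite
#' thickness, integer layer counts >= 1, non-negative counts, known enum
#' levels); failing rows are excluded and collected into an error report
#' attached as `attr(, "errors")` (columns \code{row}, \code{message}),
#' unless \code{strict = TRUE}, in which case the first failure aborts.
#'
#' @param x feature data.frame (see [scoreCapillary()] for fields).
#' @param path file path; extension .tsv selects the tab dialect under
#'   \code{dialect = "auto"}.
#' @param dialect \code{"auto"}, \code{"csv"} or \code{"tsv"}.
#' @param strict abort on the first invalid row instead of excluding it.
#' @return `readFeatureTable`: validated data.frame with an \code{errors}
#'   attribute; `writeFeatureTable`: the path, invisibly.
#' @export
writeFeatureTable <- function(x, path, dialect = "auto") {
  x <- as.data.frame(x)
  miss <- setdiff(.FEATURE_COLUMNS, names(x))
  for (m in miss) x[[m]] <- NA
  .writeTable(x[.FEATURE_COLUMNS], path, dialect)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path, dialect = "auto", strict = FALSE) {
  x <- .readTable(path, dialect)
  mandatory <- c("case_id", "capillary_id")
  miss <- setdiff(mandatory, names(x))
  if (length(miss))
    stop("feature table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  for (m in setdiff(.FEATURE_COLUMNS, names(x))) x[[m]] <- NA
  x$degraded <- !is.na(x$degraded) & as.logical(x$degraded)

  errs <- list()
  flag <- function(rows, msg) {
    for (r in rows) errs[[length(errs) + 1L]] <<- data.frame(row = r,
                                                             message = msg)
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  bad <- !is.na(x$bm_thickness_nm) &
    (!is.finite(num(x$bm_thickness_nm)) | num(x$bm_thickness_nm) <= 0)
  flag(which(bad), "bm_thickness_nm must be positive and finite")
  lc <- num(x$bm_layer_count)
  bad2 <- !is.na(x$bm_layer_count) & (!is.finite(lc) | lc < 1 | lc %% 1 != 0)
  flag(which(bad2), "bm_layer_count must be an integer >= 1")
  pc <- num(x$process_count)
  bad3 <- !is.na(x$process_count) & (!is.finite(pc) | pc < 0 | pc %% 1 != 0)
  flag(which(bad3), "process_count must be a non-negative integer")
  bad4 <- !is.na(x$activation_grade) &
    !x$activation_grade %in% names(.GRADE_LEVELS)
  flag(which(bad4), "unknown activation_grade")
  bad5 <- !is.na(x$organelle_prominence) &
    !x$organelle_prominence %in% names(.ORGANELLE_LEVELS)
  flag(which(bad5), "unknown organelle_prominence")
  bad6 <- !is.na(x$process_prominence) &
    !x$process_prominence %in% .PROMINENCE_LEVELS
  flag(which(bad6), "unknown process_prominence")
  badTri <- rep(FALSE, nrow(x))
  for (cc in c("tri_small", "tri_medium", "tri_large")) {
    v <- num(x[[cc]])
    badTri <- badTri | (!is.na(x[[cc]]) & (!is.finite(v) | v < 0 | v %% 1 != 0))
  }
  flag(which(badTri), "TRI counts must be non-negative integers")

  report <- if (length(errs)) do.call(rbind, errs)
    else data.frame(row = integer(), message = character())
  report <- report[order(report$row), , drop = FALSE]
  rownames(report) <- NULL
  if (strict && nrow(report))
    stop("invalid feature row ", report$row[1L], ": ", report$message[1L])
  keep <- setdiff(seq_len(nrow(x)), unique(report$row))
  out <- x[keep, .FEATURE_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- report
  out
}

#' Write / read a case metadata table
#'
#' @param x case data.frame (see \linkS4class{CapillaryCohort}).
#' @param path,dialect,strict as in [readFeatureTable()].
#' @return `readCaseTable`: validated data.frame with an \code{errors}
#'   attribute; `writeCaseTable`: the path, invisibly.
#' @export
writeCaseTable <- function(x, path, dialect = "auto") {
  x <- as.data.frame(x)
  for (m in setdiff(.CASE_COLUMNS, names(x))) x[[m]] <- NA
  .writeTable(x[.CASE_COLUMNS], path, dialect)
  invisible(path)
}

#' @rdname writeCaseTable
#' @export
readCaseTable <- function(path, dialect = "auto", strict = FALSE) {
  x <- .readTable(path, dialect)
  miss <- setdiff(c("case_id", "group_label", "vas"), names(x))
  if (length(miss))
    stop("case table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  for (m in setdiff(.CASE_COLUMNS, names(x))) x[[m]] <- NA
  errs <- list()
  flag <- function(rows, msg) {
    for (r in rows) errs[[length(errs) + 1L]] <<- data.frame(row = r,
                                                             message = msg)
  }
  v <- suppressWarnings(as.numeric(x$vas))
  flag(which(!is.na(x$vas) & (!is.finite(v) | v < 0 | v > 10)),
       "vas must lie in [0, 10]")
  for (cc in c("lm_capillaries", "lm_muscle_fibers", "lm_endo_perimysium")) {
    sv <- suppressWarnings(as.numeric(x[[cc]]))
    flag(which(!is.na(x[[cc]]) & !sv %in% 0:3),
         paste(cc, "must lie in {0,1,2,3}"))
  }
  report <- if (length(errs)) do.call(rbind, errs)
    else data.frame(row = integer(), message = character())
  rownames(report) <- NULL
  if (strict && nrow(report))
    stop("invalid case row ", report$row[1L], ": ", report$message[1L])
  keep <- setdiff(seq_len(nrow(x)), unique(report$row))
  out <- x[keep, .CASE_COLUMNS, drop = FALSE]
  for (cc in c("myophagocytosis", "nuclear_inclusions"))
    out[[cc]] <- as.logical(out[[cc]])
  rownames(out) <- NULL
  attr(out, "errors") <- report
  out
}

#' Write all tables of a simulated cohort
#'
#' Writes \code{features.csv}, \code{cases.csv}, \code{scores.csv} and a
#' run manifest (\code{manifest.json}) into a directory.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param seed the master seed used, recorded in the manifest.
#' @param dialect table dialect.
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohortTables <- function(sim, dir, seed = NA_integer_,
                              dialect = "csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "tsv") ".tsv" else ".csv"
  paths <- c(features = file.path(dir, paste0("features", ext)),
             cases = file.path(dir, paste0("cases", ext)),
             scores = file.path(dir, paste0("scores", ext)))
  writeFeatureTable(sim$features, paths[["features"]], dialect)
  writeCaseTable(caseData(sim$cohort), paths[["cases"]], dialect)
  .writeTable(capillaryScores(sim$cohort), paths[["scores"]], dialect)
  writeRunManifest(file.path(dir, "manifest.json"), seed = seed,
                   outputs = paths)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}

# ---- GeoJSON annotations ----------------------------------------------------

.ringToCoords <- function(m) {
  m <- rbind(m, m[1L, , drop = FALSE])  # GeoJSON rings are closed
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
}

.coordsToRing <- function(cc) {
  m <- do.call(rbind, lapply(cc, function(p) as.numeric(p[1:2])))
  .asContour(m)
}

#' Write capillary annotations as GeoJSON
#'
#' Emits a QuPath-compatible FeatureCollection: one Polygon Feature per
#' contour with a \code{classification} property (an object with a
#' \code{name} in \code{lumen} / \code{endothelium} / \code{bm_layer} /
#' \code{process}, QuPath style), plus Point Features for TRI marks.
#' BM layers are written as annuli (exterior ring + one hole). Features of
#' the same capillary share a \code{capillary_id} property. The collection
#' carries \code{units} ("nm" here) and \code{pixel_size_nm} at top level.
#'
#' @param geoms list of \linkS4class{CapillaryGeometry} (or one), optionally
#'   named by capillary id.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(geoms, path) {
  if (is(geoms, "CapillaryGeometry")) geoms <- list(geoms)
  ids <- names(geoms)
  if (is.null(ids)) ids <- sprintf("cap_%03d", seq_along(geoms))
  feats <- list()
  add <- function(geometry, cls, id, extra = list()) {
    props <- c(list(classification = list(name = cls), capillary_id = id),
               extra)
    feats[[length(feats) + 1L]] <<- list(type = "Feature",
                                         geometry = geometry,
                                         properties = props)
  }
  poly <- function(rings) list(type = "Polygon", coordinates = rings)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]; id <- ids[i]
    add(poly(list(.ringToCoords(g@lumen))), "lumen", id)
    add(poly(list(.ringToCoords(g@endotheliumOuter))), "endothelium", id)
    for (j in seq_along(g@bmLayers))
      add(poly(list(.ringToCoords(g@bmLayers[[j]]$outer),
                    .ringToCoords(g@bmLayers[[j]]$inner))),
          "bm_layer", id, list(layer_index = j))
    for (pr in g@processes)
      add(poly(list(.ringToCoords(pr$coords))), "process", id,
          if (is.na(pr$size)) list() else list(size = pr$size))
    if (nrow(g@triMarks)) for (r in seq_len(nrow(g@triMarks)))
      add(list(type = "Point",
               coordinates = c(g@triMarks$x[r], g@triMarks$y[r])),
          "tri", id, list(diameter_nm = g@triMarks$diameter_nm[r]))
  }
  fc <- list(type = "FeatureCollection", units = "nm",
             pixel_size_nm = geoms[[1L]]@pixelSizeNm, features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

.featureClass <- function(props) {
  cls <- props$classification
  if (is.list(cls)) cls <- cls$name   # QuPath-style nested object
  if (is.null(cls)) NA_character_ else as.character(cls)
}

#' Read capillary annotations from GeoJSON
#'
#' Parses a FeatureCollection (QuPath dialect accepted: nested
#' \code{classification} objects), groups Features into capillaries by
#' their \code{capillary_id} property, and applies pixel-to-nm scaling
#' when the collection declares \code{units: "pixels"} (scale factor from
#' the collection's \code{pixel_size_nm} or the \code{pixelSizeNm}
#' argument). Unclassified Features are skipped with a warning; a
#' capillary without a lumen is an annotation error.
#'
#' @param path GeoJSON file.
#' @param pixelSizeNm fallback pixel size in nm for pixel-unit files
#'   (default 7.3, the large-scale digitization convention).
#' @return named list of \linkS4class{CapillaryGeometry}.
#' @export
readAnnotations <- function(path, pixelSizeNm = 7.3) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  px <- if (!is.null(fc$pixel_size_nm)) as.numeric(fc$pixel_size_nm)
    else pixelSizeNm
  scale <- if (!is.null(fc$units) && fc$units == "pixels") px else 1
  groups <- list()
  nskip <- 0L
  for (ft in fc$features) {
    cls <- .featureClass(ft$properties)
    if (is.na(cls) || !cls %in% c("lumen", "endothelium", "bm_layer",
                                  "process", "tri")) {
      nskip <- nskip + 1L
      next
    }
    id <- ft$properties$capillary_id
    if (is.null(id)) id <- "cap_001"
    id <- as.character(id)
    if (is.null(groups[[id]]))
      groups[[id]] <- list(bm = list(), proc = list(),
                           tri = list())
    if (ft$geometry$type == "Polygon") {
      rings <- lapply(ft$geometry$coordinates,
                      function(rr) .coordsToRing(rr) * scale)
      if (cls == "lumen") groups[[id]]$lumen <- rings[[1L]]
      else if (cls == "endothelium") groups[[id]]$endo <- rings[[1L]]
      else if (cls == "bm_layer") {
        j <- ft$properties$layer_index
        ent <- list(outer = rings[[1L]],
                    inner = if (length(rings) > 1L) rings[[2L]] else NULL,
                    index = if (is.null(j)) NA else as.numeric(j))
        groups[[id]]$bm[[length(groups[[id]]$bm) + 1L]] <- ent
      } else if (cls == "process") {
        sz <- ft$properties$size
        groups[[id]]$proc[[length(groups[[id]]$proc) + 1L]] <-
          list(coords = rings[[1L]],
               size = if (is.null(sz)) NA_character_ else as.character(sz))
      }
    } else if (ft$geometry$type == "Point" && cls == "tri") {
      groups[[id]]$tri[[length(groups[[id]]$tri) + 1L]] <-
        data.frame(x = as.numeric(ft$geometry$coordinates[[1L]]) * scale,
                   y = as.numeric(ft$geometry$coordinates[[2L]]) * scale,
                   diameter_nm = as.numeric(ft$properties$diameter_nm) * scale)
    } else nskip <- nskip + 1L
  }
  if (nskip)
    warning(nskip, " unclassified or unsupported Feature(s) skipped")
  out <- lapply(names(groups), function(id) {
    g <- groups[[id]]
    if (is.null(g$lumen))
      stop("annotation error: capillary '", id, "' has no lumen Feature")
    endo <- g$endo
    if (is.null(endo)) {  # minimal enclosing ring so the object validates
      ctr <- .polyCentroid(g$lumen)
      endo <- sweep(g$lumen, 2L, ctr) * 1.01 +
        matrix(ctr, nrow(g$lumen), 2L, byrow = TRUE)
    }
    bm <- g$bm
    if (length(bm)) {
      ord <- order(vapply(bm, function(b)
        if (is.na(b$index)) .polyArea(b$outer) else b$index, numeric(1L)))
      bm <- lapply(bm[ord], function(b)
        list(inner = if (is.null(b$inner)) endo else b$inner,
             outer = b$outer))
    }
    CapillaryGeometry(g$lumen, endo, bmLayers = bm, processes = g$proc,
                      triMarks = if (length(g$tri)) do.call(rbind, g$tri)
                      else data.frame(x = numeric(), y = numeric(),
                                      diameter_nm = numeric()),
                      pixelSizeNm = px)
  })
  names(out) <- names(groups)
  out
}

# ---- scoring / cohort configuration (YAML) ----------------------------------

#' Read / write a ScoringConfig as YAML
#'
#' The YAML file holds one key per \linkS4class{ScoringConfig} slot; absent
#' keys keep their defaults, so a config file reproducing the printed
#' rubric cuts can be empty.
#'
#' @param path YAML file.
#' @param config a \linkS4class{ScoringConfig} to write.
#' @return `readScoringConfig`: a \linkS4class{ScoringConfig};
#'   `writeScoringConfig`: the path, invisibly.
#' @export
readScoringConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- slotNames("ScoringConfig")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown scoring config key(s): ", paste(unknown, collapse = ", "))
  do.call(ScoringConfig, vals)
}

#' @rdname readScoringConfig
#' @export
writeScoringConfig <- function(config, path) {
  stopifnot(is(config, "ScoringConfig"))
  vals <- lapply(slotNames("ScoringConfig"), function(s) slot(config, s))
  names(vals) <- slotNames("ScoringConfig")
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read / write a cohort configuration as YAML
#'
#' Serialises the full generative specification (every
#' \linkS4class{GroupProfile} field) so a simulation is reproducible from
#' the config file plus the master seed alone.
#'
#' @param path YAML file.
#' @param config a cohort configuration list (see [defaultCohortConfig()]).
#' @return `readCohortConfig`: a cohort configuration;
#'   `writeCohortConfig`: the path, invisibly.
#' @export
writeCohortConfig <- function(config, path) {
  profs <- lapply(config$profiles, function(p) {
    list(label = p@label, n_cases = p@nCases, htypes = as.list(p@htypes),
         probs = lapply(seq_len(4L), function(i) as.numeric(p@probs[i, ])),
         case_sd = p@caseSd, tri_case_prob = p@triCaseProb,
         tri_probs = as.numeric(p@triProbs),
         vas_mean = p@vasMean, vas_sd = p@vasSd,
         lm_probs = lapply(seq_len(3L), function(i) as.numeric(p@lmProbs[i, ])),
         myop_prob = p@myopProb, nuc_inc_prob = p@nucIncProb,
         age_mean = p@ageMean, age_sd = p@ageSd,
         ck_mean = p@ckMean, ck_sd = p@ckSd)
  })
  yaml::write_yaml(list(n_below_100 = config$nBelow100,
                        below_range = as.integer(config$belowRange),
                        profiles = profs), path)
  invisible(path)
}

#' @rdname readCohortConfig
#' @export
readCohortConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  profs <- lapply(vals$profiles, function(p)
    .makeProfile(p$label, p$n_cases, unlist(p$htypes),
                 probs = do.call(rbind, p$probs),
                 caseSd = p$case_sd, triCaseProb = p$tri_case_prob,
                 triProbs = as.numeric(unlist(p$tri_probs)),
                 vasMean = p$vas_mean, vasSd = p$vas_sd,
                 lmProbs = do.call(rbind, p$lm_probs),
                 myopProb = p$myop_prob, nucIncProb = p$nuc_inc_prob,
                 ageMean = p$age_mean, ageSd = p$age_sd,
                 ckMean = p$ck_mean, ckSd = p$ck_sd))
  names(profs) <- vapply(profs, function(p) p@label, character(1L))
  defaultCohortConfig(profiles = profs, nBelow100 = vals$n_below_100,
                      belowRange = as.integer(unlist(vals$below_range)))
}

# ---- run manifest ------------------------------------------------------------

.recordCount <- function(path) {
  if (grepl("\\.(csv|tsv)$", path)) {
    # data records excluding the header
    length(readLines(path, warn = FALSE)) - 1L
  } else NA_integer_
}

#' Write / verify a run manifest
#'
#' Every pipeline run emits one JSON manifest recording the tool version,
#' the master seed, timestamps, and for every input/output file its md5
#' checksum and (for delimited tables) its record count. A manifest plus
#' the config file is sufficient to re-run bit-identically;
#' `verifyRunManifest` re-checksums the listed files and fails on any
#' mismatch, catching silently truncated tables.
#'
#' @param path manifest file.
#' @param seed master seed of the run.
#' @param inputs,outputs named character vectors of file paths.
#' @param configPath optional config file, checksummed into the manifest.
#' @return `writeRunManifest`: the path, invisibly; `verifyRunManifest`:
#'   TRUE, or an error describing the first mismatch.
#' @export
writeRunManifest <- function(path, seed = NA_integer_,
                             inputs = character(), outputs = character(),
                             configPath = NULL) {
  fileEntry <- function(p) list(
    path = unname(p), md5 = unname(tools::md5sum(p)),
    n_records = .recordCount(p))
  man <- list(
    tool = "capmorph",
    version = as.character(utils::packageVersion("capmorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (is.null(configPath)) NULL else fileEntry(configPath),
    inputs = lapply(inputs, fileEntry),
    outputs = lapply(outputs, fileEntry))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname writeRunManifest
#' @export
verifyRunManifest <- function(path) {
  man <- jsonlite::read_json(path)
  check <- function(entry) {
    p <- entry$path
    if (!file.exists(p)) stop("manifest check failed: missing file ", p)
    md5 <- unname(tools::md5sum(p))
    if (!identical(md5, entry$md5))
      stop("manifest check failed: checksum mismatch for ", p)
    if (!is.null(entry$n_records) && !is.na(entry$n_records)) {
      nr <- .recordCount(p)
      if (nr != entry$n_records)
        stop("manifest check failed: ", p, " has ", nr,
             " records, manifest says ", entry$n_records,
             " (truncated file?)")
    }
    invisible(TRUE)
  }
  for (e in c(man$inputs, man$outputs)) check(e)
  if (!is.null(man$config)) check(man$config)
  TRUE
}
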