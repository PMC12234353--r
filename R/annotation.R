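#' Dot and reverse dot-product spectral similarity
#'
#' Peaks are binned at \code{binTol} Da (bin index = round(m/z / binTol)) and
#' intensities optionally square-root weighted before computing cosine
#' similarity on the 0-1000 scale. The dot product uses the union of bins and
#' is symmetric; the reverse dot product restricts both vectors to bins where
#' the reference has signal, so extra query peaks (noise, co-isolation) do not
#' penalize it.
#'
#' @param query,ref two-column (mz, intensity) matrices, e.g. from
#'   [parseSpectrum()]; both must be non-empty.
#' @param binTol binning tolerance in Da, default 0.01.
#' @param sqrtWeight square-root intensity weighting before cosine, default
#'   TRUE.
#' @return named numeric: \code{dot}, \code{revdot}, \code{total} (mean of the
#'   two), each in \[0, 1000\].
#' @export
spectralScores <- function(query, ref, binTol = 0.01, sqrtWeight = TRUE) {
  if (is.character(query)) query <- parseSpectrum(query)
  if (is.character(ref)) ref <- parseSpectrum(ref)
  if (nrow(query) == 0L || nrow(ref) == 0L) abort("empty spectrum")
  binify <- function(sp) {
    b <- round(sp[, 1] / binTol)
    tapply(sp[, 2], b, sum)
  }
  qb <- binify(query); rb <- binify(ref)
  bins <- union(names(qb), names(rb))
  q <- ifelse(bins %in% names(qb), qb[bins], 0)
  r <- ifelse(bins %in% names(rb), rb[bins], 0)
  q[is.na(q)] <- 0; r[is.na(r)] <- 0
  if (sqrtWeight) { q <- sqrt(q); r <- sqrt(r) }
  cosine <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    sum(u * v) / (nu * nv)
  }
  dot <- 1000 * cosine(q, r)
  inRef <- r > 0
  revdot <- 1000 * cosine(q[inRef], r[inRef])
  c(dot = dot, revdot = revdot, total = (dot + revdot) / 2)
}

#' Build a spectral library entry
#'
#' @param name compound name.
#' @param precursor_mz precursor ion m/z (Da).
#' @param ms2 packed spectrum string or (mz, intensity) matrix.
#' @param rt retention time in minutes; \code{NA} for public-database entries
#'   (only in-house reference standards carry RT).
#' @param class_meta "environmental", "endogenous" or "ambiguous".
#' @param subclass free-text subclass (e.g. "PFAS", "bile acids").
#' @param source originating library/database label.
#' @return a one-row data.frame.
#' @export
libraryEntry <- function(name, precursor_mz, ms2, rt = NA_real_,
                         class_meta = "environmental", subclass = "",
                         source = "in-house") {
  if (is.matrix(ms2)) ms2 <- formatSpectrum(ms2[, 1], ms2[, 2])
  if (!nzchar(ms2)) abort("library entry needs a non-empty MS2 spectrum")
  data.frame(name = name, precursor_mz = precursor_mz, rt = rt, ms2 = ms2,
             class_meta = class_meta, subclass = subclass, source = source,
             stringsAsFactors = FALSE)
}

#' Read and write MSP spectral libraries
#'
#' Minimal MSP text format: NAME, PRECURSORMZ, RETENTIONTIME (optional),
#' CLASS/SUBCLASS/SOURCE comment fields, Num Peaks and the peak list.
#'
#' @param path file path.
#' @param library a data.frame of [libraryEntry()] rows.
#' @return \code{readMsp} returns the library data.frame.
#' @export
writeMsp <- function(library, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(library))) {
    e <- library[i, ]
    sp <- parseSpectrum(e$ms2)
    cat(sprintf("NAME: %s\n", e$name), file = con)
    cat(sprintf("PRECURSORMZ: %.5f\n", e$precursor_mz), file = con)
    if (!is.na(e$rt)) cat(sprintf("RETENTIONTIME: %.3f\n", e$rt), file = con)
    cat(sprintf("CLASS: %s\n", e$class_meta), file = con)
    cat(sprintf("SUBCLASS: %s\n", e$subclass), file = con)
    cat(sprintf("SOURCE: %s\n", e$source), file = con)
    cat(sprintf("Num Peaks: %d\n", nrow(sp)), file = con)
    for (k in seq_len(nrow(sp)))
      cat(sprintf("%.5f %.1f\n", sp[k, 1], sp[k, 2]), file = con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' @rdname writeMsp
#' @export
readMsp <- function(path) {
  lines <- readLines(path)
  entries <- list(); cur <- NULL; peaks <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    cur$ms2 <- if (length(peaks)) paste(peaks, collapse = " ") else ""
    entries[[length(entries) + 1L]] <<- as.data.frame(cur, stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) { flush(); cur <- NULL; peaks <- NULL; next }
    if (grepl("^NAME:", ln, ignore.case = TRUE)) {
      flush(); peaks <- character(0)
      cur <- list(name = trimws(sub("^NAME:", "", ln, ignore.case = TRUE)),
                  precursor_mz = NA_real_, rt = NA_real_,
                  class_meta = "environmental", subclass = "",
                  source = "msp")
    } else if (grepl("^PRECURSORMZ:", ln, ignore.case = TRUE)) {
      cur$precursor_mz <- as.numeric(sub("^PRECURSORMZ:", "", ln, ignore.case = TRUE))
    } else if (grepl("^RETENTIONTIME:", ln, ignore.case = TRUE)) {
      cur$rt <- as.numeric(sub("^RETENTIONTIME:", "", ln, ignore.case = TRUE))
    } else if (grepl("^CLASS:", ln, ignore.case = TRUE)) {
      cur$class_meta <- trimws(sub("^CLASS:", "", ln, ignore.case = TRUE))
    } else if (grepl("^SUBCLASS:", ln, ignore.case = TRUE)) {
      cur$subclass <- trimws(sub("^SUBCLASS:", "", ln, ignore.case = TRUE))
    } else if (grepl("^SOURCE:", ln, ignore.case = TRUE)) {
      cur$source <- trimws(sub("^SOURCE:", "", ln, ignore.case = TRUE))
    } else if (grepl("^NUM PEAKS:", toupper(ln))) {
      # peak count implied by the list
    } else if (grepl("^[0-9]", ln)) {
      parts <- strsplit(ln, "[ \t;:]+")[[1]]
      peaks <- c(peaks, paste0(parts[1], ":", parts[2]))
    }
  }
  flush()
  if (length(entries) == 0)
    return(data.frame(name = character(0), precursor_mz = numeric(0),
                      rt = numeric(0), ms2 = character(0),
                      class_meta = character(0), subclass = character(0),
                      source = character(0)))
  do.call(rbind, entries)
}

#' Assign an identification confidence level to one feature
#'
#' Scores the query spectrum against library entries and keeps the best
#' total-score hit. Level 2 requires total > 700 and (dot > 600 or revdot >
#' 600); the hit is upgraded to Level 1 when the matched entry is an in-house
#' reference standard with retention time and |dRT| <= \code{rtTol}. Raising
#' any score never lowers the level (strict thresholds, per the printed
#' cut-offs).
#'
#' @param featureId feature identifier (carried into the record).
#' @param ms2 query spectrum (packed string or matrix).
#' @param rt query retention time (minutes).
#' @param library data.frame of [libraryEntry()] rows.
#' @param binTol spectral binning tolerance (Da), default 0.01.
#' @param rtTol Level-1 retention-time tolerance (minutes), default 0.2.
#' @param precursorMz optional query precursor m/z; with a finite
#'   \code{precursorTol} only entries within that window are scored.
#' @param precursorTol precursor window in Da; default \code{Inf} scores all
#'   entries.
#' @param sqrtWeight see [spectralScores()].
#' @return a one-row data.frame: feature_id, level ("1", "2" or "none"),
#'   matched_name, dot, revdot, total, class_meta, subclass.
#' @export
assignLevel <- function(featureId, ms2, rt, library, binTol = 0.01,
                        rtTol = 0.2, precursorMz = NA_real_,
                        precursorTol = Inf, sqrtWeight = TRUE) {
  none <- data.frame(feature_id = featureId, level = "none",
                     matched_name = NA_character_, dot = 0, revdot = 0,
                     total = 0, class_meta = NA_character_,
                     subclass = NA_character_, stringsAsFactors = FALSE)
  if (is.character(ms2)) ms2 <- parseSpectrum(ms2)
  if (nrow(ms2) == 0L || nrow(library) == 0L) return(none)
  cand <- library
  if (is.finite(precursorTol) && !is.na(precursorMz))
    cand <- cand[abs(cand$precursor_mz - precursorMz) <= precursorTol, ]
  if (nrow(cand) == 0L) return(none)
  scores <- t(vapply(seq_len(nrow(cand)), function(i)
    spectralScores(ms2, cand$ms2[i], binTol = binTol, sqrtWeight = sqrtWeight),
    numeric(3)))
  best <- which.max(scores[, "total"])
  sc <- scores[best, ]
  e <- cand[best, ]
  level <- "none"
  if (sc["total"] > 700 && (sc["dot"] > 600 || sc["revdot"] > 600)) {
    level <- "2"
    if (!is.na(e$rt) && !is.na(rt) && abs(e$rt - rt) <= rtTol) level <- "1"
  }
  data.frame(feature_id = featureId, level = level, matched_name = e$name,
             dot = unname(sc["dot"]), revdot = unname(sc["revdot"]),
             total = unname(sc["total"]),
             class_meta = if (level == "none") NA_character_ else e$class_meta,
             subclass = if (level == "none") NA_character_ else e$subclass,
             stringsAsFactors = FALSE)
}

#' Resolve the environmental/endogenous class of an annotated feature
#'
#' Class and subclass come from library/database metadata; when independent
#' metadata sources disagree on the class, the feature is labelled
#' \code{ambiguous}.
#'
#' @param record a one-row annotation record from [assignLevel()] with level
#'   1 or 2.
#' @param sources optional character vector of class labels from additional
#'   metadata sources; disagreement yields "ambiguous".
#' @return the record with resolved \code{class_meta}.
#' @export
classifyFeature <- function(record, sources = character(0)) {
  if (!record$level %in% c("1", "2"))
    abort("cannot classify an unannotated feature")
  labels <- unique(stats::na.omit(c(record$class_meta, sources)))
  record$class_meta <- if (length(labels) == 1L) labels else "ambiguous"
  record
}

#' Annotate every feature of a cleaned table against a spectral library
#'
#' @param x a [FeatureTable-class].
#' @param library a data.frame of [libraryEntry()] rows.
#' @param ... passed to [assignLevel()].
#' @return data.frame of annotation records, one row per feature.
#' @export
annotateFeatures <- function(x, library, ...) {
  stopifnot(is(x, "FeatureTable"))
  empty <- data.frame(feature_id = character(0), level = character(0),
                      matched_name = character(0), dot = numeric(0),
                      revdot = numeric(0), total = numeric(0),
                      class_meta = character(0), subclass = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(empty)
  rd <- rowData(x)
  recs <- lapply(seq_len(nrow(x)), function(i) {
    sp <- parseSpectrum(rd$ms2[i])
    if (nrow(sp) == 0)
      return(data.frame(feature_id = rownames(x)[i], level = "none",
                        matched_name = NA_character_, dot = 0, revdot = 0,
                        total = 0, class_meta = NA_character_,
                        subclass = NA_character_, stringsAsFactors = FALSE))
    assignLevel(rownames(x)[i], sp, rd$rt[i], library,
                precursorMz = rd$mz[i], ...)
  })
  do.call(rbind, recs)
}

#' Summarize annotation results
#'
#' @param records annotation records from [annotateFeatures()].
#' @return list with \code{n_annotated}, \code{n_level1}, \code{n_level2},
#'   \code{class_counts} (environmental/endogenous/ambiguous) and
#'   \code{annotation_rate} given \code{n_total}.
#' @param n_total total feature count the rate is computed against.
#' @export
annotationSummary <- function(records, n_total = nrow(records)) {
  ann <- records[records$level %in% c("1", "2"), , drop = FALSE]
  cc <- table(factor(ann$class_meta,
                     levels = c("environmental", "endogenous", "ambiguous")))
  list(n_annotated = nrow(ann),
       n_level1 = sum(ann$level == "1"),
       n_level2 = sum(ann$level == "2"),
       class_counts = as.list(cc),
       annotation_rate = if (n_total > 0) nrow(ann) / n_total else NA_real_)
}
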