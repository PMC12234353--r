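#' Procedural-blank ratio filter
#'
#' Retains a feature only when its maximum peak area over study samples is
#' more than \code{factor} times the mean area over procedural blanks
#' (sample maximum / blank average > factor). A blank mean of exactly 0
#' retains any feature detected in at least one sample.
#'
#' @param x a [FeatureTable-class] with at least one blank column.
#' @param factor ratio threshold, default 5.
#' @return the filtered table; removals are appended to [provenance()].
#' @export
maxBlankRatioFilter <- function(x, factor = 5) {
  stopifnot(is(x, "FeatureTable"))
  bl <- blankColumns(x)
  if (length(bl) == 0L) abort("no blank columns in table")
  sm <- sampleColumns(x)
  a <- assay(x, "area")
  sampleMax <- if (length(sm)) apply(a[, sm, drop = FALSE], 1, max) else
    rep(0, nrow(x))
  blankMean <- rowMeans(a[, bl, drop = FALSE])
  keep <- ifelse(blankMean == 0, sampleMax > 0, sampleMax / blankMean > factor)
  removed <- rownames(x)[!keep]
  out <- x[keep, ]
  out <- appendProvenance(out, "blank_ratio", removed,
                          sprintf("max/blank <= %g", factor))
  out
}

#' Merge ESI+ and ESI- feature tables on neutral mass
#'
#' The same neutral molecule M appears as \[M+H\]+ (m/z = M + 1.007276) in
#' positive mode and \[M-H\]- (m/z = M - 1.007276) in negative mode. For every
#' cross-mode pair whose neutral masses agree within \code{mzTol} and
#' retention times within \code{rtTol}, the member with the lower average
#' study-sample peak area is discarded.
#'
#' @param pos,neg blank-filtered [FeatureTable-class] objects with identical
#'   column layout.
#' @param rtTol retention-time tolerance in minutes, default 0.2.
#' @param mzTol neutral-mass tolerance in Da, default 0.002.
#' @return one merged [FeatureTable-class].
#' @export
mergeEsiModes <- function(pos, neg, rtTol = 0.2, mzTol = 0.002) {
  stopifnot(is(pos, "FeatureTable"), is(neg, "FeatureTable"))
  if (!identical(colnames(pos), colnames(neg)))
    abort("pos and neg tables must share the same columns")
  sm <- sampleColumns(pos)
  neutral <- function(ft) {
    m <- rowData(ft)$mz
    ifelse(rowData(ft)$mode == "pos", m - PROTON_MASS, m + PROTON_MASS)
  }
  Mp <- neutral(pos); Mn <- neutral(neg)
  rtP <- rowData(pos)$rt; rtN <- rowData(neg)$rt
  avg <- function(ft) {
    a <- assay(ft, "area")
    if (length(sm)) rowMeans(a[, sm, drop = FALSE]) else rep(0, nrow(ft))
  }
  avgP <- avg(pos); avgN <- avg(neg)
  dropP <- logical(nrow(pos)); dropN <- logical(nrow(neg))
  if (nrow(pos) > 0 && nrow(neg) > 0) {
    for (i in seq_len(nrow(pos))) {
      hits <- which(abs(Mn - Mp[i]) <= mzTol & abs(rtN - rtP[i]) <= rtTol)
      for (j in hits) {
        if (avgP[i] >= avgN[j]) dropN[j] <- TRUE else dropP[i] <- TRUE
      }
    }
  }
  keepP <- pos[!dropP, ]; keepN <- neg[!dropN, ]
  merged <- new("FeatureTable", rbind(as(keepP, "SummarizedExperiment"),
                                      as(keepN, "SummarizedExperiment")))
  metadata(merged)$provenance <- rbind(provenance(pos), provenance(neg))
  merged <- appendProvenance(merged, "esi_merge",
                             c(rownames(pos)[dropP], rownames(neg)[dropN]),
                             "cross-mode duplicate with lower average area")
  merged
}

#' Internal-standard PCA normalization
#'
#' Removes multivariate instrumental drift from log peak areas using the
#' principal-component scores of the log internal-standard matrix: the IS
#' matrix (standards x samples) is log-transformed, samples are centered, and
#' each feature's log areas are regressed on the first \code{nComponents}
#' sample scores; the fitted drift (mean zero across samples by construction,
#' preserving each feature's geometric-mean area) is subtracted. Zeros
#' (non-detections) are left untouched. With \code{nComponents = 0} or a
#' zero-variance IS matrix the transform is the identity.
#'
#' @param x a merged [FeatureTable-class].
#' @param isMatrix internal-standard areas, standards x study-sample columns;
#'   column names must cover the table's sample columns.
#' @param nComponents number of PCA score dimensions to remove, default 2.
#' @return the normalized table.
#' @export
normalizeByISPCA <- function(x, isMatrix, nComponents = 2) {
  stopifnot(is(x, "FeatureTable"))
  sm <- sampleColumns(x)
  if (length(sm) == 0L || nrow(x) == 0L || nComponents == 0) return(x)
  smNames <- colnames(x)[sm]
  if (!all(smNames %in% colnames(isMatrix)))
    abort("isMatrix missing sample columns: ",
          paste(setdiff(smNames, colnames(isMatrix)), collapse = ", "))
  if (nrow(isMatrix) < 2) abort("need >= 2 internal standards")
  isM <- isMatrix[, smNames, drop = FALSE]
  noIS <- colSums(isM > 0) == 0
  if (any(noIS))
    abort("sample(s) missing all IS areas: ",
          paste(smNames[noIS], collapse = ", "))
  L <- t(log(pmax(isM, .Machine$double.eps)))       # samples x IS
  Lc <- scale(L, center = TRUE, scale = FALSE)
  if (all(abs(Lc) < 1e-12)) return(x)               # no drift signal
  pc <- stats::prcomp(Lc, center = FALSE)
  k <- min(nComponents, ncol(pc$x))
  S <- pc$x[, seq_len(k), drop = FALSE]             # samples x k scores
  a <- assay(x, "area")
  for (i in seq_len(nrow(a))) {
    det <- which(a[i, sm] > 0)
    if (length(det) < k + 2) next                    # too few points to fit
    y <- log(a[i, sm][det])
    X <- cbind(1, S[det, , drop = FALSE])
    beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(beta)) next
    drift <- S[det, , drop = FALSE] %*% beta[-1]
    drift <- drift - mean(drift)                     # preserve geometric mean
    a[i, sm][det] <- exp(y - drift)
  }
  assay(x, "area") <- a
  x
}

#' Blank subtraction with pseudo-count and area floor
#'
#' Per feature: the blank average gets a pseudo-count (+0.1) to avoid zero
#' denominators; sample cells whose area is less than \code{factor} times the
#' blank average are set to 0; surviving cells have the blank average
#' subtracted; finally any cell below \code{floor} is set to 0. Blank columns
#' are consumed by this stage and dropped from the output, which makes the
#' operation idempotent (a second pass sees blank average 0 and the
#' pseudo-count path keeps every surviving cell).
#'
#' @param x a [FeatureTable-class].
#' @param factor blank-ratio threshold, default 5.
#' @param pseudo pseudo-count added to the blank average, default 0.1.
#' @param floor minimum retained area, default 90000.
#' @return the table with blank columns removed.
#' @export
blankSubtractFloor <- function(x, factor = 5, pseudo = 0.1, floor = 90000) {
  stopifnot(is(x, "FeatureTable"))
  bl <- blankColumns(x)
  nonBlank <- setdiff(seq_len(ncol(x)), bl)
  a <- assay(x, "area")
  blankMean <- if (length(bl)) rowMeans(a[, bl, drop = FALSE]) else
    rep(0, nrow(x))
  for (i in seq_len(nrow(a))) {
    v <- a[i, nonBlank]
    ratio <- v / (blankMean[i] + pseudo)
    v[ratio < factor] <- 0
    v[v > 0] <- v[v > 0] - blankMean[i]
    v[v < floor] <- 0
    a[i, nonBlank] <- v
  }
  out <- x[, nonBlank]
  assay(out, "area") <- a[, nonBlank, drop = FALSE]
  metadata(out)$provenance <- provenance(x)
  out
}

# Pearson p-value from the t distribution with n - 2 df
pearsonP <- function(r, n) {
  if (n < 3 || is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Deduplicate correlated co-eluting features
#'
#' Features that correlate almost perfectly over co-detected samples (Pearson
#' r over shared nonzero samples > \code{rThreshold}, p < \code{pThreshold})
#' and elute within \code{rtTol} minutes are treated as one analyte (in-source
#' fragments, adducts); the member with the lower average study-sample area is
#' discarded. Features are processed in descending average-area order (ties
#' broken by feature id) so the survivor set is deterministic; pairs with
#' fewer than 3 shared nonzero samples are skipped and logged.
#'
#' @param x a [FeatureTable-class] with finalized areas.
#' @param rThreshold Pearson correlation threshold, default 0.95.
#' @param pThreshold correlation p-value threshold, default 0.001.
#' @param rtTol retention-time tolerance in minutes, default 0.1.
#' @return the deduplicated table.
#' @export
dedupCorrelated <- function(x, rThreshold = 0.95, pThreshold = 0.001,
                            rtTol = 0.1) {
  stopifnot(is(x, "FeatureTable"))
  if (nrow(x) < 2) return(x)
  sm <- sampleColumns(x)
  a <- assay(x, "area")[, sm, drop = FALSE]
  avg <- rowMeans(a)
  rt <- rowData(x)$rt
  ord <- order(-avg, rownames(x))
  removed <- logical(nrow(x))
  skipped <- character(0)
  for (oi in seq_along(ord)) {
    i <- ord[oi]
    if (removed[i]) next
    for (oj in seq_along(ord)) {
      if (oj <= oi) next
      j <- ord[oj]
      if (removed[j]) next
      if (abs(rt[i] - rt[j]) > rtTol) next
      shared <- which(a[i, ] > 0 & a[j, ] > 0)
      if (length(shared) < 3) {
        skipped <- c(skipped, sprintf("%s~%s", rownames(x)[i], rownames(x)[j]))
        next
      }
      r <- suppressWarnings(stats::cor(a[i, shared], a[j, shared]))
      if (is.na(r)) next
      p <- pearsonP(r, length(shared))
      if (r > rThreshold && !is.na(p) && p < pThreshold) removed[j] <- TRUE
    }
  }
  out <- x[!removed, ]
  metadata(out)$provenance <- provenance(x)
  out <- appendProvenance(out, "dedup", rownames(x)[removed],
                          sprintf("correlated duplicate (r > %g)", rThreshold))
  if (length(skipped))
    metadata(out)$dedup_skipped_pairs <- skipped
  out
}

#' @rdname detectionFrequency
#' @export
setGeneric("detectionFrequency", function(x, ...) standardGeneric("detectionFrequency"))

#' Detection frequency of untargeted features
#'
#' Fraction of study-sample columns with nonzero area (zeros represent
#' non-detections after blank subtraction and flooring).
#'
#' @param x a [FeatureTable-class].
#' @param ... unused.
#' @return named numeric vector in \[0, 1\].
#' @export
setMethod("detectionFrequency", "FeatureTable", function(x, ...) {
  sm <- sampleColumns(x)
  a <- assay(x, "area")[, sm, drop = FALSE]
  setNames(rowMeans(a > 0), rownames(x))
})

#' Detection-frequency filter
#'
#' Drops features detected in fewer than \code{dfThreshold} of study samples
#' (boundary inclusive: DF exactly at the threshold is retained) and stores
#' the detection frequency of survivors in \code{rowData(x)$df}. QC columns
#' are dropped: the output is the cleaned feature x sample matrix that enters
#' statistical analysis.
#'
#' @param x a [FeatureTable-class] after blank subtraction.
#' @param dfThreshold detection-frequency cut-off, default 0.70.
#' @return the cleaned [FeatureTable-class] (sample columns only).
#' @export
detectionFrequencyFilter <- function(x, dfThreshold = 0.70) {
  stopifnot(is(x, "FeatureTable"))
  df <- detectionFrequency(x)
  keep <- df >= dfThreshold
  removedIds <- rownames(x)[!keep]
  out <- x[keep, sampleColumns(x)]
  rowData(out)$df <- df[keep]
  metadata(out)$provenance <- provenance(x)
  out <- appendProvenance(out, "df_filter", removedIds,
                          sprintf("DF < %g", dfThreshold))
  out
}

#' Run the full untargeted cleaning pipeline
#'
#' Fixed stage order: per-mode blank-ratio filter, ESI merge, IS-PCA
#' normalization, blank subtraction with floor, correlated deduplication,
#' detection-frequency filter. Per-stage feature counts are recorded in
#' \code{metadata(x)$funnel}.
#'
#' @param pos,neg raw per-mode [FeatureTable-class] objects.
#' @param isMatrix internal-standard area matrix (see [normalizeByISPCA()]).
#' @param blankFactor,floor,pseudo,rtTolMerge,mzTol,nComponents,rThreshold,pThreshold,rtTolDedup,dfThreshold
#'   stage parameters; defaults are the validated method's constants.
#' @return the cleaned [FeatureTable-class].
#' @export
cleanFeatures <- function(pos, neg, isMatrix = NULL,
                          blankFactor = 5, floor = 90000, pseudo = 0.1,
                          rtTolMerge = 0.2, mzTol = 0.002, nComponents = 2,
                          rThreshold = 0.95, pThreshold = 0.001,
                          rtTolDedup = 0.1, dfThreshold = 0.70) {
  funnel <- data.frame(stage = "input", n_features = nrow(pos) + nrow(neg))
  p1 <- maxBlankRatioFilter(pos, blankFactor)
  n1 <- maxBlankRatioFilter(neg, blankFactor)
  funnel <- rbind(funnel, data.frame(stage = "blank_ratio",
                                     n_features = nrow(p1) + nrow(n1)))
  m <- mergeEsiModes(p1, n1, rtTol = rtTolMerge, mzTol = mzTol)
  funnel <- rbind(funnel, data.frame(stage = "esi_merge", n_features = nrow(m)))
  if (!is.null(isMatrix))
    m <- normalizeByISPCA(m, isMatrix, nComponents = nComponents)
  m <- blankSubtractFloor(m, factor = blankFactor, pseudo = pseudo, floor = floor)
  funnel <- rbind(funnel, data.frame(stage = "blank_subtract", n_features = nrow(m)))
  m <- dedupCorrelated(m, rThreshold = rThreshold, pThreshold = pThreshold,
                       rtTol = rtTolDedup)
  funnel <- rbind(funnel, data.frame(stage = "dedup", n_features = nrow(m)))
  m <- detectionFrequencyFilter(m, dfThreshold = dfThreshold)
  funnel <- rbind(funnel, data.frame(stage = "df_filter", n_features = nrow(m)))
  metadata(m)$funnel <- funnel
  m
}
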