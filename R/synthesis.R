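COVARIATE_NAMES <- c("age", "n_pregnancies", "n_deliveries", "age_menarche",
                     "sample_year", "bmi", "tobacco")

#' Build an effect specification table for the concentration generator
#'
#' One row per analyte: log-scale baseline mean and SD of the subject random
#' intercept and residual, plus linear coefficients (on the log scale) for any
#' subset of the covariates age, n_pregnancies, n_deliveries, age_menarche,
#' sample_year, bmi, tobacco. Unspecified coefficients are 0.
#'
#' @param analyte analyte names.
#' @param baseline log-scale mean concentration (log ng/mL).
#' @param sdSubject subject random-intercept SD (log scale), >= 0.
#' @param sdResid residual SD (log scale), >= 0.
#' @param ... named numeric vectors of covariate coefficients, e.g.
#'   \code{age = 0.02}.
#' @return a data.frame consumed by [generateTargetTruth()].
#' @examples
#' effectSpec(c("PFOS", "PFOA"), baseline = log(c(15, 2)),
#'            sdSubject = 0.4, sdResid = 0.3, age = c(0.02, 0.015))
#' @export
effectSpec <- function(analyte, baseline = 0, sdSubject = 0.3, sdResid = 0.3, ...) {
  n <- length(analyte)
  ex <- list(...)
  if (length(ex) && is.null(names(ex))) abort("coefficients must be named")
  bad <- setdiff(names(ex), COVARIATE_NAMES)
  if (length(bad))
    abort("unknown covariate name(s) in effect spec: ", paste(bad, collapse = ", "))
  out <- data.frame(analyte = analyte,
                    baseline = rep_len(baseline, n),
                    sdSubject = rep_len(sdSubject, n),
                    sdResid = rep_len(sdResid, n),
                    stringsAsFactors = FALSE)
  for (cv in COVARIATE_NAMES) {
    out[[cv]] <- if (cv %in% names(ex)) rep_len(ex[[cv]], n) else 0
  }
  if (any(out$sdSubject < 0) || any(out$sdResid < 0)) abort("SDs must be >= 0")
  if (!all(is.finite(as.matrix(out[COVARIATE_NAMES])))) abort("coefficients must be finite")
  out
}

#' Generate latent-truth targeted concentrations for a cohort
#'
#' Concentrations follow a log-normal generative law: for sample j of subject
#' i, \code{conc = exp(baseline + sum(coef * covariate) + b_i + e_ij)} with
#' \code{b_i ~ N(0, sdSubject^2)} and \code{e_ij ~ N(0, sdResid^2)}. Linear
#' covariate effects on the log scale reproduce the left-skewed raw
#' distributions the square-root transform is meant to tame. Censoring is
#' deterministic: values below MLOQ/3 are flagged \code{nondetect}, values in
#' \[MLOQ/3, MLOQ) \code{below_mloq}, the rest \code{quantified}.
#'
#' @param cohort an [ExposomeCohort-class].
#' @param effects effect table from [effectSpec()].
#' @param mloqs named per-analyte MLOQ (ng/mL), all > 0.
#' @param seed integer seed.
#' @return a list with \code{matrix} (a [ConcentrationMatrix-class]) and
#'   \code{truth} (effects, per-subject random intercepts, latent
#'   concentrations) for parameter-recovery tests.
#' @export
generateTargetTruth <- function(cohort, effects, mloqs, seed = 1L) {
  md <- buildModelData(cohort)
  if (!all(effects$analyte %in% names(mloqs)))
    abort("every analyte needs an MLOQ")
  mloqs <- mloqs[effects$analyte]
  if (any(mloqs <= 0)) abort("MLOQs must be > 0")
  bad <- setdiff(intersect(colnames(effects), COVARIATE_NAMES),
                 c(colnames(md), "tobacco"))
  if (length(bad)) abort("unknown covariate in effects: ", paste(bad, collapse = ", "))

  set.seed(as.integer(seed))
  nA <- nrow(effects); nS <- nrow(md)
  subj <- unique(md$participant_id)
  bmat <- matrix(stats::rnorm(nA * length(subj)), nA, length(subj),
                 dimnames = list(effects$analyte, subj)) *
    effects$sdSubject
  conc <- matrix(0, nA, nS, dimnames = list(effects$analyte, md$sample_id))
  X <- as.matrix(md[, COVARIATE_NAMES, drop = FALSE])
  X[is.na(X)] <- 0  # missing covariates contribute no planted effect
  B <- as.matrix(effects[, COVARIATE_NAMES, drop = FALSE])
  lin <- B %*% t(X)                      # analytes x samples
  eps <- matrix(stats::rnorm(nA * nS), nA, nS) * effects$sdResid
  logc <- effects$baseline + lin + bmat[, md$participant_id, drop = FALSE] + eps
  conc[] <- exp(logc)

  status <- matrix("quantified", nA, nS, dimnames = dimnames(conc))
  below <- sweep(conc, 1, mloqs, "<")
  nd <- sweep(conc, 1, mloqs / 3, "<")
  status[below] <- "below_mloq"
  status[nd] <- "nondetect"
  cm <- concentrationMatrix(conc, status, mloqs)
  list(matrix = cm,
       truth = list(effects = effects, subjectIntercepts = bmat,
                    latent = conc, modelData = md))
}

#' Planting plan for the untargeted-table generator
#'
#' Declares the structures the generator plants so downstream filters have
#' known ground truth: cross-mode duplicate pairs (same neutral mass within
#' 0.002 Da, RT within 0.2 min), in-source-fragment pairs (proportional areas,
#' RT within 0.1 min), blank-dominated features, procedural blanks per batch,
#' pooled-QC injections, internal standards, and the per-batch multiplicative
#' drift SD shared by IS and features.
#'
#' @param nCrossModePairs,nFragmentPairs,nBlankOnly planted structure counts.
#' @param nBlanksPerBatch procedural blanks per injection batch (>= 2).
#' @param nQCPerBatch pooled-QC injections per batch.
#' @param nIS number of isotope-labeled internal standards.
#' @param driftSD SD of per-batch log-scale drift.
#' @param detectProbRange per-feature detection probability range; features
#'   draw a probability uniformly from this range so the detection-frequency
#'   filter has both survivors and casualties.
#' @return a named list.
#' @export
plantingPlan <- function(nCrossModePairs = 5L, nFragmentPairs = 5L,
                         nBlankOnly = 5L, nBlanksPerBatch = 2L,
                         nQCPerBatch = 1L, nIS = 34L, driftSD = 0.2,
                         detectProbRange = c(0.5, 1)) {
  stopifnot(nBlanksPerBatch >= 1L, nIS >= 2L)
  list(nCrossModePairs = as.integer(nCrossModePairs),
       nFragmentPairs = as.integer(nFragmentPairs),
       nBlankOnly = as.integer(nBlankOnly),
       nBlanksPerBatch = as.integer(nBlanksPerBatch),
       nQCPerBatch = as.integer(nQCPerBatch),
       nIS = as.integer(nIS), driftSD = driftSD,
       detectProbRange = detectProbRange)
}

# one mode's base feature set
simFeatures <- function(nFeat, mode, idOffset) {
  if (nFeat == 0L)
    return(data.frame(id = character(0), mz = numeric(0), rt = numeric(0),
                      base = numeric(0), detectP = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    id = sprintf("%s%05d", toupper(substr(mode, 1, 1)), idOffset + seq_len(nFeat)),
    mz = stats::runif(nFeat, 90, 1000),
    rt = stats::runif(nFeat, 0.5, 22),
    base = stats::rnorm(nFeat, log(5e5), 1.2),
    stringsAsFactors = FALSE)
}

randomSpectrum <- function() {
  k <- sample(3:8, 1L)
  formatSpectrum(sort(stats::runif(k, 50, 500)), stats::runif(k, 10, 999))
}

#' Generate synthetic per-mode untargeted feature tables
#'
#' Emulates a pair of aligned LC-HRMS feature tables (ESI+ and ESI-) over the
#' cohort's samples, procedural blanks (per injection batch) and pooled-QC
#' injections. Peak areas are log-normal around a per-feature baseline with a
#' per-batch multiplicative drift shared between features and the
#' isotope-labeled internal standards, so IS-PCA normalization has signal to
#' remove. Planted structures (cross-mode duplicates with consistent
#' \[M+H\]+/\[M-H\]- arithmetic, in-source-fragment pairs, blank-dominated
#' features) are returned as ground truth. Planted duplicates violating their
#' own m/z/RT tolerances are rejected at generation time.
#'
#' @param cohort an [ExposomeCohort-class].
#' @param nFeatures length-2 integer: base feature counts for (pos, neg).
#' @param planting a [plantingPlan()].
#' @param seed integer seed.
#' @return list with \code{pos}, \code{neg} ([FeatureTable-class]),
#'   \code{isMatrix} (IS x sample-column log-normal areas, one per mode is not
#'   needed: IS are spiked per injection), and \code{truth} (planted ids,
#'   drift factors).
#' @export
generateUntargetedTables <- function(cohort, nFeatures = c(pos = 300L, neg = 200L),
                                     planting = plantingPlan(), seed = 1L) {
  set.seed(as.integer(seed))
  s <- as.data.frame(cohortSamples(cohort))
  batches <- if (nrow(s)) sort(unique(s$batch)) else integer(0)
  sampleNames <- s$sample_id
  blankNames <- unlist(lapply(batches, function(b)
    sprintf("BLANK_B%d_%d", b, seq_len(planting$nBlanksPerBatch))))
  qcNames <- unlist(lapply(batches, function(b)
    sprintf("QC_B%d_%d", b, seq_len(planting$nQCPerBatch))))
  cols <- c(sampleNames, blankNames, qcNames)
  roles <- c(rep("sample", length(sampleNames)),
             rep("blank", length(blankNames)), rep("qc", length(qcNames)))
  colBatch <- c(s$batch,
                rep(batches, each = planting$nBlanksPerBatch),
                rep(batches, each = planting$nQCPerBatch))
  drift <- stats::rnorm(max(length(batches), 1L), 0, planting$driftSD)

  makeMode <- function(nFeat, mode, offset) {
    fd <- simFeatures(nFeat, mode, offset)
    fd$detectP <- stats::runif(nrow(fd), planting$detectProbRange[1],
                               planting$detectProbRange[2])
    fd
  }
  pos <- makeMode(nFeatures[1], "pos", 0L)
  neg <- makeMode(nFeatures[2], "neg", 0L)

  truth <- list(crossModePairs = data.frame(pos = character(0), neg = character(0)),
                fragmentPairs = data.frame(parent = character(0), fragment = character(0),
                                           mode = character(0)),
                blankOnly = character(0), drift = drift)

  # cross-mode duplicates: same neutral molecule seen as [M+H]+ and [M-H]-
  if (planting$nCrossModePairs > 0L && nrow(pos) >= planting$nCrossModePairs) {
    idx <- sample.int(nrow(pos), planting$nCrossModePairs)
    for (i in idx) {
      M <- pos$mz[i] - PROTON_MASS
      negRow <- data.frame(id = sprintf("NDUP%04d", i),
                           mz = M - PROTON_MASS,
                           rt = pos$rt[i] + stats::runif(1, -0.05, 0.05),
                           base = pos$base[i] - log(2),  # lower signal in neg
                           detectP = pos$detectP[i],
                           stringsAsFactors = FALSE)
      dM <- abs((pos$mz[i] - PROTON_MASS) - (negRow$mz + PROTON_MASS))
      if (dM > 0.002 || abs(negRow$rt - pos$rt[i]) > 0.2)
        abort("planted cross-mode duplicate violates its tolerance")
      neg <- rbind(neg, negRow)
      truth$crossModePairs <- rbind(truth$crossModePairs,
                                    data.frame(pos = pos$id[i], neg = negRow$id))
    }
  }

  buildTable <- function(fd, mode) {
    nFeat <- nrow(fd)
    area <- matrix(0, nFeat, length(cols), dimnames = list(fd$id, cols))
    if (nFeat > 0 && length(cols) > 0) {
      for (j in seq_along(cols)) {
        b <- colBatch[j]
        d <- if (length(drift)) drift[match(b, batches)] else 0
        if (roles[j] == "blank") {
          area[, j] <- exp(stats::rnorm(nFeat, log(8e3), 0.8) + d)
        } else {
          det <- stats::runif(nFeat) < fd$detectP
          a <- exp(fd$base + stats::rnorm(nFeat, 0, 0.3) + d)
          a[!det] <- 0
          area[, j] <- a
        }
      }
    }
    list(fd = fd, area = area)
  }

  bp <- buildTable(pos, "pos")
  bn <- buildTable(neg, "neg")

  # in-source fragment pairs (within-mode): proportional areas, close RT
  plantFragments <- function(bt, mode, n) {
    if (n == 0L || nrow(bt$fd) < n) return(bt)
    idx <- sample.int(nrow(bt$fd), n)
    for (i in idx) {
      fid <- sprintf("%sFRAG%04d", toupper(substr(mode, 1, 1)), i)
      frow <- bt$fd[i, ]
      frow$id <- fid
      frow$mz <- max(frow$mz - stats::runif(1, 20, 60), 51)
      frow$rt <- frow$rt + stats::runif(1, -0.05, 0.05)
      bt$fd <- rbind(bt$fd, frow)
      scl <- stats::runif(1, 0.4, 0.8)   # fragment carries less signal
      newArea <- bt$area[i, ] * scl * exp(stats::rnorm(length(cols), 0, 0.01))
      bt$area <- rbind(bt$area, newArea)
      rownames(bt$area)[nrow(bt$area)] <- fid
      truth$fragmentPairs <<- rbind(truth$fragmentPairs,
        data.frame(parent = bt$fd$id[i], fragment = fid, mode = mode))
    }
    bt
  }
  bp <- plantFragments(bp, "pos", planting$nFragmentPairs)
  bn <- plantFragments(bn, "neg", planting$nFragmentPairs)

  # blank-dominated features: signal lives in the blanks, not the samples
  plantBlankOnly <- function(bt, mode, n) {
    if (n == 0L || length(cols) == 0L) return(bt)
    for (k in seq_len(n)) {
      fid <- sprintf("%sBLK%04d", toupper(substr(mode, 1, 1)), k)
      row <- data.frame(id = fid, mz = stats::runif(1, 90, 1000),
                        rt = stats::runif(1, 0.5, 22), base = log(5e5),
                        detectP = 1, stringsAsFactors = FALSE)
      a <- numeric(length(cols))
      a[roles == "blank"] <- exp(stats::rnorm(sum(roles == "blank"), log(5e5), 0.3))
      a[roles != "blank"] <- exp(stats::rnorm(sum(roles != "blank"), log(2e4), 0.3))
      bt$fd <- rbind(bt$fd, row)
      bt$area <- rbind(bt$area, a)
      rownames(bt$area)[nrow(bt$area)] <- fid
      truth$blankOnly <<- c(truth$blankOnly, fid)
    }
    bt
  }
  bp <- plantBlankOnly(bp, "pos", planting$nBlankOnly)
  bn <- plantBlankOnly(bn, "neg", planting$nBlankOnly)

  finalize <- function(bt, mode) {
    nFeat <- nrow(bt$fd)
    ms2 <- vapply(seq_len(nFeat), function(i) randomSpectrum(), character(1))
    featureTable(bt$area, mz = bt$fd$mz, rt = bt$fd$rt, mode = mode, ms2 = ms2,
                 role = roles, batch = colBatch)
  }
  posFT <- finalize(bp, "pos")
  negFT <- finalize(bn, "neg")

  # isotope-labeled IS areas per study sample, carrying the same batch drift
  isMat <- matrix(0, planting$nIS, length(sampleNames),
                  dimnames = list(sprintf("IS%02d", seq_len(planting$nIS)),
                                  sampleNames))
  if (length(sampleNames)) {
    isBase <- stats::rnorm(planting$nIS, log(1e6), 0.5)
    for (j in seq_along(sampleNames)) {
      d <- drift[match(s$batch[j], batches)]
      isMat[, j] <- exp(isBase + d + stats::rnorm(planting$nIS, 0, 0.05))
    }
  }
  list(pos = posFT, neg = negFT, isMatrix = isMat, truth = truth)
}
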