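#' Fit a targeted calibration curve
#'
#' Ordinary least-squares line of internal-standard response ratio against
#' nominal concentration. The calibration range is the span of nominal
#' concentrations (the validated method uses 9 points over 0.01-100 ng/mL).
#'
#' @param points data.frame with columns \code{conc} (ng/mL) and \code{ratio}
#'   (analyte area / IS area).
#' @param analyte,internal_standard labels stored on the object.
#' @return a [Calibration-class].
#' @examples
#' cal <- fitCalibration(data.frame(conc = c(0.01, 0.1, 1, 10, 100),
#'                                  ratio = 0.5 * c(0.01, 0.1, 1, 10, 100)))
#' cal
#' @export
fitCalibration <- function(points, analyte = "analyte",
                           internal_standard = "IS") {
  stopifnot(is.data.frame(points), all(c("conc", "ratio") %in% colnames(points)))
  points <- points[stats::complete.cases(points[, c("conc", "ratio")]), ]
  if (length(unique(points$conc)) < 2)
    abort("degenerate calibration: need >= 2 distinct concentrations")
  fit <- stats::lm(ratio ~ conc, data = points)
  cf <- stats::coef(fit)
  new("Calibration", analyte = analyte, internal_standard = internal_standard,
      points = as.data.frame(points), slope = unname(cf["conc"]),
      intercept = unname(cf["(Intercept)"]),
      range = range(points$conc))
}

#' Fit one per-batch calibration from repeated curve injections
#'
#' Calibration curves are injected several times per batch (beginning, middle,
#' end) to absorb instrumental drift; the response ratios are averaged per
#' nominal level and a single line fitted.
#'
#' @param points data.frame with columns \code{conc}, \code{ratio} and
#'   \code{injection} identifying the repeated curves.
#' @inheritParams fitCalibration
#' @return a [Calibration-class].
#' @export
fitCalibrationBatch <- function(points, analyte = "analyte",
                                internal_standard = "IS") {
  stopifnot(all(c("conc", "ratio") %in% colnames(points)))
  avg <- stats::aggregate(ratio ~ conc, data = points, FUN = mean)
  fitCalibration(avg, analyte = analyte, internal_standard = internal_standard)
}

#' Quantify one peak against a calibration curve
#'
#' Inverts the calibration: \code{value = (area/is_area - intercept)/slope}.
#' Values above the calibration range are retained and flagged
#' \code{extrapolated} (linear extrapolation); positive values below the MLOQ
#' are \code{below_mloq}; absent or non-positive responses are
#' \code{nondetect}. Boundaries are inclusive: a value exactly at the range
#' high is \code{quantified}, as is a value exactly at MLOQ.
#'
#' @param area analyte peak area (0 or NA means no integrable peak).
#' @param is_area internal-standard peak area; must be > 0, otherwise the cell
#'   is rejected and set \code{nondetect} with a warning.
#' @param cal a [Calibration-class].
#' @param mloq method limit of quantification (ng/mL).
#' @return list(value, status).
#' @examples
#' cal <- fitCalibration(data.frame(conc = c(0.01, 100), ratio = c(0.005, 50)))
#' quantifyPeak(area = 50, is_area = 1, cal = cal, mloq = 0.05)
#' @export
quantifyPeak <- function(area, is_area, cal, mloq) {
  stopifnot(is(cal, "Calibration"), mloq > 0)
  if (is.na(is_area) || is_area <= 0) {
    warning("internal standard area <= 0; cell set to nondetect")
    return(list(value = 0, status = "nondetect"))
  }
  if (is.na(area) || area <= 0) return(list(value = 0, status = "nondetect"))
  value <- (area / is_area - cal@intercept) / cal@slope
  if (value <= 0) return(list(value = 0, status = "nondetect"))
  status <- if (value > cal@range[2]) "extrapolated"
            else if (value < mloq) "below_mloq"
            else "quantified"
  list(value = value, status = status)
}

#' Quantify a matrix of peak areas
#'
#' Applies [quantifyPeak()] cell-wise with per-analyte calibrations and MLOQs.
#'
#' @param areas analyte x sample peak-area matrix.
#' @param isAreas matching internal-standard areas (matrix or one row per
#'   analyte recycled over samples).
#' @param calibrations named list of [Calibration-class], one per analyte row.
#' @param mloqs named per-analyte MLOQ.
#' @param class per-analyte class labels.
#' @return a [ConcentrationMatrix-class].
#' @export
quantifyMatrix <- function(areas, isAreas, calibrations, mloqs,
                           class = rep("unclassified", nrow(areas))) {
  areas <- as.matrix(areas)
  if (is.vector(isAreas)) isAreas <- matrix(isAreas, nrow(areas), ncol(areas))
  conc <- matrix(0, nrow(areas), ncol(areas), dimnames = dimnames(areas))
  status <- matrix("nondetect", nrow(areas), ncol(areas), dimnames = dimnames(areas))
  for (i in seq_len(nrow(areas))) {
    an <- rownames(areas)[i]
    cal <- calibrations[[an]]
    for (j in seq_len(ncol(areas))) {
      q <- quantifyPeak(areas[i, j], isAreas[i, j], cal, mloqs[[an]])
      conc[i, j] <- q$value; status[i, j] <- q$status
    }
  }
  concentrationMatrix(conc, status, mloqs[rownames(areas)], class)
}

#' @rdname substituteCensored
#' @export
setGeneric("substituteCensored", function(x) standardGeneric("substituteCensored"))

#' Substitute left-censored concentrations
#'
#' Cells flagged \code{below_mloq} are replaced by MLOQ/2
#' (\code{substituted_half_mloq}); \code{nondetect} cells by MLOQ/4
#' (\code{substituted_quarter_mloq}). All other cells are untouched. The
#' operation is idempotent.
#'
#' @param x a [ConcentrationMatrix-class].
#' @return the matrix with censored cells substituted.
#' @export
setMethod("substituteCensored", "ConcentrationMatrix", function(x) {
  conc <- assay(x, "conc"); st <- assay(x, "status")
  ml <- rowData(x)$mloq
  for (i in seq_len(nrow(x))) {
    b <- st[i, ] == "below_mloq"
    n <- st[i, ] == "nondetect"
    conc[i, b] <- ml[i] / 2
    conc[i, n] <- ml[i] / 4
    st[i, b] <- "substituted_half_mloq"
    st[i, n] <- "substituted_quarter_mloq"
  }
  assay(x, "conc") <- conc
  assay(x, "status") <- st
  x
})

# combined status of two isomer cells: quantified wins, then extrapolated,
# then substituted-half, then substituted-quarter
combineStatus <- function(s1, s2) {
  rank <- c(quantified = 1, extrapolated = 2, substituted_half_mloq = 3,
            substituted_quarter_mloq = 4)
  names(rank)[min(rank[s1], rank[s2])]
}

# substitute one cell on the fly so isomer sums can run before or after
# substituteCensored()
substituteCell <- function(value, status, mloq) {
  if (status == "below_mloq") list(value = mloq / 2, status = "substituted_half_mloq")
  else if (status == "nondetect") list(value = mloq / 4, status = "substituted_quarter_mloq")
  else list(value = value, status = status)
}

#' Sum linear and branched isomer rows into a total-concentration row
#'
#' Chromatographically resolved branched and linear isomers of the same PFAS
#' family are quantified separately but summed into total concentrations
#' (e.g. total PFOS) before statistical analysis. Censored cells enter the sum
#' at their substituted value (MLOQ/2 or MLOQ/4), so the sum can run before or
#' after [substituteCensored()]; the combined status is \code{quantified} if
#' either input is quantified.
#'
#' @param x a [ConcentrationMatrix-class].
#' @param linear,branched row names of the two isomer rows.
#' @param name row name of the summed analyte; default \code{"<linear> (total)"}.
#' @param family optional family label; if the two rows' \code{class} labels
#'   differ the pair is rejected as mismatched families.
#' @return the matrix with the two rows replaced by one summed row.
#' @export
sumIsomers <- function(x, linear, branched, name = paste(linear, "(total)"),
                       family = NULL) {
  stopifnot(is(x, "ConcentrationMatrix"))
  if (!all(c(linear, branched) %in% rownames(x)))
    abort("isomer rows not found: ", paste(setdiff(c(linear, branched), rownames(x)),
                                           collapse = ", "))
  rd <- rowData(x)
  if (rd[linear, "class"] != rd[branched, "class"])
    abort("mismatched analyte families: ", rd[linear, "class"], " vs ",
          rd[branched, "class"])
  conc <- assay(x, "conc"); st <- assay(x, "status")
  newConc <- numeric(ncol(x)); newSt <- character(ncol(x))
  for (j in seq_len(ncol(x))) {
    a <- substituteCell(conc[linear, j], st[linear, j], rd[linear, "mloq"])
    b <- substituteCell(conc[branched, j], st[branched, j], rd[branched, "mloq"])
    newConc[j] <- a$value + b$value
    newSt[j] <- combineStatus(a$status, b$status)
  }
  keep <- setdiff(rownames(x), c(linear, branched))
  conc2 <- rbind(conc[keep, , drop = FALSE], matrix(newConc, 1,
                 dimnames = list(name, colnames(conc))))
  st2 <- rbind(st[keep, , drop = FALSE], matrix(newSt, 1,
               dimnames = list(name, colnames(st))))
  # summed row inherits the larger MLOQ of the pair (conservative)
  ml2 <- c(rd[keep, "mloq"], max(rd[linear, "mloq"], rd[branched, "mloq"]))
  cl2 <- c(rd[keep, "class"], rd[linear, "class"])
  concentrationMatrix(conc2, st2, ml2, cl2)
}

#' Detection frequency of targeted analytes
#'
#' Fraction of samples per analyte whose status counts as detected. Under the
#' default \code{"quantified"} reading, detected means quantified or
#' extrapolated (substituted cells are the censored complement); under the
#' \code{"substituted"} reading, detected means any cell not substituted at
#' MLOQ/4 (i.e. at least detected, possibly below MLOQ).
#'
#' @param x a [ConcentrationMatrix-class].
#' @param dfMode "quantified" (default) or "substituted".
#' @return named numeric vector of detection frequencies in \[0, 1\].
#' @export
targetDetectionFrequency <- function(x, dfMode = c("quantified", "substituted")) {
  dfMode <- match.arg(dfMode)
  st <- assay(x, "status")
  detected <- if (dfMode == "quantified")
    st %in% c("quantified", "extrapolated")
  else
    !(st %in% c("substituted_quarter_mloq", "nondetect"))
  m <- matrix(detected, nrow(x), ncol(x))
  setNames(rowMeans(m), rownames(x))
}

#' Apply the targeted detection-frequency filter
#'
#' Analytes are retained when their detection frequency is at or above the
#' threshold (boundary inclusive) or when explicitly forced in (analytes kept
#' due to scientific interest despite falling slightly below the cut-off).
#'
#' @param x a [ConcentrationMatrix-class], substitution already applied.
#' @param threshold detection-frequency cut-off, default 0.60.
#' @param forceInclude analyte names always retained; unknown names warn and
#'   are skipped.
#' @param dfMode see [targetDetectionFrequency()].
#' @return character vector of retained analyte names.
#' @export
selectTargets <- function(x, threshold = 0.60, forceInclude = character(0),
                          dfMode = c("quantified", "substituted")) {
  dfMode <- match.arg(dfMode)
  df <- targetDetectionFrequency(x, dfMode)
  missing <- setdiff(forceInclude, rownames(x))
  if (length(missing)) {
    warning("force-include analytes absent from matrix: ",
            paste(missing, collapse = ", "))
    forceInclude <- intersect(forceInclude, rownames(x))
  }
  keep <- names(df)[df >= threshold]
  union(keep, forceInclude)
}
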