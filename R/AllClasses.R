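#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assay<- rowData<- colData<-
NULL

STATUS_LEVELS <- c("quantified", "extrapolated", "below_mloq", "nondetect",
                   "substituted_half_mloq", "substituted_quarter_mloq")

COLUMN_ROLES <- c("sample", "blank", "qc")

#' ExposomeCohort: a longitudinal plasma-donor cohort
#'
#' Holds one row per participant (reproductive covariates) and one row per
#' blood sample (visit, age at sampling, calendar year, injection batch).
#' Participants give one or two samples; nulliparous participants give exactly
#' one.
#'
#' @slot participants a \code{DataFrame} with columns \code{id},
#'   \code{birth_year}, \code{n_pregnancies}, \code{n_deliveries},
#'   \code{age_menarche}, \code{bmi}, \code{tobacco_ever},
#'   \code{hormonal_contraception_ever}, \code{hrt_ever},
#'   \code{parity_stratum}.
#' @slot samples a \code{DataFrame} with columns \code{participant_id},
#'   \code{visit}, \code{age_at_sampling}, \code{sample_year}, \code{batch}.
#'
#' @seealso [generateCohort()]
#' @export
setClass("ExposomeCohort",
  representation(participants = "DataFrame", samples = "DataFrame"))

setValidity("ExposomeCohort", function(object) {
  p <- object@participants
  s <- object@samples
  needP <- c("id", "birth_year", "n_pregnancies", "n_deliveries",
             "age_menarche", "bmi", "tobacco_ever")
  needS <- c("participant_id", "visit", "age_at_sampling", "sample_year", "batch")
  if (!all(needP %in% colnames(p)))
    return(paste("participants missing columns:",
                 paste(setdiff(needP, colnames(p)), collapse = ", ")))
  if (!all(needS %in% colnames(s)))
    return(paste("samples missing columns:",
                 paste(setdiff(needS, colnames(s)), collapse = ", ")))
  if (nrow(s) > 0 && !all(s$participant_id %in% p$id))
    return("samples reference unknown participant ids")
  if (nrow(s) > 0 && !all(s$visit %in% c(1L, 2L)))
    return("visit must be 1 or 2")
  if (nrow(p) > 0) {
    nv <- table(factor(s$participant_id, levels = p$id))
    nulli <- p$n_pregnancies == 0
    if (any(nv[nulli] != 1L))
      return("nulliparous participants must have exactly one visit")
    if (any(nv < 1L) || any(nv > 2L))
      return("participants must have 1 or 2 visits")
    if (any(p$n_deliveries > p$n_pregnancies))
      return("n_deliveries must not exceed n_pregnancies")
  }
  TRUE
})

#' FeatureTable: an aligned LC-HRMS feature table
#'
#' A \code{SummarizedExperiment} whose single assay \code{"area"} holds peak
#' areas for features (rows) over injection columns (study samples, procedural
#' blanks, pooled QC). Row metadata carries measured ion m/z, retention time,
#' ESI mode and the deconvoluted MS2 spectrum; column metadata carries the
#' column role and injection batch. The provenance log of feature removals
#' lives in \code{metadata(x)$provenance}.
#'
#' @seealso [featureTable()], [maxBlankRatioFilter()], [mergeEsiModes()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"area" %in% SummarizedExperiment::assayNames(object))
    return("assay 'area' is required")
  rd <- rowData(object)
  need <- c("mz", "rt", "mode", "ms2")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData missing:", paste(setdiff(need, colnames(rd)), collapse = ", ")))
  cd <- colData(object)
  if (!all(c("role", "batch") %in% colnames(cd)))
    return("colData must have 'role' and 'batch'")
  if (nrow(object) > 0) {
    if (any(rd$mz <= 0)) return("mz must be > 0")
    if (any(rd$rt < 0)) return("rt must be >= 0")
    if (!all(rd$mode %in% c("pos", "neg"))) return("mode must be 'pos' or 'neg'")
    a <- assay(object, "area")
    if (any(a < 0, na.rm = TRUE)) return("areas must be >= 0")
  }
  if (ncol(object) > 0 && !all(cd$role %in% COLUMN_ROLES))
    return("column roles must be sample/blank/qc")
  TRUE
})

#' ConcentrationMatrix: targeted analyte concentrations with censoring status
#'
#' A \code{SummarizedExperiment} with assays \code{"conc"} (ng/mL) and
#' \code{"status"} (one of quantified, extrapolated, below_mloq, nondetect,
#' substituted_half_mloq, substituted_quarter_mloq) over analytes (rows) and
#' samples (columns). Row metadata carries the per-analyte MLOQ and chemical
#' class.
#'
#' @seealso [concentrationMatrix()], [substituteCensored()], [selectTargets()]
#' @export
setClass("ConcentrationMatrix", contains = "SummarizedExperiment")

setValidity("ConcentrationMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("conc", "status") %in% an))
    return("assays 'conc' and 'status' are required")
  rd <- rowData(object)
  if (!all(c("mloq", "class") %in% colnames(rd)))
    return("rowData must have 'mloq' and 'class'")
  if (nrow(object) > 0) {
    if (any(rd$mloq <= 0)) return("mloq must be > 0")
    st <- assay(object, "status")
    if (!all(st %in% STATUS_LEVELS))
      return(paste("invalid status values:",
                   paste(unique(st[!st %in% STATUS_LEVELS]), collapse = ", ")))
  }
  TRUE
})

#' Calibration: a fitted targeted calibration curve
#'
#' Ordinary least-squares line through (nominal concentration, response ratio)
#' points; the calibration range is the span of nominal concentrations.
#'
#' @slot analyte analyte name.
#' @slot internal_standard name of the isotope-labeled internal standard.
#' @slot points data.frame of \code{conc} (ng/mL) and \code{ratio}.
#' @slot slope,intercept fitted linear parameters (ratio = intercept + slope * conc).
#' @slot range numeric length-2, (low, high) ng/mL.
#' @seealso [fitCalibration()], [quantifyPeak()]
#' @export
setClass("Calibration",
  representation(analyte = "character", internal_standard = "character",
                 points = "data.frame", slope = "numeric",
                 intercept = "numeric", range = "numeric"))

setValidity("Calibration", function(object) {
  if (length(unique(object@points$conc)) < 2)
    return("calibration needs >= 2 distinct concentrations")
  if (length(object@range) != 2 || object@range[1] > object@range[2])
    return("range must be (low, high)")
  if (!is.finite(object@slope) || object@slope <= 0)
    return("slope must be finite and > 0")
  TRUE
})

setMethod("show", "ExposomeCohort", function(object) {
  p <- object@participants; s <- object@samples
  cat("ExposomeCohort with", nrow(p), "participants and", nrow(s), "samples\n")
  if (nrow(p) > 0) {
    tab <- table(cut(p$n_pregnancies, c(-Inf, 0, 2, 4, Inf),
                     labels = c("0", "1-2", "3-4", ">4")))
    cat("  pregnancies strata:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    nv <- table(table(s$participant_id))
    cat("  repeat donors:", sum(table(s$participant_id) == 2L), "\n")
    cat("  sample years:", paste(range(s$sample_year), collapse = "-"), "\n")
  }
  invisible(object)
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration for %s (IS %s): ratio = %.4g + %.4g * conc, range %.3g-%.3g ng/mL\n",
              object@analyte, object@internal_standard, object@intercept,
              object@slope, object@range[1], object@range[2]))
  invisible(object)
})

#' @describeIn ExposomeCohort-class accessor for the participant table
#' @param x an \code{ExposomeCohort}.
#' @export
participants <- function(x) {
  stopifnot(is(x, "ExposomeCohort"))
  x@participants
}

#' @describeIn ExposomeCohort-class accessor for the sample table
#' @export
cohortSamples <- function(x) {
  stopifnot(is(x, "ExposomeCohort"))
  x@samples
}

#' Column roles of a FeatureTable or ConcentrationMatrix
#'
#' @param x a \code{FeatureTable}.
#' @return character vector of roles ("sample", "blank", "qc"), one per column.
#' @export
columnRoles <- function(x) as.character(colData(x)$role)

sampleColumns <- function(x) which(columnRoles(x) == "sample")
blankColumns <- function(x) which(columnRoles(x) == "blank")
qcColumns <- function(x) which(columnRoles(x) == "qc")

#' Provenance log of feature removals
#'
#' Every cleaning stage appends one row per removed feature (stage name,
#' feature id, reason) to the provenance log, so feature counts can be
#' reconciled gate by gate.
#'
#' @param x a \code{FeatureTable}.
#' @return a data.frame with columns \code{stage}, \code{feature_id},
#'   \code{reason}.
#' @export
provenance <- function(x) {
  pv <- metadata(x)$provenance
  if (is.null(pv))
    pv <- data.frame(stage = character(0), feature_id = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  pv
}

appendProvenance <- function(x, stage, ids, reason) {
  if (length(ids) == 0L) return(x)
  pv <- rbind(provenance(x),
              data.frame(stage = stage, feature_id = ids, reason = reason,
                         stringsAsFactors = FALSE))
  metadata(x)$provenance <- pv
  x
}

#' Construct a FeatureTable
#'
#' @param areas numeric matrix of peak areas (features x columns); rownames
#'   are feature ids, colnames are injection names.
#' @param mz,rt numeric per-feature ion m/z (Da) and retention time (min).
#' @param mode "pos" or "neg", recycled over features.
#' @param ms2 character vector of packed spectra ("mz:intensity ..."),
#'   recycled; see [formatSpectrum()].
#' @param role per-column role: "sample", "blank" or "qc".
#' @param batch per-column injection batch (integer).
#' @return a \code{FeatureTable}.
#' @examples
#' a <- matrix(c(1e6, 2e6, 1e4, 2e4), 2, 2,
#'             dimnames = list(c("F1", "F2"), c("S1", "B1")))
#' ft <- featureTable(a, mz = c(195.0877, 300.1), rt = c(5, 6), mode = "pos",
#'                    ms2 = "", role = c("sample", "blank"), batch = 1L)
#' @export
featureTable <- function(areas, mz, rt, mode = "pos", ms2 = "",
                         role = "sample", batch = 1L) {
  areas <- as.matrix(areas)
  n <- nrow(areas)
  if (is.null(rownames(areas))) rownames(areas) <- sprintf("F%04d", seq_len(n))
  if (is.null(colnames(areas))) colnames(areas) <- sprintf("C%03d", seq_len(ncol(areas)))
  rd <- DataFrame(mz = as.numeric(mz), rt = as.numeric(rt),
                  mode = rep_len(as.character(mode), n),
                  ms2 = rep_len(as.character(ms2), n),
                  row.names = rownames(areas))
  cd <- DataFrame(role = rep_len(as.character(role), ncol(areas)),
                  batch = rep_len(as.integer(batch), ncol(areas)),
                  row.names = colnames(areas))
  new("FeatureTable",
      SummarizedExperiment(assays = list(area = areas), rowData = rd, colData = cd))
}

#' Construct a ConcentrationMatrix
#'
#' @param conc numeric matrix (analytes x samples), ng/mL.
#' @param status character matrix of censoring statuses, same shape.
#' @param mloq per-analyte MLOQ (ng/mL).
#' @param class per-analyte chemical class label.
#' @return a \code{ConcentrationMatrix}.
#' @export
concentrationMatrix <- function(conc, status, mloq,
                                class = rep("unclassified", nrow(conc))) {
  conc <- as.matrix(conc)
  status <- matrix(as.character(status), nrow(conc), ncol(conc),
                   dimnames = dimnames(conc))
  if (is.null(rownames(conc))) rownames(conc) <- sprintf("A%02d", seq_len(nrow(conc)))
  rd <- DataFrame(mloq = as.numeric(mloq),
                  class = rep_len(as.character(class), nrow(conc)),
                  row.names = rownames(conc))
  new("ConcentrationMatrix",
      SummarizedExperiment(assays = list(conc = conc, status = status), rowData = rd))
}

#' Per-analyte MLOQ accessor
#' @param x a \code{ConcentrationMatrix}.
#' @export
mloq <- function(x) {
  stopifnot(is(x, "ConcentrationMatrix"))
  setNames(rowData(x)$mloq, rownames(x))
}
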