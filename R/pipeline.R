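#' Default pipeline configuration
#'
#' All constants default to the validated method's printed values: blank-ratio
#' factor 5, blank pseudo-count 0.1, area floor 90000, ESI-merge tolerances
#' 0.2 min / 0.002 Da, dedup gates r > 0.95 / p < 0.001 / 0.1 min, feature DF
#' threshold 70%, target DF threshold 60%, annotation thresholds total > 700
#' and dot/revdot > 600, alpha 0.05 and literature threshold 0.005. The
#' cohort block encodes the emulated study design (26/23/27/24 parity strata,
#' 0/22/21/18 second samples, sampling years 1987-2006, 5 injection batches).
#'
#' @param seed master seed; stage seeds are derived with [childSeed()].
#' @param ... overrides for any top-level config entry.
#' @return a config list, serializable losslessly via [writeConfig()].
#' @export
pipelineConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(nWomen = 100L, strataCounts = c(26L, 23L, 27L, 24L),
                  secondSampleCounts = c(0L, 22L, 21L, 18L), nBatches = 5L),
    targets = list(dfThreshold = 0.60,
                   forceInclude = c("Cotinine", "Progesterone"),
                   dfMode = "quantified"),
    features = list(nFeatures = c(pos = 300L, neg = 200L),
                    blankFactor = 5, pseudo = 0.1, floor = 90000,
                    rtTolMerge = 0.2, mzTol = 0.002, nComponents = 2L,
                    rThreshold = 0.95, pThreshold = 0.001, rtTolDedup = 0.1,
                    dfThreshold = 0.70),
    annotation = list(binTol = 0.01, rtTol = 0.2, librarySize = 40L),
    associations = list(alpha = 0.05, literatureThreshold = 0.005,
                        pMethod = "wald", parousBy = "n_pregnancies"),
    outputDir = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round-trip; numeric vectors and nested blocks survive unchanged.
#'
#' @param config a [pipelineConfig()] list.
#' @param path file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("strataCounts", "secondSampleCounts"))
    cfg$cohort[[nm]] <- as.integer(unlist(cfg$cohort[[nm]]))
  nf <- unlist(cfg$features$nFeatures)
  if (is.null(names(nf)) && length(nf) == 2L) names(nf) <- c("pos", "neg")
  cfg$features$nFeatures <- nf
  cfg
}

# default targeted panel: the 20 retained analytes with plausible log-scale
# baselines, planted covariate effects (positive age trends for most PFAS,
# negative parity trends) and MLOQs
defaultTargetPanel <- function() {
  analytes <- c("Corticosterone", "Hydrocortisone", "Progesterone",
                "Testosterone", "Pentachlorophenol", "Caffeine", "Cotinine",
                "TCPy", "PFHpA", "NMeFOSAA", "PFHxS", "PFOA", "PFHpS",
                "PFOS", "NEtFOSAA", "FOSAA", "FOSA", "PFUnDA", "PFNA", "PFDA")
  classes <- c("steroid hormone", "steroid hormone", "steroid hormone",
               "steroid hormone", "fungicide", "food", "tobacco",
               "insecticide", rep("PFAS", 5), "PFAS", "PFAS", "PFAS", "PFAS",
               "PFAS", "PFAS", "PFAS")
  base <- log(c(6, 145, 2.5, 0.17, 1.7, 180, 20, 0.3, 0.05, 0.4, 0.7, 1.9,
                0.22, 14, 1.1, 0.9, 0.4, 0.19, 0.45, 0.17))
  isPfas <- classes == "PFAS"
  eff <- effectSpec(analytes, baseline = base, sdSubject = 0.35, sdResid = 0.3,
                    age = ifelse(isPfas, 0.02, ifelse(analytes == "Caffeine", 0.02, 0)),
                    n_pregnancies = ifelse(isPfas, -0.08, 0))
  mloqs <- setNames(c(0.1, 1, 0.05, 0.02, 0.1, 1, 0.1, 0.05, 0.02, 0.05,
                      0.02, 0.05, 0.02, 0.1, 0.05, 0.05, 0.02, 0.02, 0.02, 0.02),
                    analytes)
  # age enters on the log scale; recenter baselines so mean levels stay at the
  # panel's typical concentrations for a woman of ~43
  eff$baseline <- eff$baseline - eff$age * 43 - eff$n_pregnancies * 2.4
  list(effects = eff, mloqs = mloqs, classes = setNames(classes, analytes))
}

# build a small spectral library from a cleaned table's own spectra plus
# decoys, so a known fraction of features annotate at Level 1/2
syntheticLibrary <- function(x, n = 40L, seed = 1L) {
  set.seed(as.integer(seed))
  n <- min(n, nrow(x))
  if (n == 0L)
    return(libraryEntry("decoy", 100, formatSpectrum(c(60, 80), c(100, 100)))[0, ])
  idx <- sample.int(nrow(x), n)
  rd <- rowData(x)
  classes <- sample(c("environmental", "endogenous"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
  sub <- ifelse(classes == "environmental",
                sample(c("PFAS", "pesticides", "industrial"), n, replace = TRUE),
                sample(c("bile acids", "fatty acids", "hormones"), n, replace = TRUE))
  entries <- lapply(seq_len(n), function(k) {
    i <- idx[k]
    withRT <- stats::runif(1) < 0.15   # in-house standards carry RT
    libraryEntry(sprintf("compound_%s", rownames(x)[i]), rd$mz[i], rd$ms2[i],
                 rt = if (withRT) rd$rt[i] else NA_real_,
                 class_meta = classes[k], subclass = sub[k],
                 source = if (withRT) "in-house" else "public")
  })
  do.call(rbind, entries)
}

#' Run the full synthetic exposomics pipeline
#'
#' Stage order is fixed: cohort generation, targeted truth + censoring
#' substitution + target selection, untargeted table generation + cleaning,
#' spectral-library annotation, association models with tiered multiplicity.
#' Identical configs produce identical outputs (all stage seeds derive from
#' the master seed).
#'
#' @param config a [pipelineConfig()].
#' @return a list of stage outputs plus a run \code{manifest} recording seeds,
#'   per-stage feature counts and wall-clock seconds per stage.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  t0 <- proc.time()[["elapsed"]]
  stageTimes <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stageTimes[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  cohort <- generateCohort(nWomen = config$cohort$nWomen,
                           strataCounts = config$cohort$strataCounts,
                           secondSampleCounts = config$cohort$secondSampleCounts,
                           seed = childSeed(config$seed, 0),
                           nBatches = config$cohort$nBatches)
  md <- buildModelData(cohort)
  tick("cohort")

  panel <- defaultTargetPanel()
  tt <- generateTargetTruth(cohort, panel$effects, panel$mloqs,
                            seed = childSeed(config$seed, 1))
  cm <- tt$matrix
  rowData(cm)$class <- panel$classes[rownames(cm)]
  cm <- substituteCensored(cm)
  retained <- selectTargets(cm, threshold = config$targets$dfThreshold,
                            forceInclude = config$targets$forceInclude,
                            dfMode = config$targets$dfMode)
  cmKept <- cm[retained, ]
  tick("target_quant")

  un <- generateUntargetedTables(cohort, nFeatures = config$features$nFeatures,
                                 seed = childSeed(config$seed, 2))
  cleaned <- cleanFeatures(un$pos, un$neg, un$isMatrix,
                           blankFactor = config$features$blankFactor,
                           floor = config$features$floor,
                           pseudo = config$features$pseudo,
                           rtTolMerge = config$features$rtTolMerge,
                           mzTol = config$features$mzTol,
                           nComponents = config$features$nComponents,
                           rThreshold = config$features$rThreshold,
                           pThreshold = config$features$pThreshold,
                           rtTolDedup = config$features$rtTolDedup,
                           dfThreshold = config$features$dfThreshold)
  tick("feature_processing")

  lib <- syntheticLibrary(cleaned, n = config$annotation$librarySize,
                          seed = childSeed(config$seed, 3))
  annot <- annotateFeatures(cleaned, lib, binTol = config$annotation$binTol,
                            rtTol = config$annotation$rtTol)
  annSum <- annotationSummary(annot, n_total = nrow(cleaned))
  tick("annotation")

  concT <- transformSqrt(assay(cmKept, "conc"))
  groups <- defaultPfasGroups()
  groups <- lapply(groups, function(g) intersect(g, rownames(concT)))
  groups <- groups[vapply(groups, length, 1L) >= 2]
  groupScores <- if (length(groups)) groupAndSum(concT, groups) else
    matrix(numeric(0), 0, ncol(concT))
  featT <- transformSqrt(assay(cleaned, "area"))
  outcomes <- rbind(concT, groupScores,
                    featT[, colnames(concT), drop = FALSE])
  mdAligned <- md[colnames(outcomes), , drop = FALSE]
  assoc <- associationTable(outcomes, mdAligned,
                            pMethod = config$associations$pMethod,
                            alpha = config$associations$alpha,
                            literatureThreshold = config$associations$literatureThreshold)
  corr <- correlationStructure(assay(cmKept, "conc"),
                               mdAligned[, c("age", "n_pregnancies",
                                             "n_deliveries", "age_menarche")],
                               classes = rowData(cmKept)$class)
  tick("associations")

  funnel <- metadata(cleaned)$funnel
  manifest <- list(
    seed = config$seed,
    stage_seeds = vapply(0:3, function(k) childSeed(config$seed, k), 1L),
    n_participants = nrow(participants(cohort)),
    n_samples = nrow(cohortSamples(cohort)),
    n_targets_panel = nrow(cm),
    n_targets_retained = length(retained),
    funnel = funnel,
    n_annotated = annSum$n_annotated,
    n_models = nrow(assoc),
    bonferroni_threshold = attr(assoc, "bonferroni_threshold"),
    stage_seconds = stageTimes)

  out <- list(cohort = cohort, modelData = md, concentrations = cm,
              retainedTargets = retained, cleanedFeatures = cleaned,
              library = lib, annotations = annot,
              annotationSummary = annSum, groupScores = groupScores,
              associations = assoc, correlations = corr,
              truth = list(target = tt$truth, untargeted = un$truth),
              manifest = manifest)

  if (!is.null(config$outputDir)) exportReport(out, config$outputDir)
  out
}

#' Export pipeline summary tables
#'
#' Writes (and returns) the funnel table of feature counts at each cleaning
#' gate, the association table (outcome, exposure, coefficient, p, tier
#' flags), the group-level association table, a volcano-plot table (coef,
#' -log10 p, tiers) and a circle-diagram edge list (exposure, outcome, sign,
#' significance). Re-export is idempotent.
#'
#' @param outputs result list from [runPipeline()].
#' @param dir optional directory to write tab-separated files into.
#' @return a list of data.frames.
#' @export
exportReport <- function(outputs, dir = NULL) {
  funnel <- outputs$manifest$funnel
  funnel$n_removed <- c(0, -diff(funnel$n_features))
  assoc <- outputs$associations
  groupTab <- assoc[assoc$outcome %in% rownames(outputs$groupScores), ,
                    drop = FALSE]
  volcano <- data.frame(outcome = assoc$outcome, exposure = assoc$exposure,
                        coef = assoc$beta, neg_log10_p = -log10(assoc$p),
                        sig_alpha = assoc$sig_alpha,
                        sig_literature = assoc$sig_literature,
                        sig_bonferroni = assoc$sig_bonferroni)
  edges <- data.frame(exposure = assoc$exposure, outcome = assoc$outcome,
                      sign = sign(assoc$beta),
                      significant = assoc$sig_alpha)
  rep <- list(funnel = funnel, associations = assoc, groups = groupTab,
              volcano = volcano, edges = edges)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(rep))
      utils::write.table(rep[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}
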