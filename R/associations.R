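#' Square-root transform for left-skewed chemical levels
#'
#' Concentrations and peak areas are raised to the power 1/2 before modeling
#' to tame left-skewed (long right tail) distributions and approximate
#' normality.
#'
#' @param values non-negative numeric vector or matrix.
#' @return the elementwise square root.
#' @export
transformSqrt <- function(values) {
  if (any(values < 0, na.rm = TRUE)) abort("negative values cannot be sqrt-transformed")
  sqrt(values)
}

#' Default adjustment set per reproductive risk factor
#'
#' Confounder sets used by the association models: age models adjust for BMI,
#' number of pregnancies, sample year, age at menarche and tobacco use; parity
#' models (pregnancies or deliveries) for age, birth year, age at menarche and
#' tobacco use; age-at-menarche models for age, BMI and birth year.
#'
#' @param exposure one of "age", "n_pregnancies", "n_deliveries",
#'   "age_menarche".
#' @return character vector of covariate names.
#' @export
defaultAdjustment <- function(exposure) {
  switch(exposure,
    age = c("bmi", "n_pregnancies", "sample_year", "age_menarche", "tobacco"),
    n_pregnancies = c("age", "birth_year", "age_menarche", "tobacco"),
    n_deliveries = c("age", "birth_year", "age_menarche", "tobacco"),
    age_menarche = c("age", "bmi", "birth_year"),
    abort("unknown exposure: ", exposure))
}

#' Correlation structure of chemicals and risk factors
#'
#' Spearman correlations (with p-values) between raw chemical levels and the
#' reproductive risk factors, and Pearson correlations between transformed
#' levels within each chemical class (used to group co-varying chemicals).
#' Pairwise-complete observations; cells with a constant column are flagged
#' \code{NA}.
#'
#' @param values analyte x sample matrix of raw levels.
#' @param riskFactors sample x factor data.frame (numeric columns).
#' @param classes optional per-analyte class labels for the within-class
#'   Pearson block.
#' @return list: \code{spearman}, \code{spearman_p} (analyte x factor),
#'   \code{pearson} (named list per class of transformed-value correlation
#'   matrices).
#' @export
correlationStructure <- function(values, riskFactors, classes = NULL) {
  values <- as.matrix(values)
  rf <- as.matrix(riskFactors)
  nA <- nrow(values); nF <- ncol(rf)
  sp <- matrix(NA_real_, nA, nF, dimnames = list(rownames(values), colnames(rf)))
  spP <- sp
  for (i in seq_len(nA)) for (j in seq_len(nF)) {
    xi <- values[i, ]; yj <- rf[, j]
    ok <- is.finite(xi) & is.finite(yj)
    if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(yj[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(xi[ok], yj[ok], method = "spearman",
                                           exact = FALSE))
    sp[i, j] <- unname(ct$estimate); spP[i, j] <- ct$p.value
  }
  pearson <- list()
  if (!is.null(classes)) {
    tv <- transformSqrt(values)
    for (cl in unique(classes)) {
      rows <- which(classes == cl)
      if (length(rows) >= 2)
        pearson[[cl]] <- stats::cor(t(tv[rows, , drop = FALSE]),
                                    use = "pairwise.complete.obs")
    }
  }
  list(spearman = sp, spearman_p = spP, pearson = pearson)
}

#' Default PFAS co-exposure groups
#'
#' Three groups of highly correlated PFAS summed into co-exposure scores:
#' Group 1 (PFDA, PFNA, PFUnDA), Group 2 (FOSA, FOSAA, NEtFOSAA), Group 3
#' (PFOS, PFHpS, PFOA, PFHxS).
#'
#' @return named list of member vectors.
#' @export
defaultPfasGroups <- function() {
  list(`Group 1` = c("PFDA", "PFNA", "PFUnDA"),
       `Group 2` = c("FOSA", "FOSAA", "NEtFOSAA"),
       `Group 3` = c("PFOS", "PFHpS", "PFOA", "PFHxS"))
}

#' Sum transformed member chemicals into group scores
#'
#' Per sample, each group's score is the sum of the square-root-transformed
#' member values. Members are also retained individually downstream.
#'
#' @param transformed analyte x sample matrix of transformed values.
#' @param groups named list of member vectors, default [defaultPfasGroups()].
#' @return group x sample matrix of scores.
#' @export
groupAndSum <- function(transformed, groups = defaultPfasGroups()) {
  transformed <- as.matrix(transformed)
  if (length(groups) == 0) abort("no groups declared")
  out <- matrix(NA_real_, length(groups), ncol(transformed),
                dimnames = list(names(groups), colnames(transformed)))
  for (g in seq_along(groups)) {
    members <- groups[[g]]
    if (length(members) == 0) abort("empty member list for ", names(groups)[g])
    missing <- setdiff(members, rownames(transformed))
    if (length(missing))
      abort("group member(s) missing from matrix: ", paste(missing, collapse = ", "))
    out[g, ] <- colSums(transformed[members, , drop = FALSE])
  }
  out
}

#' Fit a subject-random-intercept linear mixed model
#'
#' REML fit of \code{outcome ~ exposure + covariates + (1 | subject)} on
#' complete cases, reporting the exposure coefficient with its standard error
#' and p-value (Wald normal approximation by default; Satterthwaite degrees of
#' freedom via lmerTest optionally). With fewer than 2 subjects contributing
#' repeated measures the model degenerates to OLS with a warning. A singular
#' (rank-deficient) fixed-effect design is flagged as non-converged.
#'
#' @param outcome numeric outcome vector (already transformed), aligned with
#'   \code{data} rows.
#' @param exposure exposure column name in \code{data}.
#' @param data per-sample covariate data.frame from [buildModelData()].
#' @param covariates adjustment set; default [defaultAdjustment()] for the
#'   exposure.
#' @param subject grouping column, default \code{"participant_id"}.
#' @param pMethod "wald" (normal approximation) or "satterthwaite".
#' @param interaction optional second column name; adds
#'   \code{exposure * interaction} and reports the product term instead.
#' @param outcomeLabel label carried into the result row.
#' @return one-row data.frame: outcome label, exposure, beta, se, p, df
#'   (NA for Wald), n_samples, n_subjects, converged.
#' @export
fitLMM <- function(outcome, exposure, data, covariates = defaultAdjustment(exposure),
                   subject = "participant_id", pMethod = c("wald", "satterthwaite"),
                   interaction = NULL, outcomeLabel = "outcome") {
  pMethod <- match.arg(pMethod)
  if (exposure %in% covariates)
    abort("exposure must not be duplicated in covariates")
  vars <- unique(c(exposure, covariates, interaction))
  df <- data.frame(.y = outcome, data[, c(vars, subject), drop = FALSE])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  term <- exposure
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  if (!is.null(interaction)) {
    rhs <- paste(rhs, sprintf("%s:%s", exposure, interaction), sep = " + ")
    if (!interaction %in% c(exposure, covariates))
      rhs <- paste(rhs, interaction, sep = " + ")
    term <- sprintf("%s:%s", exposure, interaction)
  }
  nSubj <- length(unique(df[[subject]]))
  nRep <- sum(table(df[[subject]]) > 1)
  res <- data.frame(outcome = outcomeLabel, exposure = term, beta = NA_real_,
                    se = NA_real_, p = NA_real_, df = NA_real_,
                    n_samples = nrow(df), n_subjects = nSubj,
                    converged = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(res)

  # rank check on the fixed-effect design: collinear exposures are flagged,
  # not silently dropped
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
  if (qr(X)$rank < ncol(X)) return(res)

  if (nRep < 2) {
    warning("fewer than 2 subjects with repeated measures; fitting OLS")
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
    sm <- summary(fit)$coefficients
    row <- match(term, rownames(sm))
    if (is.na(row)) return(res)
    res$beta <- sm[row, 1]; res$se <- sm[row, 2]; res$p <- sm[row, 4]
    res$converged <- TRUE
    return(res)
  }

  fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 |", subject, ")"))
  fit <- tryCatch(
    if (pMethod == "satterthwaite")
      lmerTest::lmer(fml, data = df, REML = TRUE)
    else
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(res)
  sm <- stats::coef(summary(fit))
  row <- match(term, rownames(sm))
  if (is.na(row)) return(res)
  res$beta <- sm[row, "Estimate"]
  res$se <- sm[row, "Std. Error"]
  if (pMethod == "satterthwaite") {
    res$df <- sm[row, "df"]
    res$p <- sm[row, "Pr(>|t|)"]
  } else {
    z <- res$beta / res$se
    res$p <- 2 * stats::pnorm(-abs(z))
  }
  res$converged <- TRUE
  res
}

#' Age-by-pregnancies interaction model
#'
#' Fits the age model with an added age x number-of-pregnancies product term
#' (both main effects included) and reports the product term.
#'
#' @inheritParams fitLMM
#' @return one-row data.frame as [fitLMM()].
#' @export
interactionAgePregnancies <- function(outcome, data, pMethod = "wald",
                                      outcomeLabel = "outcome") {
  fitLMM(outcome, "age", data,
         covariates = defaultAdjustment("age"),
         interaction = "n_pregnancies", pMethod = pMethod,
         outcomeLabel = outcomeLabel)
}

#' Parous-only sensitivity analysis
#'
#' Refits the model after excluding nulliparous women (by reported
#' pregnancies by default; deliveries optionally), to check that the age
#' associations keep their direction without the older nulliparous stratum.
#'
#' @inheritParams fitLMM
#' @param by "n_pregnancies" (default) or "n_deliveries": parity measure used
#'   for the subset (>= 1).
#' @return one-row data.frame as [fitLMM()].
#' @export
sensitivityParousOnly <- function(outcome, exposure, data,
                                  covariates = defaultAdjustment(exposure),
                                  by = c("n_pregnancies", "n_deliveries"),
                                  pMethod = "wald", outcomeLabel = "outcome") {
  by <- match.arg(by)
  keep <- !is.na(data[[by]]) & data[[by]] >= 1
  if (!any(keep)) abort("no parous samples in data")
  fitLMM(outcome[keep], exposure, data[keep, , drop = FALSE],
         covariates = covariates, pMethod = pMethod,
         outcomeLabel = outcomeLabel)
}

#' Tiered multiple-testing decisions
#'
#' Flags each p-value at three nested tiers: the nominal alpha (used alone for
#' targeted-analyte analyses), the literature threshold of 0.005, and the
#' Bonferroni cut-off alpha / n_tests. The tiers are nested whenever
#' \code{n_tests >= 10}.
#'
#' @param p numeric p-values.
#' @param alpha nominal significance level, default 0.05.
#' @param literatureThreshold stringent fixed threshold, default 0.005.
#' @param nTests number of tests for the Bonferroni cut-off; default
#'   \code{length(p)}.
#' @return list: \code{alpha}, \code{n_tests}, \code{threshold_literature},
#'   \code{bonferroni_threshold}, and \code{flags} data.frame with logical
#'   columns \code{sig_alpha}, \code{sig_literature}, \code{sig_bonferroni}.
#' @examples
#' adjustMultiplicity(c(0.004, 0.2), nTests = 16758)$bonferroni_threshold
#' @export
adjustMultiplicity <- function(p, alpha = 0.05, literatureThreshold = 0.005,
                               nTests = length(p)) {
  if (nTests < 1) abort("need at least one test")
  bon <- alpha / nTests
  flags <- data.frame(p = p,
                      sig_alpha = p < alpha,
                      sig_literature = p < literatureThreshold,
                      sig_bonferroni = p < bon)
  list(alpha = alpha, n_tests = nTests,
       threshold_literature = literatureThreshold,
       bonferroni_threshold = bon, flags = flags)
}

#' Run the association stage over a set of outcomes
#'
#' Fits one mixed model per (outcome, exposure) pair over the four
#' reproductive risk factors and attaches tiered multiplicity flags.
#'
#' @param outcomes outcome x sample matrix of transformed values.
#' @param data per-sample covariates from [buildModelData()] (rows aligned
#'   with the outcome columns).
#' @param exposures exposures to test.
#' @param pMethod see [fitLMM()].
#' @param alpha,literatureThreshold see [adjustMultiplicity()].
#' @return data.frame of model results with multiplicity flag columns; the
#'   Bonferroni threshold (computed over converged tests only — non-converged
#'   fits are excluded from the multiplicity count) is attached as attribute
#'   \code{"bonferroni_threshold"}.
#' @export
associationTable <- function(outcomes, data,
                             exposures = c("age", "n_pregnancies",
                                           "n_deliveries", "age_menarche"),
                             pMethod = "wald", alpha = 0.05,
                             literatureThreshold = 0.005) {
  outcomes <- as.matrix(outcomes)
  rows <- list()
  for (i in seq_len(nrow(outcomes))) {
    for (ex in exposures) {
      rows[[length(rows) + 1L]] <-
        fitLMM(outcomes[i, ], ex, data, pMethod = pMethod,
               outcomeLabel = rownames(outcomes)[i])
    }
  }
  tab <- do.call(rbind, rows)
  conv <- which(tab$converged)
  mult <- adjustMultiplicity(tab$p[conv], alpha = alpha,
                             literatureThreshold = literatureThreshold,
                             nTests = length(conv))
  tab$sig_alpha <- tab$sig_literature <- tab$sig_bonferroni <- NA
  tab$sig_alpha[conv] <- mult$flags$sig_alpha
  tab$sig_literature[conv] <- mult$flags$sig_literature
  tab$sig_bonferroni[conv] <- mult$flags$sig_bonferroni
  attr(tab, "bonferroni_threshold") <- mult$bonferroni_threshold
  tab
}
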