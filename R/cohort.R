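#' Default stratum parameters for the cohort generator
#'
#' Per parity stratum (no pregnancy, 1-2, 3-4, >4 pregnancies): means/SDs of
#' age at first and second sampling, calendar range of the first sample,
#' menarche and BMI distributions, tobacco prevalence, hormone-use
#' prevalences and the count of missing menarche entries. Values default to
#' the summary statistics of the emulated mammography-screening cohort; all
#' are overridable.
#'
#' @return a list of per-stratum parameter lists.
#' @export
defaultCohortParams <- function() {
  list(
    list(label = "nullipara", pregRange = c(0L, 0L),
         ageFirstMean = 58.28, ageFirstSD = 6.48,
         ageSecondMean = NA, ageSecondSD = NA,
         firstYearRange = c(1995L, 2006L),
         menarcheMean = 13.45, menarcheSD = 1.31, menarcheMissing = 1L,
         bmiMean = 25.36, bmiSD = 4.03, tobaccoP = 0.154,
         hcP = 0.423, hrtP = 0.154),
    list(label = "1-2 pregnancies", pregRange = c(1L, 2L),
         ageFirstMean = 34.77, ageFirstSD = 5.33,
         ageSecondMean = 43.58, ageSecondSD = 4.13,
         firstYearRange = c(1987L, 2005L),
         menarcheMean = 12.56, menarcheSD = 1.07, menarcheMissing = 0L,
         bmiMean = 23.07, bmiSD = 2.91, tobaccoP = 0.522,
         hcP = 0.957, hrtP = 0.130),
    list(label = "3-4 pregnancies", pregRange = c(3L, 4L),
         ageFirstMean = 39.99, ageFirstSD = 4.72,
         ageSecondMean = 46.35, ageSecondSD = 3.98,
         firstYearRange = c(1988L, 2006L),
         menarcheMean = 13.04, menarcheSD = 1.48, menarcheMissing = 0L,
         bmiMean = 25.02, bmiSD = 5.38, tobaccoP = 0.407,
         hcP = 0.778, hrtP = 0.074),
    list(label = ">4 pregnancies", pregRange = c(5L, 8L),
         ageFirstMean = 40.36, ageFirstSD = 3.09,
         ageSecondMean = 47.16, ageSecondSD = 4.83,
         firstYearRange = c(1988L, 2002L),
         menarcheMean = 12.92, menarcheSD = 1.33, menarcheMissing = 0L,
         bmiMean = 24.59, bmiSD = 3.75, tobaccoP = 0.458,
         hcP = 0.875, hrtP = 0.125)
  )
}

# deliveries given pregnancies, per stratum: nullipara 0; 1-2 stratum keeps
# deliveries = pregnancies; higher strata allow early terminations so
# deliveries can fall below pregnancies but never exceed them.
drawDeliveries <- function(nPreg, stratum) {
  if (nPreg == 0L) return(0L)
  if (stratum == 2L) return(nPreg)
  loss <- stats::rbinom(1L, nPreg, 0.15)
  max(0L, nPreg - loss)
}

#' Generate a synthetic longitudinal plasma cohort
#'
#' Draws women in four parity strata (no pregnancy, 1-2, 3-4, >4 pregnancies)
#' with stratum-specific ages, sampling years, reproductive covariates and
#' repeated-visit structure, then partitions the resulting blood samples into
#' five injection batches. Nulliparous women give exactly one sample; a stated
#' count of parous women per stratum gives a second sample up to 16 years
#' after the first. Parous women have their first sample within 2 years of
#' their last pregnancy.
#'
#' @param nWomen total number of women; must equal \code{sum(strataCounts)}.
#' @param strataCounts integer length-4: women per parity stratum. Default
#'   \code{c(26, 23, 27, 24)}.
#' @param secondSampleCounts integer length-4: per-stratum count of women with
#'   a second visit; element 1 must be 0. Default \code{c(0, 22, 21, 18)}.
#' @param seed integer random seed.
#' @param params stratum parameters, see [defaultCohortParams()].
#' @param nBatches number of injection batches to partition samples into.
#' @param yearRange allowed calendar window for all samples.
#' @return an [ExposomeCohort-class].
#' @examples
#' ch <- generateCohort(seed = 1)
#' ch
#' @export
generateCohort <- function(nWomen = 100L,
                           strataCounts = c(26L, 23L, 27L, 24L),
                           secondSampleCounts = c(0L, 22L, 21L, 18L),
                           seed = 1L,
                           params = defaultCohortParams(),
                           nBatches = 5L,
                           yearRange = c(1987L, 2006L)) {
  strataCounts <- as.integer(strataCounts)
  secondSampleCounts <- as.integer(secondSampleCounts)
  if (length(strataCounts) != 4L || length(secondSampleCounts) != 4L)
    abort("strataCounts and secondSampleCounts must have length 4")
  if (sum(strataCounts) != nWomen)
    abort(sprintf("strata counts sum to %d but nWomen is %d",
                  sum(strataCounts), nWomen))
  bad <- which(secondSampleCounts > strataCounts)
  if (length(bad))
    abort(sprintf("stratum %d: second-sample count %d exceeds stratum size %d",
                  bad[1], secondSampleCounts[bad[1]], strataCounts[bad[1]]))
  if (secondSampleCounts[1] != 0L)
    abort("stratum 1 (nullipara) cannot provide second samples")

  set.seed(as.integer(seed))
  pRows <- list(); sRows <- list(); w <- 0L
  for (st in seq_len(4L)) {
    pp <- params[[st]]
    n <- strataCounts[st]
    if (n == 0L) next
    repeatIdx <- if (secondSampleCounts[st] > 0L)
      sample.int(n, secondSampleCounts[st]) else integer(0)
    menMissIdx <- if (pp$menarcheMissing > 0L)
      sample.int(n, min(pp$menarcheMissing, n)) else integer(0)
    for (i in seq_len(n)) {
      w <- w + 1L
      id <- sprintf("W%03d", w)
      nPreg <- if (pp$pregRange[1] == pp$pregRange[2]) pp$pregRange[1] else
        sample(seq(pp$pregRange[1], pp$pregRange[2]), 1L)
      nDeliv <- drawDeliveries(nPreg, st)
      year1 <- sample(seq(pp$firstYearRange[1], pp$firstYearRange[2]), 1L)
      age1 <- round(min(max(stats::rnorm(1, pp$ageFirstMean, pp$ageFirstSD), 20), 74), 1)
      birthYear <- year1 - as.integer(round(age1))
      lastPregYear <- if (nPreg > 0L) year1 - sample(0:2, 1L) else NA_integer_
      menarche <- if (i %in% menMissIdx) NA_real_ else
        round(stats::rnorm(1, pp$menarcheMean, pp$menarcheSD), 1)
      bmi <- round(max(stats::rnorm(1, pp$bmiMean, pp$bmiSD), 15), 1)
      tob <- stats::runif(1) < pp$tobaccoP
      hc <- stats::runif(1) < pp$hcP
      hrt <- stats::runif(1) < pp$hrtP
      pRows[[w]] <- data.frame(id = id, birth_year = birthYear,
                               n_pregnancies = nPreg, n_deliveries = nDeliv,
                               age_menarche = menarche, bmi = bmi,
                               tobacco_ever = tob,
                               hormonal_contraception_ever = hc,
                               hrt_ever = hrt,
                               last_pregnancy_year = lastPregYear,
                               parity_stratum = st,
                               stringsAsFactors = FALSE)
      sRows[[length(sRows) + 1L]] <- data.frame(
        participant_id = id, visit = 1L, age_at_sampling = age1,
        sample_year = year1, stringsAsFactors = FALSE)
      if (i %in% repeatIdx) {
        gap <- min(max(as.integer(round(stats::rnorm(1, 8, 3))), 1L), 16L)
        year2 <- min(year1 + gap, yearRange[2])
        if (year2 <= year1) year2 <- min(year1 + 1L, yearRange[2])
        gap2 <- year2 - year1
        if (gap2 < 1L) { # first visit already at window edge: shift it back
          year1b <- year1 - 1L
          sRows[[length(sRows)]]$sample_year <- year1b
          sRows[[length(sRows)]]$age_at_sampling <- age1 - 1
          year2 <- year1; gap2 <- 1L; age1 <- age1 - 1
        }
        sRows[[length(sRows) + 1L]] <- data.frame(
          participant_id = id, visit = 2L,
          age_at_sampling = age1 + gap2, sample_year = year2,
          stringsAsFactors = FALSE)
      }
    }
  }

  p <- if (length(pRows)) do.call(rbind, pRows) else
    data.frame(id = character(0), birth_year = integer(0),
               n_pregnancies = integer(0), n_deliveries = integer(0),
               age_menarche = numeric(0), bmi = numeric(0),
               tobacco_ever = logical(0),
               hormonal_contraception_ever = logical(0),
               hrt_ever = logical(0), last_pregnancy_year = integer(0),
               parity_stratum = integer(0))
  s <- if (length(sRows)) do.call(rbind, sRows) else
    data.frame(participant_id = character(0), visit = integer(0),
               age_at_sampling = numeric(0), sample_year = integer(0))
  if (nrow(s) > 0) {
    s$sample_year <- pmin(pmax(s$sample_year, yearRange[1]), yearRange[2])
    # batches follow injection order: samples sorted by year then donor/visit
    ord <- order(s$sample_year, s$participant_id, s$visit)
    batch <- integer(nrow(s))
    batch[ord] <- as.integer(cut(seq_len(nrow(s)), breaks = nBatches, labels = FALSE))
    s$batch <- batch
    s$sample_id <- sprintf("%s_V%d", s$participant_id, s$visit)
  } else {
    s$batch <- integer(0); s$sample_id <- character(0)
  }
  new("ExposomeCohort", participants = DataFrame(p), samples = DataFrame(s))
}

#' Assemble the per-sample covariate table used by the association models
#'
#' One row per blood sample, joining the visit-level variables (age at
#' sampling, sample year, batch) with the participant-level reproductive
#' covariates.
#'
#' @param cohort an [ExposomeCohort-class].
#' @return a data.frame keyed by \code{sample_id}.
#' @export
buildModelData <- function(cohort) {
  s <- as.data.frame(cohortSamples(cohort))
  p <- as.data.frame(participants(cohort))
  if (nrow(s) == 0) {
    return(cbind(s, p[0, setdiff(colnames(p), "id"), drop = FALSE]))
  }
  m <- merge(s, p, by.x = "participant_id", by.y = "id", sort = FALSE)
  m <- m[order(m$participant_id, m$visit), ]
  rownames(m) <- m$sample_id
  m$age <- m$age_at_sampling
  m$tobacco <- as.integer(m$tobacco_ever)
  m
}

#' Write / read a cohort as delimited text
#'
#' Two tab-separated files: \code{<stem>_participants.tsv} and
#' \code{<stem>_samples.tsv}.
#'
#' @param cohort an [ExposomeCohort-class].
#' @param stem path stem for the two files.
#' @return \code{writeCohort} returns the two paths invisibly;
#'   \code{readCohort} returns an \code{ExposomeCohort}.
#' @export
writeCohort <- function(cohort, stem) {
  fp <- paste0(stem, "_participants.tsv")
  fs <- paste0(stem, "_samples.tsv")
  utils::write.table(as.data.frame(participants(cohort)), fp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohortSamples(cohort)), fs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fp, fs))
}

#' @rdname writeCohort
#' @export
readCohort <- function(stem) {
  p <- utils::read.delim(paste0(stem, "_participants.tsv"), stringsAsFactors = FALSE)
  s <- utils::read.delim(paste0(stem, "_samples.tsv"), stringsAsFactors = FALSE)
  new("ExposomeCohort", participants = DataFrame(p), samples = DataFrame(s))
}
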