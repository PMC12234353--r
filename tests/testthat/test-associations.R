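test_that("square-root transform is exact, order-preserving and tames skew", {
  expect_equal(transformSqrt(c(4, 0, 2.25)), c(2, 0, 1.5))
  expect_error(transformSqrt(c(1, -1)), "negative")
  set.seed(111)
  x <- rlnorm(10000, 0, 1)
  expect_lt(skewness(transformSqrt(x)), skewness(x))
})

test_that("correlation structure separates rank and linear association", {
  n <- 60
  x <- seq_len(n)
  y <- exp(x / 10)  # perfectly monotone, strongly nonlinear
  vals <- matrix(y, 1, n, dimnames = list("X", NULL))
  rf <- data.frame(age = x)
  cs <- correlationStructure(vals, rf)
  expect_equal(unname(cs$spearman["X", "age"]), 1.0)
  expect_lt(abs(cor(y, x)), 1.0)
  # a constant column is flagged undefined rather than guessed
  vals2 <- rbind(vals, const = rep(1, n))
  cs2 <- correlationStructure(vals2, rf)
  expect_true(is.na(cs2$spearman["const", "age"]))
})

test_that("independent columns rarely show |rho| above the n=161 null band", {
  set.seed(112)
  hits <- replicate(200, {
    abs(cor(rnorm(161), rnorm(161), method = "spearman")) < 0.16
  })
  expect_gte(mean(hits), 0.90)
})

test_that("group scores sum transformed members per sample", {
  tv <- matrix(1, 10, 4,
               dimnames = list(c("PFOS", "PFHpS", "PFOA", "PFHxS", "PFDA",
                                 "PFNA", "PFUnDA", "FOSA", "FOSAA", "NEtFOSAA"),
                               paste0("S", 1:4)))
  gs <- groupAndSum(tv)
  expect_equal(dim(gs), c(3L, 4L))
  expect_equal(unname(gs["Group 3", ]), rep(4, 4))   # 4 members, each 1.0
  expect_equal(unname(gs["Group 1", ]), rep(3, 4))
  expect_equal(vapply(defaultPfasGroups(), length, 1L),
               c(`Group 1` = 3L, `Group 2` = 3L, `Group 3` = 4L))
  expect_error(groupAndSum(tv, list(G = c("PFOS", "missing"))), "missing")
  expect_error(groupAndSum(tv, list(G = character(0))), "empty")
})

test_that("mixed model reduces to OLS when subject variance is absent", {
  ch <- sharedCohort()
  md <- buildModelData(ch)
  eff <- effectSpec("X", baseline = 0, sdSubject = 0, sdResid = 1, age = 0.02)
  tt <- generateTargetTruth(ch, eff, c(X = 1e-9), seed = 121)
  y <- log(tt$truth$latent["X", ])
  lmm <- fitLMM(y, "age", md)
  covs <- defaultAdjustment("age")
  df <- data.frame(.y = y, md[, c("age", covs, "participant_id")])
  df <- df[complete.cases(df), ]
  ols <- lm(.y ~ age + bmi + n_pregnancies + sample_year + age_menarche +
              tobacco, data = df)
  expect_true(lmm$converged)
  expect_lt(abs(lmm$beta - coef(ols)["age"]), 1e-4)
})

test_that("collinear exposure designs are flagged as non-converged", {
  ch <- sharedCohort()
  md <- buildModelData(ch)
  md$n_pregnancies <- md$age / 10   # exact collinearity with age
  y <- rnorm(nrow(md))
  res <- fitLMM(y, "age", md, covariates = c("n_pregnancies", "bmi"))
  expect_false(res$converged)
  expect_true(is.na(res$p))
})

test_that("coefficient signs are invariant to positive affine covariate rescaling", {
  ch <- sharedCohort()
  md <- buildModelData(ch)
  eff <- effectSpec("X", baseline = 0, sdSubject = 0.5, sdResid = 1, age = 0.05)
  tt <- generateTargetTruth(ch, eff, c(X = 1e-9), seed = 122)
  y <- log(tt$truth$latent["X", ])
  r1 <- fitLMM(y, "age", md)
  md2 <- md
  md2$bmi <- md2$bmi * 3 + 7
  md2$sample_year <- (md2$sample_year - 1990) / 5
  r2 <- fitLMM(y, "age", md2)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-5)
})

test_that("Wald and Satterthwaite p-values agree closely at this scale", {
  ch <- sharedCohort()
  md <- buildModelData(ch)
  eff <- effectSpec("X", baseline = 0, sdSubject = 0.5, sdResid = 1, age = 0.03)
  tt <- generateTargetTruth(ch, eff, c(X = 1e-9), seed = 123)
  y <- log(tt$truth$latent["X", ])
  w <- fitLMM(y, "age", md, pMethod = "wald")
  s <- fitLMM(y, "age", md, pMethod = "satterthwaite")
  expect_equal(w$beta, s$beta, tolerance = 1e-6)
  expect_lt(abs(w$p - s$p), 0.02)
  expect_false(is.na(s$df))
})

test_that("the parous-only sensitivity model mirrors the full model", {
  ch <- sharedCohort()
  md <- buildModelData(ch)
  eff <- effectSpec("X", baseline = 0, sdSubject = 0.4, sdResid = 0.8,
                    age = 0.05)
  tt <- generateTargetTruth(ch, eff, c(X = 1e-9), seed = 124)
  y <- log(tt$truth$latent["X", ])
  full <- fitLMM(y, "age", md)
  sens <- sensitivityParousOnly(y, "age", md)
  expect_equal(sign(sens$beta), sign(full$beta))
  expect_lt(sens$n_samples, full$n_samples)
  # all-parous input: subsetting is a no-op
  parous <- md$n_pregnancies >= 1
  direct <- fitLMM(y[parous], "age", md[parous, ])
  expect_equal(sens$beta, direct$beta, tolerance = 1e-10)
  # all-nulliparous input is rejected
  nulli <- md$n_pregnancies == 0
  expect_error(sensitivityParousOnly(y[nulli], "age", md[nulli, ]),
               "parous")
})

test_that("the age-by-pregnancies interaction term is reported", {
  ch <- sharedCohort()
  md <- buildModelData(ch)
  set.seed(125)
  y <- 0.05 * md$age * md$n_pregnancies + rnorm(nrow(md))
  res <- interactionAgePregnancies(y, md)
  expect_true(res$converged || !is.na(res$beta))
  expect_match(res$exposure, "age:n_pregnancies")
  expect_gt(res$beta, 0)
})

test_that("multiplicity tiers are nested and use the stated thresholds", {
  m <- adjustMultiplicity(c(0.004, 0.04, 0.2), nTests = 10000)
  expect_equal(m$bonferroni_threshold, 0.05 / 10000)
  f <- m$flags
  # p = 0.004 passes the 0.005 tier but not Bonferroni
  expect_true(f$sig_literature[1]); expect_false(f$sig_bonferroni[1])
  expect_true(f$sig_alpha[2]); expect_false(f$sig_literature[2])
  # nesting whenever n_tests >= 10
  expect_true(all(!f$sig_bonferroni | f$sig_literature))
  expect_true(all(!f$sig_literature | f$sig_alpha))
  expect_equal(adjustMultiplicity(0.2, nTests = 1)$bonferroni_threshold, 0.05)
  expect_error(adjustMultiplicity(numeric(0), nTests = 0), "at least one")
})

test_that("default adjustment sets match the study design", {
  expect_setequal(defaultAdjustment("age"),
                  c("bmi", "n_pregnancies", "sample_year", "age_menarche",
                    "tobacco"))
  expect_setequal(defaultAdjustment("n_pregnancies"),
                  c("age", "birth_year", "age_menarche", "tobacco"))
  expect_setequal(defaultAdjustment("age_menarche"),
                  c("age", "bmi", "birth_year"))
  expect_error(fitLMM(rnorm(10), "age",
                      data.frame(age = 1:10, participant_id = 1:10),
                      covariates = c("age")), "duplicated")
})
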