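test_that("calibration fits noiseless linear data exactly", {
  pts <- data.frame(conc = c(0.01, 0.1, 1, 10, 100), ratio = 0.5 * c(0.01, 0.1, 1, 10, 100))
  cal <- fitCalibration(pts)
  expect_equal(cal@slope, 0.5, tolerance = 1e-12)
  expect_equal(cal@intercept, 0, tolerance = 1e-12)
  expect_equal(cal@range, c(0.01, 100))
  expect_error(fitCalibration(data.frame(conc = rep(1, 5), ratio = 1:5)),
               "degenerate")
})

test_that("calibration recovers the slope from noisy 9-point curves", {
  concs <- c(0.01, 0.025, 0.1, 0.5, 1, 5, 10, 50, 100)
  trueSlope <- 0.8
  set.seed(201)
  slopes <- replicate(200, {
    cal <- fitCalibration(data.frame(conc = concs,
                                     ratio = trueSlope * concs + rnorm(9, 0, 0.01)))
    cal@slope
  })
  mcse <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - trueSlope), 3 * mcse)
})

test_that("per-batch calibration averages repeated curve injections", {
  concs <- c(0.01, 1, 100)
  pts <- data.frame(conc = rep(concs, 3),
                    ratio = c(concs * 0.4, concs * 0.5, concs * 0.6),
                    injection = rep(1:3, each = 3))
  cal <- fitCalibrationBatch(pts)
  expect_equal(cal@slope, 0.5, tolerance = 1e-10)
})

test_that("quantification statuses follow range and MLOQ with inclusive boundaries", {
  cal <- fitCalibration(data.frame(conc = c(0.01, 100), ratio = c(0.01, 100)))
  # computed value above the range high: retained, flagged extrapolated
  q <- quantifyPeak(area = 150, is_area = 1, cal = cal, mloq = 0.05)
  expect_equal(q$status, "extrapolated")
  expect_equal(q$value, 150, tolerance = 1e-9)
  # exactly at the range high: quantified
  expect_equal(quantifyPeak(100, 1, cal, 0.05)$status, "quantified")
  # exactly at MLOQ: quantified
  expect_equal(quantifyPeak(0.05, 1, cal, 0.05)$status, "quantified")
  # between zero and MLOQ: below_mloq
  expect_equal(quantifyPeak(0.03, 1, cal, 0.05)$status, "below_mloq")
  # no integrable peak
  expect_equal(quantifyPeak(0, 1, cal, 0.05)$status, "nondetect")
  # bad internal standard: rejected cell, logged as nondetect
  expect_warning(q <- quantifyPeak(10, 0, cal, 0.05), "internal standard")
  expect_equal(q$status, "nondetect")
})

test_that("quantification inverts the calibration on noiseless data", {
  cal <- fitCalibration(data.frame(conc = c(0.01, 0.1, 1, 10, 100),
                                   ratio = 0.3 * c(0.01, 0.1, 1, 10, 100) + 0.002))
  for (conc in c(0.02, 0.5, 7, 99)) {
    ratio <- 0.3 * conc + 0.002
    q <- quantifyPeak(area = ratio * 1e5, is_area = 1e5, cal = cal, mloq = 0.01)
    expect_lt(abs(q$value - conc) / conc, 1e-10)
  }
})

test_that("censored substitution uses MLOQ/2 and MLOQ/4 and is idempotent", {
  conc <- matrix(c(1.0, 0.15, 0.01, 0.5), 2, 2,
                 dimnames = list(c("A", "B"), c("S1", "S2")))
  status <- matrix(c("quantified", "below_mloq", "nondetect", "quantified"),
                   2, 2, dimnames = dimnames(conc))
  cm <- concentrationMatrix(conc, status, mloq = c(A = 0.2, B = 0.2))
  sub <- substituteCensored(cm)
  expect_equal(SummarizedExperiment::assay(sub, "conc")["B", "S1"], 0.1)   # MLOQ/2
  expect_equal(SummarizedExperiment::assay(sub, "conc")["A", "S2"], 0.05)  # MLOQ/4
  st <- SummarizedExperiment::assay(sub, "status")
  expect_false(any(st %in% c("below_mloq", "nondetect")))
  sub2 <- substituteCensored(sub)
  expect_identical(SummarizedExperiment::assay(sub2, "conc"),
                   SummarizedExperiment::assay(sub, "conc"))
  expect_identical(SummarizedExperiment::assay(sub2, "status"), st)
})

test_that("isomer sums compose quantified and substituted values", {
  conc <- matrix(c(10, 3, 2, 0, 0, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("PFOS linear", "PFOS branched", "Other"),
                                 c("S1", "S2")))
  status <- matrix(c("quantified", "quantified",
                     "quantified", "nondetect",
                     "nondetect", "nondetect"), 3, 2, byrow = TRUE,
                   dimnames = dimnames(conc))
  cm <- concentrationMatrix(conc, status, mloq = c(0.2, 0.2, 0.2),
                            class = c("PFAS", "PFAS", "food"))
  out <- sumIsomers(cm, "PFOS linear", "PFOS branched", name = "PFOS (total)")
  # both quantified: plain additivity
  expect_equal(SummarizedExperiment::assay(out, "conc")["PFOS (total)", "S1"],
               10 + 2)
  # quantified 3.0 + nondetect at MLOQ 0.2 -> 3 + 0.05
  expect_equal(SummarizedExperiment::assay(out, "conc")["PFOS (total)", "S2"],
               3.05)
  expect_equal(SummarizedExperiment::assay(out, "status")["PFOS (total)", "S2"],
               "quantified")
  # mismatched families rejected
  expect_error(sumIsomers(cm, "PFOS linear", "Other"), "mismatched")
})

test_that("both-censored isomer sums stay substituted", {
  conc <- matrix(0, 2, 1, dimnames = list(c("L", "B"), "S1"))
  status <- matrix("nondetect", 2, 1, dimnames = dimnames(conc))
  cm <- concentrationMatrix(conc, status, mloq = c(0.2, 0.2),
                            class = c("PFAS", "PFAS"))
  out <- sumIsomers(cm, "L", "B", name = "T")
  expect_equal(SummarizedExperiment::assay(out, "conc")["T", "S1"], 0.10)
  expect_equal(SummarizedExperiment::assay(out, "status")["T", "S1"],
               "substituted_quarter_mloq")
})

test_that("isomer sums equal a brute-force elementwise sum after substitution", {
  set.seed(11)
  n <- 20
  conc <- matrix(rlnorm(2 * n), 2, n, dimnames = list(c("L", "B"), NULL))
  status <- matrix(sample(c("quantified", "below_mloq", "nondetect"), 2 * n,
                          replace = TRUE), 2, n, dimnames = dimnames(conc))
  conc[status != "quantified"] <- 0
  cm <- concentrationMatrix(conc, status, mloq = c(0.4, 0.4),
                            class = c("PFAS", "PFAS"))
  out1 <- sumIsomers(cm, "L", "B", name = "T")
  # oracle: substitute first, then add the two rows elementwise
  sub <- substituteCensored(cm)
  oracle <- colSums(SummarizedExperiment::assay(sub, "conc"))
  expect_equal(unname(SummarizedExperiment::assay(out1, "conc")["T", ]),
               unname(oracle))
  # argument order does not matter for the sum
  out2 <- sumIsomers(cm, "B", "L", name = "T")
  expect_equal(SummarizedExperiment::assay(out1, "conc")["T", ],
               SummarizedExperiment::assay(out2, "conc")["T", ])
})

test_that("target selection applies the 60% rule with inclusive boundary", {
  mkcm <- function(fracDetected, n = 161) {
    k <- round(fracDetected * n)
    status <- matrix(c(rep("quantified", k),
                       rep("substituted_quarter_mloq", n - k)), 1, n)
    conc <- matrix(1, 1, n)
    rownames(conc) <- "X"
    concentrationMatrix(conc, status, mloq = 1)
  }
  expect_false("X" %in% selectTargets(mkcm(0.59)))
  expect_true("X" %in% selectTargets(mkcm(0.60)))
  # forced analytes are retained despite falling below the cut-off
  expect_true("X" %in% selectTargets(mkcm(0.30), forceInclude = "X"))
  expect_warning(sel <- selectTargets(mkcm(0.70), forceInclude = "Cotinine"),
                 "absent")
  expect_true("X" %in% sel)
})

test_that("the two detection-frequency readings differ on below-MLOQ cells", {
  status <- matrix(c(rep("quantified", 50), rep("substituted_half_mloq", 50)),
                   1, 100)
  conc <- matrix(1, 1, 100, dimnames = list("X", NULL))
  cm <- concentrationMatrix(conc, status, mloq = 1)
  expect_equal(unname(targetDetectionFrequency(cm, "quantified")), 0.5)
  expect_equal(unname(targetDetectionFrequency(cm, "substituted")), 1.0)
})
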