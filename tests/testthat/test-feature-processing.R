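test_that("blank-ratio filter keeps features with max/blank-average > 5", {
  roles <- c("sample", "sample", "blank", "blank")
  areas <- rbind(keep = c(600000, 100000, 100000, 100000),
                 drop = c(450000, 100000, 100000, 100000),
                 zeroBlank = c(100000, 0, 0, 0))
  ft <- tinyTable(areas, mz = c(100, 200, 300), rt = c(1, 2, 3), role = roles)
  out <- maxBlankRatioFilter(ft)
  expect_setequal(rownames(out), c("keep", "zeroBlank"))
  pv <- provenance(out)
  expect_equal(pv$feature_id, "drop")
  expect_error(maxBlankRatioFilter(ft[, 1:2]), "blank")
  # rerunning on its own output removes nothing
  expect_identical(rownames(maxBlankRatioFilter(out)), rownames(out))
})

test_that("ESI merge discards the lower-intensity cross-mode twin", {
  roles <- c("sample", "sample", "blank")
  pos <- tinyTable(matrix(c(2e6, 2e6, 1e3), 1, dimnames = list("P1", NULL)),
                   mz = 195.0877, rt = 5.00, mode = "pos", role = roles)
  mkneg <- function(rt) {
    x <- tinyTable(matrix(c(1e6, 1e6, 1e3), 1, dimnames = list("N1", NULL)),
                   mz = 193.0731, rt = rt, mode = "neg", role = roles)
    colnames(x) <- colnames(pos)
    x
  }
  m <- mergeEsiModes(pos, mkneg(4.95))
  expect_equal(rownames(m), "P1")
  # RT difference beyond tolerance: both retained
  m2 <- mergeEsiModes(pos, mkneg(4.70))
  expect_setequal(rownames(m2), c("P1", "N1"))
  # empty negative table: merge is the identity on the positive table
  emptyNeg <- mkneg(5)[0, ]
  m3 <- mergeEsiModes(pos, emptyNeg)
  expect_equal(rownames(m3), "P1")
})

test_that("ESI merge agrees with the exhaustive pairwise oracle", {
  ch <- sharedCohort()
  for (seed in c(21, 22)) {
    un <- generateUntargetedTables(ch, nFeatures = c(pos = 30L, neg = 18L),
                                   planting = plantingPlan(6L, 0L, 0L),
                                   seed = seed)
    m <- mergeEsiModes(un$pos, un$neg)
    expect_setequal(rownames(m), bruteForceMergeSurvivors(un$pos, un$neg))
  }
})

test_that("IS-PCA normalization is the identity without drift signal", {
  roles <- c(rep("sample", 4), "blank")
  areas <- matrix(rlnorm(10, log(5e5)), 2, 5)
  ft <- tinyTable(areas, mz = c(100, 200), rt = c(1, 2), role = roles)
  isM <- matrix(1e6, 3, 4, dimnames = list(NULL, colnames(ft)[1:4]))
  # identical IS areas across samples: zero-variance scores
  out <- normalizeByISPCA(ft, isM)
  expect_identical(SummarizedExperiment::assay(out), SummarizedExperiment::assay(ft))
  # zero components requested
  out0 <- normalizeByISPCA(ft, isM * rlnorm(12), nComponents = 0)
  expect_identical(SummarizedExperiment::assay(out0), SummarizedExperiment::assay(ft))
  # a sample missing all IS areas is rejected by name
  isBad <- isM; isBad[, 2] <- 0
  expect_error(normalizeByISPCA(ft, isBad), colnames(ft)[2])
})

test_that("IS-PCA normalization removes a planted x2 batch drift", {
  set.seed(31)
  nS <- 40; nF <- 25; nIS <- 8
  half <- rep(c(1, 2), each = nS / 2)
  driftFactor <- ifelse(half == 2, 2, 1)
  base <- matrix(rlnorm(nF * nS, log(5e5), 0.2), nF, nS)
  areas <- sweep(base, 2, driftFactor, "*")
  ft <- featureTable(areas, mz = runif(nF, 100, 900), rt = runif(nF, 1, 20),
                     role = "sample", batch = half)
  isM <- sweep(matrix(rlnorm(nIS * nS, log(1e6), 0.05), nIS, nS), 2,
               driftFactor, "*")
  colnames(isM) <- colnames(ft)
  gap <- function(a) abs(mean(log(a[, half == 2])) - mean(log(a[, half == 1])))
  before <- gap(areas)
  out <- normalizeByISPCA(ft, isM, nComponents = 2)
  after <- gap(SummarizedExperiment::assay(out))
  expect_lt(after, 0.05 * before)
})

test_that("blank subtraction applies the pseudo-count, subtraction and floor", {
  roles <- c("sample", "sample", "sample", "blank", "blank")
  areas <- rbind(pass = c(1e6, 4e5, 0, 1e5, 1e5),
                 noblank = c(1e6, 95000, 0, 0, 0),
                 floored = c(100000, 5e5, 0, 15000, 15000))
  ft <- tinyTable(areas, mz = c(100, 200, 300), rt = 1:3, role = roles)
  out <- blankSubtractFloor(ft)
  a <- SummarizedExperiment::assay(out)
  # ratio 10 > 5: blank average subtracted
  expect_equal(a["pass", 1], 1e6 - 1e5)
  # ratio 4 < 5: zeroed
  expect_equal(a["pass", 2], 0)
  # no blank response: pseudo-count keeps the cell, nothing subtracted
  expect_equal(a["noblank", 1], 1e6)
  expect_equal(a["noblank", 2], 95000)
  # post-subtraction area below 90000 floored to zero
  expect_equal(a["floored", 1], 0)
  # blank columns consumed
  expect_equal(sum(columnRoles(out) == "blank"), 0L)
  # idempotence on its own output
  out2 <- blankSubtractFloor(out)
  expect_identical(SummarizedExperiment::assay(out2), a)
})

test_that("correlated co-eluting duplicates collapse to the higher-area member", {
  set.seed(41)
  roles <- rep("sample", 10)
  base <- rlnorm(10, log(5e5), 0.4)
  areas <- rbind(A = base, B = 1.01 * base, C = rlnorm(10, log(5e5), 0.4))
  ft <- tinyTable(areas, mz = c(100, 120, 400), rt = c(5.00, 5.05, 5.02),
                  role = roles)
  out <- dedupCorrelated(ft)
  expect_setequal(rownames(out), c("B", "C"))  # B = 1.01 A has higher average
  # same correlation but RT gap beyond 0.1 min: both retained
  ft2 <- tinyTable(areas, mz = c(100, 120, 400), rt = c(5.00, 5.15, 9),
                   role = roles)
  expect_equal(nrow(dedupCorrelated(ft2)), 3L)
})

test_that("three mutually correlated features leave exactly one survivor", {
  set.seed(42)
  roles <- rep("sample", 12)
  base <- rlnorm(12, log(4e5), 0.5)
  areas <- rbind(A = base * 1.2, B = base, C = base * 0.8)
  ft <- tinyTable(areas, mz = c(100, 120, 140), rt = c(3.00, 3.04, 3.08),
                  role = roles)
  out <- dedupCorrelated(ft)
  expect_equal(nrow(out), 1L)
  expect_equal(rownames(out), "A")
  expect_setequal(rownames(out), bruteForceDedupSurvivors(ft))
})

test_that("dedup agrees with the exhaustive pairwise oracle on random tables", {
  ch <- sharedCohort()
  for (seed in c(51, 52)) {
    un <- generateUntargetedTables(ch, nFeatures = c(pos = 20L, neg = 0L),
                                   planting = plantingPlan(0L, 8L, 0L),
                                   seed = seed)
    ft <- blankSubtractFloor(un$pos)
    out <- dedupCorrelated(ft)
    expect_setequal(rownames(out), bruteForceDedupSurvivors(ft))
    # planted in-source fragments are among the casualties
    frag <- un$truth$fragmentPairs
    present <- intersect(frag$fragment, rownames(ft))
  }
})

test_that("pairs with too few shared detections are skipped, not removed", {
  roles <- rep("sample", 6)
  areas <- rbind(A = c(1e6, 2e6, 0, 0, 0, 0),
                 B = c(0, 0, 0, 0.9e6, 1.8e6, 0))
  ft <- tinyTable(areas, mz = c(100, 120), rt = c(2.0, 2.05), role = roles)
  out <- dedupCorrelated(ft)
  expect_equal(nrow(out), 2L)
  expect_true(length(S4Vectors::metadata(out)$dedup_skipped_pairs) >= 1)
})

test_that("detection-frequency filter applies the 70% rule inclusively", {
  n <- 161
  mk <- function(k) c(rlnorm(k, log(2e5)), rep(0, n - k))
  areas <- rbind(keep = mk(113),   # 113/161 = 70.2%
                 drop = mk(112),   # 112/161 = 69.6%
                 gone = rep(0, n))
  ft <- featureTable(areas, mz = c(100, 200, 300), rt = 1:3,
                     role = "sample", batch = 1L)
  out <- detectionFrequencyFilter(ft, 0.70)
  expect_equal(rownames(out), "keep")
  expect_equal(unname(SummarizedExperiment::rowData(out)$df), 113 / 161)
  pv <- provenance(out)
  expect_setequal(pv$feature_id[pv$stage == "df_filter"], c("drop", "gone"))
})

test_that("the cleaning funnel is monotone and reconciles with provenance", {
  ch <- sharedCohort()
  un <- generateUntargetedTables(ch, nFeatures = c(pos = 40L, neg = 30L),
                                 seed = 61)
  cleaned <- cleanFeatures(un$pos, un$neg, un$isMatrix)
  funnel <- S4Vectors::metadata(cleaned)$funnel
  expect_true(all(diff(funnel$n_features) <= 0))
  pv <- provenance(cleaned)
  expect_equal(funnel$n_features[1] - nrow(cleaned), nrow(pv))
  # rerunning dedup and the DF filter on the cleaned output is a no-op
  expect_equal(nrow(dedupCorrelated(cleaned)), nrow(cleaned))
  expect_equal(nrow(detectionFrequencyFilter(cleaned, 0.70)), nrow(cleaned))
})

test_that("feature tables round-trip through the delimited export", {
  ch <- sharedCohort()
  un <- generateUntargetedTables(ch, nFeatures = c(pos = 10L, neg = 0L),
                                 planting = plantingPlan(0L, 0L, 0L), seed = 71)
  path <- file.path(withr::local_tempdir(), "ft.tsv")
  writeFeatureTable(un$pos, path)
  back <- readFeatureTable(path)
  expect_equal(dim(back), dim(un$pos))
  expect_equal(columnRoles(back), columnRoles(un$pos))
  expect_equal(SummarizedExperiment::rowData(back)$mz,
               SummarizedExperiment::rowData(un$pos)$mz, tolerance = 1e-5)
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(un$pos), tolerance = 1e-4)
})
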