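# Shared fixtures: small hand-built tables and independent brute-force oracles.

# one cohort reused by read-only tests (regenerating is the expensive part)
sharedCohort <- local({
  ch <- NULL
  function() {
    if (is.null(ch)) ch <<- generateCohort(seed = 101)
    ch
  }
})

# tiny feature table: areas given as a matrix, roles/batches supplied
tinyTable <- function(areas, mz, rt, mode = "pos", role = NULL, batch = 1L,
                      ms2 = "") {
  if (is.null(role))
    role <- c(rep("sample", ncol(areas) - 1L), "blank")
  featureTable(as.matrix(areas), mz = mz, rt = rt, mode = mode, ms2 = ms2,
               role = role, batch = batch)
}

# independent O(n^2) oracle for the ESI merge: enumerate every cross-mode
# pair, collect lower-average-area members of qualifying pairs, survivors are
# everything else
bruteForceMergeSurvivors <- function(pos, neg, rtTol = 0.2, mzTol = 0.002,
                                     proton = 1.007276) {
  sm <- which(as.character(SummarizedExperiment::colData(pos)$role) == "sample")
  aP <- SummarizedExperiment::assay(pos, "area")[, sm, drop = FALSE]
  aN <- SummarizedExperiment::assay(neg, "area")[, sm, drop = FALSE]
  MP <- SummarizedExperiment::rowData(pos)$mz - proton
  MN <- SummarizedExperiment::rowData(neg)$mz + proton
  rtP <- SummarizedExperiment::rowData(pos)$rt
  rtN <- SummarizedExperiment::rowData(neg)$rt
  drop <- character(0)
  for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(neg))) {
    if (abs(MP[i] - MN[j]) <= mzTol && abs(rtP[i] - rtN[j]) <= rtTol) {
      drop <- c(drop,
                if (mean(aP[i, ]) >= mean(aN[j, ])) rownames(neg)[j]
                else rownames(pos)[i])
    }
  }
  setdiff(c(rownames(pos), rownames(neg)), drop)
}

# independent all-pairs oracle for correlated dedup: same gates, but the
# survivor set is computed by exhaustively marking lower-area members of every
# qualifying pair in descending-area sweep order
bruteForceDedupSurvivors <- function(ft, rThreshold = 0.95, pThreshold = 0.001,
                                     rtTol = 0.1) {
  sm <- which(as.character(SummarizedExperiment::colData(ft)$role) == "sample")
  a <- SummarizedExperiment::assay(ft, "area")[, sm, drop = FALSE]
  rt <- SummarizedExperiment::rowData(ft)$rt
  avg <- rowMeans(a)
  ids <- rownames(ft)
  ord <- order(-avg, ids)
  alive <- rep(TRUE, nrow(ft))
  for (i in ord) {
    if (!alive[i]) next
    for (j in ord) {
      if (identical(i, j) || !alive[j]) next
      if (avg[j] > avg[i] || (avg[j] == avg[i] && ids[j] < ids[i])) next
      if (abs(rt[i] - rt[j]) > rtTol) next
      shared <- which(a[i, ] > 0 & a[j, ] > 0)
      if (length(shared) < 3) next
      r <- suppressWarnings(stats::cor(a[i, shared], a[j, shared]))
      if (is.na(r) || abs(r) >= 1) p <- if (is.na(r)) NA else 0
      else p <- 2 * stats::pt(-abs(r * sqrt((length(shared) - 2) / (1 - r^2))),
                              df = length(shared) - 2)
      if (!is.na(r) && r > rThreshold && !is.na(p) && p < pThreshold)
        alive[j] <- FALSE
    }
  }
  ids[alive]
}

# sample skewness
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
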