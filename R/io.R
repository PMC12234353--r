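#' Write / read a feature table in an alignment-export-like delimited layout
#'
#' Tab-separated text with columns: feature id, average m/z, average RT (min),
#' ESI mode, packed MS2 spectrum ("mz:intensity" pairs), then one peak-area
#' column per injection. Column roles and batches travel in two header comment
#' lines (\code{#role}, \code{#batch}).
#'
#' @param x a [FeatureTable-class].
#' @param path file path.
#' @return \code{readFeatureTable} returns a \code{FeatureTable}.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "FeatureTable"))
  rd <- rowData(x)
  a <- assay(x, "area")
  con <- file(path, "w"); on.exit(close(con))
  cat("#role\t\t\t\t\t", paste(columnRoles(x), collapse = "\t"), "\n",
      sep = "", file = con)
  cat("#batch\t\t\t\t\t", paste(colData(x)$batch, collapse = "\t"), "\n",
      sep = "", file = con)
  header <- c("feature_id", "average_mz", "average_rt_min", "mode", "ms2",
              colnames(x))
  cat(paste(header, collapse = "\t"), "\n", sep = "", file = con)
  for (i in seq_len(nrow(x))) {
    cat(paste(c(rownames(x)[i], sprintf("%.5f", rd$mz[i]),
                sprintf("%.3f", rd$rt[i]), rd$mode[i], rd$ms2[i],
                sprintf("%.4f", a[i, ])), collapse = "\t"),
        "\n", sep = "", file = con)
  }
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  roleLine <- strsplit(sub("^#role\t*", "", lines[1]), "\t")[[1]]
  batchLine <- strsplit(sub("^#batch\t*", "", lines[2]), "\t")[[1]]
  body <- utils::read.delim(text = lines[-(1:2)], stringsAsFactors = FALSE,
                            check.names = FALSE)
  meta <- body[, 1:5]
  areas <- as.matrix(body[, -(1:5), drop = FALSE])
  rownames(areas) <- meta$feature_id
  featureTable(areas, mz = meta$average_mz, rt = meta$average_rt_min,
               mode = meta$mode, ms2 = ifelse(is.na(meta$ms2), "", meta$ms2),
               role = roleLine, batch = as.integer(batchLine))
}

#' Write a quantified concentration matrix as tidy delimited text
#'
#' One row per (analyte, sample): analyte, sample, value, status, mloq, class.
#'
#' @param x a [ConcentrationMatrix-class].
#' @param path file path.
#' @export
writeConcentrations <- function(x, path) {
  stopifnot(is(x, "ConcentrationMatrix"))
  conc <- assay(x, "conc"); st <- assay(x, "status")
  rd <- rowData(x)
  long <- data.frame(
    analyte = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    value = as.vector(conc), status = as.vector(st),
    mloq = rep(rd$mloq, times = ncol(x)),
    class = rep(rd$class, times = ncol(x)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
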