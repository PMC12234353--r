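#' Proton mass used in neutral-mass arithmetic
#'
#' Mass of a proton in Daltons, used to convert measured ion m/z to neutral
#' mass M: M = m/z - 1.007276 for \[M+H\]+ and M = m/z + 1.007276 for
#' \[M-H\]-.
#'
#' @export
PROTON_MASS <- 1.007276

#' Derive a child seed from a master seed
#'
#' Modules of the pipeline draw their randomness from child seeds derived
#' deterministically from one master seed plus a counter, so any stage can be
#' regenerated in isolation. The derivation keeps seeds within the 32-bit
#' integer range R requires.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed.
#' @examples
#' childSeed(1, 0)
#' childSeed(1, 3)
#' @export
childSeed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  as.integer((abs(master) + 1000003 * counter) %% (.Machine$integer.max - 1L) + 1L)
}

#' Parse a packed MS2 spectrum string
#'
#' Spectra travel through delimited feature tables as space-separated
#' "mz:intensity" pairs. Returns a two-column matrix (mz, intensity).
#'
#' @param x a single spectrum string, possibly empty.
#' @return numeric matrix with columns \code{mz} and \code{intensity}.
#' @export
parseSpectrum <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x))) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("mz", "intensity"))))
  }
  pairs <- strsplit(trimws(x), "\\s+")[[1]]
  parts <- do.call(rbind, strsplit(pairs, ":", fixed = TRUE))
  m <- cbind(mz = as.numeric(parts[, 1]), intensity = as.numeric(parts[, 2]))
  if (anyNA(m)) stop("malformed spectrum string: ", x)
  m
}

#' Pack an MS2 peak list into a spectrum string
#'
#' @param mz numeric vector of fragment m/z values.
#' @param intensity matching intensities.
#' @return a single "mz:intensity mz:intensity ..." string.
#' @export
formatSpectrum <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) == 0L) return("")
  paste(sprintf("%.5f:%.1f", mz, intensity), collapse = " ")
}

# internal: stop() with call. = FALSE everywhere
abort <- function(...) stop(..., call. = FALSE)
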