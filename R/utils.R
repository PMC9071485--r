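## Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats aggregate coef lm median prcomp quantile residuals
#'   rnorm rpois runif setNames var
#' @importFrom utils head read.delim write.table
#' @importFrom graphics hist
NULL

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string into operations and lengths
#'
#' @param cigar a single CIGAR string, e.g. \code{"20M5S"}.
#' @return list with integer \code{lengths} and character \code{ops}.
#' @keywords internal
.parseCigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*")
    stop("malformed CIGAR: '", cigar, "'")
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: '", cigar, "'")
  ops <- substring(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  if (any(!ops %in% CIGAR_OPS)) stop("malformed CIGAR: '", cigar, "'")
  list(lengths = lens, ops = ops)
}

## Vectorised clip/width bookkeeping for a character vector of CIGARs.
## Returns a data.frame with leading/trailing soft- and hard-clip lengths,
## the query width (all query-consuming ops) and the reference width.
.cigarTable <- function(cigars) {
  n <- length(cigars)
  out <- data.frame(lead_s = integer(n), trail_s = integer(n),
                    lead_h = integer(n), trail_h = integer(n),
                    qwidth = integer(n), rwidth = integer(n))
  parsed <- lapply(cigars, .parseCigar)
  for (i in seq_len(n)) {
    p <- parsed[[i]]
    ops <- p$ops; lens <- p$lengths
    out$qwidth[i] <- sum(lens[ops %in% QUERY_OPS])
    out$rwidth[i] <- sum(lens[ops %in% REF_OPS])
    k <- length(ops)
    j1 <- 1L
    if (ops[1L] == "H") { out$lead_h[i] <- lens[1L]; j1 <- 2L }
    j2 <- k
    if (ops[k] == "H") { out$trail_h[i] <- lens[k]; j2 <- k - 1L }
    if (j2 >= j1 && ops[j2] == "S") out$trail_s[i] <- lens[j2]
    if (j1 < j2 && ops[j1] == "S") out$lead_s[i] <- lens[j1]
  }
  out
}

## Reverse complement a character vector of DNA strings (keeps N).
.revComp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x) & !is.na(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

## Count A's in a string vector (N and every other base count as non-A).
.countA <- function(x) {
  nchar(x) - nchar(gsub("A", "", x, fixed = TRUE))
}

## Run body with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Geometric mean
#'
#' \code{exp(mean(log(x)))}; used throughout for per-gene poly(A) tail
#' lengths, which are lognormal-like so the geometric mean is the natural
#' location summary.
#'
#' @param x positive numeric vector.
#' @return the geometric mean of \code{x}.
#' @examples
#' geomMean(c(10, 1000))  # 100
#' @export
geomMean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(x > 0))
  exp(mean(log(x)))
}

#' Report a percentage ratio
#'
#' Plumbing helper used by the gene-set ledger: \code{100 * num / den}
#' rounded to one decimal, the form in which derivation fractions are
#' reported.
#'
#' @param numerator,denominator non-negative counts; \code{denominator > 0}.
#' @return percentage rounded to one decimal place.
#' @examples
#' summarizeRatio(1236, 4161)  # 29.7
#' @export
summarizeRatio <- function(numerator, denominator) {
  stopifnot(length(numerator) == 1L, length(denominator) == 1L)
  if (denominator <= 0) stop("denominator must be > 0")
  round(100 * numerator / denominator, 1L)
}
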