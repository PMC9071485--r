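# Fixture builders and an independent brute-force tail oracle.

# One aligned-read row in the readAlignments() layout.
makeRead <- function(read_id, seq, cigar, is_reverse = FALSE,
                     ref_name = "chr1", ref_start = 100L,
                     passes = 10L) {
  S4Vectors::DataFrame(read_id = read_id, seq = seq, cigar = cigar,
                       is_reverse = is_reverse, ref_name = ref_name,
                       ref_start = as.integer(ref_start),
                       passes = as.integer(passes))
}

toyAnnotation <- function() {
  GenomicRanges::GRanges(
    seqnames = c("chr1", "chr1", "chr2"),
    ranges = IRanges::IRanges(start = c(1L, 901L, 1L),
                              width = c(1000L, 400L, 500L)),
    strand = c("+", "+", "-"),
    gene_id = c("G1", "G2", "G3"))
}

# Brute-force oracle: re-derives the 3' tail from (sequence, CIGAR) by
# explicit character-walk position arithmetic, independent of the package's
# vectorised implementation. Returns the A-tract-extended tail length.
oracleTailLength <- function(seq, cigar, is_reverse) {
  ops <- character(0); lens <- integer(0)
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) {
      num <- paste0(num, ch)
    } else {
      ops <- c(ops, ch); lens <- c(lens, as.integer(num)); num <- ""
    }
  }
  consumes <- ops %in% c("M", "I", "S", "=", "X")
  # query positions of each op
  qstart <- cumsum(c(1L, ifelse(consumes, lens, 0L)))[seq_along(ops)]
  qend <- qstart + ifelse(consumes, lens, 0L) - 1L
  n <- length(ops)
  lead_s <- if (ops[1] == "S") lens[1] else
    if (ops[1] == "H" && n > 1 && ops[2] == "S") lens[2] else 0L
  trail_s <- if (ops[n] == "S") lens[n] else
    if (ops[n] == "H" && n > 1 && ops[n - 1] == "S") lens[n - 1] else 0L
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }
  if (is_reverse) {
    tail <- if (lead_s > 0) revcomp(substr(seq, 1, lead_s)) else ""
    aligned <- revcomp(substr(seq, lead_s + 1, nchar(seq) - trail_s))
  } else {
    tail <- if (trail_s > 0)
      substr(seq, nchar(seq) - trail_s + 1, nchar(seq)) else ""
    aligned <- substr(seq, lead_s + 1, nchar(seq) - trail_s)
  }
  if (nchar(tail) == 0) return(0L)
  # A-tract extension by explicit backwards walk
  i <- nchar(aligned)
  moved <- 0L
  while (i >= 1 && substr(aligned, i, i) == "A") {
    moved <- moved + 1L
    i <- i - 1L
  }
  nchar(tail) + moved
}
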