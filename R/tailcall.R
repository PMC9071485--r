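## Poly(A) tail calling from aligned long-read (CCS) records.
##
## The 3' poly(A) tail of a long read survives alignment as a soft clip at
## the transcript 3' end. Calling a tail is: extract that clip, rescue
## upstream A's that the aligner absorbed into the reference match
## (A-tract extension), then apply quality rules: discard reads with no 3'
## clip, reject tails with fewer than 4 A's among the first 8 bases, and
## optionally drop reads with too few CCS passes.

#' Extract the candidate 3' poly(A) tail from one aligned read
#'
#' Returns the soft-clipped segment at the transcript 3' end in transcript
#' orientation: the trailing soft clip of the stored sequence for a
#' forward-strand alignment, or the reverse complement of the leading soft
#' clip for a reverse-strand alignment. The sequence must be stored in
#' alignment orientation, as in SAM.
#'
#' @param seq the read sequence as stored in the alignment record.
#' @param cigar the CIGAR string.
#' @param isReverse logical; \code{TRUE} for a reverse-strand alignment.
#' @return the candidate tail string; \code{""} when the read has no 3'
#'   soft clip. A hard clip at the transcript 3' end means the tail
#'   sequence is unavailable; the read is flagged unusable with a warning
#'   and \code{""} is returned.
#' @examples
#' extractSoftClipTail(paste0(strrep("ACGT", 5), "AAAAA"), "20M5S", FALSE)
#' @export
extractSoftClipTail <- function(seq, cigar, isReverse) {
  stopifnot(length(seq) == 1L, length(cigar) == 1L, length(isReverse) == 1L)
  ct <- .cigarTable(cigar)
  if ((isReverse && ct$lead_h > 0L) || (!isReverse && ct$trail_h > 0L)) {
    warning("hard clip at the transcript 3' end: tail sequence unavailable")
    return("")
  }
  if (ct$qwidth != nchar(seq))
    stop("sequence length does not match the CIGAR query width")
  if (isReverse) {
    if (ct$lead_s == 0L) return("")
    .revComp(substr(seq, 1L, ct$lead_s))
  } else {
    if (ct$trail_s == 0L) return("")
    substr(seq, nchar(seq) - ct$trail_s + 1L, nchar(seq))
  }
}

#' Rescue aligner-absorbed A's at the tail boundary
#'
#' Aligners routinely place the first bases of a poly(A) tail inside the
#' reference match when the 3' UTR happens to end in A's. The maximal run
#' of consecutive A's at the 3' end of the aligned query suffix (transcript
#' orientation) is moved onto the front of the candidate tail. A suffix not
#' ending in A leaves the tail unchanged; N never extends a run.
#'
#' Idempotent: applying it to its own output changes nothing, because the
#' donated suffix no longer ends in A.
#'
#' @param alignedSuffix aligned (non-clipped) query sequence immediately
#'   upstream of the tail, transcript orientation.
#' @param candidateTail the candidate tail from
#'   \code{\link{extractSoftClipTail}}.
#' @return the extended tail string.
#' @examples
#' extendATract("GCGAAA", "AAAAA")  # "AAAAAAAA"
#' extendATract("GACT", "AAAA")     # unchanged
#' @export
extendATract <- function(alignedSuffix, candidateTail) {
  stopifnot(length(alignedSuffix) == 1L, length(candidateTail) == 1L)
  m <- regexpr("A+$", alignedSuffix)
  if (m < 0L) return(candidateTail)
  paste0(substring(alignedSuffix, m), candidateTail)
}

## Vectorised extension used by callTails.
.extendATracts <- function(suffixes, tails) {
  m <- regexpr("A+$", suffixes)
  hit <- m > 0L
  tails[hit] <- paste0(substring(suffixes[hit], m[hit]), tails[hit])
  tails
}

#' Classify a candidate poly(A) tail
#'
#' Applies the tail-quality rules to an (already A-tract-extended)
#' candidate tail: an empty tail is \code{REJECTED_NO_CLIP} (the read has
#' no poly(A) tail); fewer than 4 A's among the first \code{min(8, length)}
#' bases is \code{REJECTED_LOW_A} (so any tail shorter than 4 nt fails);
#' otherwise, when pass filtering is on and the pass count is known and
#' below \code{minPasses}, \code{FILTERED_LOW_PASS}; else \code{ACCEPTED}.
#' Exactly 4 A's in the first 8 passes the rule (fewer than 4 fails).
#'
#' @param candidateTail tail string over A/C/G/T/N.
#' @param passes CCS pass count; \code{NA} when the record carries none.
#' @param minPasses minimum pass count, default 7 (a read with >= 7 passes
#'   is kept).
#' @param passFilter logical; apply the pass filter at all.
#' @return a list with \code{status}, \code{tail_seq}, \code{tail_len}.
#' @examples
#' classifyTail("AAAATTTT", passes = 10)$status  # "ACCEPTED"
#' classifyTail("AACGTGCTAAAA", passes = 10)$status  # "REJECTED_LOW_A"
#' @export
classifyTail <- function(candidateTail, passes = NA_integer_, minPasses = 7L,
                         passFilter = TRUE) {
  stopifnot(length(candidateTail) == 1L)
  if (grepl("[^ACGTN]", candidateTail))
    stop("tail contains characters outside A/C/G/T/N")
  status <- .classifyTails(candidateTail, passes, minPasses, passFilter)
  list(status = status, tail_seq = candidateTail,
       tail_len = nchar(candidateTail))
}

.classifyTails <- function(tails, passes, minPasses, passFilter) {
  len <- nchar(tails)
  nA <- .countA(substr(tails, 1L, 8L))
  status <- rep("ACCEPTED", length(tails))
  lowpass <- passFilter & !is.na(passes) & passes < minPasses
  status[lowpass] <- "FILTERED_LOW_PASS"
  status[nA < 4L] <- "REJECTED_LOW_A"
  status[len == 0L] <- "REJECTED_NO_CLIP"
  status
}

#' Assign aligned reads to genes by strand-aware overlap
#'
#' Each read's aligned reference span is matched against the gene
#' annotation on the same reference and strand. When several genes
#' overlap, the gene with the largest overlap wins; exact ties go to the
#' lexicographically smallest gene id. Reads overlapping no gene (or on a
#' reference absent from the annotation) are unassigned (\code{NA}).
#'
#' @param reads a \code{DataFrame}/data.frame of aligned reads with columns
#'   \code{ref_name}, \code{ref_start} (0-based), \code{cigar},
#'   \code{is_reverse} — as produced by \code{\link{readAlignments}} —
#'   or a \code{GRanges} of read spans.
#' @param annotation a \code{GRanges} of gene intervals with a
#'   \code{gene_id} metadata column (see \code{\link{readAnnotation}}).
#' @return character vector of gene ids, \code{NA} where unassigned.
#' @export
assignToGene <- function(reads, annotation) {
  stopifnot(is(annotation, "GRanges"),
            "gene_id" %in% colnames(S4Vectors::mcols(annotation)))
  if (is(reads, "GRanges")) {
    spans <- reads
  } else {
    ct <- .cigarTable(reads$cigar)
    spans <- GenomicRanges::GRanges(
      seqnames = reads$ref_name,
      ranges = IRanges::IRanges(start = reads$ref_start + 1L,
                                width = pmax(ct$rwidth, 1L)),
      strand = ifelse(reads$is_reverse, "-", "+"))
  }
  GenomeInfoDb::seqlevels(spans) <-
    union(GenomeInfoDb::seqlevels(spans), GenomeInfoDb::seqlevels(annotation))
  GenomeInfoDb::seqlevels(annotation) <- GenomeInfoDb::seqlevels(spans)
  hits <- GenomicRanges::findOverlaps(spans, annotation,
                                      ignore.strand = FALSE)
  gene <- rep(NA_character_, length(spans))
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(spans)[S4Vectors::queryHits(hits)],
      IRanges::ranges(annotation)[S4Vectors::subjectHits(hits)]))
    gid <- annotation$gene_id[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    ## order: per read, decreasing overlap then gene id; first wins
    o <- order(qh, -ov, gid, method = "radix")
    keep <- !duplicated(qh[o])
    gene[qh[o][keep]] <- gid[o][keep]
  }
  gene
}

#' Call poly(A) tails for a table of aligned reads
#'
#' Runs the full per-read pipeline: 3'-clip extraction, A-tract extension,
#' tail classification, and (optionally) gene assignment. Reads whose
#' transcript-3' end is hard-clipped have no recoverable tail sequence and
#' are classified \code{REJECTED_NO_CLIP}.
#'
#' @param reads \code{DataFrame}/data.frame with columns \code{read_id},
#'   \code{seq}, \code{cigar}, \code{is_reverse}, \code{ref_name},
#'   \code{ref_start}, and optionally \code{passes}; see
#'   \code{\link{readAlignments}}.
#' @param annotation optional \code{GRanges} gene annotation for
#'   assignment.
#' @param minPasses minimum CCS pass count (default 7, inclusive).
#' @param passFilter logical; apply the pass filter to all reads (default
#'   \code{TRUE}).
#' @return a \code{\linkS4class{TailCallSet}}.
#' @export
callTails <- function(reads, annotation = NULL, minPasses = 7L,
                      passFilter = TRUE) {
  reads <- as.data.frame(reads)
  n <- nrow(reads)
  passes <- if ("passes" %in% names(reads)) reads$passes
            else rep(NA_integer_, n)

  ct <- .cigarTable(reads$cigar)
  bad <- ct$qwidth != nchar(reads$seq)
  if (any(bad))
    stop("sequence length does not match CIGAR query width for read(s): ",
         paste(head(reads$read_id[bad], 5L), collapse = ", "))

  rev <- as.logical(reads$is_reverse)
  ## transcript-oriented sequence and 3'/5' clip lengths
  tseq <- reads$seq
  tseq[rev] <- .revComp(tseq[rev])
  clip3 <- ifelse(rev, ct$lead_s, ct$trail_s)
  clip5 <- ifelse(rev, ct$trail_s, ct$lead_s)
  hard3 <- ifelse(rev, ct$lead_h, ct$trail_h) > 0L
  clip3[hard3] <- 0L

  len <- nchar(tseq)
  tails <- substr(tseq, len - clip3 + 1L, len)
  tails[clip3 == 0L] <- ""
  suffixes <- substr(tseq, clip5 + 1L, len - clip3)
  has <- clip3 > 0L
  tails[has] <- .extendATracts(suffixes[has], tails[has])

  status <- .classifyTails(tails, passes, minPasses, passFilter)
  tails[status == "REJECTED_NO_CLIP"] <- ""

  gene <- if (!is.null(annotation)) assignToGene(reads, annotation)
          else rep(NA_character_, n)

  calls <- S4Vectors::DataFrame(
    read_id = as.character(reads$read_id), gene_id = gene,
    tail_seq = tails, tail_len = nchar(tails),
    passes = as.integer(passes), status = status)

  audit <- data.frame(
    stage = "tailcall",
    rule = c("has_3prime_soft_clip", "min_4A_in_first_8bp",
             paste0("passes_ge_", minPasses), "accepted"),
    n_in = c(n,
             sum(status != "REJECTED_NO_CLIP"),
             sum(!status %in% c("REJECTED_NO_CLIP", "REJECTED_LOW_A")),
             n),
    n_out = c(sum(status != "REJECTED_NO_CLIP"),
              sum(!status %in% c("REJECTED_NO_CLIP", "REJECTED_LOW_A")),
              sum(status == "ACCEPTED"),
              sum(status == "ACCEPTED")))

  new("TailCallSet", calls = calls,
      params = list(min_passes = as.integer(minPasses),
                    pass_filter = passFilter),
      audit = audit)
}

#' Summarise accepted tails per gene
#'
#' Per-gene poly(A) tail statistics over \code{ACCEPTED} calls: transcript
#' count, geometric mean of tail lengths (tail-length distributions are
#' lognormal-like, so the geometric mean is the location summary), and the
#' raw lengths. Genes with fewer than \code{minTranscripts} accepted tails
#' are dropped; unassigned reads are ignored.
#'
#' @param x a \code{\linkS4class{TailCallSet}} (or a data.frame of calls
#'   with \code{gene_id}, \code{tail_len}, \code{status}).
#' @param minTranscripts per-gene transcript floor, default 10.
#' @return a \code{\linkS4class{GeneTailSummary}}.
#' @export
summarizeGeneTails <- function(x, minTranscripts = 10L) {
  calls <- if (is(x, "TailCallSet")) as.data.frame(x@calls)
           else as.data.frame(x)
  acc <- calls[calls$status == "ACCEPTED" & !is.na(calls$gene_id), ,
               drop = FALSE]
  lens <- split(acc$tail_len, acc$gene_id)
  lens <- lens[lengths(lens) >= minTranscripts]
  gm <- vapply(lens, function(v) exp(mean(log(v))), numeric(1))
  s <- S4Vectors::DataFrame(
    gene_id = names(lens),
    n_transcripts = lengths(lens),
    geom_mean_len = unname(gm),
    tail_lengths = I(unname(lens)))
  rownames(s) <- NULL
  new("GeneTailSummary", summary = s,
      min_transcripts = as.integer(minTranscripts))
}

#' Compare poly(A) tail lengths between two conditions
#'
#' Builds the standard two-condition comparison: a pairwise table of
#' per-gene geometric means over genes summarised in both conditions,
#' condition medians of those geometric means, transcript-level tail-length
#' fractions over user-supplied bins (e.g. 5-90 and 90-200 nt), and the
#' quantile-trimmed support of each condition's tail-length distribution
#' (by default the central 96%, i.e. a 2% cutoff at each end).
#'
#' @param summaryA,summaryB \code{\linkS4class{GeneTailSummary}} objects
#'   for the two conditions (processed with identical parameters).
#' @param callsA,callsB the corresponding \code{\linkS4class{TailCallSet}}
#'   objects (transcript-level histograms use all accepted tails).
#' @param bins numeric vector of bin breakpoints, default
#'   \code{c(5, 90, 200)}.
#' @param trimQuantile symmetric trim fraction for the reported support,
#'   default 0.02.
#' @return a \code{\linkS4class{TailComparison}}.
#' @export
compareTailConditions <- function(summaryA, summaryB, callsA, callsB,
                                  bins = c(5, 90, 200),
                                  trimQuantile = 0.02) {
  stopifnot(is(summaryA, "GeneTailSummary"), is(summaryB, "GeneTailSummary"))
  sA <- as.data.frame(summaryA@summary[, c("gene_id", "geom_mean_len")])
  sB <- as.data.frame(summaryB@summary[, c("gene_id", "geom_mean_len")])
  shared <- merge(sA, sB, by = "gene_id", suffixes = c("_A", "_B"))
  if (!nrow(shared)) warning("no genes summarised in both conditions")
  perGene <- S4Vectors::DataFrame(
    gene_id = shared$gene_id,
    geom_mean_A = shared$geom_mean_len_A,
    geom_mean_B = shared$geom_mean_len_B)

  lensA <- acceptedCalls(callsA)$tail_len
  lensB <- acceptedCalls(callsB)$tail_len
  binFrac <- function(lens) {
    inb <- lens[lens >= min(bins) & lens <= max(bins)]
    h <- hist(inb, breaks = bins, plot = FALSE, right = FALSE,
              include.lowest = TRUE)
    h$counts / max(1L, length(inb))
  }
  bf <- cbind(A = binFrac(lensA), B = binFrac(lensB))
  rownames(bf) <- paste0("[", bins[-length(bins)], ",", bins[-1L], ")")
  supp <- cbind(
    A = unname(quantile(lensA, c(trimQuantile, 1 - trimQuantile))),
    B = unname(quantile(lensB, c(trimQuantile, 1 - trimQuantile))))
  rownames(supp) <- c("lower", "upper")

  new("TailComparison", per_gene = perGene,
      median_A = median(shared$geom_mean_len_A),
      median_B = median(shared$geom_mean_len_B),
      bin_fractions = bf, support = supp,
      trim_quantile = trimQuantile)
}
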