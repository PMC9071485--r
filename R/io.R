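## Readers, writers and the umbrella pipeline runner.

#' Read aligned long-read records from a SAM file
#'
#' Loads primary, non-duplicate alignments (secondary, supplementary and
#' duplicate-flagged records are dropped — standard de-duplication), with
#' sequence, CIGAR, strand flag, 0-based reference start and the optional
#' CCS pass-count tag. The file must carry a header with \code{@SQ} lines;
#' conversion and parsing go through Rsamtools.
#'
#' @param path path to a SAM (or BAM) file with a header.
#' @param passTag name of the integer pass-count tag, default \code{"np"}.
#' @return a \code{DataFrame} with columns \code{read_id}, \code{seq},
#'   \code{cigar}, \code{is_reverse}, \code{ref_name}, \code{ref_start}
#'   (0-based), \code{passes} (\code{NA} where the tag is absent).
#' @export
readAlignments <- function(path, passTag = "np") {
  if (!file.exists(path)) stop("cannot read alignments: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"),
    tag = passTag)
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  passes <- res$tag[[passTag]]
  if (is.null(passes)) passes <- rep(NA_integer_, length(res$qname))
  S4Vectors::DataFrame(
    read_id = res$qname,
    seq = as.character(res$seq),
    cigar = res$cigar,
    is_reverse = as.character(res$strand) == "-",
    ref_name = as.character(res$rname),
    ref_start = res$pos - 1L,
    passes = as.integer(passes))
}

#' Read a gene annotation as strand-annotated intervals
#'
#' BED6 (0-based half-open) or GFF3 (1-based closed) gene intervals,
#' imported with rtracklayer; both arrive as \code{GRanges} (1-based
#' closed internally, the Bioconductor convention) with a \code{gene_id}
#' metadata column taken from the BED name field or the GFF3 \code{ID} /
#' \code{gene_id} / \code{Name} attribute.
#'
#' @param path annotation file path.
#' @param format \code{"bed"}, \code{"gff3"} or \code{"auto"} (by
#'   extension).
#' @return a \code{GRanges} with a \code{gene_id} column. An empty file
#'   yields an empty \code{GRanges} with a warning.
#' @export
readAnnotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) {
                   if (length(readLines(path, warn = FALSE)) == 0L)
                     GenomicRanges::GRanges()
                   else stop(e)
                 })
  if (!length(gr)) {
    warning("empty annotation: ", path)
    gr$gene_id <- character(0)
    return(gr)
  }
  mc <- S4Vectors::mcols(gr)
  gid <- if ("name" %in% colnames(mc)) mc$name
         else if ("gene_id" %in% colnames(mc)) mc$gene_id
         else if ("ID" %in% colnames(mc)) mc$ID
         else if ("Name" %in% colnames(mc)) mc$Name
         else stop("annotation has no usable gene identifier column")
  gr$gene_id <- as.character(gid)
  if ("type" %in% colnames(mc) && any(mc$type == "gene", na.rm = TRUE))
    gr <- gr[!is.na(mc$type) & mc$type == "gene"]
  gr
}

#' Write simulated alignments as a SAM file
#'
#' Emits a headered SAM file (one \code{@SQ} line per reference) from the
#' read table layout of \code{\link{simulateTailedReads}} /
#' \code{\link{readAlignments}}, with the pass count in an integer tag.
#'
#' @param reads read table (\code{DataFrame}/data.frame).
#' @param path output path.
#' @param refLengths named vector of reference lengths; defaults to a
#'   length covering every alignment.
#' @param passTag pass-count tag name, default \code{"np"}.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(reads, path, refLengths = NULL, passTag = "np") {
  reads <- as.data.frame(reads)
  ct <- .cigarTable(reads$cigar)
  if (is.null(refLengths)) {
    ends <- tapply(reads$ref_start + ct$rwidth, reads$ref_name, max)
    refLengths <- setNames(as.integer(ends + 1000L), names(ends))
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                      as.integer(refLengths)))
  flagv <- ifelse(reads$is_reverse, 16L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                   reads$read_id, flagv, reads$ref_name,
                   reads$ref_start + 1L, reads$cigar, reads$seq)
  if ("passes" %in% names(reads)) {
    hasP <- !is.na(reads$passes)
    lines[hasP] <- paste0(lines[hasP], sprintf("\t%s:i:%d", passTag,
                                               reads$passes[hasP]))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a GRanges annotation as BED6
#'
#' @param annotation \code{GRanges} with a \code{gene_id} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(annotation, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation) - 1L,
    end = GenomicRanges::end(annotation),
    name = annotation$gene_id,
    score = 0L,
    strand = as.character(GenomicRanges::strand(annotation)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write per-read and per-gene tail tables as TSV
#'
#' @param calls a \code{\linkS4class{TailCallSet}}.
#' @param summary a \code{\linkS4class{GeneTailSummary}}.
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
writeTailTables <- function(calls, summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readsPath <- file.path(dir, "tail_calls.tsv")
  genesPath <- file.path(dir, "gene_tails.tsv")
  cc <- as.data.frame(tailCalls(calls))
  write.table(cc[, c("read_id", "gene_id", "tail_len", "status", "passes")],
              readsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- as.data.frame(tailSummary(summary))
  write.table(ss[, c("gene_id", "n_transcripts", "geom_mean_len")],
              genesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(readsPath, genesPath))
}

#' Run the tail-calling stage end to end
#'
#' Reads alignments and annotation from disk (or takes them in memory),
#' calls tails, summarises genes, writes the TSV outputs and returns a run
#' report in which every read entering a filter is accounted for in
#' exactly one outcome count.
#'
#' @param alignments SAM path or a read table.
#' @param annotation annotation path or a \code{GRanges}.
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @param minPasses,passFilter see \code{\link{callTails}}.
#' @param minTranscripts see \code{\link{summarizeGeneTails}}.
#' @return list with \code{calls}, \code{summary}, \code{audit} and
#'   \code{counts} (named totals per status).
#' @export
runTailPipeline <- function(alignments, annotation, outDir = NULL,
                            minPasses = 7L, passFilter = TRUE,
                            minTranscripts = 10L) {
  reads <- if (is.character(alignments)) readAlignments(alignments)
           else alignments
  anno <- if (is.character(annotation)) readAnnotation(annotation)
          else annotation
  calls <- callTails(reads, anno, minPasses = minPasses,
                     passFilter = passFilter)
  summary <- summarizeGeneTails(calls, minTranscripts = minTranscripts)
  counts <- table(factor(tailCalls(calls)$status, levels = TAIL_STATUSES))
  if (!is.null(outDir)) writeTailTables(calls, summary, outDir)
  list(calls = calls, summary = summary, audit = auditLog(calls),
       counts = c(as.list(counts),
                  n_reads = nrow(tailCalls(calls)),
                  n_genes_summarised = nrow(tailSummary(summary))))
}
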