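## Seeded simulators with truth tables for every pipeline stage:
## tailed long-read alignments (SAM), transcription-shutoff decay series,
## and clustered two-condition expression time courses.

#' Configuration for the tailed-read simulator
#'
#' Defaults describe a realistic two-condition PAIso-seq-like experiment
#' at desk scale: 500 genes, 200 CCS reads per gene, per-gene geometric
#' mean tail lengths spread lognormally around 85 nt, per-read lognormal
#' tail-length spread, a 1% per-base substitution error inside the tail,
#' 20% reverse-strand alignments, a small fraction of tail-less reads,
#' and Poisson-distributed CCS pass counts.
#'
#' @param nGenes number of genes.
#' @param readsPerGene reads simulated per gene.
#' @param geomMean target geometric-mean tail length (nt); scalar (per-gene
#'   means are drawn around it) or a length-\code{nGenes} vector of exact
#'   per-gene geometric means.
#' @param geneLogSigma log-scale SD of per-gene geometric means around
#'   \code{geomMean} (ignored when \code{geomMean} is a vector).
#' @param readLogSigma log-scale SD of per-read tail lengths around the
#'   gene's geometric mean.
#' @param errorRate per-base substitution probability inside the tail.
#' @param fracReverse fraction of reads stored as reverse-strand
#'   alignments.
#' @param noTailFrac fraction of reads emitted without a 3' soft clip.
#' @param passLambda Poisson mean of CCS pass counts.
#' @param bodyLength aligned (non-tail) read length in nt.
#' @param seed RNG seed fixing all randomness.
#' @return a list of class \code{tailSimConfig}.
#' @export
tailSimConfig <- function(nGenes = 500L, readsPerGene = 200L, geomMean = 85,
                          geneLogSigma = 0.25, readLogSigma = 0.4,
                          errorRate = 0.01, fracReverse = 0.2,
                          noTailFrac = 0.05, passLambda = 15,
                          bodyLength = 200L, seed = 1L) {
  stopifnot(nGenes >= 1L, readsPerGene >= 1L, all(geomMean > 0),
            errorRate >= 0, errorRate <= 1, fracReverse >= 0,
            fracReverse <= 1, noTailFrac >= 0, noTailFrac <= 1)
  structure(list(nGenes = as.integer(nGenes),
                 readsPerGene = as.integer(readsPerGene),
                 geomMean = geomMean, geneLogSigma = geneLogSigma,
                 readLogSigma = readLogSigma, errorRate = errorRate,
                 fracReverse = fracReverse, noTailFrac = noTailFrac,
                 passLambda = passLambda, bodyLength = as.integer(bodyLength),
                 seed = as.integer(seed)),
            class = "tailSimConfig")
}

## Annotation used by the simulator: one interval per gene on one
## reference, forward strand, 0-based half-open, spaced so reads from
## neighbouring genes never overlap.
.simAnnotation <- function(nGenes, strands = "+", geneWidth = 1000L,
                           gap = 1000L) {
  starts <- (seq_len(nGenes) - 1L) * (geneWidth + gap)
  GenomicRanges::GRanges(
    seqnames = "chrS1",
    ranges = IRanges::IRanges(start = starts + 1L, width = geneWidth),
    strand = strands,
    gene_id = sprintf("G%04d", seq_len(nGenes)))
}

#' Simulate tailed long-read alignments with a truth table
#'
#' Emits SAM-style alignment records whose 3' soft clips encode sampled
#' poly(A) tails. Per-read tail lengths are
#' \code{round(exp(Normal(ln(gm_gene), readLogSigma)))}, truncated at 1 nt
#' (tail-length distributions are lognormal-like). Substitution errors are
#' applied to tail bases only, at \code{errorRate} per base, replacing an A
#' with a uniformly chosen other base. A configured fraction of reads
#' carries no soft clip at all. Reverse-strand records store the reverse
#' complement with a leading soft clip, exercising the strand path. The
#' last aligned base of every read body is non-A so A-tract extension is
#' exact on error-free input. Byte-identical output for identical seeds.
#'
#' @param config a \code{\link{tailSimConfig}}.
#' @return list with \code{reads} (a \code{DataFrame} in the
#'   \code{\link{readAlignments}} layout), \code{annotation}
#'   (\code{GRanges}), \code{truth} (per-read data.frame with
#'   \code{read_id}, \code{gene_id}, \code{true_tail_len},
#'   \code{is_reverse}, \code{passes}, \code{has_tail}) and
#'   \code{gene_truth} (per-gene data.frame with the true geometric mean
#'   over reads emitted with a tail).
#' @export
simulateTailedReads <- function(config = tailSimConfig()) {
  stopifnot(inherits(config, "tailSimConfig"))
  .withSeed(config$seed, {
    nG <- config$nGenes; rpg <- config$readsPerGene
    n <- nG * rpg
    ## a fracReverse share of genes sits on the minus strand; their
    ## transcripts align reverse-flagged with the tail in the leading clip
    geneStrand <- ifelse(runif(nG) < config$fracReverse, "-", "+")
    anno <- .simAnnotation(nG, strands = geneStrand)

    gm <- if (length(config$geomMean) == nG) config$geomMean
          else exp(rnorm(nG, log(config$geomMean), config$geneLogSigma))
    geneIdx <- rep(seq_len(nG), each = rpg)
    tailLen <- pmax(1L, as.integer(round(
      exp(rnorm(n, log(gm[geneIdx]), config$readLogSigma)))))
    hasTail <- runif(n) >= config$noTailFrac
    tailLen[!hasTail] <- 0L
    isRev <- geneStrand[geneIdx] == "-"
    passes <- rpois(n, config$passLambda)

    bl <- config$bodyLength
    ## one body per gene (reads of a gene share the aligned sequence);
    ## last base forced non-A so A-tract extension is exact without noise
    geneBodies <- vapply(seq_len(nG), function(i) paste0(
      paste(sample(c("A", "C", "G", "T"), bl - 1L, replace = TRUE),
            collapse = ""),
      sample(c("C", "G", "T"), 1L)), character(1))
    bodies <- geneBodies[geneIdx]

    tails <- strrep("A", tailLen)
    if (config$errorRate > 0) {
      nt <- sum(tailLen)
      err <- runif(nt) < config$errorRate
      if (any(err)) {
        idx <- cumsum(c(0L, tailLen[-n]))
        tailChars <- strsplit(paste(tails, collapse = ""), "")[[1]]
        tailChars[err] <- sample(c("C", "G", "T"), sum(err), replace = TRUE)
        joined <- paste(tailChars, collapse = "")
        tails <- substring(joined, idx + 1L, idx + tailLen)
      }
    }

    tseq <- paste0(bodies, tails)  # transcript orientation
    seqs <- ifelse(isRev, .revComp(tseq), tseq)
    cig <- ifelse(tailLen > 0L,
                  ifelse(isRev, paste0(tailLen, "S", bl, "M"),
                         paste0(bl, "M", tailLen, "S")),
                  paste0(bl, "M"))
    geneStart <- GenomicRanges::start(anno)[geneIdx] - 1L  # 0-based
    offset <- sample.int(800L - bl + 1L, n, replace = TRUE) - 1L
    refStart <- geneStart + offset
    readId <- sprintf("read%06d", seq_len(n))

    reads <- S4Vectors::DataFrame(
      read_id = readId,
      seq = seqs,
      cigar = cig,
      is_reverse = isRev,
      ref_name = "chrS1",
      ref_start = refStart,
      passes = as.integer(passes))

    truth <- data.frame(read_id = readId,
                        gene_id = anno$gene_id[geneIdx],
                        true_tail_len = tailLen,
                        is_reverse = isRev,
                        passes = as.integer(passes),
                        has_tail = hasTail)
    tl <- split(tailLen[hasTail], anno$gene_id[geneIdx][hasTail])
    geneTruth <- data.frame(
      gene_id = names(tl),
      target_geom_mean = gm[match(names(tl), anno$gene_id)],
      true_geom_mean = vapply(tl, function(v) exp(mean(log(v))), numeric(1)),
      n_reads = lengths(tl), row.names = NULL)

    list(reads = reads, annotation = anno, truth = truth,
         gene_truth = geneTruth)
  })
}

#' Simulate transcription-shutoff decay series
#'
#' \code{C(t) = exp(-k t) * exp(Normal(0, noiseSigma))} per time point,
#' renormalised so the t = 0 value is exactly 1.
#'
#' @param kTrue per-gene true decay rates (per hour), \code{>= 0}.
#' @param timepoints hours, starting at 0; default \code{c(0, 2, 4)} (the
#'   usual actinomycin-D harvest points).
#' @param noiseSigma log-scale multiplicative noise SD.
#' @param seed RNG seed.
#' @return list with \code{series} (long data.frame: \code{gene},
#'   \code{timepoint_h}, \code{value}) and \code{truth} (\code{gene},
#'   \code{k_true}).
#' @export
simulateDecaySeries <- function(kTrue, timepoints = c(0, 2, 4),
                                noiseSigma = 0.05, seed = 1L) {
  stopifnot(all(kTrue >= 0), timepoints[1L] == 0)
  .withSeed(seed, {
    nG <- length(kTrue)
    genes <- sprintf("D%04d", seq_len(nG))
    grid <- expand.grid(gene_i = seq_len(nG), tp = timepoints,
                        KEEP.OUT.ATTRS = FALSE)
    mu <- exp(-kTrue[grid$gene_i] * grid$tp)
    val <- mu * exp(rnorm(nrow(grid), 0, noiseSigma))
    series <- data.frame(gene = genes[grid$gene_i],
                         timepoint_h = grid$tp, value = val)
    ## renormalise each gene so t = 0 is exactly 1
    v0 <- series$value[series$timepoint_h == 0]
    names(v0) <- series$gene[series$timepoint_h == 0]
    series$value <- series$value / v0[series$gene]
    series <- series[order(series$gene, series$timepoint_h), ]
    rownames(series) <- NULL
    list(series = series, truth = data.frame(gene = genes, k_true = kTrue))
  })
}

#' Simulate a clustered two-condition expression time course
#'
#' Generates counts for WT and KO samples over a five-point induction time
#' course with planted cluster structure: fractions of genes follow
#' monotone-down, flat and monotone-up log2 templates (steps of +/-1 log2
#' unit per interval, well above the default discretisation threshold),
#' with Gaussian noise on the log2 scale. A designated number of planted
#' monotone-down genes is "stabilised" in KO: their KO trajectory stops
#' falling after 12 h, so they surface in the 24 h and 48 h up-called sets
#' — the planted analogue of transcripts whose decay requires the
#' deadenylase.
#'
#' @param nGenes number of genes.
#' @param fractions named fractions for templates \code{down}, \code{flat},
#'   \code{up}; must sum to 1.
#' @param noiseSigma SD of log2-scale noise, default 0.2.
#' @param timepoints induction time points (hours), default
#'   \code{c(0, 6, 12, 24, 48)}.
#' @param nStabilized number of planted-down genes stabilised in KO.
#' @param nReplicates replicates per (condition, timepoint), default 2.
#' @param seed RNG seed.
#' @return list with \code{se} (a \code{SummarizedExperiment} with a
#'   \code{counts} assay, gene lengths in \code{rowData}, and
#'   \code{colData} columns \code{condition}, \code{timepoint_h},
#'   \code{replicate}) and \code{truth} (per-gene \code{cluster} label and
#'   \code{stabilized} flag).
#' @export
simulateExpressionTimecourse <- function(nGenes = 1000L,
                                         fractions = c(down = 0.4,
                                                       flat = 0.3,
                                                       up = 0.3),
                                         noiseSigma = 0.2,
                                         timepoints = c(0, 6, 12, 24, 48),
                                         nStabilized = 100L,
                                         nReplicates = 2L, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(c("down", "flat", "up") %in% names(fractions)))
  nT <- length(timepoints)
  if (nT < 3L) stop("need at least 3 time points")
  .withSeed(seed, {
    counts_per <- round(nGenes * fractions)
    counts_per["up"] <- nGenes - counts_per["down"] - counts_per["flat"]
    labels <- rep(c("down", "flat", "up"), counts_per)
    genes <- sprintf("E%05d", seq_len(nGenes))

    ## log2 count templates with +-1 steps per interval. The flat cluster
    ## sits well above the others so library totals stay nearly constant
    ## across time points and TPM renormalisation does not distort the
    ## planted steps.
    templates <- rbind(
      down = seq(7, 7 - (nT - 1L), by = -1),
      flat = rep(10, nT),
      up = seq(7 - (nT - 1L), 7, by = 1))
    base <- templates[labels, , drop = FALSE]  # log2 TPM-scale means

    stabilized <- rep(FALSE, nGenes)
    downIdx <- which(labels == "down")
    nStab <- min(nStabilized, length(downIdx))
    stabilized[downIdx[seq_len(nStab)]] <- TRUE

    cd <- expand.grid(replicate = seq_len(nReplicates),
                      timepoint_h = timepoints,
                      condition = c("WT", "KO"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cd <- cd[, c("condition", "timepoint_h", "replicate")]
    sampleId <- sprintf("%s_t%02d_r%d", cd$condition, cd$timepoint_h,
                        cd$replicate)

    mat <- matrix(0, nGenes, nrow(cd),
                  dimnames = list(genes, sampleId))
    late <- timepoints > 12
    for (j in seq_len(nrow(cd))) {
      tpIdx <- match(cd$timepoint_h[j], timepoints)
      mu <- base[, tpIdx]
      if (cd$condition[j] == "KO" && late[tpIdx]) {
        ## stabilised transcripts stop decaying after 12 h in KO
        hold <- base[, match(12, timepoints)]
        mu[stabilized] <- hold[stabilized]
      }
      lg <- mu + rnorm(nGenes, 0, noiseSigma)
      mat[, j] <- round(2^lg)
    }

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = mat),
      rowData = S4Vectors::DataFrame(length = rep(1000L, nGenes),
                                     cluster = labels,
                                     stabilized = stabilized),
      colData = S4Vectors::DataFrame(cd, row.names = sampleId))
    truth <- data.frame(gene = genes, cluster = labels,
                        stabilized = stabilized)
    list(se = se, truth = truth)
  })
}
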