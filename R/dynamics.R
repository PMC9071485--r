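## Time-course expression processing: TPM, threshold-based differential
## calls, sign-pattern temporal clustering, and PCA.

#' Convert a count matrix to TPM
#'
#' \code{TPM_gi = 1e6 * (count_gi / length_g) / sum_g(count_gi / length_g)}.
#' Every sample column of the result sums to one million.
#'
#' @param counts gene x sample matrix of non-negative counts, or a
#'   \code{SummarizedExperiment} with a \code{counts} assay and a gene
#'   length column (\code{length}) in \code{rowData}.
#' @param geneLengths gene lengths in nt (ignored for a
#'   \code{SummarizedExperiment} carrying them in \code{rowData}).
#' @return matrix of TPM values (or the \code{SummarizedExperiment} with a
#'   \code{tpm} assay added).
#' @examples
#' computeTpm(cbind(s1 = c(10, 90)), geneLengths = c(1000, 1000))
#' @export
computeTpm <- function(counts, geneLengths = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    se <- counts
    if (is.null(geneLengths))
      geneLengths <- SummarizedExperiment::rowData(se)$length
    tpm <- computeTpm(SummarizedExperiment::assay(se, "counts"), geneLengths)
    SummarizedExperiment::assay(se, "tpm") <- tpm
    return(se)
  }
  counts <- as.matrix(counts)
  stopifnot(!is.null(geneLengths), length(geneLengths) == nrow(counts),
            all(geneLengths > 0), all(counts >= 0))
  rate <- counts / geneLengths
  tot <- colSums(rate)
  if (any(tot <= 0)) stop("sample column with zero total (cannot scale)")
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Call differentially expressed genes by pure thresholds
#'
#' A gene is called up when \code{(TPM_KO + eps) / (TPM_WT + eps) > fc}
#' and \code{log2(max(TPM_KO, TPM_WT)) > exprLog2}; down is symmetric.
#' The pseudocount \code{eps} guards against zero division while leaving
#' the fold change essentially the TPM ratio for expressed genes; the
#' expression floor is applied to the larger of the two condition means.
#' Replicate means should be supplied.
#'
#' @param tpmKo,tpmWt named numeric vectors of per-gene TPM (replicate
#'   means) over the same gene universe.
#' @param fc fold-change threshold, default 1.5.
#' @param exprLog2 expression floor on log2 TPM, default 1.
#' @param pseudocount fold-change pseudocount, default 0.1.
#' @param timepoint time point (hours) carried into the result.
#' @return a \code{\linkS4class{DegResult}}.
#' @examples
#' callDegs(c(g = 8), c(g = 4))  # g is up
#' @export
callDegs <- function(tpmKo, tpmWt, fc = 1.5, exprLog2 = 1,
                     pseudocount = 0.1, timepoint = NA_real_) {
  stopifnot(length(tpmKo) == length(tpmWt))
  if (!is.null(names(tpmKo)) && !is.null(names(tpmWt))) {
    stopifnot(setequal(names(tpmKo), names(tpmWt)))
    tpmWt <- tpmWt[names(tpmKo)]
  }
  genes <- names(tpmKo)
  if (is.null(genes)) genes <- as.character(seq_along(tpmKo))
  ratio <- (tpmKo + pseudocount) / (tpmWt + pseudocount)
  expressed <- log2(pmax(tpmKo, tpmWt)) > exprLog2
  up <- genes[expressed & ratio > fc]
  down <- genes[expressed & ratio < 1 / fc]
  new("DegResult", timepoint_h = as.numeric(timepoint), up = up,
      down = down, fc_threshold = fc, expr_threshold_log2_tpm = exprLog2)
}

#' Per-timepoint differential calls from a time-course experiment
#'
#' Averages TPM over replicates within each (condition, timepoint) and
#' calls \code{\link{callDegs}} at every time point, KO vs WT.
#'
#' @param se a \code{SummarizedExperiment} with a \code{tpm} assay and
#'   \code{colData} columns \code{condition} (\code{"WT"}/\code{"KO"}),
#'   \code{timepoint_h} and \code{replicate}.
#' @param ... passed to \code{\link{callDegs}}.
#' @return named list of \code{\linkS4class{DegResult}}, one per time
#'   point (names are the time points in hours).
#' @export
degsByTimepoint <- function(se, ...) {
  cd <- SummarizedExperiment::colData(se)
  stopifnot(all(c("condition", "timepoint_h") %in% colnames(cd)))
  tpm <- SummarizedExperiment::assay(se, "tpm")
  tps <- sort(unique(cd$timepoint_h))
  res <- lapply(tps, function(tp) {
    ko <- rowMeans(tpm[, cd$condition == "KO" & cd$timepoint_h == tp,
                       drop = FALSE])
    wt <- rowMeans(tpm[, cd$condition == "WT" & cd$timepoint_h == tp,
                       drop = FALSE])
    callDegs(ko, wt, timepoint = tp, ...)
  })
  names(res) <- as.character(tps)
  res
}

#' Cluster temporal expression profiles by sign pattern
#'
#' Discretises each gene's per-interval log2 expression change into
#' \code{-}/\code{0}/\code{+} using \code{stepThreshold} and groups genes
#' sharing a sign pattern. Deterministic and auditable: the
#' continuous-downregulation cluster is exactly the all-\code{-} pattern.
#' The \code{nTop} most populous patterns are retained (ties broken by
#' pattern string) and the covered fraction of the gene universe is
#' reported.
#'
#' @param expr gene x timepoint matrix of expression (TPM or counts-like;
#'   replicate means), or a \code{SummarizedExperiment} with a \code{tpm}
#'   assay, in which case the WT samples are averaged per time point.
#' @param nTop number of clusters to retain, default 8.
#' @param stepThreshold minimum absolute log2 change per interval to call
#'   a step up or down, default 0.5.
#' @param pseudocount added before log2, default 1.
#' @param logScale set to \code{FALSE} if \code{expr} is already on the
#'   log2 scale.
#' @return a \code{\linkS4class{ProfileClusterSet}}.
#' @export
clusterProfiles <- function(expr, nTop = 8L, stepThreshold = 0.5,
                            pseudocount = 1, logScale = TRUE) {
  if (is(expr, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(expr)
    tpm <- SummarizedExperiment::assay(expr, "tpm")
    wt <- cd$condition == "WT"
    tps <- sort(unique(cd$timepoint_h[wt]))
    expr <- vapply(tps, function(tp)
      rowMeans(tpm[, wt & cd$timepoint_h == tp, drop = FALSE]),
      numeric(nrow(tpm)))
    colnames(expr) <- as.character(tps)
  }
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 time points")
  lg <- if (logScale) log2(expr + pseudocount) else expr
  d <- lg[, -1L, drop = FALSE] - lg[, -ncol(lg), drop = FALSE]
  sign_chr <- matrix("0", nrow(d), ncol(d))
  sign_chr[d > stepThreshold] <- "+"
  sign_chr[d < -stepThreshold] <- "-"
  patterns <- apply(sign_chr, 1L, paste, collapse = "")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expr)))
  members <- split(genes, patterns)
  sizes <- sort(lengths(members), decreasing = TRUE)
  ## deterministic tie-break: size desc, then pattern
  ord <- order(-lengths(members), names(members))
  members <- members[ord]
  keep <- head(members, nTop)
  meanProf <- t(vapply(names(keep), function(p)
    colMeans(lg[patterns == p, , drop = FALSE]), numeric(ncol(lg))))
  tab <- data.frame(pattern = names(keep), n = unname(lengths(keep)),
                    stringsAsFactors = FALSE)
  new("ProfileClusterSet", clusters = keep, pattern_table = tab,
      mean_profiles = meanProf,
      covered_fraction = sum(lengths(keep)) / length(genes),
      n_genes = length(genes))
}

#' Genes in the continuous-downregulation cluster
#'
#' Members of the all-\code{-} sign pattern: genes whose expression falls
#' at every interval of the normal differentiation time course, i.e. the
#' transcripts presumed to be degraded during the transition.
#'
#' @param clusters a \code{\linkS4class{ProfileClusterSet}}.
#' @return character vector of gene ids (empty, with a warning, when no
#'   all-down cluster was retained).
#' @export
degradationCluster <- function(clusters) {
  stopifnot(is(clusters, "ProfileClusterSet"))
  k <- nchar(clusters@pattern_table$pattern[1L])
  pattern <- strrep("-", k)
  if (!pattern %in% names(clusters@clusters)) {
    warning("no continuous-downregulation ('", pattern, "') cluster found")
    return(character(0))
  }
  clusters@clusters[[pattern]]
}

#' Project samples onto the top two principal components
#'
#' Genes are centred and scaled to unit variance (zero-variance genes are
#' dropped); samples are projected onto the first two principal axes and
#' the explained-variance fraction of every axis is reported.
#'
#' @param expr gene x sample matrix (TPM, typically log-scaled upstream),
#'   or a \code{SummarizedExperiment} with a \code{tpm} assay.
#' @return list with \code{coords} (sample x PC1/PC2 data.frame) and
#'   \code{explained_variance} (fractions, all axes). A constant matrix
#'   (no variable gene) is degenerate and raises an error.
#' @export
pcaProjection <- function(expr) {
  if (is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr, "tpm")
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  v <- apply(expr, 1L, var)
  keep <- is.finite(v) & v > 0
  if (!any(keep)) stop("degenerate input: no gene varies across samples")
  pc <- prcomp(t(expr[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.frame(sample = colnames(expr),
                       PC1 = pc$x[, 1L],
                       PC2 = if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0,
                       row.names = NULL)
  list(coords = coords, explained_variance = ev)
}
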