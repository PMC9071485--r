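## S4 containers for the pipeline's central results.

#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

TAIL_STATUSES <- c("ACCEPTED", "REJECTED_NO_CLIP", "REJECTED_LOW_A",
                   "FILTERED_LOW_PASS")

#' TailCallSet: per-read poly(A) tail calls
#'
#' One row per aligned long read, holding the classified 3' poly(A) tail:
#' the tail sequence (transcript 5'->3'), its length in nucleotides, the CCS
#' pass count, the assigned gene, and the accept/reject status. Built by
#' \code{\link{callTails}}. The \code{audit} slot records how many reads each
#' filter rule saw and passed, so the cascade is auditable.
#'
#' @slot calls a \code{DataFrame} with columns \code{read_id},
#'   \code{gene_id}, \code{tail_seq}, \code{tail_len}, \code{passes},
#'   \code{status}.
#' @slot params list of the parameters used (\code{min_passes},
#'   \code{pass_filter}).
#' @slot audit data.frame of filter audit counts (stage, rule, n_in, n_out).
#' @export
setClass("TailCallSet",
  representation(calls = "DataFrame", params = "list", audit = "data.frame"))

setValidity("TailCallSet", function(object) {
  cc <- object@calls
  need <- c("read_id", "gene_id", "tail_seq", "tail_len", "passes", "status")
  if (!all(need %in% colnames(cc)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (!all(cc$status %in% TAIL_STATUSES))
    return("unknown tail status")
  if (any(cc$tail_len != nchar(cc$tail_seq)))
    return("tail_len must equal nchar(tail_seq)")
  acc <- cc$status == "ACCEPTED"
  if (any(acc & cc$tail_len < 4L))
    return("ACCEPTED tails must be at least 4 nt")
  if (any(cc$status == "REJECTED_NO_CLIP" & cc$tail_len != 0L))
    return("REJECTED_NO_CLIP implies tail_len == 0")
  TRUE
})

#' GeneTailSummary: per-gene poly(A) tail statistics
#'
#' One row per gene with at least \code{min_transcripts} accepted tails:
#' the number of accepted transcripts, the geometric mean tail length and
#' the full list of tail lengths. Built by \code{\link{summarizeGeneTails}}.
#'
#' @slot summary a \code{DataFrame} with columns \code{gene_id},
#'   \code{n_transcripts}, \code{geom_mean_len} and a list column
#'   \code{tail_lengths}.
#' @slot min_transcripts the per-gene transcript-count floor applied.
#' @export
setClass("GeneTailSummary",
  representation(summary = "DataFrame", min_transcripts = "integer"))

setValidity("GeneTailSummary", function(object) {
  s <- object@summary
  need <- c("gene_id", "n_transcripts", "geom_mean_len", "tail_lengths")
  if (!all(need %in% colnames(s)))
    return(paste("summary must have columns:", paste(need, collapse = ", ")))
  if (nrow(s)) {
    if (any(s$n_transcripts < object@min_transcripts))
      return("all summarised genes must meet the transcript-count floor")
    lo <- vapply(s$tail_lengths, min, numeric(1))
    hi <- vapply(s$tail_lengths, max, numeric(1))
    if (any(s$geom_mean_len < lo - 1e-9 | s$geom_mean_len > hi + 1e-9))
      return("geometric mean must lie within the range of tail lengths")
  }
  TRUE
})

#' TailComparison: two-condition poly(A) tail comparison
#'
#' Pairwise per-gene geometric means for genes summarised in both
#' conditions, condition medians, transcript-level length-bin fractions and
#' the quantile-trimmed distribution support (the "2% cutoff" presentation).
#'
#' @slot per_gene \code{DataFrame} with \code{gene_id}, \code{geom_mean_A},
#'   \code{geom_mean_B}.
#' @slot median_A,median_B condition medians (nt) of per-gene geometric
#'   means.
#' @slot bin_fractions matrix (bins x conditions) of transcript fractions;
#'   each column sums to 1 over the covered bins.
#' @slot support matrix (2 x conditions): trimmed lower/upper tail-length
#'   support at the trim quantile.
#' @slot trim_quantile symmetric trim fraction (default 0.02).
#' @export
setClass("TailComparison",
  representation(per_gene = "DataFrame", median_A = "numeric",
                 median_B = "numeric", bin_fractions = "matrix",
                 support = "matrix", trim_quantile = "numeric"))

setValidity("TailComparison", function(object) {
  bf <- object@bin_fractions
  if (ncol(bf) && any(abs(colSums(bf) - 1) > 1e-6))
    return("bin fractions must sum to 1 per condition")
  if (object@trim_quantile < 0 || object@trim_quantile >= 0.5)
    return("trim_quantile must be in [0, 0.5)")
  TRUE
})

#' DecayFit: first-order mRNA decay fit for one gene
#'
#' The result of regressing \code{-ln(C/C0)} on time through the origin:
#' the decay rate constant (per hour), the derived half-life
#' \code{t1/2 = ln 2 / k}, and the coefficient of determination relative to
#' the through-origin model. \code{t_half} is \code{Inf} when \code{k <= 0}
#' (a stabilised transcript), never an error.
#'
#' @slot gene_id gene identifier (may be \code{NA}).
#' @slot k_decay decay rate constant, per hour.
#' @slot t_half half-life in hours; \code{Inf} when \code{k_decay <= 0}.
#' @slot r_squared fit diagnostic relative to the through-origin model.
#' @slot n_points number of time points used.
#' @slot intercept fitted intercept (0 unless a free-intercept fit was
#'   requested).
#' @export
setClass("DecayFit",
  representation(gene_id = "character", k_decay = "numeric",
                 t_half = "numeric", r_squared = "numeric",
                 n_points = "integer", intercept = "numeric"))

setValidity("DecayFit", function(object) {
  if (object@k_decay > 0 &&
      abs(object@t_half * object@k_decay - log(2)) > 1e-12)
    return("t_half * k_decay must equal ln 2 when k_decay > 0")
  if (object@k_decay <= 0 && is.finite(object@t_half))
    return("t_half must be non-finite when k_decay <= 0")
  TRUE
})

#' ProfileClusterSet: sign-pattern temporal clusters
#'
#' Genes grouped by the sign pattern of their per-interval log2 expression
#' changes (e.g. \code{"----"} for continuous downregulation across five
#' time points). Built by \code{\link{clusterProfiles}}; only the most
#' populous patterns are retained, and \code{coveredFraction} reports what
#' share of the clustered gene universe they account for.
#'
#' @slot clusters named list (pattern -> character vector of gene ids).
#' @slot pattern_table data.frame (pattern, n) ordered by decreasing size.
#' @slot mean_profiles matrix (pattern x timepoint) of mean log2 profiles.
#' @slot covered_fraction fraction of the gene universe in the retained
#'   clusters.
#' @slot n_genes size of the clustered gene universe.
#' @export
setClass("ProfileClusterSet",
  representation(clusters = "list", pattern_table = "data.frame",
                 mean_profiles = "matrix", covered_fraction = "numeric",
                 n_genes = "integer"))

setValidity("ProfileClusterSet", function(object) {
  sizes <- lengths(object@clusters)
  tab <- object@pattern_table
  if (!identical(unname(sizes[tab$pattern]), as.integer(tab$n)))
    return("pattern_table sizes must match cluster memberships")
  all_members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(all_members))
    return("clusters must be disjoint")
  TRUE
})

#' DegResult: threshold-based differential expression call
#'
#' Up/down gene sets at one time point from the pure-threshold rule:
#' fold change above \code{fc_threshold} (with pseudocount) and expression
#' floor \code{log2 TPM > expr_threshold} on the larger condition mean.
#'
#' @slot timepoint_h time point in hours.
#' @slot up,down character vectors of gene ids; disjoint.
#' @slot fc_threshold fold-change threshold (default 1.5).
#' @slot expr_threshold_log2_tpm expression floor on log2 TPM (default 1).
#' @export
setClass("DegResult",
  representation(timepoint_h = "numeric", up = "character",
                 down = "character", fc_threshold = "numeric",
                 expr_threshold_log2_tpm = "numeric"))

setValidity("DegResult", function(object) {
  if (length(intersect(object@up, object@down)))
    return("up and down sets must be disjoint")
  TRUE
})

#' GeneSetLedger: named gene sets with recorded provenance
#'
#' A registry of named gene sets in which every set operation (input,
#' intersection, union, exclusion, disjoint categorisation) appends a
#' provenance record: the operation, its operand names and sizes, and the
#' resulting size. Recorded sizes always equal actual cardinalities, so the
#' derivation chain behind any final set can be audited. The ledger has
#' reference semantics: \code{record*} functions update it in place and
#' return the resulting gene set invisibly.
#'
#' @slot env environment holding \code{sets} (named list of character
#'   vectors) and \code{log} (provenance data.frame).
#' @export
setClass("GeneSetLedger", representation(env = "environment"))
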