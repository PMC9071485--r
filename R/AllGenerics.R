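## Generics, accessors and show methods.

#' Accessors for TailDynamics result objects
#'
#' \code{tailCalls} returns the per-read call table of a
#' \code{\linkS4class{TailCallSet}}; \code{acceptedCalls} the subset with
#' status \code{ACCEPTED}; \code{auditLog} the filter audit counts.
#' \code{tailSummary} returns the per-gene table of a
#' \code{\linkS4class{GeneTailSummary}}. \code{kDecay}, \code{halfLifeOf}
#' and \code{rSquared} read the slots of a \code{\linkS4class{DecayFit}}.
#' \code{upGenes} / \code{downGenes} read a \code{\linkS4class{DegResult}}.
#'
#' @param x a TailDynamics result object.
#' @return the corresponding slot or derived table.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tailCalls", function(x) standardGeneric("tailCalls"))
#' @rdname accessors
#' @export
setMethod("tailCalls", "TailCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("acceptedCalls", function(x) standardGeneric("acceptedCalls"))
#' @rdname accessors
#' @export
setMethod("acceptedCalls", "TailCallSet",
          function(x) x@calls[x@calls$status == "ACCEPTED", , drop = FALSE])

#' @rdname accessors
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))
#' @rdname accessors
#' @export
setMethod("auditLog", "TailCallSet", function(x) x@audit)

#' @rdname accessors
#' @export
setGeneric("tailSummary", function(x) standardGeneric("tailSummary"))
#' @rdname accessors
#' @export
setMethod("tailSummary", "GeneTailSummary", function(x) x@summary)

#' @rdname accessors
#' @export
setGeneric("kDecay", function(x) standardGeneric("kDecay"))
#' @rdname accessors
#' @export
setMethod("kDecay", "DecayFit", function(x) x@k_decay)

#' @rdname accessors
#' @export
setGeneric("halfLifeOf", function(x) standardGeneric("halfLifeOf"))
#' @rdname accessors
#' @export
setMethod("halfLifeOf", "DecayFit", function(x) x@t_half)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "DecayFit", function(x) x@r_squared)

#' @rdname accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))
#' @rdname accessors
#' @export
setMethod("upGenes", "DegResult", function(x) x@up)

#' @rdname accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))
#' @rdname accessors
#' @export
setMethod("downGenes", "DegResult", function(x) x@down)

#' Accessors for ProfileClusterSet
#'
#' @param x a \code{\linkS4class{ProfileClusterSet}}.
#' @param pattern a sign-pattern string such as \code{"----"}.
#' @return \code{clusterPatterns}: data.frame of patterns and sizes;
#'   \code{clusterMembers}: gene ids in one pattern cluster (empty vector,
#'   with a warning, when the pattern is absent); \code{coveredFraction}:
#'   share of the clustered universe inside the retained clusters.
#' @name cluster-accessors
NULL

#' @rdname cluster-accessors
#' @export
setGeneric("clusterPatterns", function(x) standardGeneric("clusterPatterns"))
#' @rdname cluster-accessors
#' @export
setMethod("clusterPatterns", "ProfileClusterSet", function(x) x@pattern_table)

#' @rdname cluster-accessors
#' @export
setGeneric("clusterMembers",
           function(x, pattern) standardGeneric("clusterMembers"))
#' @rdname cluster-accessors
#' @export
setMethod("clusterMembers", "ProfileClusterSet", function(x, pattern) {
  if (!pattern %in% names(x@clusters)) {
    warning("no cluster with pattern '", pattern, "'")
    return(character(0))
  }
  x@clusters[[pattern]]
})

#' @rdname cluster-accessors
#' @export
setGeneric("coveredFraction",
           function(x) standardGeneric("coveredFraction"))
#' @rdname cluster-accessors
#' @export
setMethod("coveredFraction", "ProfileClusterSet",
          function(x) x@covered_fraction)

setMethod("show", "TailCallSet", function(object) {
  tab <- table(factor(object@calls$status, levels = TAIL_STATUSES))
  cat("TailCallSet with", nrow(object@calls), "reads\n")
  for (s in names(tab)) cat(sprintf("  %-18s %d\n", s, tab[[s]]))
  cat("  min_passes:", object@params$min_passes,
      "| pass filter:", object@params$pass_filter, "\n")
})

setMethod("show", "GeneTailSummary", function(object) {
  cat("GeneTailSummary:", nrow(object@summary), "genes (>=",
      object@min_transcripts, "accepted transcripts each)\n")
  if (nrow(object@summary))
    cat("  geometric-mean tail length: median",
        round(median(object@summary$geom_mean_len), 1), "nt\n")
})

setMethod("show", "TailComparison", function(object) {
  cat("TailComparison over", nrow(object@per_gene), "shared genes\n")
  cat(sprintf("  median geometric-mean tail: A = %.1f nt, B = %.1f nt\n",
              object@median_A, object@median_B))
  cat("  trim quantile:", object@trim_quantile, "\n")
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit%s: k = %.4g /h, t1/2 = %s h, R^2 = %.3f (n = %d)\n",
              if (is.na(object@gene_id)) "" else
                paste0(" [", object@gene_id, "]"),
              object@k_decay,
              if (is.finite(object@t_half))
                sprintf("%.3g", object@t_half) else "Inf",
              object@r_squared, object@n_points))
})

setMethod("show", "ProfileClusterSet", function(object) {
  cat("ProfileClusterSet:", length(object@clusters), "retained clusters,",
      sprintf("%.1f%%", 100 * object@covered_fraction),
      "of", object@n_genes, "genes\n")
  print(head(object@pattern_table, 8L), row.names = FALSE)
})

setMethod("show", "DegResult", function(object) {
  cat(sprintf(
    "DegResult @ %g h: %d up, %d down (FC > %g, log2 TPM > %g)\n",
    object@timepoint_h, length(object@up), length(object@down),
    object@fc_threshold, object@expr_threshold_log2_tpm))
})

setMethod("show", "GeneSetLedger", function(object) {
  lg <- object@env$log
  cat("GeneSetLedger with", length(object@env$sets), "sets\n")
  if (nrow(lg)) print(lg, row.names = FALSE)
})
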