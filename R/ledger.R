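## Gene-set ledger: named sets plus a provenance log of every operation.
## The derivations behind "degradation-dependent" and "naive-GRN-like"
## gene sets are chains of intersections, unions and exclusions whose
## intermediate sizes are themselves results; the ledger makes that chain
## a first-class, checkable output.

.emptyLog <- function() {
  data.frame(name = character(), size = integer(), operation = character(),
             operands = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty gene-set ledger
#'
#' @return a \code{\linkS4class{GeneSetLedger}}.
#' @examples
#' led <- GeneSetLedger()
#' addGeneSet(led, "all_up", c("Nanog", "Esrrb", "Klf4"))
#' setSizes(led)
#' @export
GeneSetLedger <- function() {
  e <- new.env(parent = emptyenv())
  e$sets <- list()
  e$log <- .emptyLog()
  new("GeneSetLedger", env = e)
}

.record <- function(ledger, name, genes, operation, operands,
                    detail = "") {
  genes <- unique(as.character(genes))
  ledger@env$sets[[name]] <- genes
  ledger@env$log <- rbind(ledger@env$log, data.frame(
    name = name, size = length(genes), operation = operation,
    operands = paste(operands, collapse = " "), detail = detail,
    stringsAsFactors = FALSE))
  invisible(genes)
}

#' Register an input gene set
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param name name under which to store the set.
#' @param genes character vector of gene ids (deduplicated).
#' @return the stored set, invisibly.
#' @export
addGeneSet <- function(ledger, name, genes) {
  stopifnot(is(ledger, "GeneSetLedger"))
  .record(ledger, name, genes, "input", character(0))
}

#' Retrieve a set from the ledger
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param name the set's name.
#' @return character vector of gene ids.
#' @export
geneSet <- function(ledger, name) {
  if (!name %in% names(ledger@env$sets))
    stop("no set named '", name, "' in the ledger")
  ledger@env$sets[[name]]
}

#' @rdname geneSet
#' @export
setSizes <- function(ledger) {
  vapply(ledger@env$sets, length, integer(1))
}

#' The ledger's provenance log
#'
#' One row per recorded set: name, size, operation and operand names.
#' Recorded sizes always equal the actual cardinalities of the stored
#' sets.
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @return data.frame.
#' @export
ledgerTable <- function(ledger) ledger@env$log

#' Record a set intersection, union or exclusion
#'
#' Each computes the named operation on sets already in the ledger,
#' stores the result under \code{name}, and appends a provenance row.
#' \code{recordExclusion} is set difference (\code{x \\ y}).
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param name name for the result set.
#' @param x,y names of operand sets already in the ledger.
#' @return the resulting gene set, invisibly.
#' @name ledger-ops
NULL

#' @rdname ledger-ops
#' @export
recordIntersection <- function(ledger, name, x, y) {
  gx <- geneSet(ledger, x); gy <- geneSet(ledger, y)
  res <- intersect(gx, gy)
  .record(ledger, name, res, "intersection", c(x, y),
          detail = sprintf("|%s|=%d |%s|=%d", x, length(gx), y, length(gy)))
}

#' @rdname ledger-ops
#' @export
recordUnion <- function(ledger, name, x, y) {
  gx <- geneSet(ledger, x); gy <- geneSet(ledger, y)
  .record(ledger, name, union(gx, gy), "union", c(x, y))
}

#' @rdname ledger-ops
#' @export
recordExclusion <- function(ledger, name, x, y) {
  gx <- geneSet(ledger, x); gy <- geneSet(ledger, y)
  res <- setdiff(gx, gy)
  .record(ledger, name, res, "exclusion", c(x, y),
          detail = sprintf("removed %d", length(gx) - length(res)))
}

#' Intersect KO-upregulated genes with the degradation cluster
#'
#' Defines the "degradation-dependent" gene set: genes whose expression is
#' cleared during normal differentiation (the continuous-downregulation
#' cluster) and which fail to be cleared when the deadenylase is knocked
#' out (the union of KO-upregulated genes). Records both operand sizes and
#' the resulting fraction of the degradation cluster in the ledger.
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param upName ledger name of the union of KO-upregulated genes.
#' @param degradationName ledger name of the degradation cluster set.
#' @param name name for the result (default
#'   \code{"degradation_dependent"}).
#' @return the intersection, invisibly; the fraction (percent of the
#'   degradation set) is recorded in the ledger's detail column.
#' @export
dependentDegradationSet <- function(ledger, upName, degradationName,
                                    name = "degradation_dependent") {
  gu <- geneSet(ledger, upName)
  gd <- geneSet(ledger, degradationName)
  res <- intersect(gu, gd)
  frac <- if (length(gd)) summarizeRatio(length(res), length(gd)) else 0
  .record(ledger, name, res, "intersection", c(upName, degradationName),
          detail = sprintf("%.1f%% of %s (%d/%d)", frac, degradationName,
                           length(res), length(gd)))
}

#' Derive the late-upregulated (naive-GRN-like) gene set
#'
#' From the per-timepoint KO-upregulated sets, builds four disjoint
#' categories: genes up at all four post-induction time points
#' (continuous), genes up at both 24 h and 48 h but not all four, genes up
#' only at 24 h, and genes up only at 48 h (membership at 6/12 h does not
#' matter for the last two beyond the earlier categories). Their union,
#' minus genes already upregulated in KO at 0 h (ESC stage), is the final
#' set. Every intermediate size is recorded.
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param upByTimepoint named list of character vectors, names
#'   \code{"6"}, \code{"12"}, \code{"24"}, \code{"48"} (hours).
#' @param escUp character vector: genes upregulated in KO at 0 h.
#' @param name name for the final set (default \code{"grn_like"}).
#' @return the final gene set, invisibly.
#' @export
deriveGrnLikeSet <- function(ledger, upByTimepoint, escUp,
                             name = "grn_like") {
  need <- c("6", "12", "24", "48")
  stopifnot(all(need %in% names(upByTimepoint)))
  u6 <- unique(upByTimepoint[["6"]]);  u12 <- unique(upByTimepoint[["12"]])
  u24 <- unique(upByTimepoint[["24"]]); u48 <- unique(upByTimepoint[["48"]])

  continuous <- Reduce(intersect, list(u6, u12, u24, u48))
  shared2448 <- setdiff(intersect(u24, u48), continuous)
  only24 <- setdiff(u24, union(u48, continuous))
  only48 <- setdiff(u48, union(u24, continuous))

  cats <- list(continuous_up = continuous, up_24h_and_48h = shared2448,
               up_24h_only = only24, up_48h_only = only48)
  allMembers <- unlist(cats, use.names = FALSE)
  if (anyDuplicated(allMembers))
    stop("internal error: derivation categories are not disjoint")

  for (nm in names(cats))
    .record(ledger, nm, cats[[nm]], "categorize",
            c("up_6h", "up_12h", "up_24h", "up_48h"))
  unionSet <- .record(ledger, paste0(name, "_union"), allMembers,
                      "disjoint_union", names(cats),
                      detail = sprintf("%s = %d",
                                       paste(lengths(cats), collapse = "+"),
                                       length(allMembers)))
  addGeneSet(ledger, ".esc_up", unique(escUp))
  res <- setdiff(unionSet, escUp)
  .record(ledger, name, res, "exclusion",
          c(paste0(name, "_union"), ".esc_up"),
          detail = sprintf("removed %d ESC-upregulated",
                           length(unionSet) - length(res)))
}

#' Intersect a derived set with an external reference list
#'
#' Plain intersection with a user-supplied reference gene list (for
#' example, an externally published naive-like gene list), recorded in
#' the ledger.
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param setName ledger name of the derived set.
#' @param reference character vector of reference gene ids.
#' @param name name for the result (default
#'   \code{paste0(setName, "_in_reference")}).
#' @return the intersection, invisibly.
#' @export
intersectWithReference <- function(ledger, setName, reference,
                                   name = paste0(setName, "_in_reference")) {
  if (!length(reference)) warning("empty reference gene list")
  addGeneSet(ledger, ".reference", unique(reference))
  res <- intersect(geneSet(ledger, setName), reference)
  .record(ledger, name, res, "intersection", c(setName, ".reference"))
}

#' Write the ledger to JSON
#'
#' Serialises every named set (with size and members) and the provenance
#' log.
#'
#' @param ledger a \code{\linkS4class{GeneSetLedger}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLedgerJson <- function(ledger, path) {
  obj <- list(
    sets = lapply(ledger@env$sets,
                  function(g) list(size = length(g), genes = g)),
    log = ledger@env$log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
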