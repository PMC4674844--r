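#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 classes: `assocType` gives
#' the evidence type of a catalog or score table, `geneUniverse` the gene
#' universe, `universeSize` the hypergeometric universe size N (distinct
#' attributes for attribute-style types, genome size for PI/GI),
#' `geneAttrs` the per-gene attribute sets, `pairScores` the explicit
#' (geneA, geneB, score) rows, `cutoffs` the per-type evidence thresholds,
#' `resultRecords` a query result's ranked table, `queryGene` its query,
#' `graphNodes`/`graphEdges` a graph's structure, and `summaryTable` an
#' overlap summary's long-format table.
#'
#' @param x an object of the appropriate class.
#' @return see each method.
#' @name accessors
#' @aliases assocType geneUniverse universeSize geneAttrs pairScores
#'   cutoffs resultRecords queryGene graphNodes graphEdges summaryTable
NULL

#' @rdname accessors
#' @export
setGeneric("assocType", function(x) standardGeneric("assocType"))
#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))
#' @rdname accessors
#' @export
setGeneric("geneAttrs", function(x) standardGeneric("geneAttrs"))
#' @rdname accessors
#' @export
setGeneric("pairScores", function(x) standardGeneric("pairScores"))
#' @rdname accessors
#' @export
setGeneric("cutoffs", function(x) standardGeneric("cutoffs"))
#' @rdname accessors
#' @export
setGeneric("resultRecords", function(x) standardGeneric("resultRecords"))
#' @rdname accessors
#' @export
setGeneric("queryGene", function(x) standardGeneric("queryGene"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' @rdname accessors
setMethod("assocType", "EvidenceCatalog", function(x) x@assocType)
#' @rdname accessors
setMethod("assocType", "PairScoreTable", function(x) x@assocType)
#' @rdname accessors
setMethod("assocType", "NormalizedProfile", function(x) x@assocType)

#' @rdname accessors
setMethod("geneUniverse", "EvidenceCatalog", function(x) x@geneUniverse)
#' @rdname accessors
setMethod("geneUniverse", "PairScoreTable", function(x) x@geneUniverse)
#' @rdname accessors
setMethod("geneUniverse", "AssociationEngine", function(x) x@geneUniverse)

#' @rdname accessors
setMethod("universeSize", "EvidenceCatalog", function(x) {
  if (x@assocType %in% INTERACTION_TYPES) length(x@geneUniverse)
  else length(x@attrUniverse)
})

#' @rdname accessors
setMethod("geneAttrs", "EvidenceCatalog", function(x) x@geneAttrs)

#' @rdname accessors
setMethod("pairScores", "PairScoreTable", function(x) x@scores)

#' @rdname accessors
setMethod("cutoffs", "EvidenceThresholds", function(x) x@cutoffs)
#' @rdname accessors
setMethod("cutoffs", "AssociationEngine", function(x) x@thresholds@cutoffs)

#' @rdname accessors
setMethod("resultRecords", "QueryResult", function(x) x@records)
#' @rdname accessors
setMethod("queryGene", "QueryResult", function(x) x@query)
#' @rdname accessors
setMethod("queryGene", "AssociationGraph", function(x) x@query)

#' @rdname accessors
setMethod("graphNodes", "AssociationGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "AssociationGraph", function(x) x@edges)

#' @rdname accessors
setMethod("summaryTable", "OverlapSummary", function(x) x@table)

setMethod("show", "HypergeomParams", function(object) {
  cat(sprintf("HypergeomParams(N=%d, n=%d, m=%d, k=%d)\n",
              object@N, object@n, object@m, object@k))
})

setMethod("show", "EvidenceCatalog", function(object) {
  nAnn <- sum(lengths(object@geneAttrs) > 0)
  cat(sprintf("EvidenceCatalog [%s]: %d genes (%d annotated), N = %d\n",
              object@assocType, length(object@geneUniverse), nAnn,
              universeSize(object)))
})

setMethod("show", "PairScoreTable", function(object) {
  cat(sprintf("PairScoreTable [%s]: %d explicit pairs over %d genes\n",
              object@assocType, nrow(object@scores),
              length(object@geneUniverse)))
})

setMethod("show", "EvidenceThresholds", function(object) {
  cat(sprintf("EvidenceThresholds (%gth percentile of %g gene pairs):\n",
              object@percentile, object@nPairs))
  print(round(object@cutoffs, 4))
})

setMethod("show", "QueryResult", function(object) {
  cat(sprintf("QueryResult for %s: %d associated genes (chosen: %s)\n",
              object@query, nrow(object@records),
              paste(object@chosen, collapse = "+")))
  print(head(object@records, 5))
  if (nrow(object@records) > 5) cat("...\n")
})

setMethod("show", "AssociationGraph", function(object) {
  cat(sprintf("AssociationGraph (%s view): query %s, %d nodes, %d edges\n",
              object@viewKind, object@query, length(object@nodes),
              nrow(object@edges)))
})

setMethod("show", "OverlapSummary", function(object) {
  cat(sprintf("OverlapSummary (k = %d): %d comparisons\n",
              object@k, nrow(object@table)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d genes, %d attrs/type, background %.3g, %d planted module(s), seed %d\n",
    object@numGenes, object@attrUniverseSize, object@backgroundProb,
    length(object@plantedModules), object@seed))
})

setMethod("show", "AssociationEngine", function(object) {
  cat(sprintf("AssociationEngine: %d genes, types %s\n",
              length(object@geneUniverse),
              paste(names(object@tables), collapse = "+")))
})
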