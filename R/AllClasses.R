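#' @import methods
#' @importFrom stats phyper sd
#' @importFrom utils adist head
NULL

## Evidence type codes. EP (expression profile) is import-only: its pair
## scores come from an external compendium, never from the hypergeometric
## scorer.
ASSOC_TYPES <- c("TFB", "TFR", "MP", "FA", "PI", "GI", "LE", "EP")
SCORED_TYPES <- c("TFB", "TFR", "MP", "FA", "PI", "GI", "LE")
INTERACTION_TYPES <- c("PI", "GI")

#' Evidence type codes
#'
#' The eight biological evidence types understood by the engine:
#' `TFB` (transcription-factor binding), `TFR` (TF regulation),
#' `MP` (mutant phenotype), `FA` (functional annotation),
#' `PI` (physical interaction), `GI` (genetic interaction),
#' `LE` (literature evidence) and `EP` (expression profile).
#' All but `EP` are scored from attribute catalogs with the hypergeometric
#' index; `EP` scores are imported from a precomputed table.
#'
#' @param scoredOnly logical; if `TRUE`, return only the seven types scored
#'   from catalogs (i.e. drop `EP`).
#' @return character vector of type codes.
#' @examples
#' assocTypes()
#' assocTypes(scoredOnly = TRUE)
#' @export
assocTypes <- function(scoredOnly = FALSE) {
  if (scoredOnly) SCORED_TYPES else ASSOC_TYPES
}

## internal: condition constructors so the command layer can map errors to
## exit codes (usage vs data).
stopUsage <- function(...) {
  stop(errorCondition(paste0(...), class = c("assocUsageError", "error")))
}
stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("assocDataError", "error")))
}

.checkType <- function(assocType, allowEP = TRUE) {
  if (length(assocType) != 1L || !assocType %in% ASSOC_TYPES)
    stopUsage("unknown association type '", paste(assocType, collapse = ","),
              "'; must be one of ", paste(ASSOC_TYPES, collapse = ", "))
  if (!allowEP && assocType == "EP")
    stopUsage("type EP carries imported scores and has no attribute catalog")
  assocType
}

#' Hypergeometric test parameters for one gene pair
#'
#' Container for the four counts entering the hypergeometric overlap test:
#' `N` the attribute-universe size, `n` and `m` the attribute-set sizes of
#' the two genes, and `k` the size of the intersection of the two sets.
#'
#' @slot N integer, universe size.
#' @slot n,m integer, per-gene attribute-set sizes.
#' @slot k integer, overlap size.
#' @aliases HypergeomParams
#' @exportClass HypergeomParams
setClass("HypergeomParams",
  representation(N = "integer", n = "integer", m = "integer", k = "integer"),
  validity = function(object) {
    msg <- character()
    v <- c(N = object@N, n = object@n, m = object@m, k = object@k)
    if (any(lengths(list(object@N, object@n, object@m, object@k)) != 1L))
      return("N, n, m, k must each be a single integer")
    if (any(is.na(v)) || any(v < 0L))
      msg <- c(msg, "N, n, m, k must be non-negative")
    else {
      if (object@n > object@N) msg <- c(msg, "n must not exceed N")
      if (object@m > object@N) msg <- c(msg, "m must not exceed N")
      if (object@k > min(object@n, object@m))
        msg <- c(msg, "k must not exceed min(n, m)")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn HypergeomParams-class constructor.
#' @param N,n,m,k the four counts (coerced to integer).
#' @export
hypergeomParams <- function(N, n, m, k) {
  new("HypergeomParams", N = as.integer(N), n = as.integer(n),
      m = as.integer(m), k = as.integer(k))
}

#' Per-type evidence catalog
#'
#' One evidence type's annotation structure: for every gene of the universe,
#' the set of attributes it carries. For attribute-style types (TFB, TFR,
#' MP, FA, LE) the attributes are TFs, phenotypes, annotations or
#' publications and the test universe `N` is the number of distinct
#' attributes in the catalog. For interaction types (PI, GI) the attributes
#' are interaction-partner genes and `N` is the size of the gene universe.
#'
#' @slot assocType one of the seven scored type codes (never "EP").
#' @slot geneUniverse sorted character vector of upper-cased gene ids.
#' @slot attrUniverse character vector of attribute ids; equals
#'   `geneUniverse` for PI/GI.
#' @slot geneAttrs named list (one entry per universe gene, empty character
#'   vector when unannotated) of attribute id vectors.
#' @exportClass EvidenceCatalog
setClass("EvidenceCatalog",
  representation(assocType = "character", geneUniverse = "character",
                 attrUniverse = "character", geneAttrs = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@assocType %in% SCORED_TYPES)
      msg <- c(msg, "assocType must be one of the seven scored types")
    if (!identical(names(object@geneAttrs), object@geneUniverse))
      msg <- c(msg, "geneAttrs must have exactly one entry per universe gene, in universe order")
    if (anyDuplicated(object@geneUniverse))
      msg <- c(msg, "duplicate gene ids in universe")
    bad <- !vapply(object@geneAttrs, function(a)
      is.character(a) && !anyDuplicated(a) && all(a %in% object@attrUniverse),
      logical(1))
    if (any(bad))
      msg <- c(msg, "every attribute set must be a duplicate-free subset of the attribute universe")
    if (object@assocType %in% INTERACTION_TYPES) {
      if (!identical(object@attrUniverse, object@geneUniverse))
        msg <- c(msg, "for PI/GI the attribute universe must equal the gene universe")
      self <- mapply(function(g, a) g %in% a,
                     object@geneUniverse, object@geneAttrs)
      if (any(self))
        msg <- c(msg, "a gene must not be its own interaction partner")
    }
    if (length(msg)) msg else TRUE
  })

#' Sparse symmetric pair-score table
#'
#' Raw association scores for unordered gene pairs under one evidence type.
#' Absent pairs score 0 for the seven hypergeometric types; for the imported
#' "EP" type absent pairs are treated as the minimum observed score at
#' normalization time. Rows are stored with `geneA < geneB` and sorted.
#'
#' @slot assocType association type code.
#' @slot scores data.frame with columns `geneA`, `geneB`, `score`.
#' @slot geneUniverse sorted character vector of universe gene ids.
#' @exportClass PairScoreTable
setClass("PairScoreTable",
  representation(assocType = "character", scores = "data.frame",
                 geneUniverse = "character"),
  validity = function(object) {
    msg <- character()
    sc <- object@scores
    if (!identical(colnames(sc), c("geneA", "geneB", "score")))
      msg <- c(msg, "scores must have columns geneA, geneB, score")
    else {
      if (!object@assocType %in% ASSOC_TYPES)
        msg <- c(msg, "unknown assocType")
      if (nrow(sc)) {
        if (any(!is.finite(sc$score)))
          msg <- c(msg, "scores must be finite")
        if (object@assocType != "EP" && any(sc$score < 0))
          msg <- c(msg, "hypergeometric scores must be non-negative")
        if (any(sc$geneA >= sc$geneB))
          msg <- c(msg, "rows must satisfy geneA < geneB")
        if (anyDuplicated(paste(sc$geneA, sc$geneB)))
          msg <- c(msg, "duplicate gene pairs")
        if (!all(c(sc$geneA, sc$geneB) %in% object@geneUniverse))
          msg <- c(msg, "pair members must belong to the gene universe")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Min-max normalized score profile of one query gene
#'
#' Values of the normalized score S in \[0, 1\] for every candidate gene
#' (the whole universe minus the query) under one evidence type.
#'
#' @slot query query gene id.
#' @slot assocType type code.
#' @slot values named numeric vector over candidate genes, each in \[0, 1\].
#' @exportClass NormalizedProfile
setClass("NormalizedProfile",
  representation(query = "character", assocType = "character",
                 values = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (is.null(names(v)) || anyDuplicated(names(v)))
      msg <- c(msg, "values must be uniquely named by candidate gene")
    if (object@query %in% names(v))
      msg <- c(msg, "query gene must not appear among candidates")
    if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v > 1)))
      msg <- c(msg, "normalized scores must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Genome-wide percentile evidence cutoffs
#'
#' Per-type nearest-rank percentile (default the 95th) of the raw score
#' distribution over all unordered universe gene pairs, implicit zeros
#' (or, for EP, the minimum observed score) included.
#'
#' @slot cutoffs named numeric vector, one entry per type.
#' @slot percentile the percentile level used, in (0, 100).
#' @slot nPairs number of unordered pairs the multiset was built from.
#' @exportClass EvidenceThresholds
setClass("EvidenceThresholds",
  representation(cutoffs = "numeric", percentile = "numeric",
                 nPairs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@cutoffs)) ||
        !all(names(object@cutoffs) %in% ASSOC_TYPES))
      msg <- c(msg, "cutoffs must be named by association type")
    if (object@percentile <= 0 || object@percentile >= 100)
      msg <- c(msg, "percentile must lie strictly between 0 and 100")
    if (length(msg)) msg else TRUE
  })

#' Ranked query result
#'
#' The ranked list of candidate genes for one query: per-type normalized
#' scores for the chosen types, per-type evidence flags (raw score strictly
#' above the genome-wide cutoff) for every type the engine holds, and the
#' overall association score (OAS), the sum of chosen normalized scores.
#'
#' @slot query query gene id.
#' @slot chosen the evidence types summed into the OAS.
#' @slot flagTypes the types for which evidence flags are reported.
#' @slot records data.frame with columns `rank`, `gene`, `oas`,
#'   `score.<type>` for each chosen type and logical `evidence.<type>` for
#'   each flagged type; sorted by descending `oas`, ties by ascending gene.
#' @exportClass QueryResult
setClass("QueryResult",
  representation(query = "character", chosen = "character",
                 flagTypes = "character", records = "data.frame"),
  validity = function(object) {
    msg <- character()
    rec <- object@records
    need <- c("rank", "gene", "oas")
    if (!all(need %in% colnames(rec)))
      return("records must contain rank, gene and oas columns")
    n <- nrow(rec)
    if (n) {
      if (!identical(rec$rank, seq_len(n)))
        msg <- c(msg, "ranks must be contiguous 1..n")
      o <- order(-rec$oas, rec$gene)
      if (!identical(o, seq_len(n)))
        msg <- c(msg, "records must be sorted by descending oas, ties by gene id")
      if (any(rec$oas < -1e-12) ||
          any(rec$oas > length(object@chosen) + 1e-12))
        msg <- c(msg, "oas must lie in [0, number of chosen types]")
      if (object@query %in% rec$gene)
        msg <- c(msg, "query gene must not be listed among its candidates")
    }
    if (length(msg)) msg else TRUE
  })

#' Star-shaped association graph
#'
#' Network view of a query result. The confidence view has one edge per
#' associated gene weighted by its OAS; the evidence view has one labeled
#' edge per true evidence flag (so parallel edges are possible, and genes
#' with no flags remain isolated nodes). Every edge touches the query node.
#'
#' @slot viewKind `"confidence"` or `"evidence"`.
#' @slot query query gene id (the hub node).
#' @slot nodes character vector: the query plus the associated genes.
#' @slot edges data.frame with columns `from`, `to`, `label`, `weight`.
#' @exportClass AssociationGraph
setClass("AssociationGraph",
  representation(viewKind = "character", query = "character",
                 nodes = "character", edges = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!object@viewKind %in% c("confidence", "evidence"))
      msg <- c(msg, "viewKind must be 'confidence' or 'evidence'")
    ed <- object@edges
    if (!all(c("from", "to", "label", "weight") %in% colnames(ed)))
      return("edges must have columns from, to, label, weight")
    if (nrow(ed)) {
      if (!all(ed$from == object@query))
        msg <- c(msg, "every edge must be incident to the query node")
      if (!all(c(ed$from, ed$to) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be graph nodes")
      if (object@viewKind == "confidence" && anyDuplicated(ed$to))
        msg <- c(msg, "confidence view allows at most one edge per associated gene")
    }
    if (!object@query %in% object@nodes)
      msg <- c(msg, "query must be a node")
    if (length(msg)) msg else TRUE
  })

#' Top-k list overlap summary
#'
#' Mean and standard error, over query genes, of the overlap between top-k
#' associated-gene lists obtained under two evidence selections.
#'
#' @slot k the list length compared.
#' @slot table data.frame with columns `selectionA`, `selectionB`, `mean`,
#'   `se`, `n` (number of query genes averaged over).
#' @exportClass OverlapSummary
setClass("OverlapSummary",
  representation(k = "integer", table = "data.frame"),
  validity = function(object) {
    msg <- character()
    tb <- object@table
    if (!all(c("selectionA", "selectionB", "mean", "se", "n") %in% colnames(tb)))
      return("table must have columns selectionA, selectionB, mean, se, n")
    if (nrow(tb)) {
      if (any(tb$mean < 0) || any(tb$mean > object@k + 1e-9))
        msg <- c(msg, "mean overlap must lie in [0, k]")
      if (any(tb$se < 0)) msg <- c(msg, "standard errors must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Synthetic catalog specification
#'
#' Parameters of the seeded synthetic-data generator: universe size, the
#' attribute-universe size used for every attribute-style type, the
#' background membership (and interaction-edge) probability, and the
#' planted modules — gene sets given a common block of shared attributes
#' per type so that true associations are known.
#'
#' @slot numGenes number of genes in the universe.
#' @slot attrUniverseSize attributes per attribute-style type.
#' @slot backgroundProb background membership/edge probability.
#' @slot plantedModules list of `list(genes =, shared =)` entries.
#' @slot seed integer seed driving the single pseudo-random stream.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(numGenes = "integer", attrUniverseSize = "integer",
                 backgroundProb = "numeric", plantedModules = "list",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@numGenes < 2L) msg <- c(msg, "need at least two genes")
    if (object@attrUniverseSize < 1L)
      msg <- c(msg, "attribute universe must be non-empty")
    if (object@backgroundProb < 0 || object@backgroundProb > 1)
      msg <- c(msg, "backgroundProb must lie in [0, 1]")
    u <- syntheticGeneIds(object@numGenes)
    for (mod in object@plantedModules) {
      if (!all(c("genes", "shared") %in% names(mod)))
        { msg <- c(msg, "each planted module needs 'genes' and 'shared'"); next }
      if (!all(mod$genes %in% u))
        msg <- c(msg, "planted module genes must belong to the synthetic universe")
      if (length(mod$genes) < 2L)
        msg <- c(msg, "a planted module needs at least two genes")
      if (mod$shared > object@attrUniverseSize)
        msg <- c(msg, "shared attribute count exceeds the attribute universe")
      if (mod$shared > object@numGenes - length(mod$genes))
        msg <- c(msg, "shared partner count exceeds the available non-module genes")
      if (mod$shared < 1L) msg <- c(msg, "shared count must be positive")
    }
    if (length(msg)) msg else TRUE
  })

#' Association engine
#'
#' Bundles everything a query needs: the gene universe, one raw pair-score
#' table per evidence type (computed from catalogs for the seven
#' hypergeometric types, imported for EP), sparse symmetric score matrices
#' for fast per-query profile extraction, and the genome-wide percentile
#' cutoffs.
#'
#' @slot geneUniverse sorted universe gene ids.
#' @slot tables named list of [PairScoreTable-class] objects.
#' @slot matrices named list of sparse symmetric score matrices (EP stored
#'   shifted by `epMin` so that structural zeros equal the fill value).
#' @slot thresholds an [EvidenceThresholds-class] object.
#' @slot epMin minimum observed EP score (the fill value for absent EP
#'   pairs); 0 when no EP table is attached.
#' @exportClass AssociationEngine
setClass("AssociationEngine",
  representation(geneUniverse = "character", tables = "list",
                 matrices = "list", thresholds = "EvidenceThresholds",
                 epMin = "numeric"),
  validity = function(object) {
    msg <- character()
    tys <- names(object@tables)
    if (is.null(tys) || !all(tys %in% ASSOC_TYPES))
      msg <- c(msg, "tables must be named by association type")
    if (!identical(names(object@matrices), tys))
      msg <- c(msg, "matrices must parallel tables")
    if (!all(tys %in% names(object@thresholds@cutoffs)))
      msg <- c(msg, "thresholds must cover every table type")
    if (length(msg)) msg else TRUE
  })
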