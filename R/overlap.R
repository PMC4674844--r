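#' @include mining.R
NULL

#' Overlap of two ranked lists
#'
#' Number of genes the leading `k` entries of two rankings have in common.
#' For two independent random rankings over a universe of G genes the
#' expected overlap is k^2/G (each of the k genes of one list lands in the
#' other list's top k with probability k/G).
#'
#' @param rankedA,rankedB character vectors, best candidate first.
#' @param k list length compared.
#' @return integer overlap count in \[0, k\].
#' @export
rankOverlap <- function(rankedA, rankedB, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stopUsage("k must be a positive integer")
  length(intersect(head(rankedA, k), head(rankedB, k)))
}

## per-query machinery shared by the overlap summaries: raw profiles once,
## then the normalized ranking for any selection of types. Ranking uses the
## OAS order with ties broken by ascending gene id, so a query with no
## annotations under a selection (all-zero OAS) yields the k
## lexicographically smallest candidates — deterministic, and such queries
## stay included in the averages.
queryProfiles <- function(engine, gene) {
  raws <- lapply(availableTypes(engine), rawProfile, engine = engine,
                 gene = gene)
  names(raws) <- availableTypes(engine)
  lapply(raws, function(r) normalizeProfile(r, gene)@values)
}

rankedForSelection <- function(svals, selection) {
  oas <- Reduce(`+`, svals[selection])
  names(oas)[order(-oas, names(oas))]
}

#' Top-k list overlap between two evidence selections
#'
#' Ranks the query gene's candidates once under selection A and once under
#' selection B (each a non-empty subset of the engine's types) and counts
#' the genes common to the two top-k lists.
#'
#' @param engine an [AssociationEngine-class] object.
#' @param gene query gene id.
#' @param selectionA,selectionB non-empty character vectors of type codes.
#' @param k list length (default 50).
#' @return integer overlap count.
#' @export
topkOverlap <- function(engine, gene, selectionA, selectionB, k = 50L) {
  stopifnot(is(engine, "AssociationEngine"))
  gene <- normalizeGeneIds(gene)
  if (!gene %in% engine@geneUniverse)
    stopUsage("unknown gene '", gene, "'")
  for (sel in list(selectionA, selectionB)) {
    if (!length(sel)) stopUsage("selections must be non-empty")
    bad <- setdiff(sel, availableTypes(engine))
    if (length(bad))
      stopUsage("type(s) not held by this engine: ",
                paste(bad, collapse = ", "))
  }
  sv <- queryProfiles(engine, gene)
  rankOverlap(rankedForSelection(sv, selectionA),
              rankedForSelection(sv, selectionB), k)
}

.overlapSummary <- function(perQuery, labels, k, G) {
  means <- colMeans(perQuery)
  ses <- apply(perQuery, 2, sd) / sqrt(G)
  ses[is.na(ses)] <- 0   # single query gene
  tb <- data.frame(selectionA = labels$a, selectionB = labels$b,
                   mean = unname(means), se = unname(ses),
                   n = rep(G, length(means)), stringsAsFactors = FALSE)
  new("OverlapSummary", k = as.integer(k), table = tb)
}

#' Pairwise single-type overlap matrix
#'
#' For every (unordered) pair of single-type selections — diagonal
#' included — computes the mean and standard error (sample SD over query
#' genes divided by the square root of the number of query genes) of the
#' top-k list overlap, averaged over every gene of the universe as query.
#' Identical annotation structure between two types (e.g. the same file
#' loaded as both TFB and TFR) forces identical rankings and hence a mean
#' overlap of min(k, G - 1) with zero standard error.
#'
#' @param engine an [AssociationEngine-class] object (>= 2 universe genes).
#' @param k list length (default 50).
#' @return an [OverlapSummary-class] object with one row per type pair.
#' @export
pairwiseOverlapMatrix <- function(engine, k = 50L) {
  stopifnot(is(engine, "AssociationEngine"))
  u <- engine@geneUniverse
  if (length(u) < 2L) stopData("need at least two universe genes")
  tys <- availableTypes(engine)
  idx <- which(upper.tri(diag(length(tys)), diag = TRUE), arr.ind = TRUE)
  labA <- tys[idx[, "row"]]; labB <- tys[idx[, "col"]]
  per <- matrix(0L, nrow = length(u), ncol = length(labA))
  kk <- min(as.integer(k), length(u) - 1L)
  for (gi in seq_along(u)) {
    sv <- queryProfiles(engine, u[gi])
    tops <- lapply(tys, function(ty)
      head(rankedForSelection(sv, ty), kk))
    names(tops) <- tys
    per[gi, ] <- mapply(function(a, b)
      length(intersect(tops[[a]], tops[[b]])), labA, labB)
  }
  .overlapSummary(per, list(a = labA, b = labB), k, length(u))
}

#' Overlap of the all-types ranking with each single type
#'
#' For each single evidence type, the mean and standard error over all
#' query genes of the overlap between the top-k list obtained with every
#' engine type chosen and the top-k list of that type alone. Types whose
#' single-type lists overlap the combined list most are the ones driving
#' the overall association score.
#'
#' @inheritParams pairwiseOverlapMatrix
#' @return an [OverlapSummary-class] object with `selectionA = "ALL"` rows.
#' @export
allVsSingleOverlap <- function(engine, k = 50L) {
  stopifnot(is(engine, "AssociationEngine"))
  u <- engine@geneUniverse
  if (length(u) < 2L) stopData("need at least two universe genes")
  tys <- availableTypes(engine)
  per <- matrix(0L, nrow = length(u), ncol = length(tys))
  kk <- min(as.integer(k), length(u) - 1L)
  for (gi in seq_along(u)) {
    sv <- queryProfiles(engine, u[gi])
    topAll <- head(rankedForSelection(sv, tys), kk)
    per[gi, ] <- vapply(tys, function(ty)
      length(intersect(topAll, head(rankedForSelection(sv, ty), kk))),
      integer(1))
  }
  .overlapSummary(per, list(a = rep("ALL", length(tys)), b = tys), k,
                  length(u))
}

#' Write an overlap summary
#'
#' Long-format tab-separated table (selection_a, selection_b, mean, se, n).
#'
#' @param x an [OverlapSummary-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOverlapSummary <- function(x, path) {
  stopifnot(is(x, "OverlapSummary"))
  tb <- x@table
  writeLines(c(paste(c("selection_a", "selection_b", "mean", "se", "n"),
                     collapse = "\t"),
               paste(tb$selectionA, tb$selectionB, fmtNum(tb$mean),
                     fmtNum(tb$se), tb$n, sep = "\t")), path)
  invisible(path)
}
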