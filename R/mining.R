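#' @include integration.R
NULL

## nearest-rank percentile of the full pair-score multiset: explicit
## scores plus (M - length(explicit)) copies of the implicit fill value.
nearestRankPercentile <- function(explicit, fill, M, percentile) {
  stopifnot(M >= 1, length(explicit) <= M)
  idx <- ceiling(percentile / 100 * M)
  idx <- min(max(idx, 1L), M)
  v <- sort(c(rep.int(fill, M - length(explicit)), explicit))
  v[idx]
}

#' Genome-wide evidence thresholds
#'
#' For each evidence type, the nearest-rank percentile (default the 95th)
#' of the raw association scores of all C(G, 2) unordered universe gene
#' pairs. Pairs without an explicit table entry count with their implicit
#' value: 0 for the hypergeometric types, the minimum observed score for
#' the imported EP type. Nearest-rank means the value at position
#' ceil(p/100 * M) of the ascending sorted multiset of M values — a rule
#' that stays well-defined on the heavily tied, zero-inflated score
#' distributions these catalogs produce.
#'
#' @param tables named list of [PairScoreTable-class] objects (one per
#'   type; names default to each table's type).
#' @param geneUniverse the gene universe (>= 2 genes).
#' @param percentile percentile level in (0, 100); default 95.
#' @return an [EvidenceThresholds-class] object.
#' @export
computeThresholds <- function(tables, geneUniverse, percentile = 95) {
  geneUniverse <- sort(unique(normalizeGeneIds(geneUniverse)))
  G <- length(geneUniverse)
  if (G < 2L) stopData("need at least two universe genes for thresholds")
  if (percentile <= 0 || percentile >= 100)
    stopUsage("percentile must lie strictly between 0 and 100")
  if (is(tables, "PairScoreTable")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, assocType, character(1))
  M <- G * (G - 1) / 2
  cuts <- vapply(tables, function(tb) {
    stopifnot(is(tb, "PairScoreTable"))
    sc <- tb@scores$score
    if (length(sc) > M)
      stopData("score table [", tb@assocType,
               "] has more pairs than the universe allows")
    fill <- if (tb@assocType == "EP" && length(sc)) min(sc) else 0
    nearestRankPercentile(sc, fill, M, percentile)
  }, numeric(1))
  new("EvidenceThresholds", cutoffs = cuts, percentile = percentile,
      nPairs = M)
}

#' Build an association engine
#'
#' Scores all gene pairs of every catalog, attaches the imported EP table
#' if given, computes the genome-wide percentile thresholds, and indexes
#' each type's scores as a sparse symmetric matrix for fast per-query
#' profile extraction. All catalogs (and the EP table, if its universe was
#' declared) must share one gene universe.
#'
#' @param catalogs list of [EvidenceCatalog-class] objects (at most one
#'   per type).
#' @param epTable optional EP [PairScoreTable-class] from
#'   [importExternalScores()]; pairs naming genes outside the universe are
#'   dropped with a warning.
#' @param percentile evidence-threshold percentile; default 95.
#' @inheritParams hypergeomScore
#' @return an [AssociationEngine-class] object.
#' @export
buildEngine <- function(catalogs, epTable = NULL, percentile = 95,
                        logBase = 10, probFloor = 1e-300) {
  if (is(catalogs, "EvidenceCatalog")) catalogs <- list(catalogs)
  if (!length(catalogs)) stopUsage("no catalogs supplied")
  tys <- vapply(catalogs, assocType, character(1))
  if (anyDuplicated(tys)) stopData("more than one catalog per type")
  names(catalogs) <- tys
  u <- geneUniverse(catalogs[[1]])
  for (ct in catalogs)
    if (!identical(geneUniverse(ct), u))
      stopData("catalogs disagree on the gene universe")
  tables <- lapply(catalogs, scoreAllPairs,
                   logBase = logBase, probFloor = probFloor)
  epMin <- 0
  if (!is.null(epTable)) {
    stopifnot(is(epTable, "PairScoreTable"))
    if (epTable@assocType != "EP")
      stopData("epTable must carry assocType 'EP'")
    sc <- epTable@scores
    keep <- sc$geneA %in% u & sc$geneB %in% u
    if (any(!keep)) {
      warning(sum(!keep), " EP pair(s) outside the universe dropped")
      sc <- sc[keep, , drop = FALSE]
    }
    epTable <- PairScoreTable("EP", sc, u)
    if (nrow(sc)) epMin <- min(sc$score)
    tables$EP <- epTable
  }
  thr <- computeThresholds(tables, u, percentile)
  mats <- lapply(tables, function(tb) {
    sc <- tb@scores
    ## EP entries are stored shifted by epMin so that structural zeros
    ## coincide with the fill value for absent pairs
    x <- if (tb@assocType == "EP") sc$score - epMin else sc$score
    ia <- match(sc$geneA, u); ib <- match(sc$geneB, u)
    Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(x, x),
                         dims = c(length(u), length(u)),
                         dimnames = list(u, u))
  })
  new("AssociationEngine", geneUniverse = u, tables = tables,
      matrices = mats, thresholds = thr, epMin = epMin)
}

## raw score profile of `gene` against every other universe gene,
## implicit values filled in (0, or epMin for EP)
rawProfile <- function(engine, type, gene) {
  v <- engine@matrices[[type]][gene, ]
  if (type == "EP") v <- v + engine@epMin
  v[names(v) != gene]
}

availableTypes <- function(engine) names(engine@tables)

#' Query the engine for associated genes
#'
#' For one query gene: extracts the raw score profile of every engine
#' type, min-max normalizes each chosen type over the candidates, sums the
#' chosen normalized scores into the OAS, sorts candidates by descending
#' OAS (ties broken by ascending gene id, for determinism), truncates to
#' `topK`, and reports per-type evidence flags — raw score strictly above
#' that type's genome-wide percentile cutoff — for every type the engine
#' holds, whether chosen or not. Flags are a property of the raw score
#' distribution, so restricting `chosen` changes OAS and ranking but never
#' the flags.
#'
#' @param engine an [AssociationEngine-class] object.
#' @param gene the query gene id (case-insensitive); an unknown id raises
#'   an error listing the nearest identifiers.
#' @param chosen non-empty subset of the engine's types to sum; defaults
#'   to all of them.
#' @param topK maximum number of associated genes reported (>= 1).
#' @return a [QueryResult-class] object.
#' @export
queryAssociated <- function(engine, gene, chosen = availableTypes(engine),
                            topK = 50L) {
  stopifnot(is(engine, "AssociationEngine"))
  gene <- normalizeGeneIds(gene)
  u <- engine@geneUniverse
  if (!gene %in% u) {
    near <- u[order(adist(gene, u))]
    stopUsage("unknown gene '", gene, "'; nearest identifiers: ",
              paste(head(near, 3L), collapse = ", "))
  }
  if (!length(chosen)) stopUsage("no association types chosen")
  chosen <- unique(as.character(chosen))
  bad <- setdiff(chosen, availableTypes(engine))
  if (length(bad))
    stopUsage("type(s) not held by this engine: ",
              paste(bad, collapse = ", "))
  topK <- as.integer(topK)
  if (is.na(topK) || topK < 1L) stopUsage("topK must be a positive integer")

  raws <- lapply(availableTypes(engine), rawProfile, engine = engine,
                 gene = gene)
  names(raws) <- availableTypes(engine)
  profs <- lapply(chosen, function(ty)
    normalizeProfile(raws[[ty]], gene, ty))
  names(profs) <- chosen
  oas <- overallScore(profs, chosen)
  ord <- order(-oas, names(oas))
  keep <- head(ord, topK)
  cand <- names(oas)[keep]

  rec <- data.frame(rank = seq_along(cand), gene = cand,
                    oas = unname(oas[keep]), stringsAsFactors = FALSE)
  for (ty in chosen)
    rec[[paste0("score.", ty)]] <- unname(profs[[ty]]@values[cand])
  cuts <- engine@thresholds@cutoffs
  for (ty in availableTypes(engine))
    rec[[paste0("evidence.", ty)]] <- unname(raws[[ty]][cand] > cuts[[ty]])
  new("QueryResult", query = gene, chosen = chosen,
      flagTypes = availableTypes(engine), records = rec)
}

#' Export a query result
#'
#' `exportResult` writes the ranked table as tab-separated text with a
#' header (`rank`, `gene`, one 0/1 flag column per reported type, one
#' normalized-score column per chosen type, `oas`); `writeResultJSON`
#' writes the same content as structured JSON.
#'
#' @param result a [QueryResult-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportResult <- function(result, path) {
  stopifnot(is(result, "QueryResult"))
  rec <- result@records
  evCols <- paste0("evidence.", result@flagTypes)
  scCols <- paste0("score.", result@chosen)
  header <- c("rank", "gene", paste0("ev_", result@flagTypes),
              paste0("S_", result@chosen), "oas")
  rows <- vapply(seq_len(nrow(rec)), function(r) {
    paste(c(rec$rank[r], rec$gene[r],
            as.integer(unlist(rec[r, evCols, drop = FALSE])),
            fmtNum(unlist(rec[r, scCols, drop = FALSE])),
            fmtNum(rec$oas[r])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname exportResult
#' @export
writeResultJSON <- function(result, path) {
  stopifnot(is(result, "QueryResult"))
  obj <- list(query = result@query, chosen = result@chosen,
              flagTypes = result@flagTypes, records = result@records)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
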