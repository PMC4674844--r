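#' @include AllClasses.R
NULL

## Gene ids are case-normalized to upper case everywhere at the boundary:
## yeast gene names appear in mixed case across sources.
normalizeGeneIds <- function(x) toupper(trimws(x))

#' Construct an evidence catalog from membership pairs
#'
#' Programmatic constructor behind [loadCatalog()]. For attribute-style
#' types (`TFB`, `TFR`, `MP`, `FA`, `LE`) `memberships` holds
#' (attribute, gene) rows; for interaction types (`PI`, `GI`) it holds
#' (gene, gene) rows, which are symmetrized: each row (x, y) adds y to x's
#' partner set and x to y's. Self-interactions are dropped with a warning
#' (self-membership would inflate the overlap of every pair trivially).
#' Rows whose gene is not in the universe are skipped with one warning
#' reporting the count. Duplicate rows collapse to a single membership.
#' Every universe gene receives an entry, empty when unannotated, so that
#' per-query normalization can range over the whole genome.
#'
#' @param assocType one of the seven scored type codes.
#' @param geneUniverse character vector of gene ids (case-insensitive).
#' @param memberships two-column data.frame (or matrix): attribute and gene
#'   for attribute-style types, two genes for PI/GI. May have zero rows.
#' @param attrUniverse optional explicit attribute universe for
#'   attribute-style types; defaults to the distinct attributes observed.
#'   Ignored (forced to the gene universe) for PI/GI.
#' @return an [EvidenceCatalog-class] object.
#' @examples
#' EvidenceCatalog("TFB", c("g1", "g2", "g3"),
#'                 data.frame(attribute = c("T1", "T1", "T2"),
#'                            gene = c("g1", "g2", "g1")))
#' @export
EvidenceCatalog <- function(assocType, geneUniverse, memberships,
                            attrUniverse = NULL) {
  assocType <- .checkType(assocType, allowEP = FALSE)
  geneUniverse <- sort(unique(normalizeGeneIds(geneUniverse)))
  if (!length(geneUniverse)) stopData("gene universe is empty")
  memberships <- as.data.frame(memberships, stringsAsFactors = FALSE)
  if (ncol(memberships) != 2L)
    stopData("memberships must have exactly two columns")
  colnames(memberships) <- c("attribute", "gene")
  memberships$gene <- normalizeGeneIds(memberships$gene)

  interaction <- assocType %in% INTERACTION_TYPES
  if (interaction) {
    memberships$attribute <- normalizeGeneIds(memberships$attribute)
    self <- memberships$attribute == memberships$gene
    if (any(self)) {
      warning(sum(self), " self-interaction row(s) dropped [",
              assocType, "]")
      memberships <- memberships[!self, , drop = FALSE]
    }
    ## undirected: each row contributes both directions
    memberships <- data.frame(
      attribute = c(memberships$attribute, memberships$gene),
      gene = c(memberships$gene, memberships$attribute),
      stringsAsFactors = FALSE)
    known <- memberships$gene %in% geneUniverse &
      memberships$attribute %in% geneUniverse
  } else {
    known <- memberships$gene %in% geneUniverse
  }
  if (any(!known)) {
    warning(sum(!known) / (if (interaction) 2L else 1L),
            " row(s) with gene(s) outside the universe skipped [",
            assocType, "]")
    memberships <- memberships[known, , drop = FALSE]
  }

  if (interaction) {
    attrUniverse <- geneUniverse
  } else if (is.null(attrUniverse)) {
    attrUniverse <- sort(unique(memberships$attribute))
  } else {
    attrUniverse <- sort(unique(as.character(attrUniverse)))
    if (!all(memberships$attribute %in% attrUniverse))
      stopData("memberships contain attributes outside the declared attribute universe")
  }

  sets <- lapply(
    split(memberships$attribute,
          factor(memberships$gene, levels = geneUniverse)),
    function(a) sort(unique(a)))
  new("EvidenceCatalog", assocType = assocType,
      geneUniverse = geneUniverse, attrUniverse = attrUniverse,
      geneAttrs = sets)
}

## shared line-oriented reader: skips '#' comments and blank lines,
## errors with the 1-based line number on a malformed row.
readTwoColumn <- function(path, nCols = 2L) {
  if (!file.exists(path)) stopData("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(parts)) {
    out <- as.data.frame(matrix(character(), 0, nCols),
                         stringsAsFactors = FALSE)
    colnames(out) <- paste0("V", seq_len(nCols))
    return(out)
  }
  bad <- lengths(parts) != nCols
  if (any(bad))
    stopData("malformed row at line ", idx[which(bad)[1]], " of ", path,
             ": expected ", nCols, " tab-separated columns")
  out <- as.data.frame(matrix(unlist(parts, use.names = FALSE),
                              ncol = nCols, byrow = TRUE),
                       stringsAsFactors = FALSE)
  colnames(out) <- paste0("V", seq_len(nCols))
  out
}

#' Load an evidence catalog from a two-column file
#'
#' Reads a tab-separated attribute–gene table (gene–gene pairs for the
#' interaction types `PI`/`GI`), one pair per line, `#` comment lines
#' skipped, and builds the per-gene attribute sets. The hypergeometric
#' universe size N follows the type: the number of distinct attributes in
#' the catalog for attribute-style types, the gene-universe size for the
#' interaction types.
#'
#' @param path file path.
#' @param assocType one of the seven scored type codes (not `"EP"`).
#' @param geneUniverse the gene universe; rows naming genes outside it are
#'   skipped with a warning.
#' @return an [EvidenceCatalog-class] object.
#' @seealso [EvidenceCatalog()] for the programmatic constructor,
#'   [loadGeneUniverse()].
#' @export
loadCatalog <- function(path, assocType, geneUniverse) {
  EvidenceCatalog(assocType, geneUniverse, readTwoColumn(path, 2L))
}

#' Load a gene universe file
#'
#' One gene id per line, `#` comments skipped; ids are upper-cased,
#' de-duplicated and sorted.
#'
#' @param path file path.
#' @return sorted character vector of gene ids.
#' @export
loadGeneUniverse <- function(path) {
  if (!file.exists(path)) stopData("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  u <- sort(unique(normalizeGeneIds(lines)))
  if (!length(u)) stopData("gene universe file is empty: ", path)
  u
}

#' Hypergeometric parameters of a gene pair
#'
#' Looks up the attribute sets of two distinct universe genes and returns
#' the four counts of the overlap test: the universe size N, the set sizes
#' n and m, and the intersection size k.
#'
#' @param catalog an [EvidenceCatalog-class] object.
#' @param a,b gene ids (case-insensitive), `a != b`.
#' @return a [HypergeomParams-class] object.
#' @examples
#' cat1 <- EvidenceCatalog("TFB", c("g1", "g2"),
#'                         data.frame(attr = c("T1", "T2", "T1"),
#'                                    gene = c("g1", "g1", "g2")))
#' pairParams(cat1, "g1", "g2")   # N=2, n=2, m=1, k=1
#' @export
pairParams <- function(catalog, a, b) {
  stopifnot(is(catalog, "EvidenceCatalog"))
  a <- normalizeGeneIds(a); b <- normalizeGeneIds(b)
  for (g in c(a, b)) {
    if (!g %in% catalog@geneUniverse)
      stopUsage("gene '", g, "' is not in the universe")
  }
  if (a == b) stopUsage("self-pair: a and b must differ (got '", a, "')")
  sa <- catalog@geneAttrs[[a]]
  sb <- catalog@geneAttrs[[b]]
  hypergeomParams(universeSize(catalog), length(sa), length(sb),
                  length(intersect(sa, sb)))
}
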