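#' @include catalog.R
NULL

#' Hypergeometric association score
#'
#' The association score of a gene pair under one evidence type: the
#' negative log (base 10 by default) of the upper-tail probability
#' P(X >= k) that two random attribute sets of sizes n and m drawn from a
#' universe of N attributes share at least the observed k. The tail is
#' computed in log space via [stats::phyper()] so scores of several
#' hundred remain finite; the probability is clamped from below at
#' `probFloor` before the log so the score is always finite. A zero
#' observed overlap gives tail probability 1 and score 0, as does the
#' degenerate full overlap of full sets (n = m = k = N).
#'
#' @param N universe size, or a [HypergeomParams-class] object (in which
#'   case `n`, `m`, `k` are ignored). Vectors recycle.
#' @param n,m attribute-set sizes of the two genes.
#' @param k observed overlap.
#' @param logBase base of the logarithm (default 10).
#' @param probFloor lower clamp for the tail probability (default 1e-300).
#' @return non-negative numeric score(s).
#' @examples
#' hypergeomScore(10, 3, 3, 3)   # -log10(1/120) = 2.0792
#' hypergeomScore(10, 3, 3, 0)   # 0: a zero overlap is never surprising
#' @export
hypergeomScore <- function(N, n, m, k, logBase = 10, probFloor = 1e-300) {
  if (is(N, "HypergeomParams")) {
    p <- N
    N <- p@N; n <- p@n; m <- p@m; k <- p@k
  }
  len <- max(length(N), length(n), length(m), length(k))
  N <- as.double(rep_len(N, len)); n <- as.double(rep_len(n, len))
  m <- as.double(rep_len(m, len)); k <- as.double(rep_len(k, len))
  if (any(is.na(N) | is.na(n) | is.na(m) | is.na(k)) ||
      any(N < 0 | n < 0 | m < 0 | k < 0) ||
      any(n > N) || any(m > N) || any(k > pmin(n, m)))
    stopUsage("invalid hypergeometric parameters: need 0 <= k <= min(n, m) and n, m <= N")
  ## P(X >= k): work on the log scale, then clamp. The tail is symmetric
  ## in (n, m); evaluate with the ordered pair so that swapping the two
  ## genes gives a bit-identical score.
  lo <- pmin(n, m); hi <- pmax(n, m)
  logp <- phyper(k - 1, lo, N - lo, hi, lower.tail = FALSE, log.p = TRUE)
  logp <- pmax(logp, log(probFloor))
  score <- -logp / log(logBase)
  score[k == 0] <- 0            # tail is exactly 1; avoid -0 artifacts
  pmax(score, 0)
}

#' Score one gene pair from a catalog
#'
#' Convenience composition of [pairParams()] and [hypergeomScore()].
#'
#' @inheritParams pairParams
#' @inheritParams hypergeomScore
#' @return non-negative numeric score.
#' @export
scorePair <- function(catalog, a, b, logBase = 10, probFloor = 1e-300) {
  hypergeomScore(pairParams(catalog, a, b),
                 logBase = logBase, probFloor = probFloor)
}

#' Construct a pair-score table
#'
#' Rows are canonicalized to `geneA < geneB` and sorted. Duplicate pairs
#' with equal scores collapse; duplicates with conflicting scores are an
#' error.
#'
#' @param assocType association type code (any of the eight; `"EP"` rows
#'   may carry negative scores).
#' @param scores data.frame with columns geneA, geneB, score.
#' @param geneUniverse the gene universe the pairs live in.
#' @return a [PairScoreTable-class] object.
#' @export
PairScoreTable <- function(assocType, scores, geneUniverse) {
  assocType <- .checkType(assocType)
  geneUniverse <- sort(unique(normalizeGeneIds(geneUniverse)))
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  if (ncol(scores) != 3L)
    stopData("scores must have three columns (geneA, geneB, score)")
  colnames(scores) <- c("geneA", "geneB", "score")
  scores$geneA <- normalizeGeneIds(scores$geneA)
  scores$geneB <- normalizeGeneIds(scores$geneB)
  scores$score <- as.numeric(scores$score)
  if (nrow(scores)) {
    if (any(scores$geneA == scores$geneB))
      stopData("self-pairs are not allowed in a score table")
    swap <- scores$geneA > scores$geneB
    tmp <- scores$geneA[swap]
    scores$geneA[swap] <- scores$geneB[swap]
    scores$geneB[swap] <- tmp
    key <- paste(scores$geneA, scores$geneB, sep = "\r")
    if (anyDuplicated(key)) {
      rng <- tapply(scores$score, key, function(s) max(s) - min(s))
      if (any(rng > 0)) {
        bad <- names(rng)[rng > 0][1]
        stopData("conflicting duplicate scores for pair ",
                 gsub("\r", "-", bad, fixed = TRUE))
      }
      scores <- scores[!duplicated(key), , drop = FALSE]
    }
    scores <- scores[order(scores$geneA, scores$geneB), , drop = FALSE]
    rownames(scores) <- NULL
  }
  new("PairScoreTable", assocType = assocType, scores = scores,
      geneUniverse = geneUniverse)
}

#' Score all gene pairs of a catalog
#'
#' Computes the hypergeometric association score for every unordered pair
#' of universe genes with a non-empty attribute overlap (k >= 1); pairs
#' with k = 0 score exactly 0 and are left implicit. Overlap counts come
#' from one sparse cross-product of the gene-by-attribute membership
#' matrix, so the cost scales with the number of co-annotated pairs rather
#' than the full quadratic grid.
#'
#' @param catalog an [EvidenceCatalog-class] object.
#' @inheritParams hypergeomScore
#' @return a [PairScoreTable-class] object.
#' @export
scoreAllPairs <- function(catalog, logBase = 10, probFloor = 1e-300) {
  stopifnot(is(catalog, "EvidenceCatalog"))
  u <- catalog@geneUniverse
  attrs <- catalog@attrUniverse
  empty <- data.frame(geneA = character(), geneB = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!length(attrs))
    return(new("PairScoreTable", assocType = catalog@assocType,
               scores = empty, geneUniverse = u))
  sets <- catalog@geneAttrs
  i <- rep.int(seq_along(u), lengths(sets))
  j <- match(unlist(sets, use.names = FALSE), attrs)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(u), length(attrs)))
  K <- as(as(Matrix::tcrossprod(M), "generalMatrix"), "TsparseMatrix")
  sel <- K@i < K@j & K@x >= 1
  ia <- K@i[sel] + 1L; ib <- K@j[sel] + 1L; kk <- K@x[sel]
  if (!length(ia))
    return(new("PairScoreTable", assocType = catalog@assocType,
               scores = empty, geneUniverse = u))
  nsz <- lengths(sets)
  H <- hypergeomScore(universeSize(catalog), nsz[ia], nsz[ib], kk,
                      logBase = logBase, probFloor = probFloor)
  o <- order(ia, ib)
  scores <- data.frame(geneA = u[ia][o], geneB = u[ib][o],
                       score = as.numeric(H)[o], stringsAsFactors = FALSE)
  new("PairScoreTable", assocType = catalog@assocType, scores = scores,
      geneUniverse = u)
}

## deterministic numeric formatting used by every writer
fmtNum <- function(x) sprintf("%.12g", x)

#' Read and write pair-score tables
#'
#' Score tables serialize to three-column tab-separated files
#' (gene_a, gene_b, score), genes in lexicographic order within a row and
#' rows sorted, so a rerun on identical input is byte-identical. `#`
#' comment lines are skipped on read; a non-numeric score is an error
#' naming the offending line.
#'
#' @param x a [PairScoreTable-class] object.
#' @param path file path.
#' @param assocType type code to attach to the read table.
#' @param geneUniverse optional universe for the read table; defaults to
#'   the genes observed in the file.
#' @return `writeScoreTable` returns `path` invisibly; `readScoreTable`
#'   returns a [PairScoreTable-class].
#' @export
writeScoreTable <- function(x, path) {
  stopifnot(is(x, "PairScoreTable"))
  sc <- x@scores
  writeLines(paste(sc$geneA, sc$geneB, fmtNum(sc$score), sep = "\t"), path)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path, assocType, geneUniverse = NULL) {
  df <- readTwoColumn(path, 3L)
  sc <- suppressWarnings(as.numeric(df$V3))
  if (anyNA(sc) && nrow(df)) {
    bad <- which(is.na(sc))[1]
    ## recover the original line number for the message
    lines <- readLines(path, warn = FALSE)
    dataLines <- which(!grepl("^\\s*(#|$)", lines))
    stopData("non-numeric score at line ", dataLines[bad], " of ", path)
  }
  if (is.null(geneUniverse))
    geneUniverse <- sort(unique(normalizeGeneIds(c(df$V1, df$V2))))
  PairScoreTable(assocType,
                 data.frame(geneA = df$V1, geneB = df$V2, score = sc,
                            stringsAsFactors = FALSE),
                 geneUniverse)
}

#' Look up a pair score
#'
#' Symmetric lookup in a sparse score table; an absent pair returns
#' `default` (0, the implicit value for the hypergeometric types).
#'
#' @param table a [PairScoreTable-class] object.
#' @param a,b gene ids.
#' @param default value returned for pairs without an explicit row.
#' @return numeric score.
#' @export
lookupScore <- function(table, a, b, default = 0) {
  stopifnot(is(table, "PairScoreTable"))
  a <- normalizeGeneIds(a); b <- normalizeGeneIds(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  sc <- table@scores
  hit <- match(paste(lo, hi, sep = "\r"),
               paste(sc$geneA, sc$geneB, sep = "\r"))
  ifelse(is.na(hit), default, sc$score[hit])
}
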