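#' @include scoring.R
NULL

#' Import an external expression-profile score table
#'
#' Expression-profile (EP) association scores are not computed here; they
#' come precomputed from an expression-compendium search engine and are
#' imported as a three-column tab-separated file (gene_a, gene_b, score).
#' The table is symmetric by construction; a pair listed twice with the
#' same score collapses to one entry, conflicting duplicates are an error.
#' Pairs absent from the table are treated as carrying the minimum
#' observed score at normalization time (coverage of such compendia is
#' partial, and absence is non-evidence).
#'
#' @param path file path.
#' @param geneUniverse optional gene universe; defaults to the genes seen
#'   in the file.
#' @return a [PairScoreTable-class] with `assocType == "EP"`.
#' @export
importExternalScores <- function(path, geneUniverse = NULL) {
  readScoreTable(path, "EP", geneUniverse)
}

#' Min-max normalize a raw score profile
#'
#' Rescales a query gene's raw association scores over all candidate genes
#' into \[0, 1\]: S(b) = (H(b) - min H) / (max H - min H), the min and max
#' running over every candidate b (the whole universe except the query
#' itself; including the query would let the trivial self-association
#' dominate the max). When all raw scores are equal — an uninformative
#' evidence type for this query — every S is 0, so the type contributes
#' nothing downstream.
#'
#' @param raw named numeric vector of raw scores over the candidate genes
#'   (an entry named after the query, if present, is dropped).
#' @param query the query gene id.
#' @param assocType type code recorded on the profile.
#' @return a [NormalizedProfile-class] object.
#' @examples
#' p <- normalizeProfile(c(g2 = 0, g3 = 1, g4 = 4), "g1", "TFB")
#' p@values   # 0, 0.25, 1
#' @export
normalizeProfile <- function(raw, query, assocType = "TFB") {
  query <- normalizeGeneIds(query)
  assocType <- .checkType(assocType)
  if (is.null(names(raw))) stopData("raw profile must be named by gene")
  names(raw) <- normalizeGeneIds(names(raw))
  raw <- raw[names(raw) != query]
  if (!length(raw)) stopData("empty candidate set for query ", query)
  if (any(!is.finite(raw))) stopData("raw scores must be finite")
  lo <- min(raw); hi <- max(raw)
  vals <- if (hi > lo) (raw - lo) / (hi - lo) else raw * 0
  new("NormalizedProfile", query = query, assocType = assocType,
      values = vals)
}

#' Overall association score
#'
#' Sums the normalized scores of the chosen evidence types per candidate
#' gene: OAS(b) = sum over chosen i of S_i(query, b), ranging over
#' \[0, number of chosen types\].
#'
#' @param profiles list of [NormalizedProfile-class] objects for one query,
#'   named by (or carrying) their association type.
#' @param chosen non-empty character vector of type codes to sum.
#' @return named numeric vector of OAS values over the candidates.
#' @export
overallScore <- function(profiles, chosen) {
  if (!length(chosen)) stopUsage("no association types chosen")
  chosen <- unique(vapply(chosen, .checkType, character(1)))
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, assocType, character(1))
  missing <- setdiff(chosen, names(profiles))
  if (length(missing))
    stopUsage("no profile for chosen type(s): ",
              paste(missing, collapse = ", "))
  profs <- profiles[chosen]
  qs <- unique(vapply(profs, function(p) p@query, character(1)))
  if (length(qs) != 1L)
    stopData("profiles mix different query genes: ",
             paste(qs, collapse = ", "))
  cand <- names(profs[[1]]@values)
  oas <- numeric(length(cand))
  names(oas) <- cand
  for (p in profs) {
    if (!setequal(names(p@values), cand))
      stopData("profiles cover different candidate sets")
    oas <- oas + p@values[cand]
  }
  oas
}
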