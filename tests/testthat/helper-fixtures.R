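# Programmatic fixtures; no files are shipped, everything is built at
# test time under fixed seeds.

geneIds <- function(n) sprintf("G%03d", seq_len(n))

# random attribute-style catalog (membership probability p)
randomCatalog <- function(nGenes = 10, nAttrs = 8, p = 0.3,
                          type = "TFB", seed = 1) {
  set.seed(seed)
  genes <- geneIds(nGenes)
  attrs <- sprintf("A%02d", seq_len(nAttrs))
  mem <- matrix(runif(nGenes * nAttrs) < p, nGenes, nAttrs)
  idx <- which(mem, arr.ind = TRUE)
  EvidenceCatalog(type, genes,
                  data.frame(attribute = attrs[idx[, 2]],
                             gene = genes[idx[, 1]]),
                  attrUniverse = attrs)
}

# random interaction catalog (edge probability p)
randomInteractionCatalog <- function(nGenes = 10, p = 0.3, type = "PI",
                                     seed = 1) {
  set.seed(seed)
  genes <- geneIds(nGenes)
  pairs <- t(combn(genes, 2))
  on <- runif(nrow(pairs)) < p
  EvidenceCatalog(type, genes,
                  data.frame(a = pairs[on, 1], b = pairs[on, 2]))
}

# named attribute sets of a catalog (plain list form for the oracles)
catalogSets <- function(catalog) geneAttrs(catalog)

# tiny deterministic engine: 8-gene universe, planted pair G001/G002
# sharing most attributes under every type, full EP cover
tinyEngineInputs <- function(seed = 42, nGenes = 8) {
  set.seed(seed)
  genes <- geneIds(nGenes)
  catalogs <- list()
  for (ty in assocTypes(scoredOnly = TRUE)) {
    if (ty %in% c("PI", "GI")) {
      pairs <- t(combn(genes, 2))
      on <- runif(nrow(pairs)) < 0.25
      df <- data.frame(a = pairs[on, 1], b = pairs[on, 2])
      partners <- setdiff(genes, genes[1:2])[1:3]
      df <- rbind(df,
                  data.frame(a = rep(genes[1:2], each = 3),
                             b = rep(partners, 2)))
      catalogs[[ty]] <- EvidenceCatalog(ty, genes, df)
    } else {
      attrs <- sprintf("%s%02d", ty, 1:10)
      mem <- matrix(runif(nGenes * 10) < 0.2, nGenes, 10)
      mem[1:2, 1:5] <- TRUE
      idx <- which(mem, arr.ind = TRUE)
      catalogs[[ty]] <- EvidenceCatalog(
        ty, genes, data.frame(attribute = attrs[idx[, 2]],
                              gene = genes[idx[, 1]]),
        attrUniverse = attrs)
    }
  }
  pairs <- t(combn(genes, 2))
  sc <- runif(nrow(pairs))
  sc[pairs[, 1] == genes[1] & pairs[, 2] == genes[2]] <- 1.5
  ep <- PairScoreTable("EP",
                       data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                                  score = sc), genes)
  list(catalogs = catalogs, ep = ep, genes = genes)
}

tinyEngine <- function(seed = 42, nGenes = 8, percentile = 95) {
  inp <- tinyEngineInputs(seed, nGenes)
  buildEngine(inp$catalogs, inp$ep, percentile = percentile)
}

writeTempFile <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
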