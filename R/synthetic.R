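#' @include catalog.R integration.R
NULL

#' Synthetic gene identifiers
#'
#' Zero-padded identifiers `G001`, `G002`, ... used by the synthetic
#' generator (width grows with the universe size).
#'
#' @param numGenes universe size.
#' @return character vector of gene ids.
#' @export
syntheticGeneIds <- function(numGenes) {
  sprintf("G%0*d", max(3L, nchar(as.character(numGenes))),
          seq_len(numGenes))
}

#' Specify a synthetic catalog bundle
#'
#' Defaults describe the validation condition used throughout the package:
#' a 100-gene universe, 50 attributes per attribute-style type, a 5%
#' background membership (and interaction-edge) probability, and one
#' planted pair of genes sharing a block of 10 common attributes per type.
#' With those settings the planted pair's overlap is overwhelmingly
#' unlikely by chance under every type, so the partner should surface at
#' rank 1 for the planted query.
#'
#' @param numGenes universe size (default 100).
#' @param attrUniverseSize attributes per attribute-style type (default 50).
#' @param backgroundProb background membership probability (default 0.05).
#' @param plantedModules list of `list(genes = <ids>, shared = <count>)`;
#'   defaults to one module of the first two genes sharing 10 attributes.
#' @param seed integer seed; one stream drives all types in a fixed order,
#'   so identical seeds give byte-identical output files.
#' @return a [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(numGenes = 100L, attrUniverseSize = 50L,
                          backgroundProb = 0.05,
                          plantedModules = NULL, seed = 1L) {
  numGenes <- as.integer(numGenes)
  if (is.null(plantedModules))
    plantedModules <- list(list(genes = syntheticGeneIds(numGenes)[1:2],
                                shared = 10L))
  new("SyntheticSpec", numGenes = numGenes,
      attrUniverseSize = as.integer(attrUniverseSize),
      backgroundProb = as.numeric(backgroundProb),
      plantedModules = plantedModules, seed = as.integer(seed))
}

## unordered pair index helpers over a sorted universe
allPairIdx <- function(G) {
  ia <- rep.int(seq_len(G - 1L), (G - 1L):1L)
  ib <- sequence((G - 1L):1L) + ia
  list(a = ia, b = ib)
}

#' Generate a synthetic evidence bundle
#'
#' Draws seven evidence catalogs and an expression-profile score table
#' from a seeded spec and writes them in the exact file formats the
#' loaders consume. Background (gene, attribute) memberships — and, for
#' the interaction types, background undirected edges — occur
#' independently with probability `backgroundProb`. Genes of a planted
#' module additionally share `shared` common attributes per attribute
#' type, and `shared` common interaction partners per interaction type.
#' EP background pairs draw scores uniformly on \[0, 1\]; module pairs get
#' 1 plus uniform noise, so planted pairs separate cleanly from
#' background. One pseudo-random stream seeded with `spec@seed` drives all
#' types in a fixed order (TFB, TFR, MP, FA, PI, GI, LE, EP), making
#' output byte-identical across reruns of the same spec.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @param dir output directory (created if needed). Files written:
#'   `tfb.tsv` ... `le.tsv`, `ep.tsv`, `universe.txt`.
#' @return invisibly, a list with the loaded `catalogs` (named list of
#'   [EvidenceCatalog-class]), the `epTable`, the `universe`, the `spec`
#'   and the file `paths`.
#' @export
generateSyntheticData <- function(spec, dir) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  G <- spec@numGenes
  U <- spec@attrUniverseSize
  genes <- syntheticGeneIds(G)
  attrs <- sprintf("A%0*d", max(3L, nchar(as.character(U))), seq_len(U))
  set.seed(spec@seed)

  paths <- character(0)
  writePairs <- function(df, file) {
    p <- file.path(dir, file)
    o <- order(df[[1]], df[[2]])
    writeLines(paste(df[[1]][o], df[[2]][o], sep = "\t"), p)
    p
  }

  for (ty in ASSOC_TYPES) {
    fname <- paste0(tolower(ty), ".tsv")
    if (ty %in% c("TFB", "TFR", "MP", "FA", "LE")) {
      mem <- matrix(runif(G * U) < spec@backgroundProb, G, U)
      for (mod in spec@plantedModules) {
        shared <- sample.int(U, mod$shared)
        mem[match(mod$genes, genes), shared] <- TRUE
      }
      idx <- which(mem, arr.ind = TRUE)
      df <- data.frame(attr = attrs[idx[, 2]], gene = genes[idx[, 1]],
                       stringsAsFactors = FALSE)
      paths[ty] <- writePairs(df, fname)
    } else if (ty %in% INTERACTION_TYPES) {
      pr <- allPairIdx(G)
      on <- runif(length(pr$a)) < spec@backgroundProb
      ea <- genes[pr$a[on]]; eb <- genes[pr$b[on]]
      for (mod in spec@plantedModules) {
        partners <- sample(setdiff(genes, mod$genes), mod$shared)
        ea <- c(ea, rep(mod$genes, each = mod$shared))
        eb <- c(eb, rep(partners, times = length(mod$genes)))
      }
      lo <- pmin(ea, eb); hi <- pmax(ea, eb)
      keep <- !duplicated(paste(lo, hi))
      df <- data.frame(a = lo[keep], b = hi[keep],
                       stringsAsFactors = FALSE)
      paths[ty] <- writePairs(df, fname)
    } else { # EP
      pr <- allPairIdx(G)
      sc <- runif(length(pr$a))
      for (mod in spec@plantedModules) {
        mi <- match(mod$genes, genes)
        inMod <- pr$a %in% mi & pr$b %in% mi
        sc[inMod] <- 1 + runif(sum(inMod))
      }
      p <- file.path(dir, fname)
      writeLines(paste(genes[pr$a], genes[pr$b], fmtNum(sc), sep = "\t"),
                 p)
      paths[ty] <- p
    }
  }
  upath <- file.path(dir, "universe.txt")
  writeLines(genes, upath)
  paths["universe"] <- upath

  ## catalogs are rebuilt from the written files, but with the full drawn
  ## attribute universe attached: an attribute that happens never to be
  ## drawn still belongs to the test universe N (files carry memberships
  ## only, so loadCatalog on them derives N from the attributes observed)
  catalogs <- lapply(SCORED_TYPES, function(ty)
    EvidenceCatalog(ty, genes, readTwoColumn(paths[[ty]], 2L),
                    attrUniverse = if (ty %in% INTERACTION_TYPES) NULL
                                   else attrs))
  names(catalogs) <- SCORED_TYPES
  invisible(list(catalogs = catalogs,
                 epTable = importExternalScores(paths[["EP"]], genes),
                 universe = genes, spec = spec, paths = paths))
}

#' Hand-written worked example catalog
#'
#' A 12-gene, 10-TF binding catalog small enough to score by hand,
#' mirroring the kind of detail view a regulon-similarity lookup produces:
#' the designated query/partner pair `GENE01`/`GENE02` are both bound by
#' exactly TFs `TF01`-`TF05`, every other gene carries at most one of
#' those TFs, and `GENE12` is unannotated. The documented score of the
#' pair is the hypergeometric index with N = 10, n = m = k = 5:
#' P(X >= 5) = 1/C(10,5) = 1/252, so H = -log10(1/252) = 2.4014.
#'
#' @return list with `memberships` (attribute–gene data.frame),
#'   `universe`, the `pair` the documentation scores, its `params`
#'   (N, n, m, k) and documented `score`, and the per-gene `setSizes`.
#' @examples
#' toy <- workedToyCatalog()
#' cat1 <- EvidenceCatalog("TFB", toy$universe, toy$memberships)
#' scorePair(cat1, "GENE01", "GENE02")   # 2.4014
#' @export
workedToyCatalog <- function() {
  sets <- list(
    GENE01 = paste0("TF0", 1:5),
    GENE02 = paste0("TF0", 1:5),
    GENE03 = c("TF01", "TF06"),
    GENE04 = c("TF02", "TF07"),
    GENE05 = c("TF03", "TF08"),
    GENE06 = c("TF04", "TF09"),
    GENE07 = c("TF05", "TF10"),
    GENE08 = c("TF06", "TF07"),
    GENE09 = c("TF08", "TF09"),
    GENE10 = c("TF10"),
    GENE11 = c("TF06"),
    GENE12 = character(0))
  memberships <- data.frame(
    attribute = unlist(sets, use.names = FALSE),
    gene = rep(names(sets), lengths(sets)),
    stringsAsFactors = FALSE)
  list(memberships = memberships,
       universe = names(sets),
       pair = c("GENE01", "GENE02"),
       params = c(N = 10L, n = 5L, m = 5L, k = 5L),
       score = -log10(1 / choose(10, 5)),
       setSizes = lengths(sets))
}

#' Write the worked example catalog to files
#'
#' Writes the [workedToyCatalog()] membership table and universe in the
#' loader formats.
#'
#' @param dir output directory.
#' @return named character vector of file paths, invisibly.
#' @export
writeToyCatalog <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- workedToyCatalog()
  tfb <- file.path(dir, "tfb.tsv")
  o <- order(toy$memberships$attribute, toy$memberships$gene)
  writeLines(paste(toy$memberships$attribute[o], toy$memberships$gene[o],
                   sep = "\t"), tfb)
  upath <- file.path(dir, "universe.txt")
  writeLines(toy$universe, upath)
  invisible(c(TFB = tfb, universe = upath))
}
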