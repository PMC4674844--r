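test_that("identical selections overlap completely, disjoint rankings not at all", {
  engine <- tinyEngine(seed = 12)
  u <- geneUniverse(engine)
  G <- length(u)
  expect_identical(topkOverlap(engine, u[1], "TFB", "TFB", k = 5), 5L)
  expect_identical(topkOverlap(engine, u[1], "TFB", "TFB", k = 100),
                   G - 1L)
  expect_identical(
    topkOverlap(engine, u[1], c("TFB", "PI"), c("TFB", "PI"), k = 3), 3L)
  # plain list overlap helper
  expect_identical(rankOverlap(c("a", "b", "c"), c("x", "y", "z"), 3), 0L)
  expect_identical(rankOverlap(letters, rev(letters), 13), 0L)
  expect_error(rankOverlap(letters, letters, 0), "k must be")
})

test_that("pairwise matrix covers every type pair with exact diagonal", {
  engine <- tinyEngine(seed = 21)
  u <- geneUniverse(engine)
  pw <- pairwiseOverlapMatrix(engine, k = 3)
  tb <- summaryTable(pw)
  expect_equal(nrow(tb), choose(8, 2) + 8)   # 28 off-diagonal + 8 diag
  diag <- tb[tb$selectionA == tb$selectionB, ]
  expect_true(all(diag$mean == 3))
  expect_true(all(diag$se == 0))
  expect_true(all(tb$n == length(u)))
  expect_true(all(tb$mean >= 0 & tb$mean <= 3))
})

test_that("identical TFB and TFR inputs force full TFB-TFR overlap", {
  # construction-level analogue of two perfectly correlated regulon types
  set.seed(5)
  genes <- geneIds(20)
  attrs <- sprintf("A%02d", 1:15)
  mem <- matrix(runif(20 * 15) < 0.25, 20, 15)
  idx <- which(mem, arr.ind = TRUE)
  df <- data.frame(attribute = attrs[idx[, 2]], gene = genes[idx[, 1]])
  catalogs <- list(
    TFB = EvidenceCatalog("TFB", genes, df, attrUniverse = attrs),
    TFR = EvidenceCatalog("TFR", genes, df, attrUniverse = attrs))
  for (ty in c("MP", "FA", "LE")) {
    mem2 <- matrix(runif(20 * 15) < 0.2, 20, 15)
    i2 <- which(mem2, arr.ind = TRUE)
    catalogs[[ty]] <- EvidenceCatalog(
      ty, genes,
      data.frame(attribute = attrs[i2[, 2]], gene = genes[i2[, 1]]),
      attrUniverse = attrs)
  }
  for (ty in c("PI", "GI")) {
    pairs <- t(combn(genes, 2))
    on <- runif(nrow(pairs)) < 0.2
    catalogs[[ty]] <- EvidenceCatalog(ty, genes,
                                      data.frame(a = pairs[on, 1],
                                                 b = pairs[on, 2]))
  }
  engine <- buildEngine(catalogs)
  pw <- pairwiseOverlapMatrix(engine, k = 10)
  tb <- summaryTable(pw)
  row <- tb[(tb$selectionA == "TFB" & tb$selectionB == "TFR") |
            (tb$selectionA == "TFR" & tb$selectionB == "TFB"), ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$mean, 10)
  expect_identical(row$se, 0)
})

test_that("all-vs-single degenerates to full overlap when one type carries all signal", {
  # only TFB annotated; every other type empty -> OAS is TFB alone
  genes <- geneIds(12)
  catalogs <- list()
  set.seed(8)
  attrs <- sprintf("A%02d", 1:10)
  mem <- matrix(runif(12 * 10) < 0.4, 12, 10)
  idx <- which(mem, arr.ind = TRUE)
  catalogs$TFB <- EvidenceCatalog("TFB", genes,
                                  data.frame(attribute = attrs[idx[, 2]],
                                             gene = genes[idx[, 1]]),
                                  attrUniverse = attrs)
  emptyDf <- data.frame(attribute = character(0), gene = character(0))
  for (ty in c("TFR", "MP", "FA", "LE"))
    catalogs[[ty]] <- EvidenceCatalog(ty, genes, emptyDf)
  for (ty in c("PI", "GI"))
    catalogs[[ty]] <- EvidenceCatalog(ty, genes, emptyDf)
  engine <- buildEngine(catalogs)
  av <- allVsSingleOverlap(engine, k = 5)
  tb <- summaryTable(av)
  expect_identical(nrow(tb), 7L)
  expect_true(all(tb$selectionA == "ALL"))
  tfbRow <- tb[tb$selectionB == "TFB", ]
  expect_identical(tfbRow$mean, 5)
  expect_identical(tfbRow$se, 0)
})

test_that("all-vs-single agrees with an independent recomputation of both rankings", {
  inp <- tinyEngineInputs(seed = 501, nGenes = 10)
  engine <- buildEngine(inp$catalogs, inp$ep)
  av <- allVsSingleOverlap(engine, k = 4)
  tb <- summaryTable(av)
  u <- inp$genes
  setsPerType <- lapply(inp$catalogs, function(ct)
    list(sets = geneAttrs(ct), N = universeSize(ct)))
  epsc <- pairScores(inp$ep)
  for (ty in c("TFB", "PI", "EP")) {
    per <- vapply(u, function(q) {
      cand <- sort(setdiff(u, q))
      epRaw <- vapply(cand, function(b) {
        hit <- which((epsc$geneA == q & epsc$geneB == b) |
                     (epsc$geneA == b & epsc$geneB == q))
        if (length(hit)) epsc$score[hit] else min(epsc$score)
      }, numeric(1))
      oasAll <- bruteOAS(setsPerType, q, u, assocTypes(), epRaw)
      oasOne <- bruteOAS(setsPerType, q, u, ty, epRaw)
      topA <- names(oasAll)[order(-oasAll, names(oasAll))][1:4]
      topB <- names(oasOne)[order(-oasOne, names(oasOne))][1:4]
      length(intersect(topA, topB))
    }, numeric(1))
    row <- tb[tb$selectionB == ty, ]
    expect_equal(row$mean, mean(per))
    expect_equal(row$se, sd(per) / sqrt(length(u)))
  }
})

test_that("overlap summaries serialize to the long format", {
  engine <- tinyEngine()
  pw <- pairwiseOverlapMatrix(engine, k = 3)
  p <- tempfile(fileext = ".tsv")
  writeOverlapSummary(pw, p)
  lines <- readLines(p)
  expect_identical(lines[1], "selection_a\tselection_b\tmean\tse\tn")
  expect_identical(length(lines), nrow(summaryTable(pw)) + 1L)
})
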