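test_that("generation is byte-identical under a fixed seed", {
  spec <- syntheticSpec(numGenes = 30, attrUniverseSize = 12,
                        backgroundProb = 0.1, seed = 7)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  generateSyntheticData(spec, d1)
  generateSyntheticData(spec, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the draw
  d3 <- file.path(tempfile(), "c")
  generateSyntheticData(syntheticSpec(numGenes = 30, attrUniverseSize = 12,
                                      backgroundProb = 0.1, seed = 8), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "tfb.tsv"))),
                         unname(tools::md5sum(file.path(d3, "tfb.tsv")))))
})

test_that("with zero background only the planted pair scores", {
  spec <- syntheticSpec(numGenes = 10, attrUniverseSize = 10,
                        backgroundProb = 0,
                        plantedModules = list(list(genes = c("G001", "G002"),
                                                   shared = 5)),
                        seed = 3)
  out <- generateSyntheticData(spec, tempfile())
  for (ty in c("TFB", "MP", "LE")) {
    tb <- scoreAllPairs(out$catalogs[[ty]])
    sc <- pairScores(tb)
    expect_identical(nrow(sc), 1L)
    expect_identical(c(sc$geneA, sc$geneB), c("G001", "G002"))
    expect_gt(sc$score, 0)
  }
  # interaction types: the planted pair shares 5 partners; partner genes
  # also pairwise share the two module genes
  pi <- pairScores(scoreAllPairs(out$catalogs$PI))
  expect_identical(unname(lookupScore(scoreAllPairs(out$catalogs$PI),
                                      "G001", "G002") > 0), TRUE)
})

test_that("the generated bundle loads cleanly and covers the whole universe", {
  spec <- syntheticSpec(numGenes = 25, seed = 11)
  expect_silent(out <- generateSyntheticData(spec, tempfile()))
  expect_identical(length(out$universe), 25L)
  for (ct in out$catalogs) {
    expect_identical(geneUniverse(ct), out$universe)
    expect_identical(length(geneAttrs(ct)), 25L)
  }
  # EP covers every unordered pair
  expect_equal(nrow(pairScores(out$epTable)), choose(25, 2))
  # planted pair scores above 1 in EP, background below 1
  expect_gt(lookupScore(out$epTable, "G001", "G002"), 1)
})

test_that("infeasible specs are rejected", {
  expect_error(syntheticSpec(numGenes = 10, attrUniverseSize = 5,
                             plantedModules = list(list(genes = c("G001", "G002"),
                                                        shared = 8))),
               "exceeds the attribute universe")
  expect_error(syntheticSpec(numGenes = 4,
                             plantedModules = list(list(genes = c("G001", "G002"),
                                                        shared = 3))),
               "non-module")
  expect_error(syntheticSpec(numGenes = 10, backgroundProb = 1.2), "backgroundProb")
})

test_that("planted module pairs dominate the background score distribution", {
  hits <- 0L
  for (s in 1:5) {
    spec <- syntheticSpec(numGenes = 60, attrUniverseSize = 50,
                          backgroundProb = 0.05,
                          plantedModules = list(list(
                            genes = sprintf("G%03d", 1:5), shared = 10)),
                          seed = 400 + s)
    out <- generateSyntheticData(spec, tempfile())
    tb <- scoreAllPairs(out$catalogs$TFB)
    modPairs <- t(combn(sprintf("G%03d", 1:5), 2))
    modScores <- lookupScore(tb, modPairs[, 1], modPairs[, 2])
    bg <- pairScores(tb)
    bgScores <- bg$score[!(bg$geneA %in% sprintf("G%03d", 1:5) &
                           bg$geneB %in% sprintf("G%03d", 1:5))]
    q95 <- if (length(bgScores)) quantile(bgScores, 0.95) else 0
    hits <- hits + sum(modScores > q95)
  }
  # >= 95% of module pairs exceed the background 95th percentile
  expect_gte(hits / (5 * 10), 0.95)
})

test_that("the worked toy catalog matches its documentation", {
  toy <- workedToyCatalog()
  expect_identical(length(toy$universe), 12L)
  cat1 <- EvidenceCatalog("TFB", toy$universe, toy$memberships)
  expect_identical(universeSize(cat1), 10L)
  expect_identical(unname(lengths(geneAttrs(cat1))[toy$universe]),
                   unname(toy$setSizes[toy$universe]))
  # documented score verified against the enumeration oracle
  pp <- pairParams(cat1, toy$pair[1], toy$pair[2])
  expect_identical(c(pp@N, pp@n, pp@m, pp@k), unname(toy$params))
  expect_equal(scorePair(cat1, toy$pair[1], toy$pair[2]), toy$score,
               tolerance = 1e-9)
  expect_equal(10^(-toy$score), enumTail(10, 5, 5, 5), tolerance = 1e-12)

  # file form loads without warnings and reproduces the catalog
  paths <- writeToyCatalog(tempfile())
  expect_no_warning(cat2 <- loadCatalog(paths["TFB"], "TFB",
                                        toy$universe))
  expect_identical(geneAttrs(cat2), geneAttrs(cat1))
})
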