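test_that("nearest-rank thresholds behave on distinct, constant and zero-inflated scores", {
  # 100 pairs with distinct scores 1..100 over a 15-gene universe (105 pairs,
  # 5 implicit zeros): use exactly 100 explicit + 0-score tail
  genes <- geneIds(15)   # C(15,2) = 105 pairs
  pairs <- t(combn(genes, 2))

  # (a) fully distinct over an exact 100-pair universe is awkward with
  # C(G,2); instead check the defining rule directly on 105 values
  sc <- data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                   score = as.numeric(1:105))
  tb <- PairScoreTable("TFB", sc, genes)
  thr <- computeThresholds(list(tb), genes)
  expect_equal(unname(cutoffs(thr)["TFB"]), 100)  # ceil(.95*105) = 100
  expect_identical(sum(sc$score > cutoffs(thr)["TFB"]), 5L)

  # (b) all pair scores equal: cutoff is that value, nothing is flagged
  scc <- data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                    score = rep(2.5, 105))
  thrc <- computeThresholds(list(PairScoreTable("TFB", scc, genes)), genes)
  expect_equal(unname(cutoffs(thrc)["TFB"]), 2.5)
  expect_identical(sum(scc$score > cutoffs(thrc)["TFB"]), 0L)

  # (c) zero-inflated: 10 positive among many implicit zeros -> cutoff 0,
  # exactly the positive pairs flagged
  genes2 <- geneIds(46)  # C(46,2) = 1035 pairs
  pos <- data.frame(geneA = rep("G001", 10), geneB = geneIds(46)[2:11],
                    score = seq(0.5, 5, by = 0.5))
  thr0 <- computeThresholds(list(PairScoreTable("MP", pos, genes2)), genes2)
  expect_equal(unname(cutoffs(thr0)["MP"]), 0)
  expect_identical(sum(pos$score > cutoffs(thr0)["MP"]), 10L)
})

test_that("thresholds require a non-trivial universe and sane percentile", {
  expect_error(computeThresholds(list(), "g1"), "two universe genes")
  genes <- geneIds(5)
  tb <- PairScoreTable("TFB", data.frame(geneA = "G001", geneB = "G002",
                                         score = 1), genes)
  expect_error(computeThresholds(list(tb), genes, percentile = 100),
               "percentile")
})

test_that("flagged fraction is 5% (one nearest-rank step) under distinct scores", {
  set.seed(31)
  genes <- geneIds(46)   # 1035 pairs
  pairs <- t(combn(genes, 2))
  sc <- data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                   score = sample(seq_len(nrow(pairs))) / 7)
  tb <- PairScoreTable("LE", sc, genes)
  thr <- computeThresholds(list(tb), genes)
  frac <- mean(sc$score > cutoffs(thr)["LE"])
  M <- nrow(pairs)
  expect_lte(abs(frac - 0.05), 1 / M + 1e-12)
})

test_that("query ranks a planted partner first and keeps ties deterministic", {
  engine <- tinyEngine(seed = 42)
  res <- queryAssociated(engine, "G001", topK = 5)
  expect_identical(resultRecords(res)$gene[1], "G002")
  expect_identical(resultRecords(res)$rank, 1:5)

  # topK larger than the universe returns every other gene
  resAll <- queryAssociated(engine, "G001", topK = 1000)
  expect_identical(nrow(resultRecords(resAll)), 7L)
  expect_false("G001" %in% resultRecords(resAll)$gene)

  # equal OAS ties break by ascending gene id
  rec <- resultRecords(resAll)
  o <- order(-rec$oas, rec$gene)
  expect_identical(o, seq_len(nrow(rec)))
})

test_that("query errors are informative", {
  engine <- tinyEngine()
  expect_error(queryAssociated(engine, "G00X"), "nearest identifiers")
  expect_error(queryAssociated(engine, "G001", chosen = character(0)),
               "chosen")
  expect_error(queryAssociated(engine, "G001", topK = 0), "topK")
  expect_error(queryAssociated(engine, "G001", chosen = "XX"), "XX")
})

test_that("OAS matches an independent end-to-end recomputation from the catalogs", {
  for (s in c(3, 4)) {
    inp <- tinyEngineInputs(seed = 300 + s, nGenes = 12)
    engine <- buildEngine(inp$catalogs, inp$ep)
    u <- inp$genes
    setsPerType <- lapply(inp$catalogs, function(ct)
      list(sets = geneAttrs(ct), N = universeSize(ct)))
    for (q in u[c(1, 5, 9)]) {
      res <- queryAssociated(engine, q, topK = length(u) - 1)
      rec <- resultRecords(res)
      # independent oracle: raw EP with min-fill, phyper per pair, minmax, sum
      cand <- sort(setdiff(u, q))
      epsc <- pairScores(inp$ep)
      epRaw <- vapply(cand, function(b) {
        hit <- which((epsc$geneA == q & epsc$geneB == b) |
                     (epsc$geneA == b & epsc$geneB == q))
        if (length(hit)) epsc$score[hit] else min(epsc$score)
      }, numeric(1))
      oracle <- bruteOAS(setsPerType, q, u, assocTypes(), epRaw)
      got <- setNames(rec$oas, rec$gene)
      expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
    }
  }
})

test_that("restricting chosen types changes ranking but never the evidence flags", {
  engine <- tinyEngine(seed = 55)
  u <- geneUniverse(engine)
  full <- queryAssociated(engine, "G003", topK = length(u))
  part <- queryAssociated(engine, "G003", chosen = c("MP", "GI"),
                          topK = length(u))
  fv <- resultRecords(full); pv <- resultRecords(part)
  fv <- fv[order(fv$gene), ]; pv <- pv[order(pv$gene), ]
  for (ty in assocTypes())
    expect_identical(fv[[paste0("evidence.", ty)]],
                     pv[[paste0("evidence.", ty)]])
})

test_that("evidence flags compare raw scores strictly against the cutoffs", {
  engine <- tinyEngine(seed = 91)
  res <- queryAssociated(engine, "G001", topK = 7)
  rec <- resultRecords(res)
  cuts <- cutoffs(engine)
  tfb <- engine@tables$TFB
  raw <- vapply(rec$gene, function(b) lookupScore(tfb, "G001", b),
                numeric(1))
  expect_identical(rec$evidence.TFB, unname(raw > cuts["TFB"]))
})

test_that("result export writes the documented header and 0/1 flags", {
  engine <- tinyEngine()
  res <- queryAssociated(engine, "G001", chosen = c("TFB", "EP"), topK = 3)
  p <- tempfile(fileext = ".tsv")
  exportResult(res, p)
  lines <- readLines(p)
  expect_identical(lines[1],
    paste(c("rank", "gene", paste0("ev_", assocTypes()),
            "S_TFB", "S_EP", "oas"), collapse = "\t"))
  expect_identical(length(lines), 4L)
  flags <- strsplit(lines[2], "\t")[[1]][3:10]
  expect_true(all(flags %in% c("0", "1")))

  pj <- tempfile(fileext = ".json")
  writeResultJSON(res, pj)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(back$query, "G001")
  expect_identical(nrow(back$records), 3L)
})
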