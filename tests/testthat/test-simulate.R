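# Small study configuration used throughout: keeps generator tests fast while
# preserving every planted feature of the default conditions.
smallConfig <- function(seed = 7, nTsLnc = 24, nTsPc = 12) {
  simulationConfig(nTissues = 6, nLnc = 120, nPc = 80, nUeLnc = 20,
                   nTsLnc = nTsLnc, nUePc = 24, nTsPc = nTsPc,
                   nBackground = 400, seed = seed)
}

test_that("the generator is a deterministic function of its seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateLncDataset(d1, smallConfig())
  simulateLncDataset(d2, smallConfig())
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 15)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulateLncDataset(d3, smallConfig(seed = 8))
  expect_false(identical(unname(tools::md5sum(file.path(d3, f1))),
                         unname(h1)))
})

test_that("inconsistent planted counts are rejected", {
  expect_error(simulationConfig(nLnc = 100, nUeLnc = 80, nTsLnc = 40),
               "exceed")
})

test_that("ground truth and annotation agree on every gene id", {
  d <- withr::local_tempdir()
  simulateLncDataset(d, smallConfig())
  truth <- read.delim(file.path(d, "ground_truth.tsv"))
  gm <- readGeneModels(file.path(d, "genes.gtf"))
  expect_setequal(truth$gene_id, geneRanges(gm)$gene_id)
  expect_setequal(unique(truth$label), c("other", "TS", "UE"))
  # expression table transcripts all belong to annotated genes
  ex <- read.delim(file.path(d, "expression.samples.tsv"), check.names = FALSE)
  expect_true(all(ex$gene_id %in% truth$gene_id))
})

test_that("planted UE genes are detected everywhere with a low coefficient of variation", {
  d <- withr::local_tempdir()
  simulateLncDataset(d, smallConfig())
  truth <- read.delim(file.path(d, "ground_truth.tsv"))
  ex <- read.delim(file.path(d, "expression.samples.tsv"), check.names = FALSE)
  smap <- read.delim(file.path(d, "sample_map.tsv"))
  m <- as.matrix(ex[, smap$sample_id])
  rownames(m) <- ex$feature_id
  tm <- aggregateToTissues(m, setNames(smap$tissue, smap$sample_id))
  ueTx <- paste0(truth$gene_id[truth$label == "UE"], ".t1")
  cv <- apply(tm[ueTx, ], 1, coefficientOfVariation)
  widths <- expressionWidth(tm[ueTx, ], 0.14)
  expect_gte(mean(cv < 1 & widths == ncol(tm)), 0.99)
})

test_that("the estimated detection threshold separates background from signal", {
  d <- withr::local_tempdir()
  simulateLncDataset(d, smallConfig())
  ex <- read.delim(file.path(d, "expression.samples.tsv"), check.names = FALSE)
  bg <- read.delim(file.path(d, "background.tsv"))
  smap <- read.delim(file.path(d, "sample_map.tsv"))
  m <- as.matrix(ex[ex$biotype == "lncRNA", smap$sample_id])
  tm <- aggregateToTissues(m, setNames(smap$tissue, smap$sample_id))
  dt <- estimateDetectionThreshold(tm[tm > 0],
                                   bg$fpkm[bg$biotype == "lncRNA"])
  # background is exponential(mean 0.05); the cutoff must sit between the
  # background bulk and the planted signal's lower tail
  expect_gt(thresholdValue(dt), 0.05)
  expect_lt(thresholdValue(dt), 0.8)
  nbg <- sum(bg$biotype == "lncRNA")
  expect_lt(dt@fpCount / nbg, 0.1)
  expect_lt(dt@fnCount / sum(tm > 0), 0.1)
})

test_that("a configuration without TS genes yields no TS classifications", {
  d <- withr::local_tempdir()
  simulateLncDataset(d, smallConfig(seed = 9, nTsLnc = 0, nTsPc = 0))
  ex <- read.delim(file.path(d, "expression.samples.tsv"), check.names = FALSE)
  smap <- read.delim(file.path(d, "sample_map.tsv"))
  m <- as.matrix(ex[, smap$sample_id])
  rownames(m) <- ex$feature_id
  tm <- aggregateToTissues(m, setNames(smap$tissue, smap$sample_id))
  te <- TissueExpression(tm, ex$biotype, gene_id = ex$gene_id)
  res <- classifyTranscripts(te, c(lncRNA = 0.14, protein_coding = 0.21))
  g <- classifyGenes(res, ex$gene_id)
  expect_equal(sum(g$label == "TS"), 0L)
})

test_that("planted proximity fractions are recovered from the generated files", {
  d <- withr::local_tempdir()
  cfg <- simulationConfig(nTissues = 6, nLnc = 400, nPc = 300, nUeLnc = 80,
                          nTsLnc = 60, nUePc = 100, nTsPc = 30,
                          nBackground = 200, seed = 11)
  simulateLncDataset(d, cfg)
  truth <- read.delim(file.path(d, "ground_truth.tsv"))
  gm <- readGeneModels(file.path(d, "genes.gtf"))
  genes <- geneRanges(gm)
  lncT <- truth[truth$biotype == "lncRNA", ]
  ueGR <- genes[match(lncT$gene_id[lncT$label == "UE"], genes$gene_id)]
  ess <- read.delim(file.path(d, "essential_genes.tsv"))$gene_id
  essGR <- genes[match(ess, genes$gene_id)]
  got <- proximityFraction(ueGR, essGR, 5e4)$fraction
  want <- mean(lncT$has_essential_50kb[lncT$label == "UE"])
  expect_equal(got, want)
  # UE protein-coding neighbors within 100 kb match the planted indicator
  uePcGR <- genes[match(truth$gene_id[truth$label == "UE" &
                                        truth$biotype == "protein_coding"],
                        genes$gene_id)]
  fr <- neighborsWithin(ueGR, uePcGR)$fractions[["100000"]]
  expect_equal(fr, mean(lncT$has_ue_pc_100kb[lncT$label == "UE"]))
})

test_that("the worked micro example carries its oracle-checked intermediates", {
  mi <- workedMicroExample()
  expect_lte(nrow(mi$fpkm), 20)
  expect_equal(ncol(mi$fpkm), 3)
  expect_equal(coefficientOfVariation(mi$fpkm["UE_1", ]), 0.1082532,
               tolerance = 1e-6)
  expect_equal(jsSpecificity(mi$fpkm["TS_1", ])$score, 1)
  expect_equal(unname(expressionWidth(mi$fpkm["OTH_1", ], 0.14)), 2L)
})
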