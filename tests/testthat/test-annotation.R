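test_that("GTF parsing computes exon/intron/genomic lengths and groups transcripts", {
  gtfFile <- withr::local_tempfile(fileext = ".gtf")
  tx <- data.frame(gene_id = c("g1", "g2", "g2"),
                   transcript_id = c("t1", "t2a", "t2b"),
                   biotype = "lncRNA", source = "GENCODE",
                   chrom = "chr1", strand = "+",
                   stringsAsFactors = FALSE)
  tx$exons <- list(cbind(c(1, 201), c(100, 300)),
                   cbind(1000, 1500),
                   cbind(c(1000, 1400), c(1100, 1600)))
  writeToyGtf(gtfFile, tx)
  gm <- readGeneModels(gtfFile)
  expect_length(gm, 2L)
  st <- transcriptStats(gm)
  t1 <- st[st$transcript_id == "t1", ]
  expect_equal(t1$exonic_length, 200L)
  expect_equal(t1$intronic_length, 100L)
  expect_equal(t1$genomic_length, 300L)
  expect_equal(sum(st$gene_id == "g2"), 2L)
  # gene locus is the union span of its transcripts
  g2 <- geneRanges(gm)[geneRanges(gm)$gene_id == "g2"]
  expect_equal(c(start(g2), end(g2)), c(1000L, 1600L))
})

test_that("GTF edge cases: empty file, malformed record, biotype filter", {
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_length(readGeneModels(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("# comment", "chr1\tsrc\texon\t1\t100"), bad)
  expect_error(readGeneModels(bad), "line 2")

  gtfFile <- withr::local_tempfile(fileext = ".gtf")
  tx <- data.frame(gene_id = c("L1", "P1"), transcript_id = c("tL", "tP"),
                   biotype = c("lncRNA", "protein_coding"),
                   source = "GENCODE", chrom = "chr1", strand = "+",
                   stringsAsFactors = FALSE)
  tx$exons <- list(cbind(1, 500), cbind(1000, 2000))
  writeToyGtf(gtfFile, tx)
  gm <- readGeneModels(gtfFile, biotypeFilter = "lncRNA")
  expect_equal(geneRanges(gm)$gene_id, "L1")
})

test_that("overlapFraction handles identity, partial, nested and cross-chromosome pairs", {
  a <- gr("c1", 1, 100)
  expect_equal(overlapFraction(a, a), 1)
  expect_equal(overlapFraction(a, gr("c1", 51, 150)), 0.5)
  expect_equal(overlapFraction(gr("c1", 1, 1000), gr("c1", 1, 100)), 1)
  expect_equal(overlapFraction(a, gr("c2", 1, 100)), 0)
  # jaccard switch: [1,1000] vs nested [1,100] -> 100/1000
  expect_equal(overlapFraction(gr("c1", 1, 1000), gr("c1", 1, 100),
                               denominator = "jaccard"), 0.1)
})

test_that("overlapFraction is symmetric, bounded, and 1 only under containment", {
  set.seed(7)
  for (i in 1:50) {
    s1 <- sample(1000, 1); s2 <- sample(1000, 1)
    a <- gr("c1", s1, s1 + sample(500, 1))
    b <- gr("c1", s2, s2 + sample(500, 1))
    f1 <- overlapFraction(a, b); f2 <- overlapFraction(b, a)
    expect_identical(f1, f2)
    expect_gte(f1, 0); expect_lte(f1, 1)
    contained <- (start(a) >= start(b) && end(a) <= end(b)) ||
      (start(b) >= start(a) && end(b) <= end(a))
    expect_identical(f1 == 1, contained)
  }
})

test_that("cross-source redundancy sweep keeps the priority source and matches a brute-force filter", {
  loci <- gr("c1", c(1, 1), c(1000, 1000),
             gene_id = c("G1", "E1"), biotype = "lncRNA",
             source = c("GENCODE", "Ensembl"))
  out <- buildNonredundantSet(loci)
  expect_equal(out$genes$gene_id, "G1")
  expect_equal(out$log$removed_id, "E1")
  expect_equal(out$log$kept_id, "G1")

  # below the 0.8 cutoff both survive
  loci2 <- gr("c1", c(1, 501), c(1000, 1500),
              gene_id = c("G1", "E1"), biotype = "lncRNA",
              source = c("GENCODE", "Ensembl"))
  expect_equal(sort(buildNonredundantSet(loci2)$genes$gene_id),
               c("E1", "G1"))

  # chain G~E 0.9, E~C 0.9, G~C 0.3: greedy priority sweep keeps only G
  chain <- gr("c1", c(1, 600, 650), c(1000, 1099, 1149),
              gene_id = c("G", "E", "C"), biotype = "lncRNA",
              source = c("GENCODE", "Ensembl", "Cabili"))
  # layout check before asserting the sweep
  expect_gt(overlapFraction(chain[1], chain[2]), 0.8)
  expect_gt(overlapFraction(chain[2], chain[3]), 0.8)
  expect_lt(overlapFraction(chain[1], chain[3]), 0.8)
  out3 <- buildNonredundantSet(chain)
  # brute-force oracle: drop anything redundant with a higher-priority locus
  pr <- c(GENCODE = 1, Ensembl = 2, Cabili = 3)
  keepOracle <- vapply(seq_along(chain), function(i) {
    !any(vapply(seq_along(chain), function(j)
      pr[chain$source[j]] < pr[chain$source[i]] &&
        overlapFraction(chain[i], chain[j]) > 0.8, TRUE))
  }, TRUE)
  expect_setequal(out3$genes$gene_id, chain$gene_id[keepOracle])
  expect_equal(out3$genes$gene_id, "G")
})

test_that("redundancy sweep is idempotent and leaves no cross-source pair above the cutoff", {
  set.seed(11)
  n <- 60
  st <- sample(50000, n)
  loci <- gr("c1", st, st + sample(500:2000, n, replace = TRUE),
             gene_id = sprintf("x%02d", 1:n), biotype = "lncRNA",
             source = sample(c("GENCODE", "Ensembl", "Cabili"), n,
                             replace = TRUE))
  out <- buildNonredundantSet(loci)
  k <- out$genes
  for (i in seq_along(k)) for (j in seq_along(k)) {
    if (i < j && k$source[i] != k$source[j])
      expect_lte(overlapFraction(k[i], k[j]), 0.8)
  }
  again <- buildNonredundantSet(k)
  expect_equal(again$genes$gene_id, k$gene_id)
  expect_equal(nrow(again$log), 0L)
  # same-source duplicates are deliberately kept
  dup <- gr("c1", c(1, 1), c(500, 500), gene_id = c("a", "b"),
            biotype = "lncRNA", source = "GENCODE")
  expect_length(buildNonredundantSet(dup)$genes, 2L)
})

test_that("promoter windows are strand-aware, symmetric and clipped at the chromosome start", {
  # + strand TSS at 1-based 10001: window [8001, 12000]
  p <- promoterRegions(gr("c1", 10001, 20000, "+"))
  expect_equal(c(start(p), end(p)), c(8001L, 12000L))
  # TSS near the start is clipped to position 1
  pc <- promoterRegions(gr("c1", 1001, 5000, "+"))
  expect_equal(c(start(pc), end(pc)), c(1L, 3000L))
  # - strand transcript spanning [5001, 8000]: TSS is the 3'-most base
  pm <- promoterRegions(gr("c1", 5001, 8000, "-"))
  expect_equal(c(start(pm), end(pm)), c(6001L, 10000L))
})

test_that("interval distance is the gap length, 0 on overlap, Inf across chromosomes", {
  expect_equal(intervalDistance(gr("c1", 1, 100), gr("c1", 51, 150)), 0)
  expect_equal(intervalDistance(gr("c1", 1, 100), gr("c1", 131, 200)), 30)
  expect_equal(intervalDistance(gr("c1", 1, 100), gr("c2", 1, 100)), Inf)
})

test_that("BED round-trip reproduces retained loci exactly", {
  loci <- gr("c1", c(100, 5000), c(2000, 9000), c("+", "-"),
             gene_id = c("gA", "gB"), biotype = "lncRNA", source = "GENCODE")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLociBed(loci, bed)
  back <- readLociBed(bed)
  expect_equal(start(back), start(loci))
  expect_equal(end(back), end(loci))
  expect_equal(as.character(strand(back)), as.character(strand(loci)))
  expect_equal(back$gene_id, loci$gene_id)
})
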