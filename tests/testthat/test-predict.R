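test_that("neighbor assignment respects the distance ladder and records the nearest gene", {
  lnc <- gr("c1", c(1e6, 5e6), c(1.01e6, 5.01e6), gene_id = c("l1", "l2"))
  pc <- gr("c1", c(1.005e6, 5.07e6), c(1.008e6, 5.09e6),
           gene_id = c("p_in", "p_60kb"))
  nb <- neighborsWithin(lnc, pc)
  l1 <- nb$perLnc[nb$perLnc$lnc_id == "l1", ]
  expect_true(all(unlist(l1[grep("within_", names(l1))])))
  expect_equal(l1$nearest_id, "p_in")
  l2 <- nb$perLnc[nb$perLnc$lnc_id == "l2", ]
  expect_false(l2$within_50000)
  expect_true(l2$within_100000)
  expect_equal(l2$nearest_distance, 5.07e6 - 5.01e6 - 1)
})

test_that("a planted neighbor fraction is recovered within its binomial interval", {
  set.seed(61)
  n <- 500
  plant <- runif(n) < 0.8
  starts <- seq_len(n) * 3e5
  lnc <- gr("c1", starts, starts + 5000, gene_id = sprintf("l%04d", 1:n))
  gapv <- round(runif(sum(plant), 1e3, 9e4))
  pc <- gr("c1", starts[plant] + 5000 + gapv,
           starts[plant] + 5000 + gapv + 1e4,
           gene_id = sprintf("p%04d", seq_len(sum(plant))))
  fr <- neighborsWithin(lnc, pc)$fractions[["100000"]]
  ci <- 0.8 + c(-3, 3) * sqrt(0.8 * 0.2 / n)
  expect_gt(fr, ci[1]); expect_lt(fr, ci[2])
})

test_that("same-tissue filtering restricts the TS neighbor variant", {
  lnc <- gr("c1", 1e6, 1.01e6, gene_id = "l1")
  pc <- gr("c1", c(1.02e6, 1.03e6), c(1.021e6, 1.031e6),
           gene_id = c("pSame", "pOther"))
  nb <- neighborsWithin(lnc, pc, sameTissue = TRUE,
                        lncTissue = c(l1 = "liver"),
                        pcTissue = c(pSame = "liver", pOther = "brain"))
  expect_equal(nb$pairs$pc_id, "pSame")
})

test_that("co-expression correlations match the direct formula", {
  expect_equal(coexpression(c(1, 2, 3), c(1, 2, 3), log2p1 = FALSE), 1)
  expect_equal(coexpression(c(1, 2, 3), c(7, 5, 3), log2p1 = FALSE), -1)
  expect_equal(coexpression(c(1, 2, 3, 4), c(1, 3, 2, 4), log2p1 = FALSE),
               0.8)
  expect_true(is.na(coexpression(c(1, 2, 3), c(5, 5, 5), log2p1 = FALSE)))
})

test_that("the neighbor randomization test uses the add-one empirical p", {
  set.seed(62)
  tissues <- 10
  lncRows <- matrix(rexp(5 * tissues), 5)
  bg <- matrix(rexp(50 * tissues), 50)
  # observed correlations far above anything the null can reach
  rt <- randomizationTest(rep(1, 5), lncRows, bg, nPerm = 1000, seed = 1)
  expect_equal(rt$p, 1 / 1001)
  expect_length(rt$nullMeans, 1000)
  expect_error(randomizationTest(rep(1, 5), lncRows, bg, nPerm = 0), "nPerm")
  expect_error(randomizationTest(rep(1, 5), lncRows, bg[1:3, ], nPerm = 10),
               "background")
})

test_that("GO enrichment matches exact enumeration and applies both filters", {
  ann <- data.frame(gene_id = paste0("g", 1:4), term_id = "T1",
                    term_name = "term one", stringsAsFactors = FALSE)
  uni <- paste0("g", 1:10)
  full <- goEnrichment(paste0("g", 1:5), ann, uni, filter = FALSE)
  expect_equal(full$p_raw, 6 / 252, tolerance = 1e-12)
  expect_equal(full$overlap, 4L)

  # single-gene overlaps are dropped no matter how small the p-value
  ann1 <- data.frame(gene_id = "g1", term_id = "T2", term_name = "singleton")
  expect_equal(nrow(goEnrichment("g1", ann1, uni, maxAdjP = 1)), 0L)

  expect_error(goEnrichment("zz", ann, uni), "subset")
  expect_error(goEnrichment("g1", ann, character(0)), "universe")

  # random small universes against the choose() oracle
  set.seed(63)
  for (i in 1:20) {
    N <- sample(5:50, 1)
    uni <- sprintf("u%02d", 1:N)
    ann <- data.frame(gene_id = sample(uni, min(N, 20), replace = TRUE),
                      term_id = sample(c("A", "B", "C"), min(N, 20),
                                       replace = TRUE))
    ann <- unique(ann)
    gs <- sample(uni, sample(2:N, 1))
    res <- goEnrichment(gs, ann, uni, filter = FALSE)
    for (r in seq_len(nrow(res))) {
      expect_equal(res$p_raw[r],
                   hyperTailOracle(res$overlap[r], res$term_size[r], N,
                                   length(gs)),
                   tolerance = 1e-10)
    }
    # BH is monotone non-decreasing along the raw-p ranking
    expect_true(all(diff(res$p_adjusted[order(res$p_raw)]) >= -1e-12))
  }
})

test_that("BH adjustment reproduces the hand step-up on a known triple", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("band enrichment matches the enumeration oracle and its degenerate cases", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      chrom = rep(c("c1", "c2"), each = 50),
                      band = rep(sprintf("b%02d", 1:20), each = 5),
                      stringsAsFactors = FALSE)
  # category of 20; band b01 holds 4 of them among its 5 genes
  cat20 <- c(genes$gene_id[1:4], genes$gene_id[6:21])
  be <- bandEnrichment(cat20, genes)
  b01 <- be$band[be$band$unit == "b01", ]
  expect_equal(b01$category_count, 4L)
  expect_equal(b01$p_raw, hyperTailOracle(4, 20, 100, 5), tolerance = 1e-12)
  expect_equal(b01$p_raw, 0.005354, tolerance = 1e-4)
  expect_true(b01$significant)
  # empty band: p = 1 within rounding
  b20 <- be$band[be$band$unit == "b20", ]
  expect_equal(b20$category_count, 0L)
  expect_equal(b20$p_raw, 1, tolerance = 1e-12)
  # saturated category: the overlap is forced to the band size and the
  # upper tail P(X >= size) is exactly 1 in every band
  sat <- bandEnrichment(genes$gene_id, genes)
  expect_equal(sat$band$category_count, sat$band$unit_size)
  expect_equal(sat$band$p_raw, rep(1, nrow(sat$band)))
})

test_that("co-modification clustering recovers planted blocks and transfers their terms", {
  set.seed(64)
  nl <- 10; np <- 10
  ids <- c(sprintf("L%02d", 1:nl), sprintf("P%02d", 1:np))
  block <- rep(rep(1:2, each = 5), 2)
  marks <- paste0("M", 1:6)
  profiles <- lapply(seq_along(marks), function(mi) {
    high <- (block == 1) == (mi <= 3)
    mu <- ifelse(high, 10, 1)
    m <- matrix(rnorm(length(ids) * 40, rep(mu, 40), 0.9), length(ids), 40)
    rownames(m) <- ids
    pmax(m, 0)
  })
  names(profiles) <- marks
  uni <- sprintf("P%02d", 1:20)
  ann <- data.frame(gene_id = sprintf("P%02d", 1:10),
                    term_id = rep(c("GO:A", "GO:B"), each = 5),
                    term_name = rep(c("block A process", "block B process"),
                                    each = 5), stringsAsFactors = FALSE)
  pr <- predictTsFunction(profiles, ids[1:nl], ids[nl + 1:np], ann, uni,
                          tissue = "liver")
  expect_equal(pr$k, 2L)
  expect_equal(adjustedRand(pr$members$cluster, block), 1)
  # every lncRNA inherits exactly its block's planted term
  for (i in 1:nl) {
    got <- pr$predictions$term_id[pr$predictions$lncRNA_id == ids[i]]
    expect_equal(got, if (block[i] == 1) "GO:A" else "GO:B")
  }
  # permuting the input rows leaves memberships unchanged
  perm <- sample(length(ids))
  profPerm <- lapply(profiles, function(m) m[perm, ])
  pr2 <- predictTsFunction(profPerm, ids[1:nl], ids[nl + 1:np], ann, uni)
  m1 <- setNames(pr$members$cluster, pr$members$member_id)
  m2 <- setNames(pr2$members$cluster, pr2$members$member_id)
  expect_equal(adjustedRand(m1[ids], m2[ids]), 1)
})

test_that("degenerate clustering inputs produce empty predictions", {
  prof <- list(M1 = matrix(1:4, 2, 2, dimnames = list(c("a", "b"), NULL)))
  expect_warning(out <- predictTsFunction(prof, "a", "b",
                                          data.frame(gene_id = "b",
                                                     term_id = "T"), "b"),
                 "fewer than 3")
  expect_equal(nrow(out$predictions), 0L)
})

test_that("clusters without protein-coding members predict nothing", {
  set.seed(65)
  ids <- c(sprintf("L%02d", 1:6), sprintf("P%02d", 1:3))
  block <- c(rep(1, 3), rep(2, 3), rep(1, 3))   # block 2 is lncRNA-only
  profiles <- lapply(1:2, function(mi) {
    high <- (block == 1) == (mi == 1)
    m <- matrix(rnorm(9 * 40, rep(ifelse(high, 10, 1), 40), 0.5), 9, 40)
    rownames(m) <- ids
    pmax(m, 0)
  })
  names(profiles) <- c("M1", "M2")
  ann <- data.frame(gene_id = sprintf("P%02d", 1:3), term_id = "GO:X",
                    term_name = "x")
  pr <- predictTsFunction(profiles, ids[1:6], ids[7:9], ann,
                          sprintf("P%02d", 1:10), k = 2)
  lnc2 <- ids[block == 2]
  expect_false(any(pr$predictions$lncRNA_id %in% lnc2))
})
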