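# Shared builders for small in-code fixtures.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

gr <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                         ...)
}

# Write a minimal GTF for the given transcript table.  `exons` is a list of
# 2-column matrices (start, end in 1-based closed coordinates).
writeToyGtf <- function(path, tx) {
  lines <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    at <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; gene_source "%s";',
                  tx$gene_id[i], tx$transcript_id[i], tx$biotype[i],
                  tx$source[i])
    ex <- tx$exons[[i]]
    sprintf("%s\tsrc\texon\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom[i], ex[, 1], ex[, 2], tx$strand[i], at)
  }))
  writeLines(lines, path)
  path
}

# GeneModels built directly in code: one single-exon transcript per gene with
# the requested genomic lengths (no introns unless nExon > 1).
makeGeneModels <- function(ids, lengths, chrom = "chr1", spacing = 1e6,
                           nExon = 1L, biotype = "lncRNA",
                           source = "GENCODE", strand = "+") {
  starts <- seq_along(ids) * spacing
  nExon <- rep(nExon, length.out = length(ids))
  strand <- rep(strand, length.out = length(ids))
  exl <- GenomicRanges::GRangesList(lapply(seq_along(ids), function(i) {
    k <- nExon[i]
    if (k == 1L) return(gr(chrom, starts[i], starts[i] + lengths[i] - 1L,
                           strand[i]))
    exLen <- max(50L, as.integer(lengths[i] * 0.2 / k))
    gap <- as.integer((lengths[i] - k * exLen) / (k - 1))
    st <- starts[i] + (seq_len(k) - 1L) * (exLen + gap)
    en <- st + exLen - 1L
    en[k] <- starts[i] + lengths[i] - 1L
    gr(chrom, st, en, strand[i])
  }))
  names(exl) <- paste0(ids, ".t1")
  S4Vectors::mcols(exl)$gene_id <- ids
  genes <- gr(chrom, starts, starts + lengths - 1L, strand,
              gene_id = ids, biotype = biotype, source = source)
  new("GeneModels", genes = genes, exons = exl)
}

# Adjusted Rand index between two labelings (closed form on the pair
# contingency table); independent of any clustering code under test.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# Exact upper-tail hypergeometric by direct enumeration over choose();
# the independent oracle for every enrichment p-value in the suite.
hyperTailOracle <- function(k, K, N, n) {
  js <- seq(k, min(K, n))
  js <- js[n - js <= N - K]
  if (!length(js)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Brute-force Jensen-Shannon specificity: literal entropy formula against
# every single-tissue point distribution.
jsOracle <- function(v) {
  p <- v / sum(v)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  best <- -Inf; arg <- NA
  for (t in seq_along(p)) {
    e <- numeric(length(p)); e[t] <- 1
    jsd <- H((p + e) / 2) - (H(p) + H(e)) / 2
    sc <- 1 - sqrt(max(jsd, 0))
    if (sc > best) { best <- sc; arg <- t }
  }
  list(score = best, tissue = arg)
}
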