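#' Configuration for the synthetic dataset generator
#'
#' Returns the default study conditions the generator emulates: 20 tissues, a
#' lncRNA set with planted ubiquitous (all tissues, low CV), tissue-specific
#' (one tissue, point-mass profile) and intermediate genes, an exponential
#' near-zero background from untranscribed regions, compact gene structures
#' for UE genes, elevated conservation at UE exons and promoters, CpG islands
#' at a third of UE promoters, block-structured active histone marks at TS
#' promoters, enhancers with per-cell-line presence, and essential genes
#' placed near UE loci.
#'
#' @param nTissues number of tissues.
#' @param nLnc,nPc number of lncRNA and protein-coding genes.
#' @param nUeLnc,nTsLnc planted UE / TS lncRNA counts.
#' @param nUePc,nTsPc planted UE / TS protein-coding counts.
#' @param bgMeanLnc,bgMeanPc mean of the exponential background FPKM.
#' @param nBackground background regions per biotype.
#' @param ueMeanlog,ueSdlog lognormal base expression of UE genes.
#' @param ueNoiseSdlog multiplicative tissue noise of UE genes (sdlog 0.198
#'   gives CV about 0.2).
#' @param tsMeanlog,tsSdlog lognormal on-tissue expression of TS (and
#'   expressed-tissue values of intermediate) genes.
#' @param ueNeighborFrac fraction of UE lncRNAs given a UE protein-coding
#'   neighbor within 100 kb.
#' @param ueEssentialFrac,tsEssentialFrac,otherEssentialFrac fraction of each
#'   lncRNA class given an essential gene within 50 kb.
#' @param ueCgiFrac,bgCgiFrac CpG-island fraction at UE / non-UE promoters.
#' @param ueEnhancerFrac,tsEnhancerFrac,otherEnhancerFrac fraction of each
#'   class given an enhancer within 10 kb.
#' @param markHigh,markLow Poisson mean read depth of the high / low block of
#'   the six active marks at TS promoters.
#' @param nCellLines cell-line panel size for enhancers.
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   it.
#' @return named list of generator settings.
#' @export
simulationConfig <- function(nTissues = 20, nLnc = 2000, nPc = 1000,
                             nUeLnc = 200, nTsLnc = 300,
                             nUePc = 240, nTsPc = 120,
                             bgMeanLnc = 0.05, bgMeanPc = 0.07,
                             nBackground = 5000,
                             ueMeanlog = 2, ueSdlog = 0.6, ueNoiseSdlog = 0.198,
                             tsMeanlog = 0.8, tsSdlog = 0.8,
                             ueNeighborFrac = 0.837,
                             ueEssentialFrac = 0.345, tsEssentialFrac = 0.121,
                             otherEssentialFrac = 0.121,
                             ueCgiFrac = 1 / 3, bgCgiFrac = 0.05,
                             ueEnhancerFrac = 0.6, tsEnhancerFrac = 0.3,
                             otherEnhancerFrac = 0.2,
                             markHigh = 20, markLow = 2,
                             nCellLines = 13, seed = 42) {
  cfg <- as.list(environment())
  fr <- c(cfg$nUeLnc, cfg$nTsLnc)
  if (sum(fr) > cfg$nLnc || cfg$nUePc + cfg$nTsPc > cfg$nPc)
    stop("planted class counts exceed the gene totals")
  stopifnot(cfg$nTissues >= 3, cfg$seed == as.integer(cfg$seed))
  cfg
}

.ACTIVE_MARKS <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac", "H3K27ac",
                   "H3K36me3")

.geneStructure <- function(n, meanLog10Len, exonMin, exonMax) {
  len <- pmax(600L, as.integer(round(10^stats::rnorm(n, meanLog10Len, 0.12))))
  k <- sample(exonMin:exonMax, n, replace = TRUE)
  list(length = len, exons = k)
}

.exonLayout <- function(start, len, k) {
  # k exons inside [start, start+len-1]; roughly equal exons of ~15% of span
  if (k == 1L) return(cbind(start, start + len - 1L))
  exLen <- rep(max(100L, as.integer(len * 0.15)), k)
  gap <- as.integer((len - sum(exLen)) / (k - 1))
  if (gap < 1L) { exLen <- rep(max(50L, as.integer(len / (2 * k))), k)
                  gap <- as.integer((len - sum(exLen)) / (k - 1)) }
  st <- start + c(0L, cumsum(exLen[-k] + gap))
  en <- st + exLen - 1L
  en[k] <- start + len - 1L
  cbind(st, en)
}

#' Generate a self-consistent synthetic dataset bundle
#'
#' Writes, under \code{dir}: \code{genes.gtf}, \code{expression.samples.tsv},
#' \code{sample_map.tsv}, \code{background.tsv}, \code{conservation.bedGraph},
#' \code{marks/<mark>.bedGraph} for the six active marks, \code{cgi.bed},
#' \code{enhancers.bed}, \code{tf_edges.tsv}, \code{mirna_edges.tsv},
#' \code{essential_genes.tsv}, \code{go_annotation.tsv}, \code{bands.tsv},
#' \code{promoters.fasta} and \code{ground_truth.tsv}.  The same seed
#' produces a byte-identical bundle.
#'
#' @param dir output directory (created if needed).
#' @param config list from [simulationConfig()].
#' @return invisibly, a list with the ground-truth data.frame and file paths.
#' @export
simulateLncDataset <- function(dir, config = simulationConfig()) {
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "marks"), showWarnings = FALSE)
  nT <- config$nTissues
  tissues <- sprintf("T%02d", seq_len(nT))
  cells <- sprintf("CL%02d", seq_len(config$nCellLines))

  ## ---- gene tables -------------------------------------------------------
  nLnc <- config$nLnc; nPc <- config$nPc
  lncLab <- rep("other", nLnc)
  lncLab[seq_len(config$nUeLnc)] <- "UE"
  lncLab[config$nUeLnc + seq_len(config$nTsLnc)] <- "TS"
  pcLab <- rep("other", nPc)
  pcLab[seq_len(config$nUePc)] <- "UE"
  pcLab[config$nUePc + seq_len(config$nTsPc)] <- "TS"
  lnc <- data.frame(gene_id = sprintf("LNC%05d", seq_len(nLnc)),
                    biotype = "lncRNA", label = lncLab,
                    stringsAsFactors = FALSE)
  pc <- data.frame(gene_id = sprintf("PC%05d", seq_len(nPc)),
                   biotype = "protein_coding", label = pcLab,
                   stringsAsFactors = FALSE)
  lnc$ts_tissue <- NA_character_
  lnc$ts_tissue[lnc$label == "TS"] <-
    tissues[(seq_len(config$nTsLnc) - 1L) %% nT + 1L]
  pc$ts_tissue <- NA_character_
  pc$ts_tissue[pc$label == "TS"] <-
    tissues[(seq_len(config$nTsPc) - 1L) %% nT + 1L]

  ## ---- genome layout -----------------------------------------------------
  perChrom <- 1000L
  # slots are wide enough that a planted neighbor (gap <= 90 kb plus gene
  # body) can never fall inside the 100-kb window of the adjacent slot
  slotSpacing <- 300000L
  lnc$chrom <- sprintf("chrL%d", (seq_len(nLnc) - 1L) %/% perChrom + 1L)
  slot <- (seq_len(nLnc) - 1L) %% perChrom + 1L
  lnc$start <- slot * slotSpacing + sample.int(10000L, nLnc, replace = TRUE)
  lnc$strand <- sample(c("+", "-"), nLnc, replace = TRUE)
  st <- list(UE = .geneStructure(sum(lncLab == "UE"), log10(5000), 1L, 3L),
             TS = .geneStructure(sum(lncLab == "TS"), log10(10000), 2L, 6L),
             other = .geneStructure(sum(lncLab == "other"), log10(8000), 1L, 5L))
  lnc$length <- NA_integer_; lnc$exons <- NA_integer_
  for (lb in names(st)) {
    lnc$length[lnc$label == lb] <- st[[lb]]$length
    lnc$exons[lnc$label == lb] <- st[[lb]]$exons
  }
  pcSt <- .geneStructure(nPc, log10(20000), 4L, 9L)
  pc$length <- pcSt$length; pc$exons <- pcSt$exons
  pc$strand <- sample(c("+", "-"), nPc, replace = TRUE)
  # unplanted protein-coding genes live on their own chromosome, far from
  # every lncRNA; planted ones are relocated next to their target below
  pc$chrom <- "chrP1"
  pc$start <- (seq_len(nPc)) * slotSpacing +
    sample.int(10000L, nPc, replace = TRUE)

  ## ---- neighbor / essential planting ------------------------------------
  lnc$ue_pc_neighbor <- NA_character_
  lnc$essential_neighbor <- NA_character_
  uePcPool <- which(pc$label == "UE")
  otherPcPool <- which(pc$label == "other")
  placeNear <- function(li, pi, maxGap, minGap = 1000) {
    gap <- as.integer(round(stats::runif(1, minGap, maxGap)))
    side <- sample(c(-1L, 1L), 1L)
    pc$chrom[pi] <<- lnc$chrom[li]
    pc$start[pi] <<- if (side > 0L) lnc$start[li] + lnc$length[li] + gap
                     else lnc$start[li] - gap - pc$length[pi]
    invisible(NULL)
  }
  for (li in which(lnc$label == "UE")) {
    if (stats::runif(1) < config$ueNeighborFrac && length(uePcPool)) {
      pi <- uePcPool[1L]; uePcPool <- uePcPool[-1L]
      placeNear(li, pi, maxGap = 90000)
      lnc$ue_pc_neighbor[li] <- pc$gene_id[pi]
    }
  }
  essFrac <- c(UE = config$ueEssentialFrac, TS = config$tsEssentialFrac,
               other = config$otherEssentialFrac)
  for (li in seq_len(nLnc)) {
    if (stats::runif(1) < essFrac[[lnc$label[li]]] && length(otherPcPool)) {
      pi <- otherPcPool[1L]; otherPcPool <- otherPcPool[-1L]
      placeNear(li, pi, maxGap = 45000)
      lnc$essential_neighbor[li] <- pc$gene_id[pi]
    }
  }
  essential <- c(pc$gene_id[!is.na(match(pc$gene_id, lnc$essential_neighbor))],
                 pc$gene_id[otherPcPool[seq_len(min(30, length(otherPcPool)))]])

  ## ---- transcripts / GTF -------------------------------------------------
  genes <- rbind(lnc[c("gene_id", "biotype", "label", "ts_tissue", "chrom",
                       "start", "strand", "length", "exons")],
                 cbind(pc[c("gene_id", "biotype", "label", "ts_tissue",
                            "chrom", "start", "strand", "length", "exons")]))
  genes$end <- genes$start + genes$length - 1L
  # every 20th gene carries a second, broadly expressed isoform: exercises
  # the any-transcript gene rule downstream
  genes$n_tx <- ifelse(seq_len(nrow(genes)) %% 20L == 0L, 2L, 1L)
  gtf <- character(0)
  txTab <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrsG <- sprintf('gene_id "%s"; gene_biotype "%s"; gene_source "GENCODE";',
                      g$gene_id, g$biotype)
    gtf <- c(gtf, sprintf("%s\tGENCODE\tgene\t%d\t%d\t.\t%s\t.\t%s",
                          g$chrom, g$start, g$end, g$strand, attrsG))
    for (tx in seq_len(g$n_tx)) {
      txId <- sprintf("%s.t%d", g$gene_id, tx)
      txTab[[length(txTab) + 1L]] <- data.frame(
        transcript_id = txId, gene_id = g$gene_id, isoform = tx,
        stringsAsFactors = FALSE)
      at <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_biotype ',
                           '"%s"; gene_source "GENCODE";'),
                    g$gene_id, txId, g$biotype)
      gtf <- c(gtf, sprintf("%s\tGENCODE\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, g$start, g$end, g$strand, at))
      ex <- .exonLayout(g$start, g$length, g$exons)
      gtf <- c(gtf, sprintf("%s\tGENCODE\texon\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, ex[, 1], ex[, 2], g$strand, at))
    }
  }
  writeLines(gtf, file.path(dir, "genes.gtf"))
  txTab <- do.call(rbind, txTab)

  ## ---- expression --------------------------------------------------------
  drawProfile <- function(lb, tsTissue, bio) {
    v <- numeric(nT)
    if (lb == "UE") {
      ml <- config$ueMeanlog + if (bio == "protein_coding") 0.5 else 0
      base <- stats::rlnorm(1, ml, config$ueSdlog)
      v <- base * stats::rlnorm(nT, 0, config$ueNoiseSdlog)
    } else if (lb == "TS") {
      ml <- config$tsMeanlog + if (bio == "protein_coding") 0.4 else 0
      v[match(tsTissue, tissues)] <- stats::rlnorm(1, ml, config$tsSdlog)
    } else {
      w <- sample(2:(nT - 1L), 1L)
      on <- sample.int(nT, w)
      ml <- config$tsMeanlog + if (bio == "protein_coding") 0.4 else 0
      v[on] <- stats::rlnorm(w, ml, config$tsSdlog)
    }
    v
  }
  expr <- matrix(0, nrow(txTab), nT,
                 dimnames = list(txTab$transcript_id, tissues))
  gidx <- match(txTab$gene_id, genes$gene_id)
  for (r in seq_len(nrow(txTab))) {
    g <- genes[gidx[r], ]
    lb <- if (txTab$isoform[r] == 1L) g$label else "other"
    expr[r, ] <- drawProfile(lb, g$ts_tissue, g$biotype)
  }
  # UE pc neighbors track their lncRNA's tissue profile (co-expression)
  for (li in which(!is.na(lnc$ue_pc_neighbor))) {
    lncTx <- paste0(lnc$gene_id[li], ".t1")
    pcTx <- paste0(lnc$ue_pc_neighbor[li], ".t1")
    rel <- expr[lncTx, ] / mean(expr[lncTx, ])
    expr[pcTx, ] <- mean(expr[pcTx, ]) * rel^0.8 *
      stats::rlnorm(nT, 0, 0.1)
  }
  nSampPerTissue <- ifelse(seq_len(nT) <= 5L, 2L, 1L)
  sampleIds <- unlist(lapply(seq_len(nT), function(t)
    sprintf("S_%s_%d", tissues[t], seq_len(nSampPerTissue[t]))))
  sampleTissue <- rep(tissues, nSampPerTissue)
  samp <- matrix(0, nrow(expr), length(sampleIds),
                 dimnames = list(rownames(expr), sampleIds))
  for (j in seq_along(sampleIds)) {
    tcol <- expr[, sampleTissue[j]]
    first <- !grepl("_2$", sampleIds[j])
    samp[, j] <- if (first) tcol else tcol * stats::runif(nrow(expr), 0.4, 0.95)
  }
  exprOut <- data.frame(feature_id = rownames(samp), gene_id = txTab$gene_id,
                        biotype = genes$biotype[gidx], samp,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(exprOut, file.path(dir, "expression.samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = sampleIds, tissue = sampleTissue),
                     file.path(dir, "sample_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bg <- data.frame(
    region_id = sprintf("BG%05d", seq_len(2L * config$nBackground)),
    biotype = rep(c("lncRNA", "protein_coding"), each = config$nBackground),
    fpkm = c(stats::rexp(config$nBackground, 1 / config$bgMeanLnc),
             stats::rexp(config$nBackground, 1 / config$bgMeanPc)))
  utils::write.table(bg, file.path(dir, "background.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- conservation ------------------------------------------------------
  consMean <- c(UE = 0.6, TS = 0.08, other = 0.2)
  consLines <- character(0)
  for (i in seq_len(nLnc)) {
    g <- genes[i, ]
    mu <- consMean[[g$label]]
    ex <- .exonLayout(g$start, g$length, g$exons)
    val <- round(pmin(1, pmax(0, stats::rnorm(nrow(ex) + 4L, mu, 0.05))), 4)
    tss <- if (g$strand == "+") g$start else g$end
    promChunks <- cbind(tss - 2000L + (0:3) * 1000L,
                        tss - 2000L + (1:4) * 1000L - 1L)
    seg <- rbind(promChunks, ex)
    consLines <- c(consLines, sprintf("%s\t%d\t%d\t%s", g$chrom,
                                      pmax(0L, seg[, 1] - 1L), seg[, 2], val))
  }
  writeLines(consLines, file.path(dir, "conservation.bedGraph"))

  ## ---- histone marks over promoters -------------------------------------
  tsGenes <- genes[genes$label == "TS", ]
  ord <- order(tsGenes$ts_tissue, tsGenes$biotype, tsGenes$gene_id)
  tsGenes <- tsGenes[ord, ]
  blk <- unlist(lapply(split(seq_len(nrow(tsGenes)), tsGenes$ts_tissue),
                       function(ii) {
    bio <- tsGenes$biotype[ii]
    b <- integer(length(ii))
    # alternate within each biotype so both blocks get coding members
    for (bt in unique(bio)) b[bio == bt] <- seq_len(sum(bio == bt)) %% 2L + 1L
    b
  }))
  tsGenes$cluster <- blk   # rows are sorted by tissue, matching split order
  markGenes <- rbind(cbind(tsGenes[c("gene_id", "chrom", "start", "end",
                                     "strand")], cluster = tsGenes$cluster),
                     cbind(genes[genes$label == "UE",
                                 c("gene_id", "chrom", "start", "end",
                                   "strand")], cluster = 0L))
  for (mi in seq_along(.ACTIVE_MARKS)) {
    lines <- character(0)
    for (r in seq_len(nrow(markGenes))) {
      g <- markGenes[r, ]
      # runs tile the promoter window exactly (strand-aware TSS convention)
      pst <- if (g$strand == "+") g$start - 2000L else g$end - 1999L
      lam <- if (g$cluster == 0L) (config$markHigh + config$markLow) / 2
             else if ((g$cluster == 1L) == (mi <= 3L)) config$markHigh
             else config$markLow
      depth <- stats::rpois(40L, lam)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", g$chrom,
                                pst - 1L + (0:39) * 100L,
                                pst - 1L + (1:40) * 100L, depth))
    }
    writeLines(lines, file.path(dir, "marks",
                                paste0(.ACTIVE_MARKS[mi], ".bedGraph")))
  }

  ## ---- CGIs, enhancers, promoter sequences -------------------------------
  cgiFrac <- ifelse(genes$label[seq_len(nLnc)] == "UE", config$ueCgiFrac,
                    config$bgCgiFrac)
  hasCgi <- stats::runif(nLnc) < cgiFrac
  tssAll <- ifelse(genes$strand == "+", genes$start, genes$end)
  cgiSt <- tssAll[seq_len(nLnc)][hasCgi] - 250L
  cgi <- sprintf("%s\t%d\t%d\tCGI%04d", genes$chrom[seq_len(nLnc)][hasCgi],
                 cgiSt - 1L, cgiSt + 499L, seq_len(sum(hasCgi)))
  writeLines(cgi, file.path(dir, "cgi.bed"))

  enhFrac <- c(UE = config$ueEnhancerFrac, TS = config$tsEnhancerFrac,
               other = config$otherEnhancerFrac)
  enhLines <- character(0); enhId <- 0L
  lnc$enhancer_class <- NA_character_
  for (i in seq_len(nLnc)) {
    lb <- genes$label[i]
    if (stats::runif(1) >= enhFrac[[lb]]) next
    enhId <- enhId + 1L
    gap <- as.integer(stats::runif(1, 500, 8000))
    stE <- genes$end[i] + gap
    klass <- if (lb == "UE") "UE" else if (lb == "TS") "TS"
             else sample(c("UE", "TS"), 1L)
    ncl <- if (klass == "UE") sample(3:8, 1L) else sample(1:2, 1L)
    cl <- paste(sort(sample(cells, ncl)), collapse = ",")
    state <- sample(c("strong", "weak"), 1L)
    lnc$enhancer_class[i] <- klass
    enhLines <- c(enhLines, sprintf("%s\t%d\t%d\tENH%05d\t%s\t%s",
                                    genes$chrom[i], stE - 1L, stE + 799L,
                                    enhId, cl, state))
  }
  for (j in seq_len(100L)) {   # background enhancers far from every lncRNA
    stE <- as.integer(stats::runif(1, 1e6, 2.4e8))
    ncl <- sample.int(6L, 1L)
    enhLines <- c(enhLines, sprintf("chrP1\t%d\t%d\tENHB%03d\t%s\t%s",
                                    stE - 1L, stE + 799L, j,
                                    paste(sort(sample(cells, ncl)),
                                          collapse = ","),
                                    sample(c("strong", "weak"), 1L)))
  }
  writeLines(enhLines, file.path(dir, "enhancers.bed"))

  base <- c("A", "C", "G", "T")
  fa <- character(2L * nLnc)
  for (i in seq_len(nLnc)) {
    s <- sample(base, 4000L, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
    if (hasCgi[i]) {
      core <- sample(c("C", "G"), 600L, replace = TRUE)
      core[seq(1, 599, 2)] <- "C"; core[seq(2, 600, 2)] <- "G"
      s[1701:2300] <- core
    }
    fa[2L * i - 1L] <- paste0(">", genes$gene_id[i])
    fa[2L * i] <- paste(s, collapse = "")
  }
  writeLines(fa, file.path(dir, "promoters.fasta"))

  ## ---- regulators, GO, bands, essential ----------------------------------
  tfs <- sprintf("TF%03d", 1:50)
  mirs <- sprintf("miR%03d", 1:100)
  tfLam <- c(UE = 8, TS = 3, other = 4)
  mirLam <- c(UE = 5, TS = 2, other = 2)
  edges <- list()
  for (i in seq_len(nLnc)) {
    lb <- genes$label[i]
    ntf <- min(length(tfs), stats::rpois(1, tfLam[[lb]]))
    nmir <- min(length(mirs), stats::rpois(1, mirLam[[lb]]))
    if (ntf) edges[[length(edges) + 1L]] <- data.frame(
      regulator_id = sample(tfs, ntf), target_id = genes$gene_id[i],
      regulator_type = "TF", stringsAsFactors = FALSE)
    if (nmir) edges[[length(edges) + 1L]] <- data.frame(
      regulator_id = sample(mirs, nmir), target_id = genes$gene_id[i],
      regulator_type = "miRNA", stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  utils::write.table(edges[edges$regulator_type == "TF", ],
                     file.path(dir, "tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges[edges$regulator_type == "miRNA", ],
                     file.path(dir, "mirna_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  hkTerms <- data.frame(term_id = sprintf("GO:000000%d", 1:5),
                        term_name = paste0("housekeeping process ", 1:5))
  bgTerms <- data.frame(term_id = sprintf("GO:00090%02d", 1:50),
                        term_name = paste0("background process ", 1:50))
  go <- list()
  for (pi in which(pc$label == "UE")) {
    pick <- sample.int(5L, 2L)
    go[[length(go) + 1L]] <- data.frame(gene_id = pc$gene_id[pi],
                                        term_id = hkTerms$term_id[pick],
                                        term_name = hkTerms$term_name[pick],
                                        stringsAsFactors = FALSE)
  }
  tsPcGenes <- tsGenes[tsGenes$biotype == "protein_coding", ]
  clTerm <- function(tissue, cluster)
    sprintf("GO:1%s%02d", sub("T", "9", tissue), cluster)
  for (r in seq_len(nrow(tsPcGenes))) {
    tm <- clTerm(tsPcGenes$ts_tissue[r], tsPcGenes$cluster[r])
    go[[length(go) + 1L]] <- data.frame(
      gene_id = tsPcGenes$gene_id[r], term_id = tm,
      term_name = paste0(tsPcGenes$ts_tissue[r], " cluster ",
                         tsPcGenes$cluster[r], " process"),
      stringsAsFactors = FALSE)
  }
  for (pi in seq_len(nPc)) {
    pick <- sample.int(50L, 3L)
    go[[length(go) + 1L]] <- data.frame(gene_id = pc$gene_id[pi],
                                        term_id = bgTerms$term_id[pick],
                                        term_name = bgTerms$term_name[pick],
                                        stringsAsFactors = FALSE)
  }
  go <- do.call(rbind, go)
  utils::write.table(go, file.path(dir, "go_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  utils::write.table(data.frame(gene_id = essential),
                     file.path(dir, "essential_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  bandOf <- function(chrom, start) sprintf("%s_b%02d", chrom,
                                           pmin(10L, start %/% 26000000L + 1L))
  bands <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      band = bandOf(genes$chrom, genes$start),
                      stringsAsFactors = FALSE)
  utils::write.table(bands, file.path(dir, "bands.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- ground truth ------------------------------------------------------
  clusterId <- rep(NA_character_, nrow(genes))
  m <- match(genes$gene_id, tsGenes$gene_id)
  clusterId[!is.na(m)] <- paste0(tsGenes$ts_tissue[m[!is.na(m)]], "_",
                                 c("A", "B")[tsGenes$cluster[m[!is.na(m)]]])
  truth <- data.frame(
    gene_id = genes$gene_id, biotype = genes$biotype, label = genes$label,
    ts_tissue = genes$ts_tissue, cluster_id = clusterId,
    ue_pc_neighbor = c(lnc$ue_pc_neighbor, rep(NA, nPc)),
    has_ue_pc_100kb = c(!is.na(lnc$ue_pc_neighbor), rep(NA, nPc)),
    essential_neighbor = c(lnc$essential_neighbor, rep(NA, nPc)),
    has_essential_50kb = c(!is.na(lnc$essential_neighbor), rep(NA, nPc)),
    cgi_promoter = c(hasCgi, rep(NA, nPc)),
    enhancer_class = c(lnc$enhancer_class, rep(NA, nPc)),
    stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(truth = truth, dir = dir,
                 files = list.files(dir, recursive = TRUE)))
}

#' A hand-checkable micro dataset
#'
#' Twelve single-transcript genes over three tissues with round FPKM values,
#' small enough that every intermediate quantity (CV, specificity score,
#' width, label) can be recomputed by hand.  Thresholds are fixed at 0.14
#' (lncRNA) / 0.21 (protein coding).
#'
#' @return list with \code{fpkm} (matrix), \code{biotype}, \code{thresholds}
#'   and \code{expected} (data.frame of expected labels and widths).
#' @export
workedMicroExample <- function() {
  tissues <- c("Ta", "Tb", "Tc")
  rows <- rbind(
    UE_1  = c(5,    6,    5),
    UE_2  = c(2,    2,    2),
    TS_1  = c(0,    0,    9),
    TS_2  = c(0,    3,    0),
    OTH_1 = c(1,    1,    0),
    OTH_2 = c(0.2,  0.05, 0.3),
    OTH_3 = c(0,    0,    0),
    PCU_1 = c(30,   28,   35),
    PCT_1 = c(12,   0,    0),
    PCO_1 = c(0.5,  0.22, 0),
    PCO_2 = c(7,    0,    4),
    PCO_3 = c(0.1,  0.05, 0.02))
  colnames(rows) <- tissues
  biotype <- c(rep("lncRNA", 7), rep("protein_coding", 5))
  expected <- data.frame(
    feature_id = rownames(rows),
    label = c("UE", "UE", "TS", "TS", "other", "other", "other",
              "UE", "TS", "other", "other", "other"),
    width = c(3, 3, 1, 1, 2, 2, 0, 3, 1, 2, 2, 0),
    stringsAsFactors = FALSE)
  list(fpkm = rows, biotype = biotype,
       thresholds = c(lncRNA = 0.14, protein_coding = 0.21),
       expected = expected)
}
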