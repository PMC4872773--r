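#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis.  Detection
#' thresholds are estimated from the background tables by default
#' (\code{thresholds = "estimate"}) or can be fixed, e.g.
#' \code{c(lncRNA = 0.14, protein_coding = 0.21)}.
#'
#' @param thresholds "estimate" or a named numeric per biotype.
#' @param cvMax,tsMin classification cutoffs.
#' @param promoterUp,promoterDown promoter window around the TSS (nt).
#' @param tfUp,tfDown TF-assignment window around the TSS (nt).
#' @param enhancerWindow,essentialWindow proximity windows (nt).
#' @param neighborWindows distance ladder for the neighbor analysis (nt).
#' @param enhancerRule "moreThanTwo" or "atLeastTwo" cell lines for the UE
#'   enhancer call.
#' @param ueEnrichWindow neighbor window feeding the UE GO enrichment (nt).
#' @param maxAdjP,minOverlap GO enrichment reporting filters.
#' @param nPerm permutations for the co-expression randomization test.
#' @param seed seed for the pipeline's stochastic steps.
#' @return named list.
#' @export
pipelineConfig <- function(thresholds = "estimate", cvMax = 1, tsMin = 0.4,
                           promoterUp = 2000, promoterDown = 2000,
                           tfUp = 5000, tfDown = 1000,
                           enhancerWindow = 1e4, essentialWindow = 5e4,
                           neighborWindows = c(5e3, 1e4, 2.5e4, 5e4, 1e5),
                           enhancerRule = "moreThanTwo",
                           ueEnrichWindow = 1e5, maxAdjP = 0.1,
                           minOverlap = 2, nPerm = 1000, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("promoterUp", "promoterDown", "tfUp", "tfDown",
                             "enhancerWindow", "essentialWindow",
                             "neighborWindows")]) >= 0))
  if (is.numeric(cfg$thresholds) && any(cfg$thresholds <= 0))
    stop("fixed thresholds must be positive")
  cfg
}

.readTsv <- function(path, what) {
  if (!file.exists(path)) stop("missing ", what, " file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.geneLevelFpkm <- function(mat, geneIds) {
  u <- unique(geneIds)
  single <- !(geneIds %in% geneIds[duplicated(geneIds)])
  out <- matrix(0, length(u), ncol(mat), dimnames = list(u, colnames(mat)))
  out[geneIds[single], ] <- mat[single, , drop = FALSE]
  for (g in unique(geneIds[!single]))
    out[g, ] <- apply(mat[geneIds == g, , drop = FALSE], 2L, max)
  out
}

#' Run the full analysis on a dataset bundle
#'
#' Executes annotation, expression assembly, threshold estimation,
#' classification, structural / conservation / CpG / regulator
#' characterization, promoter metaprofiles, enhancer and essential-gene
#' proximity, neighbor-based UE function prediction with a co-expression
#' randomization test, per-tissue co-modification clustering for TS
#' function prediction, and band enrichment.  Inputs follow the file layout
#' written by [simulateLncDataset()].  All outputs are plain TSV/JSON and
#' are a pure function of the bundle and configuration, so a rerun produces
#' identical files.
#'
#' @param bundleDir directory with the input bundle.
#' @param outDir output directory (created).
#' @param config list from [pipelineConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(bundleDir, outDir, config = pipelineConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  wtsv <- function(d, f) utils::write.table(d, file.path(outDir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  counts <- list()

  ## ---- annotation --------------------------------------------------------
  gm <- readGeneModels(file.path(bundleDir, "genes.gtf"))
  nr <- buildNonredundantSet(gm, priority = unique(geneRanges(gm)$source))
  gm <- nr$models
  writeLociBed(geneRanges(gm), file.path(outDir, "genes.nonredundant.bed"))
  wtsv(nr$log, "redundancy_log.tsv")
  genes <- geneRanges(gm)
  counts$genes <- length(genes)
  counts$transcripts <- length(exonsByTranscript(gm))

  ## ---- expression & thresholds ------------------------------------------
  ex <- .readTsv(file.path(bundleDir, "expression.samples.tsv"), "expression")
  smap <- .readTsv(file.path(bundleDir, "sample_map.tsv"), "sample map")
  sampleCols <- setdiff(names(ex), c("feature_id", "gene_id", "biotype"))
  sm <- as.matrix(ex[sampleCols])
  rownames(sm) <- ex$feature_id
  tissueMat <- aggregateToTissues(sm, stats::setNames(smap$tissue,
                                                      smap$sample_id))
  te <- TissueExpression(tissueMat, biotype = ex$biotype,
                         level = "transcript", gene_id = ex$gene_id)
  bgTab <- .readTsv(file.path(bundleDir, "background.tsv"), "background")
  if (identical(config$thresholds, "estimate")) {
    thr <- lapply(unique(ex$biotype), function(b) {
      v <- tissueMat[ex$biotype == b, ]
      estimateDetectionThreshold(v[v > 0], bgTab$fpkm[bgTab$biotype == b],
                                 biotype = b)
    })
    names(thr) <- unique(ex$biotype)
    thresholds <- vapply(thr, thresholdValue, 0)
    jsonlite::write_json(
      lapply(thr, function(t) list(biotype = t@biotype,
                                   threshold = t@threshold,
                                   fp = t@fpCount, fn = t@fnCount,
                                   candidates = t@nCandidates)),
      file.path(outDir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  } else {
    thresholds <- config$thresholds
    jsonlite::write_json(as.list(thresholds),
                         file.path(outDir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  counts$thresholds <- as.list(thresholds)

  ## ---- classification ----------------------------------------------------
  txRes <- classifyTranscripts(te, thresholds, cvMax = config$cvMax,
                               tsMin = config$tsMin)
  gRes <- classifyGenes(txRes, ex$gene_id)
  bioByGene <- ex$biotype[match(gRes$feature_id, ex$gene_id)]
  gTab <- as.data.frame(gRes)
  gTab$biotype <- bioByGene
  wtsv(as.data.frame(txRes), "classification.transcripts.tsv")
  wtsv(gTab, "classification.genes.tsv")
  counts$labels <- as.list(table(paste(gTab$biotype, gTab$label)))

  lncTab <- gTab[gTab$biotype == "lncRNA", ]
  pcTab <- gTab[gTab$biotype == "protein_coding", ]
  lncGroups <- stats::setNames(lncTab$label, lncTab$feature_id)
  lncGR <- genes[match(lncTab$feature_id, genes$gene_id)]
  pcGR <- genes[match(pcTab$feature_id, genes$gene_id)]

  ## ---- structural / conservation / CpG / regulator features -------------
  ss <- structureStats(gm, lncGroups)
  wtsv(ss$perGene, "structure_per_gene.tsv")
  wtsv(ss$medians, "structure_medians.tsv")

  prom <- promoterRegions(lncGR, config$promoterUp, config$promoterDown)
  consPath <- file.path(bundleDir, "conservation.bedGraph")
  featTab <- data.frame(gene_id = lncTab$feature_id, label = lncTab$label,
                        stringsAsFactors = FALSE)
  if (file.exists(consPath)) {
    cons <- trackToRle(rtracklayer::import(consPath, format = "bedGraph"))
    featTab$promoter_conservation <- meanConservation(prom, cons)
    exonsByGene <- S4Vectors::split(
      unlist(exonsByTranscript(gm)),
      rep(mcols(exonsByTranscript(gm))$gene_id,
          lengths(exonsByTranscript(gm))))
    exonUnion <- reduce(exonsByGene)
    exCons <- vapply(relist(meanConservation(unlist(exonUnion), cons),
                            exonUnion), mean, 0, na.rm = TRUE)
    featTab$exon_conservation <- exCons[featTab$gene_id]
  }
  cgiPath <- file.path(bundleDir, "cgi.bed")
  faPath <- file.path(bundleDir, "promoters.fasta")
  cpg <- categorizePromoterCpg(
    prom,
    cgi = if (file.exists(cgiPath)) rtracklayer::import(cgiPath,
                                                        format = "BED"),
    sequences = if (file.exists(faPath)) Biostrings::readDNAStringSet(faPath))
  featTab$cgi_overlap <- cpg$cgi_overlap
  featTab$cpg_class <- cpg$cpg_class
  edges <- rbind(.readTsv(file.path(bundleDir, "tf_edges.tsv"), "TF edges"),
                 .readTsv(file.path(bundleDir, "mirna_edges.tsv"),
                          "miRNA edges"))
  reg <- countRegulators(featTab$gene_id, edges)
  featTab$tf_count <- reg$tf_count
  featTab$mirna_count <- reg$mirna_count
  wtsv(featTab, "lnc_features.tsv")

  ## ---- epigenome ---------------------------------------------------------
  markDir <- file.path(bundleDir, "marks")
  markFiles <- if (dir.exists(markDir))
    list.files(markDir, pattern = "\\.bedGraph$", full.names = TRUE)
  else character()
  markFiles <- sort(markFiles)
  markTracks <- lapply(markFiles, function(mf)
    trackToRle(rtracklayer::import(mf, format = "bedGraph")))
  names(markTracks) <- sub("\\.bedGraph$", "", basename(markFiles))
  profRows <- list()
  for (mk in names(markTracks)) {
    pps <- binPromoterSignal(prom, markTracks[[mk]], mark = mk)
    agg <- aggregateProfiles(pps, lncGroups)
    for (g in rownames(agg))
      profRows[[paste(mk, g)]] <- data.frame(mark = mk, label = g,
                                             bin = seq_len(ncol(agg)),
                                             mean_signal = agg[g, ])
  }
  if (length(profRows)) wtsv(do.call(rbind, profRows), "promoter_profiles.tsv")

  enh <- classifyEnhancers(readEnhancerBed(file.path(bundleDir,
                                                     "enhancers.bed")),
                           rule = config$enhancerRule)
  essIds <- .readTsv(file.path(bundleDir, "essential_genes.tsv"),
                     "essential genes")$gene_id
  essGR <- pcGR[pcGR$gene_id %in% essIds]
  proxRows <- list()
  for (lb in unique(lncTab$label)) {
    fs <- lncGR[lncGroups[lncGR$gene_id] == lb]
    proxRows[[lb]] <- data.frame(
      label = lb, n = length(fs),
      enhancer_frac = proximityFraction(fs, enh,
                                        config$enhancerWindow)$fraction,
      ue_enhancer_frac = proximityFraction(
        fs, enh[enh$ubiquity_label == "UE"],
        config$enhancerWindow)$fraction,
      ts_enhancer_frac = proximityFraction(
        fs, enh[enh$ubiquity_label == "TS"],
        config$enhancerWindow)$fraction,
      essential_frac = proximityFraction(fs, essGR,
                                         config$essentialWindow)$fraction)
  }
  wtsv(do.call(rbind, proxRows), "proximity.tsv")
  counts$enhancers <- as.list(table(enh$ubiquity_label))

  ## ---- UE function prediction -------------------------------------------
  geneFpkm <- .geneLevelFpkm(tissueMat, ex$gene_id)
  ueLnc <- lncGR[lncGroups[lncGR$gene_id] == "UE"]
  uePc <- pcGR[pcTab$label[match(pcGR$gene_id, pcTab$feature_id)] == "UE"]
  go <- .readTsv(file.path(bundleDir, "go_annotation.tsv"), "GO annotation")
  universe <- pcTab$feature_id
  predictions <- list()
  if (length(ueLnc)) {
    nb <- neighborsWithin(ueLnc, uePc, windows = config$neighborWindows)
    wtsv(nb$perLnc, "ue_neighbors.tsv")
    wtsv(data.frame(window = names(nb$fractions),
                    fraction = unname(nb$fractions)),
         "ue_neighbor_fractions.tsv")
    rt <- NULL
    if (nrow(nb$pairs)) {
      cors <- coexpression(geneFpkm[nb$pairs$lnc_id, , drop = FALSE],
                           geneFpkm[nb$pairs$pc_id, , drop = FALSE])
      bgIds <- setdiff(pcTab$feature_id, nb$pairs$pc_id)
      rt <- randomizationTest(cors, geneFpkm[nb$pairs$lnc_id, , drop = FALSE],
                              geneFpkm[bgIds, , drop = FALSE],
                              nPerm = config$nPerm, seed = config$seed)
    }
    nbSet <- unique(nb$pairs$pc_id[nb$pairs$distance <=
                                     config$ueEnrichWindow])
    ueEnr <- goEnrichment(nbSet, go, universe, maxAdjP = config$maxAdjP,
                          minOverlap = config$minOverlap)
    wtsv(ueEnr, "ue_enrichment.tsv")
    if (nrow(ueEnr)) {
      withNb <- unique(nb$pairs$lnc_id)
      predictions$ue <- data.frame(
        lncRNA_id = rep(withNb, each = nrow(ueEnr)),
        term_id = rep(ueEnr$term_id, length(withNb)),
        term_name = rep(ueEnr$term_name, length(withNb)),
        p_adjusted = rep(ueEnr$p_adjusted, length(withNb)),
        cluster_id = NA_character_, evidence = "neighbor",
        stringsAsFactors = FALSE)
    }
    jsonlite::write_json(
      list(observed_mean = if (is.null(rt)) NULL else rt$observedMean,
           p = if (is.null(rt)) NULL else rt$p,
           n_perm = config$nPerm,
           null_mean = if (is.null(rt)) NULL else mean(rt$nullMeans)),
      file.path(outDir, "ue_coexpression.json"), auto_unbox = TRUE,
      digits = NA)
  }

  ## ---- TS function prediction by co-modification ------------------------
  tsLncTab <- lncTab[lncTab$label == "TS", ]
  tsPcTab <- pcTab[pcTab$label == "TS", ]
  clusterReport <- list()
  for (tis in sort(unique(stats::na.omit(tsLncTab$ts_tissue)))) {
    lncIds <- tsLncTab$feature_id[tsLncTab$ts_tissue == tis]
    pcIds <- tsPcTab$feature_id[!is.na(tsPcTab$ts_tissue) &
                                  tsPcTab$ts_tissue == tis]
    members <- c(lncIds, pcIds)
    if (length(members) < 3L || !length(markFiles)) next
    mgr <- genes[match(members, genes$gene_id)]
    mprom <- promoterRegions(mgr, config$promoterUp, config$promoterDown)
    profs <- lapply(markTracks, function(tr)
      profileMatrix(binPromoterSignal(mprom, tr)))
    pr <- predictTsFunction(profs, lncIds, pcIds, go, universe, tissue = tis,
                            maxAdjP = config$maxAdjP,
                            minOverlap = config$minOverlap)
    if (nrow(pr$predictions)) predictions[[tis]] <- pr$predictions
    clusterReport[[tis]] <- list(k = pr$k, n = length(members),
                                 n_lnc = length(lncIds), n_pc = length(pcIds))
  }
  predCols <- c("lncRNA_id", "term_id", "term_name", "p_adjusted",
                "cluster_id", "evidence")
  predictions <- lapply(predictions, function(d) { d$cluster_id <-
    as.character(d$cluster_id); d[predCols] })
  predTab <- if (length(predictions)) do.call(rbind, predictions) else
    data.frame(lncRNA_id = character(), term_id = character(),
               term_name = character(), p_adjusted = numeric(),
               cluster_id = character(), evidence = character())
  rownames(predTab) <- NULL
  wtsv(predTab, "predictions.tsv")
  jsonlite::write_json(clusterReport, file.path(outDir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$predictions <- nrow(predTab)

  ## ---- band enrichment ---------------------------------------------------
  bandsPath <- file.path(bundleDir, "bands.tsv")
  if (file.exists(bandsPath)) {
    bands <- .readTsv(bandsPath, "bands")
    lncBands <- bands[bands$gene_id %in% lncTab$feature_id, ]
    for (lb in c("UE", "TS")) {
      be <- bandEnrichment(lncTab$feature_id[lncTab$label == lb], lncBands)
      wtsv(be$band, sprintf("band_enrichment_%s.tsv", lb))
      wtsv(be$chromosome, sprintf("chrom_enrichment_%s.tsv", lb))
    }
  }

  manifest <- list(config = config, counts = counts,
                   bundle_files = sort(list.files(bundleDir,
                                                  recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
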