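#' Protein-coding neighbors of lncRNAs at several distance windows
#'
#' For each lncRNA locus, finds the protein-coding gene loci within each gap
#' distance window, and the nearest one.  With \code{sameTissue = TRUE} only
#' protein-coding genes tissue-specific to the lncRNA's own tissue count
#' (the bracketed same-tissue variant of the TS analysis).
#'
#' @param lnc \code{GRanges} of lncRNA loci with \code{gene_id}.
#' @param pc \code{GRanges} of protein-coding loci with \code{gene_id}.
#' @param windows numeric vector of gap distances in nt.
#' @param sameTissue restrict neighbors to the same tissue.
#' @param lncTissue,pcTissue named vectors gene_id -> tissue (required when
#'   \code{sameTissue}).
#' @return list: \code{perLnc} data.frame with nearest_id, nearest_distance
#'   and one logical \code{within_<w>} column per window; \code{fractions}
#'   named numeric (fraction of lncRNAs with a neighbor per window);
#'   \code{pairs} data.frame (lnc_id, pc_id, distance) within the largest
#'   window.
#' @export
neighborsWithin <- function(lnc, pc, windows = c(5e3, 1e4, 2.5e4, 5e4, 1e5),
                            sameTissue = FALSE, lncTissue = NULL,
                            pcTissue = NULL) {
  windows <- sort(windows)
  wmax <- max(windows)
  perLnc <- data.frame(lnc_id = lnc$gene_id, nearest_id = NA_character_,
                       nearest_distance = Inf, stringsAsFactors = FALSE)
  pairs <- data.frame(lnc_id = character(), pc_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (length(pc)) {
    hits <- findOverlaps(lnc, pc, maxgap = wmax, ignore.strand = TRUE)
    if (length(hits)) {
      d <- intervalDistance(lnc[queryHits(hits)], pc[subjectHits(hits)])
      keep <- rep(TRUE, length(hits))
      if (sameTissue) {
        stopifnot(!is.null(lncTissue), !is.null(pcTissue))
        keep <- !is.na(lncTissue[lnc$gene_id[queryHits(hits)]]) &
          lncTissue[lnc$gene_id[queryHits(hits)]] ==
            pcTissue[pc$gene_id[subjectHits(hits)]]
        keep[is.na(keep)] <- FALSE
      }
      pairs <- data.frame(lnc_id = lnc$gene_id[queryHits(hits)][keep],
                          pc_id = pc$gene_id[subjectHits(hits)][keep],
                          distance = d[keep], stringsAsFactors = FALSE)
      if (nrow(pairs)) {
        o <- order(pairs$lnc_id, pairs$distance)
        first <- pairs[o, ][!duplicated(pairs$lnc_id[o]), ]
        m <- match(perLnc$lnc_id, first$lnc_id)
        perLnc$nearest_id <- first$pc_id[m]
        perLnc$nearest_distance <- first$distance[m]
        perLnc$nearest_distance[is.na(perLnc$nearest_distance)] <- Inf
      }
    }
  }
  for (w in windows)
    perLnc[[paste0("within_", format(w, scientific = FALSE))]] <-
      perLnc$nearest_distance <= w
  fractions <- vapply(windows, function(w) mean(perLnc$nearest_distance <= w), 0)
  names(fractions) <- format(windows, scientific = FALSE)
  list(perLnc = perLnc, fractions = fractions, pairs = pairs)
}

#' Co-expression of paired expression profiles
#'
#' Correlation between matched rows of two matrices over the same tissue
#' columns, after an optional log2(FPKM + 1) transform.  Pairs with a
#' zero-variance member are undefined and returned as \code{NA}.
#'
#' @param x,y numeric matrices with one row per pair (or single vectors).
#' @param method "pearson" or "spearman".
#' @param log2p1 transform values by log2(x + 1) first (default TRUE).
#' @return numeric vector of correlations per pair.
#' @export
coexpression <- function(x, y, method = c("pearson", "spearman"),
                         log2p1 = TRUE) {
  method <- match.arg(method)
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (is.null(dim(y))) y <- matrix(y, 1L)
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  if (log2p1) { x <- log2(x + 1); y <- log2(y + 1) }
  vapply(seq_len(nrow(x)), function(i) {
    a <- x[i, ]; b <- y[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }, 0)
}

#' Permutation test for neighbor co-expression
#'
#' Repeatedly replaces the true neighbors by the same number of
#' protein-coding genes drawn from a background set (pseudo-neighbors),
#' recomputes the paired correlations and their mean, and compares the
#' observed mean against that null.  The empirical p-value uses the add-one
#' estimator p = (1 + #\{null >= observed\}) / (1 + nPerm).
#'
#' @param observedCors correlations of the true lncRNA-neighbor pairs.
#' @param lncRows matrix of lncRNA expression rows, one per observed pair.
#' @param backgroundRows matrix of background protein-coding expression rows
#'   (must exclude true neighbors and have at least as many rows as pairs).
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param method,log2p1 passed to [coexpression()].
#' @return list: \code{p}, \code{observedMean}, \code{nullMeans} (length
#'   \code{nPerm}).
#' @export
randomizationTest <- function(observedCors, lncRows, backgroundRows,
                              nPerm = 1000, seed = NULL,
                              method = "pearson", log2p1 = TRUE) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  if (is.null(dim(lncRows))) lncRows <- matrix(lncRows, 1L)
  npair <- nrow(lncRows)
  if (nrow(backgroundRows) < npair)
    stop("background smaller than the number of neighbor pairs")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(observedCors, na.rm = TRUE)
  nullMeans <- vapply(seq_len(nPerm), function(i) {
    j <- sample.int(nrow(backgroundRows), npair)
    mean(coexpression(lncRows, backgroundRows[j, , drop = FALSE],
                      method = method, log2p1 = log2p1), na.rm = TRUE)
  }, 0)
  list(p = (1 + sum(nullMeans >= obs)) / (1 + nPerm),
       observedMean = obs, nullMeans = nullMeans)
}

#' Hypergeometric GO term enrichment with BH correction
#'
#' Upper-tail hypergeometric test of the overlap between a gene set and each
#' annotated term over a gene universe, Benjamini-Hochberg adjusted across
#' all tested terms.  By default only terms with adjusted p below
#' \code{maxAdjP} and at least \code{minOverlap} contributing genes are
#' reported.
#'
#' @param geneSet character vector (subset of \code{universe}).
#' @param annotation data.frame with gene_id, term_id and optionally
#'   term_name.
#' @param universe character vector of all considered genes.
#' @param maxAdjP,minOverlap reporting filters (defaults 0.1 and 2).
#' @param filter set FALSE to return all tested terms.
#' @return data.frame: term_id, term_name, overlap, set_size, term_size,
#'   universe_size, p_raw, p_adjusted, genes (comma-separated contributors).
#' @export
goEnrichment <- function(geneSet, annotation, universe, maxAdjP = 0.1,
                         minOverlap = 2, filter = TRUE) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% universe))
    stop("geneSet must be a subset of the universe")
  ann <- unique(annotation[annotation$gene_id %in% universe,
                           c("gene_id", "term_id",
                             intersect("term_name", names(annotation)))])
  if (!nrow(ann))
    return(data.frame(term_id = character(), term_name = character(),
                      overlap = integer(), set_size = integer(),
                      term_size = integer(), universe_size = integer(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(geneSet)
  byTerm <- split(ann$gene_id, ann$term_id)
  termNames <- if ("term_name" %in% names(ann))
    vapply(split(as.character(ann$term_name), ann$term_id), `[`, "", 1L)
  else stats::setNames(names(byTerm), names(byTerm))
  res <- do.call(rbind, lapply(names(byTerm), function(tm) {
    tg <- byTerm[[tm]]
    K <- length(tg)
    hit <- intersect(geneSet, tg)
    k <- length(hit)
    data.frame(term_id = tm, term_name = unname(termNames[tm]), overlap = k,
               set_size = n, term_size = K, universe_size = N,
               p_raw = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  res <- res[order(res$p_raw), c("term_id", "term_name", "overlap", "set_size",
                                 "term_size", "universe_size", "p_raw",
                                 "p_adjusted", "genes")]
  rownames(res) <- NULL
  if (filter) res <- res[res$p_adjusted < maxAdjP & res$overlap >= minOverlap, ]
  res
}

#' Predict TS lncRNA function by epigenetic co-modification clustering
#'
#' Builds one feature vector per TS gene (lncRNA or protein-coding) from its
#' active-mark promoter profiles (by default the mean over the 40 bins per
#' mark, z-scored per mark across genes), clusters all genes jointly by
#' average-linkage hierarchical clustering under the 1 - Pearson correlation
#' distance, cuts the tree at the k in \code{2..kMax} maximizing the mean
#' silhouette width (unless \code{k} is given), and runs GO enrichment on the
#' protein-coding members of each cluster.  Each lncRNA inherits the enriched
#' terms of its cluster; clusters without protein-coding members predict
#' nothing.
#'
#' @param profiles named list, one element per mark, each a matrix
#'   (genes x bins) whose rownames cover all members.
#' @param lncIds,pcIds member ids (TS in the same tissue).
#' @param goAnnotation,goUniverse passed to [goEnrichment()].
#' @param tissue label carried into the output.
#' @param k fixed number of clusters (NULL = silhouette-chosen).
#' @param kMax largest k tried (capped at n - 1).
#' @param summary "binMean" (default) or "full" (concatenate all bins).
#' @param maxAdjP,minOverlap enrichment filters.
#' @return list: \code{members} data.frame (member_id, type, cluster),
#'   \code{predictions} data.frame (lncRNA_id, term_id, term_name,
#'   p_adjusted, cluster_id, evidence), \code{enrichment} per-cluster list,
#'   \code{k}, \code{tissue}.  Fewer than 3 members yields an empty result
#'   with a warning.
#' @export
predictTsFunction <- function(profiles, lncIds, pcIds, goAnnotation,
                              goUniverse, tissue = NA_character_, k = NULL,
                              kMax = 15, summary = c("binMean", "full"),
                              maxAdjP = 0.1, minOverlap = 2) {
  summary <- match.arg(summary)
  members <- c(lncIds, pcIds)
  empty <- list(members = data.frame(member_id = character(),
                                     type = character(), cluster = integer()),
                predictions = data.frame(lncRNA_id = character(),
                                         term_id = character(),
                                         term_name = character(),
                                         p_adjusted = numeric(),
                                         cluster_id = integer(),
                                         evidence = character()),
                enrichment = list(), k = 0L, tissue = tissue)
  if (length(members) < 3L) {
    warning("fewer than 3 members; no clustering performed")
    return(empty)
  }
  feat <- do.call(cbind, lapply(names(profiles), function(mk) {
    m <- profiles[[mk]][members, , drop = FALSE]
    v <- if (summary == "binMean") cbind(rowMeans(m)) else m
    sc <- scale(v)                      # per-mark z-score across genes
    sc[, apply(v, 2L, stats::sd) > 0, drop = FALSE]
  }))
  if (ncol(feat) < 2L)
    stop("at least two informative mark features are required for the ",
         "correlation distance")
  d <- stats::as.dist(1 - stats::cor(t(feat)))
  hc <- stats::hclust(d, method = "average")
  if (is.null(k)) {
    ks <- seq(2L, min(kMax, length(members) - 1L))
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, 0)
    k <- ks[which.max(sil)]
  }
  cl <- stats::cutree(hc, k)
  mem <- data.frame(member_id = members,
                    type = rep(c("lncRNA", "protein_coding"),
                               c(length(lncIds), length(pcIds))),
                    cluster = unname(cl), stringsAsFactors = FALSE)
  enr <- list()
  preds <- list()
  for (cc in sort(unique(mem$cluster))) {
    pcm <- mem$member_id[mem$cluster == cc & mem$type == "protein_coding"]
    lncm <- mem$member_id[mem$cluster == cc & mem$type == "lncRNA"]
    if (!length(pcm)) next
    e <- goEnrichment(pcm, goAnnotation, goUniverse, maxAdjP = maxAdjP,
                      minOverlap = minOverlap)
    enr[[as.character(cc)]] <- e
    if (nrow(e) && length(lncm))
      preds[[as.character(cc)]] <- data.frame(
        lncRNA_id = rep(lncm, each = nrow(e)),
        term_id = rep(e$term_id, length(lncm)),
        term_name = rep(e$term_name, length(lncm)),
        p_adjusted = rep(e$p_adjusted, length(lncm)),
        cluster_id = cc, evidence = "comodification",
        stringsAsFactors = FALSE)
  }
  preds <- if (length(preds)) do.call(rbind, preds) else empty$predictions
  rownames(preds) <- NULL
  list(members = mem, predictions = preds, enrichment = enr, k = k,
       tissue = tissue)
}

#' Chromosome and band enrichment of a gene category
#'
#' Upper-tail hypergeometric test of category membership per chromosome band
#' and per chromosome, against the universe of all annotated genes of the
#' same biotype.  Significance is called at raw p <= alpha with no
#' multiplicity correction.
#'
#' @param categoryGenes character vector of gene ids in the category.
#' @param genes data.frame with gene_id, chrom and band columns (the
#'   universe).
#' @param alpha significance cutoff on the raw p (default 0.05).
#' @return list of data.frames \code{band} and \code{chromosome}, each with
#'   unit, category_count, unit_size, p_raw and significant.
#' @export
bandEnrichment <- function(categoryGenes, genes, alpha = 0.05) {
  N <- nrow(genes)
  n <- sum(genes$gene_id %in% categoryGenes)
  one <- function(unitCol) {
    units <- split(genes$gene_id, genes[[unitCol]])
    do.call(rbind, lapply(names(units), function(u) {
      K <- length(units[[u]])
      kk <- sum(units[[u]] %in% categoryGenes)
      p <- stats::phyper(kk - 1, n, N - n, K, lower.tail = FALSE)
      data.frame(unit = u, category_count = kk, unit_size = K, p_raw = p,
                 significant = p <= alpha, stringsAsFactors = FALSE)
    }))
  }
  list(band = one("band"), chromosome = one("chrom"))
}
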