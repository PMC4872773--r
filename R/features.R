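#' @importFrom IRanges Views viewSums RleList
#' @importFrom GenomicRanges coverage
NULL

#' Structural statistics for gene groups
#'
#' Per-gene structure summaries (transcript count, and per-transcript exon
#' count and exonic / intronic / genomic lengths collapsed to the gene by
#' maximum span and sum of exons of the longest transcript), with group
#' medians and pairwise Wilcoxon rank-sum comparisons between groups.
#'
#' @param models a [GeneModels-class].
#' @param groups named character/factor: group label per gene_id (genes
#'   absent from \code{groups} are dropped).
#' @return list with \code{perGene} (data.frame), \code{medians} and
#'   \code{tests} (pairwise \code{wilcox.test} p-values on genomic and
#'   intronic length).
#' @export
structureStats <- function(models, groups) {
  ts <- transcriptStats(models)
  ts <- ts[ts$gene_id %in% names(groups), ]
  byGene <- split(ts, ts$gene_id)
  perGene <- do.call(rbind, lapply(byGene, function(d) {
    main <- d[which.max(d$genomic_length), ]
    data.frame(gene_id = main$gene_id,
               transcript_count = nrow(d),
               exon_count = main$exon_count,
               exonic_length = main$exonic_length,
               genomic_length = main$genomic_length,
               intronic_length = main$intronic_length,
               stringsAsFactors = FALSE)
  }))
  rownames(perGene) <- NULL
  perGene$group <- as.character(groups[perGene$gene_id])
  num <- c("exon_count", "exonic_length", "genomic_length", "intronic_length")
  medians <- aggregate(perGene[num], by = list(group = perGene$group), median)
  gl <- unique(perGene$group)
  tests <- list()
  if (length(gl) >= 2) {
    for (i in seq_len(length(gl) - 1)) for (j in seq(i + 1, length(gl))) {
      a <- perGene[perGene$group == gl[i], ]
      b <- perGene[perGene$group == gl[j], ]
      # normal approximation with tie correction: structural lengths are
      # heavily tied (e.g. zero introns), so the exact path is unavailable
      tests[[paste(gl[i], gl[j], sep = "_vs_")]] <- c(
        genomic_length = stats::wilcox.test(a$genomic_length,
                                            b$genomic_length,
                                            exact = FALSE)$p.value,
        intronic_length = stats::wilcox.test(a$intronic_length,
                                             b$intronic_length,
                                             exact = FALSE)$p.value)
    }
  }
  list(perGene = perGene, medians = medians, tests = tests)
}

#' Turn a scored interval track into per-nucleotide run-length form
#'
#' @param track \code{GRanges} with a numeric \code{score} mcol (e.g. read
#'   from bedGraph).  Positions not covered by any interval are "missing".
#' @return list of \code{RleList}: \code{score} (missing positions 0) and
#'   \code{covered} (1 where the track has a value).
#' @export
trackToRle <- function(track) {
  list(score = coverage(track, weight = "score"),
       covered = coverage(track))
}

#' Mean per-nucleotide score of regions under a track
#'
#' Arithmetic mean of the track's per-nucleotide values over each region.
#' Positions with no track value are excluded from the denominator; a region
#' entirely uncovered yields \code{NA}.
#'
#' @param regions \code{GRanges}.
#' @param track \code{GRanges} with \code{score} (bedGraph-style) or the
#'   result of [trackToRle()].
#' @return numeric vector of means, parallel to \code{regions}.
#' @export
meanConservation <- function(regions, track) {
  rl <- if (is(track, "GRanges")) trackToRle(track) else track
  out <- rep(NA_real_, length(regions))
  chroms <- as.character(seqnames(regions))
  for (ch in unique(chroms)) {
    ii <- which(chroms == ch)
    if (!ch %in% names(rl$score)) next
    sc <- rl$score[[ch]]
    cv <- rl$covered[[ch]]
    L <- length(sc)
    st <- pmax(start(regions)[ii], 1L)
    en <- pmin(end(regions)[ii], L)
    ok <- en >= st
    if (!any(ok)) next
    sums <- viewSums(Views(sc, st[ok], en[ok]))
    ns <- viewSums(Views(cv, st[ok], en[ok]))
    m <- ifelse(ns > 0, sums / ns, NA_real_)
    out[ii[ok]] <- m
  }
  out
}

#' Derive TF -> gene regulatory edges from binding sites near TSSs
#'
#' A TF site is assigned to a feature when it overlaps the window from
#' \code{upstream} nt before to \code{downstream} nt after the feature's TSS.
#'
#' @param features \code{GRanges} with \code{gene_id} (strand-aware TSS).
#' @param sites \code{GRanges} of TF binding sites with a \code{tf} mcol.
#' @param upstream,downstream TSS window (defaults 5 kb / 1 kb).
#' @return data.frame of edges (regulator_id, target_id, regulator_type).
#' @export
tfEdgesFromSites <- function(features, sites, upstream = 5000, downstream = 1000) {
  win <- promoterRegions(features, upstream = upstream, downstream = downstream)
  hits <- findOverlaps(win, sites, ignore.strand = TRUE)
  ed <- data.frame(regulator_id = sites$tf[subjectHits(hits)],
                   target_id = features$gene_id[queryHits(hits)],
                   regulator_type = "TF", stringsAsFactors = FALSE)
  unique(ed)
}

#' Count distinct TF and miRNA regulators per feature
#'
#' @param featureIds features to report (absent features count 0 / 0).
#' @param edges data.frame with regulator_id, target_id and regulator_type
#'   in \{"TF", "miRNA"\}; duplicate edges are collapsed.
#' @return data.frame (feature_id, tf_count, mirna_count).
#' @export
countRegulators <- function(featureIds, edges) {
  edges <- unique(edges[c("regulator_id", "target_id", "regulator_type")])
  cnt <- function(type) {
    e <- edges[edges$regulator_type == type, ]
    tab <- table(e$target_id)
    v <- as.integer(tab[featureIds])
    v[is.na(v)] <- 0L
    v
  }
  data.frame(feature_id = featureIds, tf_count = cnt("TF"),
             mirna_count = cnt("miRNA"), stringsAsFactors = FALSE)
}

#' Classify promoter CpG content and CpG-island overlap
#'
#' CGI overlap is positive when the promoter intersects at least one CpG
#' island interval by any amount.  The CpG class follows the standard
#' high/intermediate/low promoter scheme on 500-nt sliding windows: high when
#' some window has GC fraction >= \code{gcHigh} and CpG observed/expected
#' ratio >= \code{oeHigh}; low when no window reaches \code{oeLow}; else
#' intermediate.
#'
#' @param promoters \code{GRanges} of promoter windows with \code{gene_id}.
#' @param cgi \code{GRanges} of CpG islands (may be NULL to skip overlap).
#' @param sequences named \code{DNAStringSet} (or character) of promoter
#'   sequences; names must match \code{gene_id}.  NULL skips the CpG class.
#' @param window,gcHigh,oeHigh,oeLow scheme parameters.
#' @return data.frame (gene_id, cgi_overlap, cpg_class).
#' @export
categorizePromoterCpg <- function(promoters, cgi = NULL, sequences = NULL,
                                  window = 500, gcHigh = 0.55, oeHigh = 0.6,
                                  oeLow = 0.4) {
  out <- data.frame(gene_id = promoters$gene_id,
                    cgi_overlap = NA, cpg_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(cgi)) {
    out$cgi_overlap <- IRanges::overlapsAny(promoters, cgi, ignore.strand = TRUE)
  }
  if (!is.null(sequences)) {
    seqs <- stats::setNames(as.character(sequences), names(sequences))
    idx <- match(out$gene_id, names(seqs))
    out$cpg_class[!is.na(idx)] <- vapply(seqs[idx[!is.na(idx)]], cpgClass, "",
                                         window = window, gcHigh = gcHigh,
                                         oeHigh = oeHigh, oeLow = oeLow,
                                         USE.NAMES = FALSE)
  }
  out
}

#' CpG class of a single sequence
#' @rdname categorizePromoterCpg
#' @param sequence character or DNAString.
#' @export
cpgClass <- function(sequence, window = 500, gcHigh = 0.55, oeHigh = 0.6,
                     oeLow = 0.4) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains non-ACGTN symbols")
  n <- length(s)
  if (n < window) window <- n
  isC <- as.integer(s == "C")
  isG <- as.integer(s == "G")
  isCpG <- c(as.integer(s[-n] == "C" & s[-1] == "G"), 0L)
  csum <- function(v) {
    cs <- cumsum(v)
    cs[window:n] - c(0, cs)[seq_len(n - window + 1)]
  }
  nC <- csum(isC)
  nG <- csum(isG)
  # a CpG straddling the window end is not counted inside it
  nCpG <- {
    cs <- cumsum(isCpG)
    last <- seq(window, n)
    cs[last - 1L] - c(0, cs)[seq_len(n - window + 1)]
  }
  gc <- (nC + nG) / window
  oe <- ifelse(nC * nG > 0, nCpG * window / (nC * nG), 0)
  if (any(gc >= gcHigh & oe >= oeHigh)) "high"
  else if (all(oe < oeLow)) "low"
  else "intermediate"
}
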