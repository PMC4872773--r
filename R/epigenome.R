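#' Bin per-nucleotide coverage over promoter windows
#'
#' Splits each promoter into \code{nbins} equal bins and reports the mean
#' per-nucleotide coverage in each.  Bins are ordered 5' to 3' along the
#' gene, i.e. the bin order is mirrored for minus-strand features so that
#' "upstream" bins line up across strands.  Promoters clipped at a
#' chromosome end are flagged and their out-of-range positions excluded.
#'
#' @param promoters \code{GRanges} of equal-width promoter windows carrying
#'   \code{gene_id} (width must be divisible by \code{nbins}).
#' @param track coverage as a bedGraph-style \code{GRanges} with
#'   \code{score}, or the result of [trackToRle()].
#' @param nbins number of bins (default 40, i.e. 100-nt bins on 4-kb
#'   promoters).
#' @param mark,cellLine labels stored on the result.
#' @return A [PromoterProfileSet-class].
#' @export
binPromoterSignal <- function(promoters, track, nbins = 40,
                              mark = "signal", cellLine = "NA") {
  expectedWidth <- unique(width(promoters))
  if (length(expectedWidth) != 1L)
    stop("promoters must share one width")
  if (expectedWidth %% nbins != 0L)
    stop("promoter width not divisible by nbins")
  bw <- expectedWidth / nbins
  rl <- if (is(track, "GRanges")) trackToRle(track) else track
  n <- length(promoters)
  prof <- matrix(NA_real_, n, nbins)
  clipped <- logical(n)
  chroms <- as.character(seqnames(promoters))
  neg <- as.character(strand(promoters)) == "-"
  for (i in seq_len(n)) {
    ch <- chroms[i]
    sc <- if (ch %in% names(rl$score)) rl$score[[ch]] else S4Vectors::Rle(0, 0)
    st <- start(promoters)[i]; en <- end(promoters)[i]
    v <- numeric(expectedWidth)
    lo <- max(st, 1L); hi <- min(en, length(sc))
    if (hi >= lo)
      v[(lo - st + 1L):(hi - st + 1L)] <- as.numeric(S4Vectors::window(sc, lo, hi))
    # positions past the track's last run are plain zero coverage, not clipping
    clipped[i] <- width(promoters)[i] < expectedWidth || st < 1L
    if (neg[i]) v <- rev(v)
    prof[i, ] <- colMeans(matrix(v, nrow = bw))
  }
  rownames(prof) <- promoters$gene_id
  new("PromoterProfileSet", profiles = prof, mark = mark, cellLine = cellLine,
      binWidth = bw, clipped = clipped)
}

#' Average promoter profiles over a gene category
#'
#' @param x a [PromoterProfileSet-class] or plain matrix (features x bins).
#' @param groups optional named vector mapping feature id -> group; when
#'   NULL a single overall mean profile is returned.
#' @return numeric matrix, one row per group (or a single row "all").
#' @export
aggregateProfiles <- function(x, groups = NULL) {
  m <- if (is(x, "PromoterProfileSet")) profileMatrix(x) else as.matrix(x)
  if (is.null(groups)) {
    out <- matrix(colMeans(m), 1L, ncol(m), dimnames = list("all", colnames(m)))
    return(out)
  }
  groups <- groups[rownames(m)]
  gl <- sort(unique(as.character(groups[!is.na(groups)])))
  out <- t(vapply(gl, function(g) colMeans(m[which(groups == g), , drop = FALSE]),
                  numeric(ncol(m))))
  rownames(out) <- gl
  out
}

#' Label enhancers as ubiquitous or tissue-specific
#'
#' Under the default rule an enhancer detected in more than two cell lines is
#' ubiquitous (UE) and otherwise tissue-specific (TS); the alternative
#' \code{"atLeastTwo"} rule draws the line at two or more cell lines.
#'
#' @param enhancers \code{GRanges} with a \code{cell_lines} mcol, either a
#'   \code{CharacterList} or comma-separated character.
#' @param rule "moreThanTwo" (default) or "atLeastTwo".
#' @return the input with an added \code{ubiquity_label} mcol ("UE"/"TS").
#' @export
classifyEnhancers <- function(enhancers, rule = c("moreThanTwo", "atLeastTwo")) {
  rule <- match.arg(rule)
  cl <- enhancers$cell_lines
  n <- if (is.character(cl)) lengths(strsplit(cl, ",", fixed = TRUE))
       else lengths(cl)
  if (any(n == 0L)) stop("enhancer with empty cell-line set")
  cut <- if (rule == "moreThanTwo") 2L else 1L
  enhancers$ubiquity_label <- ifelse(n > cut, "UE", "TS")
  enhancers
}

#' Fraction of features with a target within a distance window
#'
#' A feature counts when at least one target interval lies within
#' \code{window} nt of its locus (gap distance; overlap counts at any
#' window).  Used for enhancer proximity (10 kb), essential-gene proximity
#' (50 kb), and the enhancer-class-restricted variants.
#'
#' @param features non-empty \code{GRanges}.
#' @param targets \code{GRanges}.
#' @param window maximum gap in nt (>= 0).
#' @return list with \code{fraction} and \code{hits}, a logical vector named
#'   by \code{features$gene_id} (or index).
#' @export
proximityFraction <- function(features, targets, window) {
  if (length(features) == 0L) stop("empty feature set")
  stopifnot(window >= 0)
  hits <- rep(FALSE, length(features))
  if (length(targets)) {
    nd <- GenomicRanges::distanceToNearest(features, targets,
                                           ignore.strand = TRUE)
    hits[queryHits(nd)] <- mcols(nd)$distance <= window
  }
  names(hits) <- if (!is.null(features$gene_id)) features$gene_id
                 else seq_along(features)
  list(fraction = mean(hits), hits = hits)
}

#' Read an extended enhancer BED file
#'
#' Columns: chrom, start (0-based), end, name, cell_lines (comma-separated),
#' and optionally state ("strong"/"weak").
#'
#' @param path file path.
#' @return \code{GRanges} with \code{cell_lines} (and \code{state}) mcols.
#' @export
readEnhancerBed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:5] <- c("chrom", "start", "end", "name", "cell_lines")
  gr <- GRanges(d$chrom, IRanges(d$start + 1L, d$end))
  gr$name <- d$name
  gr$cell_lines <- d$cell_lines
  if (ncol(d) >= 6) gr$state <- d[[6]]
  gr
}
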