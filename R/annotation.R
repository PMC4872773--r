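#' @importFrom GenomicRanges findOverlaps promoters distance reduce
#' @importFrom IRanges IRanges ranges
#' @importFrom S4Vectors queryHits subjectHits split
NULL

.GTF_BIOTYPE_KEYS <- c("gene_biotype", "gene_type", "biotype")

#' Read gene models from a GTF file
#'
#' Parses exon records, groups them into transcripts and genes, and computes
#' exonic / intronic / genomic lengths.  Gene loci are the union span of their
#' transcripts.  GTF coordinates are 1-based closed and are kept in the native
#' \code{GRanges} representation.
#'
#' @param path GTF file.
#' @param biotypeFilter optional character vector; keep only these biotypes.
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path, biotypeFilter = NULL) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(body) == 0L) {
    return(new("GeneModels", genes = GRanges(), exons = GRangesList()))
  }
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(!startsWith(ln, "#") & nzchar(ln))[which(nf != 9L)[1L]]
    stop("malformed GTF record at line ", bad, " of ", path,
         " (expected 9 tab-separated fields, got ", nf[nf != 9L][1L], ")")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- mcols(gr)
  bk <- .GTF_BIOTYPE_KEYS[.GTF_BIOTYPE_KEYS %in% names(mc)][1]
  if (is.na(bk)) stop("GTF carries no gene biotype attribute")
  src <- if ("gene_source" %in% names(mc)) mc$gene_source else
    as.character(mc$source %||% "unknown")
  ex <- gr[mc$type == "exon"]
  if (length(ex) == 0L) {
    warning("GTF contains no exon records")
    return(new("GeneModels", genes = GRanges(), exons = GRangesList()))
  }
  if (anyNA(ex$gene_id) || anyNA(ex$transcript_id))
    stop("exon record missing gene_id/transcript_id attribute in ", path)
  # transcripts announced but lacking exon rows are rejected with a warning
  txAll <- unique(mcols(gr)$transcript_id[mcols(gr)$type %in%
                                            c("transcript", "exon")])
  txAll <- txAll[!is.na(txAll)]
  noExon <- setdiff(txAll, unique(ex$transcript_id))
  if (length(noExon))
    warning("rejected ", length(noExon), " transcript(s) without exons: ",
            paste(utils::head(noExon, 5), collapse = ", "))
  o <- order(ex$transcript_id, start(ex))
  ex <- ex[o]
  txIds <- as.character(ex$transcript_id)
  geneIds <- as.character(ex$gene_id)
  bare <- ex
  mcols(bare) <- NULL
  exl <- S4Vectors::split(bare, factor(txIds, levels = unique(txIds)))
  mcols(exl)$gene_id <- geneIds[!duplicated(txIds)][
    match(names(exl), unique(txIds))]

  exBio <- as.character(mcols(gr)[[bk]][mcols(gr)$type == "exon"])[o]
  exSrc <- src[mcols(gr)$type == "exon"][o]
  first <- !duplicated(ex$gene_id)
  geneInfo <- data.frame(gene_id = as.character(ex$gene_id)[first],
                         biotype = exBio[first], source = exSrc[first],
                         stringsAsFactors = FALSE)
  span <- unlist(range(S4Vectors::split(ex, factor(ex$gene_id,
                                                   levels = geneInfo$gene_id))))
  genes <- GRanges(seqnames(span), ranges(span), strand = strand(span))
  mcols(genes) <- DataFrame(geneInfo)
  if (!is.null(biotypeFilter)) {
    keep <- genes$biotype %in% biotypeFilter
    genes <- genes[keep]
    exl <- exl[mcols(exl)$gene_id %in% genes$gene_id]
  }
  new("GeneModels", genes = genes, exons = exl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-transcript structural statistics
#'
#' @param x a [GeneModels-class]
#' @return data.frame with transcript_id, gene_id, exon_count, exonic_length,
#'   genomic_length and intronic_length (= genomic - exonic, >= 0).
#' @export
transcriptStats <- function(x) {
  ex <- exonsByTranscript(x)
  exonic <- vapply(width(ex), sum, 0L)
  sp <- unlist(range(ex))
  genomic <- width(sp)
  data.frame(transcript_id = names(ex),
             gene_id = mcols(ex)$gene_id,
             exon_count = lengths(ex),
             exonic_length = as.integer(exonic),
             genomic_length = as.integer(genomic),
             intronic_length = as.integer(genomic - exonic),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise overlap fraction of two interval sets
#'
#' Fraction of overlap between parallel ranges \code{a[i]} and \code{b[i]}.
#' With \code{denominator = "min"} (default) the overlap length is divided by
#' the shorter range's length, so a range nested in another scores 1;
#' \code{"jaccard"} divides by the union length.  Ranges on different
#' chromosomes score 0.  Strand is ignored.
#'
#' @param a,b parallel \code{GRanges} (recycled if one has length 1).
#' @param denominator "min" or "jaccard".
#' @return numeric vector in [0, 1].
#' @export
overlapFraction <- function(a, b, denominator = c("min", "jaccard")) {
  denominator <- match.arg(denominator)
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  den <- if (denominator == "min") pmin(width(a), width(b))
         else width(a) + width(b) - ov
  as.numeric(ov) / as.numeric(den)
}

#' Collapse cross-source redundant loci by source priority
#'
#' Sweeps loci in priority order and removes any locus whose overlap fraction
#' with a locus from a strictly higher-priority source exceeds
#' \code{minOverlap}.  Redundancy within one source is deliberately not
#' collapsed.  The sweep is idempotent and its output contains no
#' cross-source pair above the cutoff.
#'
#' @param x a \code{GRanges} with \code{gene_id} and \code{source} mcols, or a
#'   [GeneModels-class] (filtered in place).
#' @param priority character vector of sources, highest first.
#' @param minOverlap redundancy cutoff on [overlapFraction()].
#' @param denominator passed to [overlapFraction()].
#' @return list with \code{genes} (or \code{models}) retained and \code{log},
#'   a data.frame (removed_id, kept_id, overlap_fraction).
#' @export
buildNonredundantSet <- function(x, priority = c("GENCODE", "Ensembl", "Cabili"),
                                 minOverlap = 0.8,
                                 denominator = c("min", "jaccard")) {
  denominator <- match.arg(denominator)
  isGM <- is(x, "GeneModels")
  genes <- if (isGM) geneRanges(x) else x
  if (!all(genes$source %in% priority))
    stop("sources outside the priority list: ",
         paste(setdiff(unique(genes$source), priority), collapse = ", "))
  rank <- match(genes$source, priority)
  drop <- logical(length(genes))
  log <- list()
  for (r in seq_along(priority)[-1L]) {
    lower <- which(rank == r)
    higher <- which(rank < r)
    if (!length(lower) || !length(higher)) next
    hits <- findOverlaps(genes[lower], genes[higher], ignore.strand = TRUE)
    if (!length(hits)) next
    fr <- overlapFraction(genes[lower][queryHits(hits)],
                          genes[higher][subjectHits(hits)], denominator)
    red <- fr > minOverlap
    if (!any(red)) next
    qi <- queryHits(hits)[red]; si <- subjectHits(hits)[red]; fv <- fr[red]
    best <- vapply(split(seq_along(qi), qi),
                   function(ii) ii[which.max(fv[ii])], 0L)
    drop[lower[as.integer(names(best))]] <- TRUE
    log[[length(log) + 1L]] <- data.frame(
      removed_id = genes$gene_id[lower[as.integer(names(best))]],
      kept_id = genes$gene_id[higher[si[best]]],
      overlap_fraction = fv[best], stringsAsFactors = FALSE)
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(removed_id = character(), kept_id = character(),
               overlap_fraction = numeric())
  rownames(log) <- NULL
  kept <- genes[!drop]
  if (isGM) {
    ex <- exonsByTranscript(x)[mcols(exonsByTranscript(x))$gene_id %in%
                                 kept$gene_id]
    list(models = new("GeneModels", genes = kept, exons = ex), log = log)
  } else list(genes = kept, log = log)
}

#' Promoter windows around transcription start sites
#'
#' The promoter of a feature is the window from \code{upstream} nt before to
#' \code{downstream} nt after its strand-aware 5' end (defaults give the
#' symmetric 4 kb window).  For a multi-transcript gene locus the 5' end of
#' the union span is the 5'-most TSS.  Windows are clipped at the chromosome
#' start.
#'
#' @param x \code{GRanges}; unstranded ranges are treated as plus-strand.
#' @param upstream,downstream window extents in nt.
#' @return \code{GRanges} of promoter windows (mcols preserved).
#' @export
promoterRegions <- function(x, upstream = 2000, downstream = 2000) {
  p <- suppressWarnings(promoters(x, upstream = upstream,
                                  downstream = downstream))
  start(p) <- pmax(start(p), 1L)
  p
}

#' Genomic distance between parallel interval sets
#'
#' Gap length between \code{a[i]} and \code{b[i]}: 0 when they overlap or are
#' adjacent, \code{Inf} across chromosomes.  Strand is ignored.
#'
#' @param a,b parallel \code{GRanges}.
#' @return numeric vector (non-negative, possibly \code{Inf}).
#' @export
intervalDistance <- function(a, b) {
  d <- suppressWarnings(distance(a, b, ignore.strand = TRUE))
  d <- as.numeric(d)
  d[is.na(d)] <- Inf
  d
}

#' Write retained loci to BED
#'
#' 1-based closed internal coordinates are converted to BED's 0-based
#' half-open convention by \code{rtracklayer}.
#'
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param path output BED file.
#' @return invisibly, \code{path}.
#' @export
writeLociBed <- function(genes, path) {
  out <- genes
  names(out) <- out$gene_id
  mcols(out) <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read loci back from BED
#' @param path BED file.
#' @return \code{GRanges} with \code{gene_id} restored from the name column.
#' @export
readLociBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$gene_id <- gr$name
  gr$name <- NULL
  gr$score <- NULL
  gr
}
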