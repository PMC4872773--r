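#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
NULL

#' Gene models parsed from a GTF annotation
#'
#' Container pairing gene-level loci with the exon structure of their
#' transcripts.  The \code{genes} slot is a \code{GRanges} with one range per
#' gene (the union span of its transcripts) and metadata columns
#' \code{gene_id}, \code{biotype}, \code{source} and optionally \code{band};
#' the \code{exons} slot is a \code{GRangesList} named by transcript id whose
#' inner ranges are the (sorted, disjoint) exons, with a \code{gene_id}
#' metadata column on the list.
#'
#' @slot genes GRanges of gene loci.
#' @slot exons GRangesList of exons per transcript.
#' @export
setClass("GeneModels", representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  ex <- object@exons
  msg <- character()
  need <- c("gene_id", "biotype", "source")
  if (length(g) && !all(need %in% names(mcols(g))))
    msg <- c(msg, paste("genes must carry mcols:", paste(need, collapse = ", ")))
  else if (length(g) && anyDuplicated(g$gene_id))
    msg <- c(msg, "duplicated gene_id")
  if (length(ex)) {
    if (is.null(names(ex)) || anyDuplicated(names(ex)))
      msg <- c(msg, "exons must be uniquely named by transcript_id")
    if (is.null(mcols(ex)$gene_id))
      msg <- c(msg, "exons must carry a gene_id mcol")
    else if (length(msg) == 0L && !all(mcols(ex)$gene_id %in% g$gene_id))
      msg <- c(msg, "transcript gene_id absent from gene table")
    if (any(vapply(ex, length, 0L) == 0L))
      msg <- c(msg, "transcript without exons")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModels number of genes
#' @param x,object a \code{GeneModels}
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

setMethod("show", "GeneModels", function(object) {
  tab <- table(object@genes$biotype)
  cat("GeneModels with", length(object@genes), "genes /",
      length(object@exons), "transcripts\n")
  cat("  biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @describeIn GeneModels gene-level loci as a GRanges
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname GeneModels
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @describeIn GeneModels exons per transcript as a GRangesList
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))
#' @rdname GeneModels
#' @export
setMethod("exonsByTranscript", "GeneModels", function(x) x@exons)

#' Tissue-level FPKM expression container
#'
#' A thin \code{SummarizedExperiment} with a single \code{"fpkm"} assay
#' (features in rows, tissues in columns), a \code{biotype} row annotation and
#' a \code{level} flag ("transcript" or "gene") in \code{metadata()}.
#'
#' @export
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
  msg <- character()
  if (!"fpkm" %in% assayNames(object)) msg <- c(msg, "assay 'fpkm' required")
  else {
    v <- assay(object, "fpkm")
    if (anyNA(v) || any(v < 0)) msg <- c(msg, "FPKM values must be >= 0 and non-missing")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique feature ids (rownames) required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique tissue ids (colnames) required")
  if (!"biotype" %in% names(rowData(object)))
    msg <- c(msg, "rowData must carry 'biotype'")
  lv <- metadata(object)$level
  if (is.null(lv) || !lv %in% c("transcript", "gene"))
    msg <- c(msg, "metadata()$level must be 'transcript' or 'gene'")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueExpression object
#'
#' @param fpkm numeric matrix, features x tissues, with dimnames.
#' @param biotype character vector per feature ("lncRNA"/"protein_coding").
#' @param level "transcript" or "gene".
#' @param gene_id optional gene id per feature (transcript level).
#' @return A \code{TissueExpression}.
#' @export
TissueExpression <- function(fpkm, biotype, level = c("transcript", "gene"),
                             gene_id = NULL) {
  level <- match.arg(level)
  fpkm <- as.matrix(fpkm)
  rd <- DataFrame(biotype = rep(biotype, length.out = nrow(fpkm)))
  if (!is.null(gene_id)) rd$gene_id <- gene_id
  se <- SummarizedExperiment(assays = list(fpkm = fpkm), rowData = rd)
  metadata(se)$level <- level
  new("TissueExpression", se)
}

#' @describeIn TissueExpression the FPKM assay matrix
#' @param object a \code{TissueExpression}
#' @export
setGeneric("fpkm", function(object) standardGeneric("fpkm"))
#' @rdname TissueExpression
#' @export
setMethod("fpkm", "TissueExpression", function(object) assay(object, "fpkm"))

setMethod("show", "TissueExpression", function(object) {
  cat("TissueExpression:", nrow(object), metadata(object)$level, "features x",
      ncol(object), "tissues\n")
  cat("  biotypes:", paste(names(table(rowData(object)$biotype)), collapse = ", "), "\n")
})

#' Background-calibrated FPKM detection threshold
#'
#' Result of balancing false positives (background values called expressed)
#' against false negatives (transcribed values called silent) over the grid of
#' candidate cutoffs.
#'
#' @slot biotype character, which gene class the threshold applies to.
#' @slot threshold numeric FPKM cutoff (> 0).
#' @slot fpCount,fnCount counts at the chosen cutoff.
#' @slot nCandidates size of the candidate grid searched.
#' @export
setClass("DetectionThreshold",
         representation(biotype = "character", threshold = "numeric",
                        fpCount = "integer", fnCount = "integer",
                        nCandidates = "integer"))

setValidity("DetectionThreshold", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive value")
  if (object@fpCount < 0L || object@fnCount < 0L)
    msg <- c(msg, "FP/FN counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DetectionThreshold", function(object) {
  cat(sprintf("DetectionThreshold [%s]: FPKM >= %.4g (FP=%d, FN=%d over %d candidates)\n",
              object@biotype, object@threshold, object@fpCount, object@fnCount,
              object@nCandidates))
})

#' @describeIn DetectionThreshold numeric cutoff value
#' @param object a \code{DetectionThreshold}
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))
#' @rdname DetectionThreshold
#' @export
setMethod("thresholdValue", "DetectionThreshold", function(object) object@threshold)

#' Binned promoter signal profiles
#'
#' Per-feature promoter metaprofile: mean per-nucleotide coverage in
#' equal-width bins ordered 5' to 3' along the gene.  Rows are features,
#' columns bins.
#'
#' @slot profiles numeric matrix (features x bins), rownames = feature ids.
#' @slot mark assay name (e.g. "H3K4me3").
#' @slot cellLine cell line / tissue the signal comes from.
#' @slot binWidth bin width in nucleotides.
#' @slot clipped logical per feature; TRUE where the promoter ran off the
#'   chromosome start and missing positions were excluded.
#' @export
setClass("PromoterProfileSet",
         representation(profiles = "matrix", mark = "character",
                        cellLine = "character", binWidth = "numeric",
                        clipped = "logical"))

setValidity("PromoterProfileSet", function(object) {
  msg <- character()
  p <- object@profiles
  if (is.null(rownames(p))) msg <- c(msg, "profiles need rownames (feature ids)")
  if (any(p[!is.na(p)] < 0)) msg <- c(msg, "profile values must be >= 0")
  if (length(object@clipped) != nrow(p))
    msg <- c(msg, "clipped flag must be parallel to rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PromoterProfileSet", function(object) {
  cat(sprintf("PromoterProfileSet: %d promoters x %d bins (%g nt), mark=%s, cell=%s\n",
              nrow(object@profiles), ncol(object@profiles), object@binWidth,
              object@mark, object@cellLine))
})

#' @describeIn PromoterProfileSet the features x bins matrix
#' @param object a \code{PromoterProfileSet}
#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))
#' @rdname PromoterProfileSet
#' @export
setMethod("profileMatrix", "PromoterProfileSet", function(object) object@profiles)
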