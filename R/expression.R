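#' Collapse a samples matrix to tissue level by maximum
#'
#' For tissues assayed in several samples the tissue value of a feature is the
#' highest FPKM observed among that tissue's samples.
#'
#' @param sampleMat numeric matrix, features x samples (colnames = sample ids).
#' @param sampleToTissue named character vector mapping sample id -> tissue.
#' @return numeric matrix, features x tissues.
#' @export
aggregateToTissues <- function(sampleMat, sampleToTissue) {
  sampleMat <- as.matrix(sampleMat)
  missing <- setdiff(colnames(sampleMat), names(sampleToTissue))
  if (length(missing))
    stop("samples missing from the tissue map: ",
         paste(missing, collapse = ", "))
  tissue <- sampleToTissue[colnames(sampleMat)]
  tl <- unique(tissue)
  out <- vapply(tl, function(t) {
    cols <- which(tissue == t)
    if (length(cols) == 1L) sampleMat[, cols]
    else do.call(pmax, lapply(cols, function(j) sampleMat[, j]))
  }, numeric(nrow(sampleMat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(sampleMat), tl))
  out
}

#' Estimate an FPKM detection threshold against untranscribed background
#'
#' Scans every distinct positive value pooled from the transcribed and
#' background sets as a candidate cutoff t and counts false positives
#' (background values >= t) and false negatives (transcribed values < t).
#' The reported threshold is the smallest candidate minimizing FP + FN, i.e.
#' the cutoff balancing the two error kinds with a bias toward sensitivity on
#' ties.
#'
#' @param transcribed FPKM values from annotated, transcribed features.
#' @param untranscribed background FPKM values from regions with no annotated
#'   transcription.
#' @param biotype label carried into the result.
#' @return A [DetectionThreshold-class].
#' @export
estimateDetectionThreshold <- function(transcribed, untranscribed,
                                       biotype = "lncRNA") {
  if (!length(transcribed) || !length(untranscribed))
    stop("both transcribed and untranscribed value sets must be non-empty")
  cand <- sort(unique(c(transcribed, untranscribed)))
  cand <- cand[cand > 0]
  if (all(untranscribed <= 0)) {
    warning("all-zero background; falling back to the smallest positive transcribed value")
    t0 <- min(transcribed[transcribed > 0])
    return(new("DetectionThreshold", biotype = biotype, threshold = t0,
               fpCount = 0L, fnCount = sum(transcribed < t0),
               nCandidates = length(cand)))
  }
  su <- sort(untranscribed)
  st <- sort(transcribed)
  # FP(t) = #{bg >= t}; FN(t) = #{transcribed < t}, via sorted-rank lookups
  fp <- length(su) - findInterval(cand, su, left.open = TRUE)
  fn <- findInterval(cand, st, left.open = TRUE)
  i <- which.min(fp + fn)            # which.min takes the first (smallest) tie
  new("DetectionThreshold", biotype = biotype, threshold = cand[i],
      fpCount = as.integer(fp[i]), fnCount = as.integer(fn[i]),
      nCandidates = length(cand))
}

#' Expression width: number of tissues a feature is detected in
#'
#' A feature is detected in a tissue when its FPKM is at or above the
#' biotype's detection threshold (inclusive, so the threshold itself counts).
#'
#' @param x numeric vector (one feature) or matrix (features x tissues).
#' @param threshold detection cutoff (scalar, or one value per feature for a
#'   matrix).
#' @return integer count(s) of tissues.
#' @export
expressionWidth <- function(x, threshold) {
  if (is(threshold, "DetectionThreshold")) threshold <- thresholdValue(threshold)
  if (is.matrix(x)) {
    as.integer(rowSums(x >= threshold))
  } else {
    sum(x >= threshold)
  }
}
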