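#' Coefficient of variation across tissues
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.  A zero
#' mean makes the ratio undefined and is reported as \code{Inf}.
#'
#' @param x numeric vector of FPKM values.
#' @return non-negative number, or \code{Inf} when the mean is 0.
#' @export
coefficientOfVariation <- function(x) {
  m <- mean(x)
  if (m == 0) return(Inf)
  stats::sd(x) / m
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon tissue-specificity score
#'
#' The expression profile is normalized to a probability vector p and
#' compared, tissue by tissue, against the ideal single-tissue point
#' distribution e_t via the Jensen-Shannon divergence (base-2 entropy,
#' 0 log 0 = 0): JSD(p, e_t) = H((p + e_t)/2) - (H(p) + H(e_t))/2.  The
#' per-tissue score is 1 - sqrt(JSD); the score of the profile is the maximum
#' over tissues, attained at the tissue the profile is most specific to.  The
#' score is scale-invariant and equals 1 exactly for a point-mass profile.
#'
#' @param profile non-negative expression vector over tissues (at least one
#'   positive entry); names, if present, label the tissues.
#' @param log2p1 apply log2(x + 1) to the profile before normalizing.
#' @return list with \code{score} in [0, 1] and \code{tissue} (name or index
#'   of the argmax tissue).
#' @export
jsSpecificity <- function(profile, log2p1 = FALSE) {
  if (any(profile < 0) || anyNA(profile)) stop("profile must be non-negative")
  if (log2p1) profile <- log2(profile + 1)
  s <- sum(profile)
  if (s == 0) stop("all-zero profile has no specificity score")
  p <- profile / s
  hp <- .entropy2(p)
  # H((p+e_t)/2) differs from the constant part only in the t-th coordinate
  half <- p / 2
  hh <- ifelse(half > 0, -half * log2(half), 0)
  constH <- sum(hh)
  qt <- (p + 1) / 2
  ht <- constH - hh + (-qt * log2(qt))
  jsd <- ht - hp / 2
  jsd[jsd < 0] <- 0                      # guard tiny negative rounding
  sc <- 1 - sqrt(jsd)
  i <- which.max(sc)
  tissue <- if (!is.null(names(profile))) names(profile)[i] else i
  list(score = sc[[i]], tissue = tissue)
}

#' Classify transcripts as ubiquitously expressed, tissue-specific or other
#'
#' A transcript is UE when it is detected (FPKM at or above its biotype's
#' threshold) in every tissue and its coefficient of variation across tissues
#' is below \code{cvMax}; it is TS when it is detected in exactly one tissue
#' and its Jensen-Shannon specificity score exceeds \code{tsMin}; otherwise
#' it is "other".
#'
#' @param x a [TissueExpression-class] or an FPKM matrix (features x tissues).
#' @param thresholds named numeric, detection threshold per biotype (or a
#'   single number when \code{x} is a plain matrix); values may also be
#'   [DetectionThreshold-class] objects.
#' @param cvMax strict upper bound on the CV for the UE call (default 1).
#' @param tsMin strict lower bound on the specificity score for the TS call
#'   (default 0.4).
#' @param log2p1 passed to [jsSpecificity()].
#' @return \code{DataFrame} with feature_id, level, label, cv, specificity,
#'   width and ts_tissue.
#' @export
classifyTranscripts <- function(x, thresholds, cvMax = 1, tsMin = 0.4,
                                log2p1 = FALSE) {
  if (is(x, "TissueExpression")) {
    m <- fpkm(x)
    bio <- rowData(x)$biotype
    level <- metadata(x)$level
  } else {
    m <- as.matrix(x)
    bio <- rep(names(thresholds)[1] %||% "feature", nrow(m))
    level <- "transcript"
  }
  thresholds <- vapply(thresholds, function(t)
    if (is(t, "DetectionThreshold")) thresholdValue(t) else as.numeric(t), 0)
  thr <- if (!is.null(names(thresholds)) && all(bio %in% names(thresholds)))
    thresholds[bio] else rep(thresholds[1], nrow(m))
  nT <- ncol(m)
  width <- as.integer(rowSums(m >= thr))
  cv <- apply(m, 1L, coefficientOfVariation)
  label <- rep("other", nrow(m))
  spec <- rep(NA_real_, nrow(m))
  tsTissue <- rep(NA_character_, nrow(m))
  pos <- rowSums(m) > 0
  for (i in which(pos)) {
    js <- jsSpecificity(m[i, ], log2p1 = log2p1)
    spec[i] <- js$score
    if (width[i] == 1L && js$score > tsMin) {
      label[i] <- "TS"
      tsTissue[i] <- colnames(m)[which(m[i, ] >= thr[i])]
    }
  }
  label[width == nT & cv < cvMax] <- "UE"
  DataFrame(feature_id = rownames(m), level = level, label = label,
            cv = unname(cv), specificity = spec, width = width,
            ts_tissue = tsTissue)
}

#' Lift transcript classifications to gene level
#'
#' A gene is UE (TS) when at least one of its transcripts is UE (TS).  A gene
#' with both a UE and a TS transcript is contradictory under that rule; it is
#' flagged and labeled UE, since ubiquitous transcription of any isoform is
#' incompatible with whole-gene tissue restriction.  The reported cv /
#' specificity / width are those of the transcript that determined the label
#' (highest-width UE transcript, or the TS transcript).
#'
#' @param txResults \code{DataFrame} from [classifyTranscripts()].
#' @param geneIds character vector parallel to \code{txResults} rows giving
#'   each transcript's gene.
#' @return \code{DataFrame} with feature_id (gene), level = "gene", label,
#'   cv, specificity, width, ts_tissue and conflict flag.
#' @export
classifyGenes <- function(txResults, geneIds) {
  stopifnot(length(geneIds) == nrow(txResults))
  geneIds <- as.character(geneIds)
  lab <- txResults$label
  # pick the deciding transcript per gene: UE beats TS beats widest other
  pr <- (lab == "UE") * 2L + (lab == "TS")
  o <- order(geneIds, -pr, -txResults$width)
  first <- o[!duplicated(geneIds[o])]
  g <- geneIds[first]
  hasUE <- g %in% geneIds[lab == "UE"]
  hasTS <- g %in% geneIds[lab == "TS"]
  DataFrame(feature_id = g, level = "gene",
            label = ifelse(hasUE, "UE", ifelse(hasTS, "TS", "other")),
            cv = txResults$cv[first],
            specificity = txResults$specificity[first],
            width = txResults$width[first],
            ts_tissue = ifelse(!hasUE & hasTS, txResults$ts_tissue[first],
                               NA_character_),
            conflict = hasUE & hasTS)
}
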