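## Diversity metrics: richness, Shannon entropy, evenness, cell-count
## normalization to [0, 1], and the percent-frequency / log2 expansion
## transforms.

#' Shannon entropy of clone counts
#'
#' H = -sum p_i log(p_i) with p_i = c_i / sum(c), in the requested logarithm
#' base (natural log by default, matching the ecology convention; base 2
#' gives bits). A single clone has entropy 0.
#'
#' @param counts positive numeric vector of per-clonotype read counts.
#' @param base logarithm base (default \code{exp(1)}).
#' @return Shannon entropy (scalar).
#' @export
shannonEntropy <- function(counts, base = exp(1)) {
  if (length(counts) == 0L) stop("empty counts")
  if (any(counts <= 0)) stop("counts must be positive")
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Cell-count-normalized diversity summary
#'
#' Computes richness (unique clonotypes), Shannon entropy and Pielou
#' evenness, then normalizes entropy and richness by their per-repertoire
#' maxima derived from the number of cells used for library generation: a
#' repertoire of N input cells can contain at most N distinct clones, so the
#' maximum richness is N and the maximum entropy is log(N) (the uniform
#' repertoire over N cells). Both normalized values are clamped to [0, 1].
#'
#' @param x a \code{\link{Repertoire}}, or a numeric vector of counts (then
#'   \code{cellCount} must be given).
#' @param cellCount number of input cells (taken from the repertoire when
#'   \code{x} is one).
#' @param base entropy logarithm base.
#' @return one-row data.frame: \code{richness}, \code{shannon_entropy},
#'   \code{evenness}, \code{max_entropy}, \code{max_richness},
#'   \code{normalized_entropy}, \code{normalized_richness},
#'   \code{cell_count}.
#' @export
diversitySummary <- function(x, cellCount = NULL, base = exp(1)) {
  if (is(x, "Repertoire")) {
    counts <- clonotypes(x)$count
    if (is.null(cellCount)) cellCount <- cellCount(x)
  } else {
    counts <- x
    if (is.null(cellCount)) stop("cellCount required for a counts vector")
  }
  stopifnot(cellCount >= 1)
  S <- richness(as.numeric(counts))
  H <- if (S == 0L) 0 else shannonEntropy(counts, base = base)
  evenness <- if (S > 1L) H / log(S, base = base) else 0
  maxH <- log(cellCount, base = base)
  if (cellCount < S)
    warning("cell count below richness; possible metadata error ",
            "(normalized richness clamped to 1)")
  normH <- if (maxH > 0) min(max(H / maxH, 0), 1) else 0
  data.frame(richness = S, shannon_entropy = H, evenness = evenness,
             max_entropy = maxH, max_richness = cellCount,
             normalized_entropy = normH,
             normalized_richness = min(max(S / cellCount, 0), 1),
             cell_count = cellCount)
}

#' Diversity table for a whole study
#'
#' One \code{\link{diversitySummary}} row per repertoire, prefixed with the
#' sample metadata.
#'
#' @param x a \code{\link{RepertoireSet}}.
#' @param base entropy logarithm base.
#' @return data.frame, one row per subject x compartment.
#' @export
studyDiversity <- function(x, base = exp(1)) {
  rows <- lapply(seq_len(length(x)), function(i) {
    r <- x[[i]]
    cbind(data.frame(subject = subjectId(r), group = groupLabel(r),
                     compartment = compartment(r),
                     total_inframe_reads = totalReads(r)),
          diversitySummary(r, base = base))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Clonal expansion profile
#'
#' Converts clone counts to percent total frequency (100 * c_i / sum c) and
#' its log2 transform (the degree of expansion), sorted by decreasing
#' frequency for cumulative-curve plotting.
#'
#' @param repertoire a \code{\link{Repertoire}} (or numeric counts vector).
#' @param keyMode key type for the \code{key} column (ignored for a counts
#'   vector).
#' @return data.frame with \code{key}, \code{count},
#'   \code{percent_total_frequency}, \code{log2_frequency}, sorted by
#'   decreasing frequency.
#' @export
expansionProfile <- function(repertoire, keyMode = "v_cdr3_j") {
  if (is(repertoire, "Repertoire")) {
    counts <- clonotypes(repertoire)$count
    keys <- clonotypeKeys(repertoire, mode = keyMode)
  } else {
    counts <- repertoire
    keys <- as.character(seq_along(counts))
  }
  stopifnot(sum(counts) > 0)
  pct <- 100 * counts / sum(counts)
  out <- data.frame(key = keys, count = counts,
                    percent_total_frequency = pct,
                    log2_frequency = log2(pct),
                    stringsAsFactors = FALSE)
  out[order(-out$percent_total_frequency, out$key), , drop = FALSE]
}
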