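## Clonal expansion binning, frequency-window selection, cross-subject and
## cross-compartment clonotype sharing.

#' Bin clonotypes by degree of expansion
#'
#' Classifies each clonotype by its in-frame read count with strict
#' thresholds: counts below 100 are "small" expansions, counts above 10,000
#' are "hyperexpanded", everything else (including exactly 100 and exactly
#' 10,000) is "intermediate". The three bin counts always sum to the
#' richness.
#'
#' @param x a \code{\link{Repertoire}} or numeric counts vector.
#' @param smallThreshold exclusive upper bound of the small bin.
#' @param hyperThreshold exclusive lower bound of the hyperexpanded bin.
#' @return named integer vector: \code{small}, \code{intermediate},
#'   \code{hyperexpanded}.
#' @export
binExpansion <- function(x, smallThreshold = 100, hyperThreshold = 10000) {
  counts <- if (is(x, "Repertoire")) clonotypes(x)$count else x
  c(small = sum(counts < smallThreshold),
    intermediate = sum(counts >= smallThreshold & counts <= hyperThreshold),
    hyperexpanded = sum(counts > hyperThreshold))
}

#' Select clonotypes inside a log2 frequency window
#'
#' Returns the keys of an expansion profile whose log2 percent total
#' frequency lies in the closed interval [lo, hi].
#'
#' @param profile data.frame from \code{\link{expansionProfile}}.
#' @param lo,hi window bounds on the log2 percent scale (inclusive).
#' @return character vector of keys.
#' @export
frequencyWindowFilter <- function(profile, lo, hi) {
  stopifnot(lo <= hi)
  profile$key[profile$log2_frequency >= lo & profile$log2_frequency <= hi]
}

#' Clonotypes shared by every subject of a group
#'
#' A clonotype is "shared" (public) when it is present in the repertoire of
#' every subject of a disease group within one compartment. Keys are either
#' the full V gene / CDR3 amino acid / J gene triple or the CDR3 amino-acid
#' sequence alone. An optional log2 percent-frequency window restricts each
#' subject's repertoire before intersecting.
#'
#' @param repertoires list of \code{\link{Repertoire}} objects (>= 2), or a
#'   \code{\link{RepertoireSet}}.
#' @param keyMode \code{"v_cdr3_j"} or \code{"cdr3_aa"}.
#' @param window optional numeric length-2 vector (lo, hi) of log2 percent
#'   frequencies.
#' @return character vector of shared keys.
#' @export
sharedClonotypes <- function(repertoires, keyMode = c("v_cdr3_j", "cdr3_aa"),
                             window = NULL) {
  keyMode <- match.arg(keyMode)
  if (is(repertoires, "RepertoireSet"))
    repertoires <- repertoires@repertoires
  stopifnot(length(repertoires) >= 2L)
  keysets <- lapply(repertoires, function(r) {
    keys <- clonotypeKeys(r, mode = keyMode)
    if (!is.null(window)) {
      prof <- expansionProfile(r, keyMode = keyMode)
      keys <- intersect(keys, frequencyWindowFilter(prof, window[1], window[2]))
    }
    unique(keys)
  })
  Reduce(intersect, keysets)
}

#' Exclusive and common portions of two shared sets
#'
#' Partitions two sets of shared clonotype keys into the part exclusive to
#' each and the common part, as in the cross-group comparison of public PB
#' clonotypes.
#'
#' @param setA,setB character vectors of clonotype keys.
#' @return list with counts \code{a_only}, \code{b_only}, \code{common} and
#'   the corresponding key vectors \code{a_only_keys}, \code{b_only_keys},
#'   \code{common_keys}.
#' @export
exclusiveAndCommon <- function(setA, setB) {
  common <- intersect(setA, setB)
  aOnly <- setdiff(setA, setB)
  bOnly <- setdiff(setB, setA)
  list(a_only = length(aOnly), b_only = length(bOnly),
       common = length(common), a_only_keys = aOnly, b_only_keys = bOnly,
       common_keys = common)
}

#' Hyperexpanded CSF clonotypes shared with peripheral blood
#'
#' For one subject's paired samples: intersects the hyperexpanded CSF
#' clonotypes (strictly more than \code{hyperThreshold} in-frame reads,
#' V/CDR3aa/J key) with the full PB repertoire and reports how much of the
#' CSF repertoire the shared clones carry. When the CSF has no hyperexpanded
#' clonotype the ratio and percentage are reported as absent (\code{NA}).
#'
#' @param csf,pb the subject's CSF and PB \code{\link{Repertoire}}s.
#' @param hyperThreshold hyperexpansion threshold (exclusive).
#' @return list: \code{n_hyper} (hyperexpanded CSF clonotypes),
#'   \code{n_shared} (of these, found in PB), \code{percent_csf} (percent of
#'   all CSF in-frame reads carried by the shared clones), \code{shared_keys}.
#' @export
crossCompartmentHyperexpanded <- function(csf, pb, hyperThreshold = 10000) {
  stopifnot(subjectId(csf) == subjectId(pb))
  clc <- clonotypes(csf)
  hyper <- clc$count > hyperThreshold
  nHyper <- sum(hyper)
  if (nHyper == 0L)
    return(list(n_hyper = 0L, n_shared = NA_integer_,
                percent_csf = NA_real_, shared_keys = character(0)))
  hyperKeys <- clonotypeKey(clc$v_call[hyper], clc$cdr3_aa[hyper],
                            clc$j_call[hyper])
  pbKeys <- clonotypeKeys(pb)
  shared <- intersect(hyperKeys, pbKeys)
  csfKeys <- clonotypeKeys(csf)
  sharedReads <- sum(clc$count[csfKeys %in% shared])
  list(n_hyper = nHyper, n_shared = length(shared),
       percent_csf = 100 * sharedReads / totalReads(csf),
       shared_keys = shared)
}

#' Cross-compartment hyperexpanded sharing table for a study
#'
#' One row per subject: total PB and CSF in-frame reads, the shared /
#' hyperexpanded ratio and the percentage of the CSF repertoire carried by
#' shared hyperexpanded clones.
#'
#' @param x a \code{\link{RepertoireSet}} with paired PB/CSF samples.
#' @param hyperThreshold hyperexpansion threshold (exclusive).
#' @return data.frame, one row per subject.
#' @export
crossCompartmentTable <- function(x, hyperThreshold = 10000) {
  info <- sampleInfo(x)
  subjects <- unique(info$subject)
  rows <- lapply(subjects, function(s) {
    pb <- x[[paste0(s, "_PB")]]
    csf <- x[[paste0(s, "_CSF")]]
    cc <- crossCompartmentHyperexpanded(csf, pb, hyperThreshold)
    data.frame(subject = s, group = groupLabel(pb),
               total_pb_reads = totalReads(pb),
               total_csf_reads = totalReads(csf),
               n_hyper_csf = cc$n_hyper, n_shared = cc$n_shared,
               percent_csf_repertoire = cc$percent_csf,
               shared_clones = paste(cc$shared_keys, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
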