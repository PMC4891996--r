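## S4 containers: GermlineSet, Repertoire, RepertoireSet, SimulationConfig.

#' GermlineSet: germline V/D/J segment references
#'
#' Holds germline TRB segment nucleotide templates together with the 0-based
#' position of the conserved anchor codon: the cysteine codon for V segments
#' and the phenylalanine codon for J segments (D segments carry no anchor).
#' The validity method checks that every V anchor codon translates to C and
#' every J anchor codon to F.
#'
#' @slot sequences a named \code{DNAStringSet}, one entry per segment.
#' @slot segmentClass character vector, one of \code{"V"}, \code{"D"},
#'   \code{"J"} per segment.
#' @slot anchorIndex integer vector of 0-based anchor codon start positions
#'   (\code{NA} for D segments).
#'
#' @param x a \code{GermlineSet}.
#' @aliases segmentIds segmentClass anchorIndex segmentSequences
#' @export
setClass("GermlineSet",
  representation(sequences = "DNAStringSet",
                 segmentClass = "character",
                 anchorIndex = "integer"))

setValidity("GermlineSet", function(object) {
  seqs <- object@sequences
  ids <- names(seqs)
  msgs <- character(0)
  n <- length(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "segment ids must be present and unique")
  if (length(object@segmentClass) != n || length(object@anchorIndex) != n)
    msgs <- c(msgs, "segmentClass and anchorIndex must match length of sequences")
  if (!all(object@segmentClass %in% c("V", "D", "J")))
    msgs <- c(msgs, "segmentClass must be V, D or J")
  if (length(msgs) > 0) return(msgs)
  if (any(Biostrings::width(seqs) == 0L))
    msgs <- c(msgs, "empty segment sequence")
  vj <- which(object@segmentClass %in% c("V", "J"))
  for (i in vj) {
    a <- object@anchorIndex[i]
    id <- ids[i]
    if (is.na(a)) {
      msgs <- c(msgs, sprintf("segment %s: missing anchor_index", id))
      next
    }
    if (a + 3L > Biostrings::width(seqs)[i]) {
      msgs <- c(msgs, sprintf("segment %s: anchor codon extends past sequence end", id))
      next
    }
    codon <- as.character(Biostrings::subseq(seqs[[i]], a + 1L, a + 3L))
    aa <- .translate(codon)
    want <- if (object@segmentClass[i] == "V") "C" else "F"
    if (!identical(aa, want))
      msgs <- c(msgs, sprintf("segment %s: anchor codon %s translates to %s, expected %s",
                              id, codon, aa, want))
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' @rdname GermlineSet-class
#' @export
GermlineSet <- function(sequences, segmentClass, anchorIndex) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  new("GermlineSet", sequences = sequences,
      segmentClass = as.character(segmentClass),
      anchorIndex = as.integer(anchorIndex))
}

setMethod("segmentIds", "GermlineSet", function(x) names(x@sequences))
setMethod("segmentClass", "GermlineSet", function(x) x@segmentClass)
setMethod("anchorIndex", "GermlineSet",
          function(x) setNames(x@anchorIndex, names(x@sequences)))
setMethod("segmentSequences", "GermlineSet", function(x) x@sequences)
setMethod("length", "GermlineSet", function(x) length(x@sequences))

#' @rdname GermlineSet-class
#' @param i index (numeric, logical, or segment id) for subsetting.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GermlineSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  initialize(x, sequences = x@sequences[i],
             segmentClass = x@segmentClass[i],
             anchorIndex = x@anchorIndex[i])
})

setMethod("show", "GermlineSet", function(object) {
  tab <- table(factor(object@segmentClass, levels = c("V", "D", "J")))
  cat(sprintf("GermlineSet with %d segments (%d V, %d D, %d J)\n",
              length(object), tab[["V"]], tab[["D"]], tab[["J"]]))
})

.CLONO_REQUIRED <- c("v_call", "j_call", "cdr3_nt", "cdr3_aa", "count")
.CLONO_COLS <- c("v_call", "d_call", "j_call", "cdr3_nt", "cdr3_aa", "count",
                 "n_from_v", "n_from_d", "n_from_j", "n_additions")

#' Repertoire: one subject x compartment clonotype collection
#'
#' Container for the collapsed productive clonotypes of one TCRB library,
#' together with its sample metadata (subject, disease group, compartment and
#' the number of input cells used for library generation, which drives the
#' diversity normalization). The \code{clonotypes} slot is a data.frame with
#' columns \code{v_call}, \code{d_call}, \code{j_call}, \code{cdr3_nt},
#' \code{cdr3_aa}, \code{count} (in-frame read count) and the germline
#' contribution breakdown \code{n_from_v}, \code{n_from_d}, \code{n_from_j},
#' \code{n_additions} (NA until computed). Every CDR3 runs from the conserved
#' cysteine to the conserved phenylalanine inclusive, so \code{cdr3_aa} always
#' starts with C and ends with F, and the clonotype key
#' (\code{v_call}, \code{cdr3_aa}, \code{j_call}) is unique.
#'
#' @slot clonotypes data.frame as described above.
#' @slot subject,group,compartment single character strings.
#' @slot cellCount number of cells used for library generation.
#'
#' @param x a \code{Repertoire}.
#' @aliases clonotypes subjectId groupLabel compartment cellCount totalReads
#'   clonotypeKeys
#' @export
setClass("Repertoire",
  representation(clonotypes = "data.frame",
                 subject = "character",
                 group = "character",
                 compartment = "character",
                 cellCount = "numeric"))

setValidity("Repertoire", function(object) {
  cl <- object@clonotypes
  msgs <- character(0)
  miss <- setdiff(.CLONO_REQUIRED, names(cl))
  if (length(miss) > 0)
    return(sprintf("missing clonotype columns: %s", paste(miss, collapse = ", ")))
  if (length(object@subject) != 1L || length(object@compartment) != 1L ||
      length(object@group) != 1L || length(object@cellCount) != 1L)
    msgs <- c(msgs, "subject, group, compartment, cellCount must be scalar")
  if (object@cellCount < 1)
    msgs <- c(msgs, "cellCount must be >= 1")
  if (nrow(cl) > 0) {
    if (any(cl$count < 1)) msgs <- c(msgs, "clonotype counts must be >= 1")
    if (!all(substr(cl$cdr3_aa, 1L, 1L) == "C"))
      msgs <- c(msgs, "every cdr3_aa must start with the conserved C")
    if (!all(substr(cl$cdr3_aa, nchar(cl$cdr3_aa), nchar(cl$cdr3_aa)) == "F"))
      msgs <- c(msgs, "every cdr3_aa must end with the conserved F")
    if (!all(nchar(cl$cdr3_nt) == 3L * nchar(cl$cdr3_aa)))
      msgs <- c(msgs, "cdr3_nt length must be 3x cdr3_aa length")
    key <- paste(cl$v_call, cl$cdr3_aa, cl$j_call, sep = "|")
    if (anyDuplicated(key))
      msgs <- c(msgs, "clonotype keys (v_call, cdr3_aa, j_call) must be unique")
    if (all(c("n_from_v", "n_from_d", "n_from_j", "n_additions") %in% names(cl))) {
      ok <- is.na(cl$n_from_v) |
        (cl$n_from_v + cl$n_from_d + cl$n_from_j + cl$n_additions == nchar(cl$cdr3_nt))
      if (!all(ok))
        msgs <- c(msgs, "germline contributions must sum to CDR3 length")
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' @rdname Repertoire-class
#' @param clonotypes data.frame of clonotypes (see slot description).
#' @param subject,group,compartment sample metadata strings.
#' @param cellCount number of input cells (>= 1).
#' @export
Repertoire <- function(clonotypes, subject, group, compartment, cellCount) {
  for (col in setdiff(.CLONO_COLS, names(clonotypes))) {
    clonotypes[[col]] <- rep(if (col == "d_call") NA_character_
                             else NA_integer_, nrow(clonotypes))
  }
  clonotypes <- clonotypes[, .CLONO_COLS, drop = FALSE]
  clonotypes$count <- as.integer(clonotypes$count)
  rownames(clonotypes) <- NULL
  new("Repertoire", clonotypes = clonotypes, subject = as.character(subject),
      group = as.character(group), compartment = as.character(compartment),
      cellCount = as.numeric(cellCount))
}

setMethod("clonotypes", "Repertoire", function(x) x@clonotypes)
setMethod("subjectId", "Repertoire", function(x) x@subject)
setMethod("groupLabel", "Repertoire", function(x) x@group)
setMethod("compartment", "Repertoire", function(x) x@compartment)
setMethod("cellCount", "Repertoire", function(x) x@cellCount)
setMethod("totalReads", "Repertoire", function(x) sum(x@clonotypes$count))
setMethod("richness", "Repertoire", function(x) nrow(x@clonotypes))
setMethod("richness", "numeric", function(x) sum(x > 0))
setMethod("clonotypeKeys", "Repertoire", function(x, mode = "v_cdr3_j") {
  cl <- x@clonotypes
  clonotypeKey(cl$v_call, cl$cdr3_aa, cl$j_call, mode = mode)
})

setMethod("show", "Repertoire", function(object) {
  cat(sprintf("Repertoire %s / %s (group %s)\n", object@subject,
              object@compartment, object@group))
  cat(sprintf("  %d clonotypes, %d in-frame reads, %g input cells\n",
              nrow(object@clonotypes), totalReads(object), object@cellCount))
})

#' RepertoireSet: a study of repertoires
#'
#' A list of \code{Repertoire} objects with unique (subject, compartment)
#' pairs, typically the paired PB/CSF repertoires of all study subjects.
#'
#' @slot repertoires list of \code{Repertoire}.
#' @param x a \code{RepertoireSet}.
#' @aliases sampleInfo
#' @export
setClass("RepertoireSet", representation(repertoires = "list"))

setValidity("RepertoireSet", function(object) {
  if (!all(vapply(object@repertoires, is, logical(1), class2 = "Repertoire")))
    return("all elements must be Repertoire objects")
  key <- vapply(object@repertoires,
                function(r) paste(subjectId(r), compartment(r)), character(1))
  if (anyDuplicated(key)) return("(subject, compartment) pairs must be unique")
  TRUE
})

#' @rdname RepertoireSet-class
#' @param repertoires list of \code{Repertoire} objects.
#' @export
RepertoireSet <- function(repertoires) {
  names(repertoires) <- vapply(repertoires, function(r)
    paste(subjectId(r), compartment(r), sep = "_"), character(1))
  new("RepertoireSet", repertoires = repertoires)
}

setMethod("length", "RepertoireSet", function(x) length(x@repertoires))

#' @rdname RepertoireSet-class
#' @param i index or sample name (\code{"<subject>_<compartment>"}).
#' @export
setMethod("[[", "RepertoireSet", function(x, i) x@repertoires[[i]])

#' @rdname RepertoireSet-class
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RepertoireSet", function(x, i, j, ..., drop = TRUE) {
  new("RepertoireSet", repertoires = x@repertoires[i])
})

setMethod("sampleInfo", "RepertoireSet", function(x) {
  do.call(rbind, lapply(x@repertoires, function(r) {
    data.frame(subject = subjectId(r), group = groupLabel(r),
               compartment = compartment(r), cell_count = cellCount(r),
               richness = richness(r), total_inframe_reads = totalReads(r),
               row.names = NULL)
  }))
})

#' @rdname RepertoireSet-class
#' @param group,compartment optional filters; \code{NULL} keeps everything.
#' @export
filterSamples <- function(x, group = NULL, compartment = NULL) {
  keep <- vapply(x@repertoires, function(r) {
    (is.null(group) || groupLabel(r) %in% group) &&
      (is.null(compartment) || compartment(r) %in% compartment)
  }, logical(1))
  new("RepertoireSet", repertoires = x@repertoires[keep])
}

setMethod("show", "RepertoireSet", function(object) {
  cat(sprintf("RepertoireSet with %d repertoires\n", length(object)))
  if (length(object) > 0) print(sampleInfo(object))
})

#' SimulationConfig: study-design parameters for the repertoire simulator
#'
#' Bundles every knob of the synthetic study generator. The defaults encode
#' the packaged study conditions: 5 + 5 subjects in groups MS and IIH, paired
#' PB/CSF libraries, power-law clone abundances, hyperexpanded CSF spike-in
#' clones above the 10,000-read hyperexpansion threshold, a small controlled
#' PB/CSF sharing fraction, and group-level public PB clonotypes with an
#' exclusive/common split of 204 (MS only) / 158 (IIH only) / 94 (common).
#' Cell counts default to 1e6 (PB) and 1e5 (CSF), the order of magnitude of
#' the PBMC and CSF inputs the design emulates. Reads are 150 bases in
#' forward (5') and reverse (3') orientation.
#'
#' @slot seed integer RNG seed; a fixed seed makes the whole study
#'   byte-reproducible.
#' @slot nSubjectsPerGroup subjects per disease group.
#' @slot nClonesPB,nClonesCSF private (non-public, non-spike) clones per
#'   subject and compartment.
#' @slot abundanceModel \code{"power_law"}, \code{"log_normal"} or
#'   \code{"uniform"}.
#' @slot powerExponent exponent a of P(count = k) proportional to k^-a.
#' @slot abundanceMax largest non-spike clone count.
#' @slot logMu,logSigma log-normal parameters.
#' @slot uniformCount count used by the uniform model.
#' @slot nSpikesPB,nSpikesCSF hyperexpanded spike-in clones per compartment.
#' @slot spikeReadCount read count given to each spike (> 10,000 to land in
#'   the hyperexpanded bin).
#' @slot nSharedHyper number of CSF spikes also planted in the same subject's
#'   PB repertoire (drives the cross-compartment hyperexpanded table).
#' @slot pbCsfSharingFraction fraction of CSF clones copied from the same
#'   subject's PB repertoire.
#' @slot publicExclusive named vector: public PB clonotypes exclusive to each
#'   group.
#' @slot publicCommon public PB clonotypes planted in every subject of both
#'   groups.
#' @slot readLength read length in bases.
#' @slot perBaseErrorRate substitution error probability per sequenced base.
#' @slot cellCountPB,cellCountCSF input cells per library.
#' @slot nonproductiveRate fraction of private clones generated with an
#'   out-of-frame or stop-containing junction.
#' @slot dUsageProb probability that a junction contains a D-segment fragment.
#' @slot groups group labels (first = case, second = control).
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nSubjectsPerGroup = "integer",
                 nClonesPB = "integer", nClonesCSF = "integer",
                 abundanceModel = "character", powerExponent = "numeric",
                 abundanceMax = "integer", logMu = "numeric",
                 logSigma = "numeric", uniformCount = "integer",
                 nSpikesPB = "integer", nSpikesCSF = "integer",
                 spikeReadCount = "integer", nSharedHyper = "integer",
                 pbCsfSharingFraction = "numeric", publicExclusive = "numeric",
                 publicCommon = "integer", readLength = "integer",
                 perBaseErrorRate = "numeric", cellCountPB = "numeric",
                 cellCountCSF = "numeric", nonproductiveRate = "numeric",
                 dUsageProb = "numeric", groups = "character"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  counts <- c(object@nSubjectsPerGroup, object@nClonesPB, object@nClonesCSF,
              object@nSpikesPB, object@nSpikesCSF, object@spikeReadCount,
              object@nSharedHyper, object@publicExclusive, object@publicCommon,
              object@readLength)
  if (any(counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  fracs <- c(object@pbCsfSharingFraction, object@perBaseErrorRate,
             object@nonproductiveRate, object@dUsageProb)
  if (any(fracs < 0 | fracs > 1)) msgs <- c(msgs, "fractions must be in [0, 1]")
  if (!object@abundanceModel %in% c("power_law", "log_normal", "uniform"))
    msgs <- c(msgs, "unknown abundance model")
  if (length(object@groups) != 2L) msgs <- c(msgs, "exactly two groups required")
  if (!identical(sort(names(object@publicExclusive)), sort(object@groups)))
    msgs <- c(msgs, "publicExclusive must be named by the two groups")
  if (object@nSharedHyper > object@nSpikesCSF)
    msgs <- c(msgs, "nSharedHyper cannot exceed nSpikesCSF")
  if (length(msgs) == 0) TRUE else msgs
})

#' @rdname SimulationConfig-class
#' @param seed,nSubjectsPerGroup,nClonesPB,nClonesCSF,abundanceModel see slots.
#' @param powerExponent,abundanceMax,logMu,logSigma,uniformCount see slots.
#' @param nSpikesPB,nSpikesCSF,spikeReadCount,nSharedHyper see slots.
#' @param pbCsfSharingFraction,publicExclusive,publicCommon see slots.
#' @param readLength,perBaseErrorRate,cellCountPB,cellCountCSF see slots.
#' @param nonproductiveRate,dUsageProb,groups see slots.
#' @export
simulationConfig <- function(seed = 1L, nSubjectsPerGroup = 5L,
                             nClonesPB = 300L, nClonesCSF = 120L,
                             abundanceModel = "power_law",
                             powerExponent = 2.5, abundanceMax = 3000L,
                             logMu = 1, logSigma = 1, uniformCount = 10L,
                             nSpikesPB = 0L, nSpikesCSF = 2L,
                             spikeReadCount = 12000L, nSharedHyper = 1L,
                             pbCsfSharingFraction = 0.1,
                             publicExclusive = c(MS = 204, IIH = 158),
                             publicCommon = 94L, readLength = 150L,
                             perBaseErrorRate = 0, cellCountPB = 1e6,
                             cellCountCSF = 1e5, nonproductiveRate = 0.1,
                             dUsageProb = 0.85, groups = c("MS", "IIH")) {
  new("SimulationConfig", seed = as.integer(seed),
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      nClonesPB = as.integer(nClonesPB), nClonesCSF = as.integer(nClonesCSF),
      abundanceModel = abundanceModel, powerExponent = powerExponent,
      abundanceMax = as.integer(abundanceMax), logMu = logMu,
      logSigma = logSigma, uniformCount = as.integer(uniformCount),
      nSpikesPB = as.integer(nSpikesPB), nSpikesCSF = as.integer(nSpikesCSF),
      spikeReadCount = as.integer(spikeReadCount),
      nSharedHyper = as.integer(nSharedHyper),
      pbCsfSharingFraction = pbCsfSharingFraction,
      publicExclusive = publicExclusive, publicCommon = as.integer(publicCommon),
      readLength = as.integer(readLength), perBaseErrorRate = perBaseErrorRate,
      cellCountPB = cellCountPB, cellCountCSF = cellCountCSF,
      nonproductiveRate = nonproductiveRate, dUsageProb = dUsageProb,
      groups = groups)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d+%d subjects (%s), %d PB / %d CSF ",
                     "private clones,\n  %s abundances, %d CSF spikes of %d reads, ",
                     "sharing %.2f, publics %s+%d common,\n  read length %d, ",
                     "error rate %g, seed %d\n"),
              object@nSubjectsPerGroup, object@nSubjectsPerGroup,
              paste(object@groups, collapse = "/"),
              object@nClonesPB, object@nClonesCSF, object@abundanceModel,
              object@nSpikesCSF, object@spikeReadCount,
              object@pbCsfSharingFraction,
              paste(object@publicExclusive, collapse = "/"),
              object@publicCommon, object@readLength,
              object@perBaseErrorRate, object@seed))
})
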