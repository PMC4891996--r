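## Read annotation: germline V/J assignment by local alignment, CDR3
## extraction between the conserved cysteine and phenylalanine, productivity
## classification, clonotype collapsing and germline-contribution breakdown.

.ALIGN_GAP_OPEN <- 3
.ALIGN_GAP_EXT <- 1
.MIN_SEGMENT_SCORE <- 20

## Local alignment scores of many reads against one reference
## (match +1, mismatch -1, gap open -3, gap extend -1).
.alignScores <- function(reads, refSeq) {
  Biostrings::pairwiseAlignment(reads, refSeq, type = "local",
                                substitutionMatrix = .dnaSubMat(),
                                gapOpening = .ALIGN_GAP_OPEN,
                                gapExtension = .ALIGN_GAP_EXT,
                                scoreOnly = TRUE)
}

## nreads x nrefs score matrix; columns ordered by segment id so that
## max.col(ties.method = "first") implements the lexicographic tie-break.
.scoreMatrix <- function(reads, refs) {
  ord <- order(names(refs))
  refs <- refs[ord]
  m <- vapply(seq_along(refs), function(i) .alignScores(reads, refs[[i]]),
              numeric(length(reads)))
  m <- matrix(m, nrow = length(reads), ncol = length(refs))
  colnames(m) <- names(refs)
  m
}

#' Assign the best-matching germline segment to each read
#'
#' Locally aligns every read, on both strands, against every reference of a
#' \code{GermlineSet} and reports the highest-scoring segment (ties broken by
#' the lexicographically smallest segment id). A best score below
#' \code{minScore} yields no call (\code{NA}).
#'
#' @param reads a \code{DNAStringSet} or character vector.
#' @param references a \code{\link{GermlineSet}} (typically subset to one
#'   segment class).
#' @param minScore minimum alignment score for a call.
#' @return data.frame with \code{read_id}, \code{segment_id}, \code{score},
#'   \code{strand}.
#' @export
assignSegment <- function(reads, references, minScore = .MIN_SEGMENT_SCORE) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  refs <- segmentSequences(references)
  sf <- .scoreMatrix(reads, refs)
  sr <- .scoreMatrix(Biostrings::reverseComplement(reads), refs)
  bf <- sf[cbind(seq_len(nrow(sf)), max.col(sf, ties.method = "first"))]
  br <- sr[cbind(seq_len(nrow(sr)), max.col(sr, ties.method = "first"))]
  useRev <- br > bf
  best <- ifelse(useRev, br, bf)
  id <- ifelse(useRev,
               colnames(sr)[max.col(sr, ties.method = "first")],
               colnames(sf)[max.col(sf, ties.method = "first")])
  called <- best >= minScore
  data.frame(
    read_id = if (is.null(names(reads))) as.character(seq_along(reads))
              else names(reads),
    segment_id = ifelse(called, id, NA_character_),
    score = ifelse(called, best, NA_real_),
    strand = ifelse(called, ifelse(useRev, "reverse", "forward"), NA_character_),
    stringsAsFactors = FALSE)
}

#' Classify CDR3 productivity
#'
#' A junction is productive when its length is divisible by 3 and its
#' translation contains no stop codon. Non-ACGT characters make the call
#' ambiguous (nonproductive).
#'
#' @param cdr3_nt character vector of CDR3 nucleotide sequences.
#' @return data.frame with \code{productive} (logical) and \code{reason}
#'   (\code{"ok"}, \code{"frameshift"}, \code{"stop"}, \code{"ambiguous"}).
#' @export
classifyProductive <- function(cdr3_nt) {
  stopifnot(all(nchar(cdr3_nt) > 0L))
  reason <- rep("ok", length(cdr3_nt))
  reason[grepl("[^ACGT]", cdr3_nt)] <- "ambiguous"
  reason[reason == "ok" & nchar(cdr3_nt) %% 3L != 0L] <- "frameshift"
  ok <- reason == "ok"
  if (any(ok)) {
    aa <- .translate(cdr3_nt[ok])
    reason[ok][grepl("*", aa, fixed = TRUE)] <- "stop"
  }
  data.frame(productive = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

## Map a reference (subject) position to a read (pattern) position through a
## gapped alignment. Indel-containing alignments are ambiguous around
## homopolymer runs (the aligner may place the gap on either side of the
## anchor codon), so the anchor is pinned by its flanking aligned neighbour
## on the side where the register is fixed by templated sequence: for a
## junction start the subject position immediately 5' of the target (+1),
## for a junction end the position immediately 3' (-1). Falls back to the
## direct column mapping when the neighbour is unaligned; returns NA when
## the target cannot be placed.
.walkMapOne <- function(readChr, refSeq, targetSubjPos, side = c("start", "end")) {
  side <- match.arg(side)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(readChr), refSeq,
                                      type = "local",
                                      substitutionMatrix = .dnaSubMat(),
                                      gapOpening = .ALIGN_GAP_OPEN,
                                      gapExtension = .ALIGN_GAP_EXT)
  P <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  S <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  p0 <- Biostrings::start(Biostrings::pattern(pa))
  s0 <- Biostrings::start(Biostrings::subject(pa))
  pattIdx <- cumsum(P != "-")
  subjIdx <- cumsum(S != "-")
  colOf <- function(t) which(subjIdx == (t - s0 + 1L) & S != "-")[1]
  if (side == "end") {
    jn <- colOf(targetSubjPos + 1L)
    if (!is.na(jn) && P[jn] != "-") return(p0 - 1L + pattIdx[jn] - 1L)
  } else {
    jn <- colOf(targetSubjPos - 1L)
    if (!is.na(jn) && P[jn] != "-") return(p0 - 1L + pattIdx[jn] + 1L)
  }
  i <- colOf(targetSubjPos)
  if (is.na(i) || P[i] == "-") NA_integer_ else p0 - 1L + pattIdx[i]
}

## Full alignments of a batch of (already oriented) reads against one
## reference, returning coordinates needed for anchor mapping.
.alignCoords <- function(reads, refSeq) {
  pa <- Biostrings::pairwiseAlignment(reads, refSeq, type = "local",
                                      substitutionMatrix = .dnaSubMat(),
                                      gapOpening = .ALIGN_GAP_OPEN,
                                      gapExtension = .ALIGN_GAP_EXT)
  list(p1 = Biostrings::start(Biostrings::pattern(pa)),
       p2 = Biostrings::end(Biostrings::pattern(pa)),
       s1 = Biostrings::start(Biostrings::subject(pa)),
       s2 = Biostrings::end(Biostrings::subject(pa)),
       nindel = rowSums(Biostrings::nindel(pa)@insertion) +
         rowSums(Biostrings::nindel(pa)@deletion))
}

#' Annotate reads: V/J calls, CDR3, productivity
#'
#' Runs the per-read annotation pipeline: identical read sequences are
#' collapsed and each unique sequence is locally aligned, on both strands,
#' against every V and J reference; the strand maximizing the combined best
#' V + best J score is kept, and calls below \code{minScore} are dropped. The
#' CDR3 is then taken from the read interval running from the position
#' aligned to the V conserved-cysteine codon through the position aligned to
#' the J conserved-phenylalanine codon (both codons included); reads in which
#' either anchor falls outside the aligned region, or the anchors are
#' inconsistently ordered, are counted as \code{no_junction}.
#'
#' The junction content is always taken verbatim from the read: local
#' alignments routinely over-extend past the true germline boundary through
#' chance matches in the non-templated region, so substituting reference
#' sequence for aligned positions would silently corrupt true junction
#' nucleotides. Alignments containing indels are not used for junction
#' extraction (such reads are counted as \code{no_junction}).
#'
#' @param reads a \code{DNAStringSet} or named character vector.
#' @param germline a \code{\link{GermlineSet}} with V and J segments.
#' @param minScore minimum per-segment alignment score.
#' @return data.frame, one row per read: \code{read_id}, \code{v_call},
#'   \code{v_score}, \code{j_call}, \code{j_score}, \code{strand},
#'   \code{cdr3_nt}, \code{cdr3_aa}, \code{frame_ok}, \code{stop_free},
#'   \code{productive}, \code{fate} (one of \code{no_call},
#'   \code{no_junction}, \code{nonproductive}, \code{productive}); the
#'   read-fate tally is attached as attribute \code{"fate_tally"}.
#' @export
annotateReads <- function(reads, germline, minScore = .MIN_SEGMENT_SCORE) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  readIds <- if (is.null(names(reads))) as.character(seq_along(reads))
             else names(reads)
  seqChar <- as.character(reads)
  uniq <- unique(seqChar)
  u2r <- match(seqChar, uniq)
  useqs <- Biostrings::DNAStringSet(uniq)

  vRefs <- segmentSequences(germline)[segmentClass(germline) == "V"]
  jRefs <- segmentSequences(germline)[segmentClass(germline) == "J"]
  anchors <- anchorIndex(germline)

  urev <- Biostrings::reverseComplement(useqs)
  svf <- .scoreMatrix(useqs, vRefs); svr <- .scoreMatrix(urev, vRefs)
  sjf <- .scoreMatrix(useqs, jRefs); sjr <- .scoreMatrix(urev, jRefs)

  n <- length(useqs)
  rowBest <- function(m) {
    j <- max.col(m, ties.method = "first")
    list(score = m[cbind(seq_len(nrow(m)), j)], id = colnames(m)[j])
  }
  bvf <- rowBest(svf); bvr <- rowBest(svr)
  bjf <- rowBest(sjf); bjr <- rowBest(sjr)
  useRev <- (bvr$score + bjr$score) > (bvf$score + bjf$score)

  v_call <- ifelse(useRev, bvr$id, bvf$id)
  v_score <- ifelse(useRev, bvr$score, bvf$score)
  j_call <- ifelse(useRev, bjr$id, bjf$id)
  j_score <- ifelse(useRev, bjr$score, bjf$score)
  called <- v_score >= minScore & j_score >= minScore
  v_call[!called] <- NA_character_
  j_call[!called] <- NA_character_

  oriented <- as.character(useqs)
  oriented[useRev] <- as.character(urev)[useRev]

  cdr3_nt <- rep(NA_character_, n)
  nas <- rep(NA_real_, n)
  vcoord <- list(p1 = nas, p2 = nas, s1 = nas, s2 = nas, nindel = nas)
  jcoord <- vcoord
  fill <- function(tgt, src, idx) {
    for (f in names(src)) tgt[[f]][idx] <- src[[f]]
    tgt
  }
  for (vg in unique(v_call[called])) {
    idx <- which(called & v_call == vg)
    vcoord <- fill(vcoord, .alignCoords(Biostrings::DNAStringSet(oriented[idx]),
                                        vRefs[[vg]]), idx)
  }
  for (jg in unique(j_call[called])) {
    idx <- which(called & j_call == jg)
    jcoord <- fill(jcoord, .alignCoords(Biostrings::DNAStringSet(oriented[idx]),
                                        jRefs[[jg]]), idx)
  }

  for (i in which(called)) {
    aV <- anchors[[v_call[i]]]; aJ <- anchors[[j_call[i]]]
    ## anchors must lie inside the aligned reference intervals
    gapfree <- vcoord$nindel[i] == 0 && jcoord$nindel[i] == 0
    vs1 <- vcoord$s1[i]; vs2 <- vcoord$s2[i]
    js1 <- jcoord$s1[i]; js2 <- jcoord$s2[i]
    if (!(vs1 <= aV + 1L && vs2 >= aV + 3L)) next
    if (!(js1 <= aJ + 1L && js2 >= aJ + 3L)) next
    if (gapfree) {
      s <- vcoord$p1[i] + (aV + 1L - vs1)     # read pos of Cys codon start
      e <- jcoord$p1[i] + (aJ + 3L - js1)     # read pos of Phe codon end
    } else {
      ## rare indel-containing alignment: map the anchors through the
      ## gapped alignment explicitly
      s <- if (vcoord$nindel[i] == 0) vcoord$p1[i] + (aV + 1L - vs1)
           else .walkMapOne(oriented[i], vRefs[[v_call[i]]], aV + 1L, "start")
      e <- if (jcoord$nindel[i] == 0) jcoord$p1[i] + (aJ + 3L - js1)
           else .walkMapOne(oriented[i], jRefs[[j_call[i]]], aJ + 3L, "end")
    }
    if (is.na(s) || is.na(e) || s >= e || e - s + 1L < 6L) next
    if (s < 1L || e > nchar(oriented[i])) next
    cdr3_nt[i] <- substr(oriented[i], s, e)
  }

  frame_ok <- !is.na(cdr3_nt) & nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- rep(NA_character_, n)
  cdr3_aa[frame_ok] <- .translate(cdr3_nt[frame_ok])
  stop_free <- frame_ok & !grepl("*", ifelse(is.na(cdr3_aa), "", cdr3_aa),
                                 fixed = TRUE)
  ambiguous <- !is.na(cdr3_nt) & grepl("[^ACGT]", cdr3_nt)
  productive <- frame_ok & stop_free & !ambiguous
  fate <- ifelse(!called, "no_call",
                 ifelse(is.na(cdr3_nt), "no_junction",
                        ifelse(productive, "productive", "nonproductive")))

  ex <- u2r  # expand unique-sequence results back to reads
  out <- data.frame(
    read_id = readIds,
    v_call = v_call[ex], v_score = v_score[ex],
    j_call = j_call[ex], j_score = j_score[ex],
    strand = ifelse(called, ifelse(useRev, "reverse", "forward"),
                    NA_character_)[ex],
    cdr3_nt = cdr3_nt[ex], cdr3_aa = cdr3_aa[ex],
    frame_ok = frame_ok[ex], stop_free = stop_free[ex],
    productive = productive[ex], fate = fate[ex],
    stringsAsFactors = FALSE)
  tally <- table(factor(out$fate, levels = c("no_call", "no_junction",
                                             "nonproductive", "productive")))
  attr(out, "fate_tally") <- as.list(tally)
  out
}

#' Extract the CDR3 of a single read
#'
#' Convenience wrapper around the annotation engine for one read with known
#' V and J calls: returns the junction between the conserved cysteine and
#' phenylalanine, or \code{NA} when an anchor falls outside the aligned
#' region or the anchors are inconsistently ordered.
#'
#' @param read a single-sequence \code{DNAStringSet} or character string.
#' @param v_call,j_call segment ids.
#' @param germline a \code{\link{GermlineSet}}.
#' @return list with \code{cdr3_nt}, \code{cdr3_aa} (both \code{NA} when not
#'   found).
#' @export
extractCDR3 <- function(read, v_call, j_call, germline) {
  sub <- germline[c(v_call, j_call)]
  ann <- annotateReads(Biostrings::DNAStringSet(as.character(read)[1]), sub)
  list(cdr3_nt = ann$cdr3_nt[1], cdr3_aa = ann$cdr3_aa[1])
}

#' Collapse annotated reads into a counted clonotype repertoire
#'
#' Unique productive (V gene, CDR3 amino acid, J gene) combinations among the
#' annotations are collapsed into one \code{ClonotypeRecord} each, with the
#' in-frame read count equal to the number of contributing reads. The
#' representative \code{cdr3_nt} is the most frequent nucleotide junction of
#' the key.
#'
#' @param annotations data.frame from \code{\link{annotateReads}}.
#' @param subject,group,compartment sample metadata.
#' @param cellCount input cell count for the library.
#' @return a \code{\link{Repertoire}} (empty, with a warning, when no
#'   productive annotation exists).
#' @export
collapseClonotypes <- function(annotations, subject, group, compartment,
                               cellCount) {
  prod <- annotations[annotations$productive %in% TRUE, , drop = FALSE]
  if (nrow(prod) == 0L) {
    warning("no productive annotations; returning empty repertoire")
    empty <- data.frame(v_call = character(0), d_call = character(0),
                        j_call = character(0), cdr3_nt = character(0),
                        cdr3_aa = character(0), count = integer(0))
    return(Repertoire(empty, subject, group, compartment, cellCount))
  }
  key <- paste(prod$v_call, prod$cdr3_aa, prod$j_call, sep = "|")
  split_idx <- split(seq_len(nrow(prod)), key)
  rows <- lapply(split_idx, function(ii) {
    nt <- prod$cdr3_nt[ii]
    rep_nt <- names(sort(table(nt), decreasing = TRUE))[1]
    data.frame(v_call = prod$v_call[ii[1]], d_call = NA_character_,
               j_call = prod$j_call[ii[1]], cdr3_nt = rep_nt,
               cdr3_aa = prod$cdr3_aa[ii[1]], count = length(ii),
               stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, c(rows, make.row.names = FALSE))
  Repertoire(cl, subject, group, compartment, cellCount)
}

#' Germline nucleotide contributions of a CDR3
#'
#' Decomposes each clonotype's CDR3 into the nucleotides contributed by the
#' germline V, D and J genes and the non-templated additions:
#' \code{n_from_v} is the longest exact extension of the called V germline
#' (from its conserved-cysteine codon) into the CDR3, \code{n_from_j} the
#' symmetric extension from the 3' side, and \code{n_from_d} the longest
#' substring of the remaining core that occurs in any D reference (ties go
#' to the longer D segment, then the lexicographically smaller id). The
#' remainder is \code{n_additions}; the four components sum to the CDR3
#' length.
#'
#' @param repertoire a \code{\link{Repertoire}} with V/J calls.
#' @param germline a \code{\link{GermlineSet}} containing the called V/J
#'   segments and the D references.
#' @return the repertoire with \code{d_call}, \code{n_from_v},
#'   \code{n_from_d}, \code{n_from_j}, \code{n_additions} filled in.
#' @export
germlineContributions <- function(repertoire, germline) {
  cl <- clonotypes(repertoire)
  if (nrow(cl) == 0L) return(repertoire)
  seqs <- as.character(segmentSequences(germline))
  anchors <- anchorIndex(germline)
  dIds <- sort(segmentIds(germline)[segmentClass(germline) == "D"])
  dSeqs <- seqs[dIds]
  dOrder <- dIds[order(-nchar(dSeqs), dIds)]  # tie rule: longer D, then id

  for (i in seq_len(nrow(cl))) {
    cdr3 <- cl$cdr3_nt[i]
    len <- nchar(cdr3)
    vSeq <- seqs[[cl$v_call[i]]]; aV <- anchors[[cl$v_call[i]]]
    jSeq <- seqs[[cl$j_call[i]]]; aJ <- anchors[[cl$j_call[i]]]
    nV <- .commonPrefixLen(cdr3, substr(vSeq, aV + 1L, nchar(vSeq)))
    nJ <- .commonSuffixLen(cdr3, substr(jSeq, 1L, aJ + 3L))
    nJ <- min(nJ, len - nV)
    core <- substr(cdr3, nV + 1L, len - nJ)
    nD <- 0L; dCall <- NA_character_
    nc <- nchar(core)
    if (nc > 0L) {
      found <- FALSE
      for (L in rev(seq_len(nc))) {
        for (st in seq_len(nc - L + 1L)) {
          frag <- substr(core, st, st + L - 1L)
          hit <- dOrder[vapply(dOrder, function(d)
            grepl(frag, seqs[[d]], fixed = TRUE), logical(1))]
          if (length(hit) > 0L) {
            nD <- L; dCall <- hit[1L]; found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
    cl$n_from_v[i] <- nV
    cl$n_from_j[i] <- nJ
    cl$n_from_d[i] <- nD
    cl$n_additions[i] <- len - nV - nJ - nD
    cl$d_call[i] <- dCall
  }
  initialize(repertoire, clonotypes = cl)
}

#' Per-repertoire summary distributions
#'
#' Computes the read-weighted CDR3 amino-acid length distribution, the V x J
#' pairing percentage matrix (summing to 100), and the positional amino-acid
#' composition per CDR3 length stratum (each position column summing to 1).
#'
#' @param repertoire a non-empty \code{\link{Repertoire}}.
#' @return list with \code{lengthDistribution} (named numeric, proportions),
#'   \code{vjPairing} (matrix of percentages), \code{aaComposition} (list of
#'   20 x L frequency matrices, one per CDR3 length).
#' @export
repertoireSummaries <- function(repertoire) {
  cl <- clonotypes(repertoire)
  stopifnot(nrow(cl) > 0L)
  w <- cl$count
  lens <- nchar(cl$cdr3_aa)
  lengthDist <- tapply(w, lens, sum) / sum(w)
  vj <- tapply(w, list(cl$v_call, cl$j_call), sum)
  vj[is.na(vj)] <- 0
  vj <- 100 * vj / sum(vj)
  comp <- lapply(sort(unique(lens)), function(L) {
    idx <- which(lens == L)
    m <- matrix(0, nrow = length(.AA20), ncol = L,
                dimnames = list(.AA20, seq_len(L)))
    for (i in idx) {
      aa <- strsplit(cl$cdr3_aa[i], "")[[1]]
      for (p in seq_len(L)) m[aa[p], p] <- m[aa[p], p] + w[i]
    }
    sweep(m, 2, colSums(m), "/")
  })
  names(comp) <- sort(unique(lens))
  list(lengthDistribution = c(lengthDist), vjPairing = vj,
       aaComposition = comp)
}
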