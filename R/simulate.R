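## Synthetic repertoire and read simulator. Generates ground-truth studies
## with the statistical structure the downstream analysis assumes: skewed
## clone abundances, hyperexpanded spike-ins, paired-compartment sharing and
## group-level public clonotypes, plus raw 150-base forward/reverse reads.

#' Sample per-clone read counts
#'
#' Draws clone abundances under the configured model and overwrites
#' \code{nSpikes} randomly chosen clones with the fixed hyperexpanded spike
#' count. Power-law counts follow P(count = k) proportional to k^-a on
#' 1..\code{abundanceMax}.
#'
#' @param nClones number of clones.
#' @param config a \code{\link{SimulationConfig}}.
#' @param nSpikes clones forced to \code{spikeReadCount} reads.
#' @return integer vector of counts (>= 1), length \code{nClones}.
#' @export
sampleCloneAbundances <- function(nClones, config, nSpikes = 0L) {
  stopifnot(nClones >= 1L, nSpikes <= nClones)
  counts <- switch(config@abundanceModel,
    power_law = {
      k <- seq_len(config@abundanceMax)
      sample(k, nClones, replace = TRUE, prob = k^(-config@powerExponent))
    },
    log_normal = pmax(1L, as.integer(round(rlnorm(nClones, config@logMu,
                                                  config@logSigma)))),
    uniform = rep(config@uniformCount, nClones))
  if (nSpikes > 0L) {
    if (config@spikeReadCount <= 10000L)
      warning("spikeReadCount <= 10,000: spikes will not fall in the ",
              "hyperexpanded bin")
    idx <- sample(nClones, nSpikes)
    counts[idx] <- config@spikeReadCount
  }
  counts <- as.integer(counts)
  if (nSpikes > 0L) attr(counts, "spike_index") <- sort(idx)
  counts
}

## Draw a truncated geometric N-addition length (mean 3, cap 12 per side).
.nAddLen <- function() min(rgeom(1L, 0.25), 12L)

#' Recombine a clonotype from germline segments
#'
#' Builds one V(D)J rearrangement: the V template through its conserved Cys
#' codon plus a few templated nucleotides, non-templated N additions flanking
#' an optionally trimmed D fragment, and the J template from a few bases 5'
#' of its conserved Phe codon through the end of the segment. The returned
#' amplicon is flanked by the 5' template-switch anchor and the
#' constant-region primer site, mirroring the library structure the reads
#' are drawn from. Productive clones have an in-frame, stop-free CDR3
#' (conserved C through conserved F); nonproductive clones carry a frameshift
#' or an internal stop.
#'
#' @param v,j segment ids present in \code{germline}.
#' @param germline a \code{\link{GermlineSet}} containing V, D and J segments.
#' @param config a \code{\link{SimulationConfig}}.
#' @param productive logical: generate a productive junction?
#' @return list with v_call, d_call, j_call, cdr3_nt, cdr3_aa, amplicon and
#'   the true germline contribution breakdown.
#' @export
recombineClonotype <- function(v, j, germline, config = simulationConfig(),
                               productive = TRUE) {
  seqs <- as.character(segmentSequences(germline))
  anchors <- anchorIndex(germline)
  vSeq <- seqs[[v]]; jSeq <- seqs[[j]]
  aV <- anchors[[v]]; aJ <- anchors[[j]]
  dIds <- segmentIds(germline)[segmentClass(germline) == "D"]

  useD <- length(dIds) > 0 && runif(1L) < config@dUsageProb
  npMode <- if (productive) "" else sample(c("frameshift", "stop"), 1L)
  for (attempt in 1:100) {
    ## resample the whole junction each attempt: a stop codon may sit in the
    ## templated V/D/J portions, which only new trimming can remove
    vExtra <- sample(0:min(6L, nchar(vSeq) - (aV + 3L)), 1L)
    jExtra <- sample(0:min(8L, aJ), 1L)
    vPart <- substr(vSeq, aV + 1L, aV + 3L + vExtra)
    jPart <- substr(jSeq, aJ + 1L - jExtra, aJ + 3L)
    d_call <- NA_character_
    dFrag <- ""
    if (useD) {
      d_call <- sample(dIds, 1L)
      dSeq <- seqs[[d_call]]
      trim5 <- min(rgeom(1L, 0.25), nchar(dSeq))
      trim3 <- min(rgeom(1L, 0.25), nchar(dSeq) - trim5)
      dFrag <- substr(dSeq, trim5 + 1L, nchar(dSeq) - trim3)
      if (nchar(dFrag) == 0L) d_call <- NA_character_
    }
    n1 <- .nAddLen(); n2 <- .nAddLen()
    if (npMode == "stop") n1 <- max(n1, 5L)  # room for an in-frame stop in the core
    len <- nchar(vPart) + n1 + nchar(dFrag) + n2 + nchar(jPart)
    if (productive || npMode == "stop") {
      n2 <- n2 + (3L - len %% 3L) %% 3L
    } else if (len %% 3L == 0L) {
      n2 <- n2 + sample(1:2, 1L)  # force a frameshift
    }
    n1seq <- paste(sample(.NT4, n1, replace = TRUE), collapse = "")
    n2seq <- paste(sample(.NT4, n2, replace = TRUE), collapse = "")
    cdr3 <- paste0(vPart, n1seq, dFrag, n2seq, jPart)
    if (!productive) break
    aa <- .translate(cdr3)
    if (!grepl("*", aa, fixed = TRUE)) break
  }
  if (npMode == "stop") {
    ## overwrite a codon lying wholly inside the non-templated N1 region
    ## (the stop must not sit on germline-templated positions)
    coreStart <- nchar(vPart) + 1L
    ncod <- nchar(cdr3) %/% 3L
    cand <- which(3L * seq_len(ncod) - 2L >= coreStart &
                    3L * seq_len(ncod) <= nchar(vPart) + n1)
    ci <- cand[sample.int(length(cand), 1L)]
    substr(cdr3, 3L * ci - 2L, 3L * ci) <- "TAA"
  }
  cdr3_aa <- if (nchar(cdr3) %% 3L == 0L) .translate(cdr3) else NA_character_

  amplicon <- paste0(.SMARTER_ANCHOR, substr(vSeq, 1L, aV), cdr3,
                     substr(jSeq, aJ + 4L, nchar(jSeq)), .CONST_STUB)
  list(v_call = v, d_call = d_call, j_call = j,
       cdr3_nt = cdr3, cdr3_aa = cdr3_aa, amplicon = amplicon,
       cdr3_start = nchar(.SMARTER_ANCHOR) + aV + 1L,
       n_from_v = nchar(vPart), n_from_d = nchar(dFrag),
       n_from_j = nchar(jPart), n_additions = n1 + n2,
       productive = productive)
}

#' Emit sequencing reads for one clonotype
#'
#' Produces \code{count} forward reads (the 5'-most \code{readLength} bases
#' of the amplicon) and \code{count} reverse reads (reverse complement of the
#' 3'-most \code{readLength} bases), with independent per-base substitution
#' errors at the configured rate. An amplicon shorter than the read length
#' yields full-amplicon reads.
#'
#' @param amplicon amplicon nucleotide string.
#' @param count clone read count (pairs emitted).
#' @param config a \code{\link{SimulationConfig}}.
#' @return list with \code{sequence} (character, 2*count reads, forward
#'   first) and \code{orientation} ("forward"/"reverse").
#' @export
emitReads <- function(amplicon, count, config = simulationConfig()) {
  stopifnot(count >= 1L)
  L <- nchar(amplicon)
  rl <- min(config@readLength, L)
  fwd <- substr(amplicon, 1L, rl)
  rev <- .revcomp(substr(amplicon, L - rl + 1L, L))
  seqs <- c(rep(fwd, count), rep(rev, count))
  if (config@perBaseErrorRate > 0) {
    nerr <- rbinom(length(seqs), rl, config@perBaseErrorRate)
    for (i in which(nerr > 0L)) {
      pos <- sample(rl, nerr[i])
      s <- strsplit(seqs[i], "")[[1]]
      s[pos] <- vapply(s[pos],
                       function(b) sample(setdiff(.NT4, b), 1L), character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  }
  list(sequence = seqs,
       orientation = rep(c("forward", "reverse"), each = count))
}

## Generate a clonotype whose (v_call, cdr3_aa, j_call) key is new to the
## study-wide registry, so planted sharing structure is exact.
.newClonotype <- function(germline, config, registry, productive = TRUE) {
  vIds <- segmentIds(germline)[segmentClass(germline) == "V"]
  jIds <- segmentIds(germline)[segmentClass(germline) == "J"]
  repeat {
    cl <- recombineClonotype(sample(vIds, 1L), sample(jIds, 1L), germline,
                             config, productive = productive)
    key <- if (productive) paste(cl$v_call, cl$cdr3_aa, cl$j_call, sep = "|")
           else paste("np", cl$v_call, cl$cdr3_nt, cl$j_call, sep = "|")
    if (!exists(key, envir = registry, inherits = FALSE)) {
      assign(key, TRUE, envir = registry)
      return(cl)
    }
  }
}

.cloneDf <- function(clones, counts) {
  data.frame(
    v_call = vapply(clones, `[[`, character(1), "v_call"),
    d_call = vapply(clones, `[[`, character(1), "d_call"),
    j_call = vapply(clones, `[[`, character(1), "j_call"),
    cdr3_nt = vapply(clones, `[[`, character(1), "cdr3_nt"),
    cdr3_aa = vapply(clones, function(x) as.character(x$cdr3_aa), character(1)),
    count = as.integer(counts),
    n_from_v = vapply(clones, `[[`, numeric(1), "n_from_v"),
    n_from_d = vapply(clones, `[[`, numeric(1), "n_from_d"),
    n_from_j = vapply(clones, `[[`, numeric(1), "n_from_j"),
    n_additions = vapply(clones, `[[`, numeric(1), "n_additions"),
    productive = vapply(clones, `[[`, logical(1), "productive"),
    amplicon = vapply(clones, `[[`, character(1), "amplicon"),
    cdr3_start = vapply(clones, `[[`, integer(1), "cdr3_start"),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic paired-compartment study
#'
#' Builds per-subject paired PB/CSF repertoires for the two disease groups
#' with planted ground truth: group-level public PB clonotypes (exclusive and
#' common pools shared by every subject of a group), a controlled PB/CSF
#' sharing fraction within each subject, hyperexpanded CSF spike-in clones
#' (a configurable number of which are also planted in the paired PB), and a
#' configurable rate of nonproductive rearrangements. Reads are then emitted
#' for every clone. The whole study is a deterministic function of the
#' config seed.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param outDir optional directory; when given, per-sample FASTQ files,
#'   truth clonotype tables, a manifest JSON, a sample sheet and a config
#'   echo YAML are written there.
#' @param germline germline reference (defaults to the packaged one).
#' @return list with \code{truth} (a \code{\link{RepertoireSet}} of the
#'   productive truth repertoires), \code{reads} (named list of
#'   \code{DNAStringSet}, one per sample), \code{manifest} (per-clone truth
#'   data.frame including nonproductive clones and planted flags) and
#'   \code{config}.
#' @export
generateStudy <- function(config = simulationConfig(), outDir = NULL,
                          germline = builtinGermline()) {
  set.seed(config@seed)
  registry <- new.env(hash = TRUE, parent = emptyenv())
  groups <- config@groups

  nShared <- round(config@pbCsfSharingFraction * config@nClonesCSF)
  if (nShared > config@nClonesCSF)
    stop("sharing fraction demands more shared clones than exist")

  common <- lapply(seq_len(config@publicCommon), function(i)
    .newClonotype(germline, config, registry))
  exclusive <- lapply(groups, function(g)
    lapply(seq_len(config@publicExclusive[[g]]), function(i)
      .newClonotype(germline, config, registry)))
  names(exclusive) <- groups

  truth <- list()
  reads <- list()
  manifest <- list()

  for (g in groups) {
    for (s in seq_len(config@nSubjectsPerGroup)) {
      subj <- sprintf("%s-%d", g, s)

      ## --- PB: public pool + private clones (some nonproductive) ---
      publics <- c(common, exclusive[[g]])
      nNonprod <- round(config@nClonesPB * config@nonproductiveRate)
      privates <- c(
        lapply(seq_len(config@nClonesPB - nNonprod), function(i)
          .newClonotype(germline, config, registry)),
        lapply(seq_len(nNonprod), function(i)
          .newClonotype(germline, config, registry, productive = FALSE)))
      pbClones <- c(publics, privates)
      pbCounts <- sampleCloneAbundances(length(pbClones), config,
                                        nSpikes = config@nSpikesPB)
      pbFlags <- c(rep("common", length(common)),
                   rep(g, length(exclusive[[g]])),
                   rep("", length(privates)))

      ## --- CSF: shared-with-PB subset + fresh clones + hyper spikes ---
      prodPriv <- which(vapply(privates, `[[`, logical(1), "productive"))
      sharedIdx <- sample(prodPriv, nShared)
      sharedClones <- privates[sharedIdx]
      nCsfNew <- config@nClonesCSF - nShared
      nCsfNonprod <- round(nCsfNew * config@nonproductiveRate)
      csfNew <- c(
        lapply(seq_len(nCsfNew - nCsfNonprod), function(i)
          .newClonotype(germline, config, registry)),
        lapply(seq_len(nCsfNonprod), function(i)
          .newClonotype(germline, config, registry, productive = FALSE)))
      spikes <- lapply(seq_len(config@nSpikesCSF), function(i)
        .newClonotype(germline, config, registry))
      csfClones <- c(sharedClones, csfNew, spikes)
      csfCounts <- c(sampleCloneAbundances(nShared + nCsfNew, config),
                     rep(config@spikeReadCount, config@nSpikesCSF))
      if (config@nSpikesCSF > 0 && config@spikeReadCount <= 10000L)
        warning("spikeReadCount <= 10,000: spikes will not be hyperexpanded")
      csfShared <- c(rep(TRUE, nShared), rep(FALSE, nCsfNew),
                     seq_len(config@nSpikesCSF) <= config@nSharedHyper)

      ## spikes shared with PB get planted there too, with a background count
      if (config@nSharedHyper > 0L) {
        sh <- spikes[seq_len(config@nSharedHyper)]
        pbClones <- c(pbClones, sh)
        pbCounts <- c(pbCounts, sampleCloneAbundances(config@nSharedHyper, config))
        pbFlags <- c(pbFlags, rep("", config@nSharedHyper))
      }
      pbShared <- c(rep(FALSE, length(pbClones) - config@nSharedHyper -
                          length(privates)), rep(FALSE, length(privates)),
                    rep(TRUE, config@nSharedHyper))
      pbShared[length(publics) + sharedIdx] <- TRUE

      for (comp in c("PB", "CSF")) {
        clones <- if (comp == "PB") pbClones else csfClones
        counts <- if (comp == "PB") pbCounts else csfCounts
        df <- .cloneDf(clones, counts)
        df$subject <- subj
        df$group <- g
        df$compartment <- comp
        df$clone_id <- sprintf("%s_%s_c%04d", subj, comp, seq_len(nrow(df)))
        df$public <- if (comp == "PB") pbFlags else rep("", nrow(df))
        df$shared_pb_csf <- if (comp == "PB") pbShared else csfShared
        df$spike <- counts > 10000L

        sampleReads <- vector("list", nrow(df))
        for (k in seq_len(nrow(df))) {
          em <- emitReads(df$amplicon[k], df$count[k], config)
          names(em$sequence) <- sprintf("%s|%s|%d",
                                        df$clone_id[k],
                                        substr(em$orientation, 1L, 1L),
                                        seq_along(em$sequence))
          sampleReads[[k]] <- em$sequence
        }
        allReads <- unlist(sampleReads, use.names = TRUE)
        rs <- Biostrings::DNAStringSet(allReads)
        sampleName <- paste(subj, comp, sep = "_")
        reads[[sampleName]] <- rs
        manifest[[sampleName]] <- df

        prod <- df[df$productive, , drop = FALSE]
        truth[[sampleName]] <- Repertoire(
          prod[, c("v_call", "d_call", "j_call", "cdr3_nt", "cdr3_aa", "count",
                   "n_from_v", "n_from_d", "n_from_j", "n_additions")],
          subject = subj, group = g, compartment = comp,
          cellCount = if (comp == "PB") config@cellCountPB else config@cellCountCSF)
      }
    }
  }

  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  out <- list(truth = RepertoireSet(truth), reads = reads,
              manifest = manifest, config = config)
  if (!is.null(outDir)) writeStudy(out, outDir)
  out
}

#' Write a simulated study to disk
#'
#' Writes per-sample FASTQ files (constant placeholder qualities), truth
#' clonotype tables, the clone manifest (JSON), a sample sheet and a config
#' echo (YAML) under \code{outDir}.
#'
#' @param study result of \code{\link{generateStudy}}.
#' @param outDir output directory (created if absent).
#' @return \code{outDir}, invisibly.
#' @export
writeStudy <- function(study, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  info <- sampleInfo(study$truth)
  info$fastq <- paste0(info$subject, "_", info$compartment, ".fastq")
  for (i in seq_len(nrow(info))) {
    nm <- paste(info$subject[i], info$compartment[i], sep = "_")
    rs <- study$reads[[nm]]
    quals <- Biostrings::BStringSet(vapply(Biostrings::width(rs),
                                           function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(rs, file.path(outDir, info$fastq[i]),
                                format = "fastq", qualities = quals)
    writeClonotypeTable(study$truth[[nm]],
                        file.path(outDir, paste0(nm, "_truth.tsv")))
  }
  write.table(info, file.path(outDir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man <- study$manifest
  man$amplicon <- NULL
  jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                       dataframe = "columns", digits = NA)
  cfg <- study$config
  slots <- slotNames(cfg)
  yaml::write_yaml(setNames(lapply(slots, function(s) slot(cfg, s)), slots),
                   file.path(outDir, "config.yaml"))
  invisible(outDir)
}

#' Which reads of a clone span the junction?
#'
#' A read spans the junction when its window contains the complete CDR3 plus
#' at least \code{flank} nucleotides of V context upstream and J context
#' downstream — the minimum alignable context for a segment call. Forward
#' reads cover the 5'-most \code{readLength} bases of the amplicon, reverse
#' reads the 3'-most.
#'
#' @param manifest clone manifest rows (needs \code{amplicon},
#'   \code{cdr3_start}, \code{cdr3_nt}).
#' @param orientation \code{"forward"} or \code{"reverse"}.
#' @param readLength read length in bases.
#' @param flank minimum flanking context per side (default the segment call
#'   score threshold).
#' @return logical vector, one per manifest row.
#' @export
junctionSpanning <- function(manifest, orientation, readLength = 150L,
                             flank = 20L) {
  L <- nchar(manifest$amplicon)
  s <- manifest$cdr3_start
  e <- s + nchar(manifest$cdr3_nt) - 1L
  if (orientation == "forward") {
    s - flank >= 1L & e + flank <= pmin(readLength, L)
  } else {
    s - flank >= pmax(1L, L - readLength + 1L) & e + flank <= L
  }
}

#' Simulate CDR3 motif families
#'
#' Generates CDR3 amino-acid sequences in planted families: members of one
#' family share a fixed core motif at a fixed position, with random flanking
#' residues. Used to exercise the motif clustering machinery against known
#' labels.
#'
#' @param nFamilies number of families.
#' @param perFamily sequences per family.
#' @param coreLength shared core motif length.
#' @param totalLength CDR3 length (C...F inclusive).
#' @param corePos 1-based position of the core within the CDR3.
#' @return data.frame with columns \code{sequence}, \code{family}.
#' @export
simulateMotifFamilies <- function(nFamilies = 4L, perFamily = 8L,
                                  coreLength = 6L, totalLength = 14L,
                                  corePos = 5L) {
  stopifnot(corePos + coreLength - 1L < totalLength)
  res <- lapply(seq_len(nFamilies), function(f) {
    core <- paste(sample(.AA20, coreLength, replace = TRUE), collapse = "")
    seqs <- vapply(seq_len(perFamily), function(i) {
      left <- paste(sample(.AA20, corePos - 2L, replace = TRUE), collapse = "")
      right <- paste(sample(.AA20, totalLength - corePos - coreLength,
                            replace = TRUE), collapse = "")
      paste0("C", left, core, right, "F")
    }, character(1))
    data.frame(sequence = seqs, family = f)
  })
  out <- do.call(rbind, res)
  out[!duplicated(out$sequence), , drop = FALSE]
}

#' Simulate two CDR3 groups with a planted consensus difference
#'
#' Both groups draw from the same positional scaffold consensus (each
#' position keeps the scaffold residue with probability \code{conservation},
#' otherwise a random residue), but the positions in \code{divergentPos} are
#' fixed to \code{residueA} in group A and \code{residueB} in group B. Used
#' to exercise the group-consensus comparison.
#'
#' @param nPerGroup sequences per group.
#' @param totalLength CDR3 length.
#' @param divergentPos 1-based positions carrying the planted difference.
#' @param residueA,residueB residues planted at those positions.
#' @param conservation probability of keeping the scaffold residue elsewhere.
#' @return list with character vectors \code{A} and \code{B}.
#' @export
simulateConsensusGroups <- function(nPerGroup = 30L, totalLength = 14L,
                                    divergentPos = c(8L, 9L),
                                    residueA = "G", residueB = "S",
                                    conservation = 0.7) {
  scaffold <- c("C", sample(.AA20, totalLength - 2L, replace = TRUE), "F")
  draw <- function(res) {
    vapply(seq_len(nPerGroup), function(i) {
      s <- vapply(seq_len(totalLength), function(p) {
        if (p == 1L || p == totalLength || runif(1L) < conservation)
          scaffold[p] else sample(.AA20, 1L)
      }, character(1))
      s[divergentPos] <- res
      paste(s, collapse = "")
    }, character(1))
  }
  list(A = draw(residueA), B = draw(residueB))
}
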