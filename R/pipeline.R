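## File-based pipeline orchestration: simulate -> annotate -> diversity ->
## expansion -> share -> motif -> report. Every stage reads its inputs from
## and writes its outputs to a run directory, so each stage is independently
## testable and a rerun with the same config and seed reproduces identical
## outputs.

.STAGES <- c("simulate", "annotate", "diversity", "expansion", "share",
             "motif", "report")

#' Pipeline run configuration
#'
#' Bundles the simulator config with the analysis parameters of the
#' downstream stages. Unknown arguments are rejected.
#'
#' @param sim a \code{\link{SimulationConfig}}.
#' @param keyMode clonotype key mode for sharing analyses.
#' @param entropyBase logarithm base for entropy.
#' @param minScore minimum segment alignment score.
#' @param smallThreshold,hyperThreshold expansion bin thresholds.
#' @param windowPB,windowCSF log2 percent-frequency windows of the
#'   differentially expanded ranges used for the windowed sharing view.
#' @param clusterHeight,clusterMinSize motif cluster cut parameters.
#' @return list of class \code{"tcr_run_config"}.
#' @export
runConfig <- function(sim = simulationConfig(), keyMode = "v_cdr3_j",
                      entropyBase = exp(1), minScore = 20,
                      smallThreshold = 100, hyperThreshold = 10000,
                      windowPB = c(-9.9, -5.1), windowCSF = c(-5.7, -3.2),
                      clusterHeight = 0.6, clusterMinSize = 2L) {
  stopifnot(is(sim, "SimulationConfig"),
            keyMode %in% c("v_cdr3_j", "cdr3_aa"))
  structure(list(sim = sim, keyMode = keyMode, entropyBase = entropyBase,
                 minScore = minScore, smallThreshold = smallThreshold,
                 hyperThreshold = hyperThreshold, windowPB = windowPB,
                 windowCSF = windowCSF, clusterHeight = clusterHeight,
                 clusterMinSize = as.integer(clusterMinSize)),
            class = "tcr_run_config")
}

.needs <- function(outDir, path, stage, neededBy) {
  f <- file.path(outDir, path)
  if (!file.exists(f))
    stop("stage '", neededBy, "' needs output of stage '", stage,
         "'; run it first (missing ", path, ")", call. = FALSE)
  f
}

.readStudyRepertoires <- function(outDir) {
  samples <- read.delim(file.path(outDir, "sim", "samples.tsv"))
  reps <- lapply(seq_len(nrow(samples)), function(i) {
    nm <- paste(samples$subject[i], samples$compartment[i], sep = "_")
    readClonotypeTable(file.path(outDir, "rep", paste0(nm, "_clonotypes.tsv")))
  })
  RepertoireSet(reps)
}

#' Run one pipeline stage
#'
#' Executes a single stage against a run directory, checking that the
#' prerequisite stage outputs exist. Stages: \code{simulate} (write the
#' synthetic study), \code{annotate} (FASTQ -> clonotype tables),
#' \code{diversity} (per-sample metrics), \code{expansion} (bin counts and
#' expansion profiles), \code{share} (public clonotypes, group overlap,
#' cross-compartment hyperexpanded table), \code{motif} (clustering of the
#' group-exclusive shared PB clonotypes), \code{report} (merged JSON
#' report).
#'
#' @param stage stage name.
#' @param outDir run directory.
#' @param config a \code{\link{runConfig}}.
#' @param germline germline reference for annotation.
#' @return invisibly, the stage's primary output (varies by stage).
#' @export
runStage <- function(stage, outDir, config = runConfig(),
                     germline = builtinGermline()) {
  stage <- match.arg(stage, .STAGES)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      study <- generateStudy(config$sim, outDir = file.path(outDir, "sim"))
      invisible(study)
    },
    annotate = {
      sheet <- .needs(outDir, file.path("sim", "samples.tsv"),
                      "simulate", "annotate")
      samples <- read.delim(sheet)
      dir.create(file.path(outDir, "rep"), showWarnings = FALSE)
      log <- list()
      for (i in seq_len(nrow(samples))) {
        nm <- paste(samples$subject[i], samples$compartment[i], sep = "_")
        reads <- readSequencingReads(file.path(outDir, "sim",
                                               samples$fastq[i]))
        ann <- annotateReads(reads, germline, minScore = config$minScore)
        rep <- collapseClonotypes(ann, samples$subject[i], samples$group[i],
                                  samples$compartment[i],
                                  samples$cell_count[i])
        rep <- germlineContributions(rep, germline)
        writeClonotypeTable(rep, file.path(outDir, "rep",
                                           paste0(nm, "_clonotypes.tsv")))
        log[[nm]] <- c(list(n_reads = length(reads)),
                       attr(ann, "fate_tally"))
      }
      jsonlite::write_json(log, file.path(outDir, "rep",
                                          "annotation_log.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(log)
    },
    diversity = {
      .needs(outDir, "rep", "annotate", "diversity")
      reps <- .readStudyRepertoires(outDir)
      div <- studyDiversity(reps, base = config$entropyBase)
      dir.create(file.path(outDir, "diversity"), showWarnings = FALSE)
      write.table(div, file.path(outDir, "diversity", "metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(div)
    },
    expansion = {
      .needs(outDir, "rep", "annotate", "expansion")
      reps <- .readStudyRepertoires(outDir)
      dir.create(file.path(outDir, "expansion"), showWarnings = FALSE)
      bins <- lapply(seq_len(length(reps)), function(i) {
        r <- reps[[i]]
        b <- binExpansion(r, config$smallThreshold, config$hyperThreshold)
        prof <- expansionProfile(r, keyMode = config$keyMode)
        nm <- paste(subjectId(r), compartment(r), sep = "_")
        write.table(prof, file.path(outDir, "expansion",
                                    paste0(nm, "_profile.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        data.frame(subject = subjectId(r), group = groupLabel(r),
                   compartment = compartment(r), small = b[["small"]],
                   intermediate = b[["intermediate"]],
                   hyperexpanded = b[["hyperexpanded"]])
      })
      bins <- do.call(rbind, c(bins, make.row.names = FALSE))
      write.table(bins, file.path(outDir, "expansion", "bins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(bins)
    },
    share = {
      .needs(outDir, "rep", "annotate", "share")
      reps <- .readStudyRepertoires(outDir)
      groups <- unique(sampleInfo(reps)$group)
      dir.create(file.path(outDir, "share"), showWarnings = FALSE)
      sets <- list()
      rows <- list()
      for (g in groups) for (comp in c("PB", "CSF")) {
        sub <- filterSamples(reps, group = g, compartment = comp)
        keys <- sharedClonotypes(sub, keyMode = config$keyMode)
        sets[[paste(g, comp, sep = "_")]] <- keys
        if (length(keys) > 0)
          rows[[paste(g, comp)]] <- data.frame(group = g, compartment = comp,
                                               key = keys)
      }
      shared_tab <- if (length(rows) > 0)
        do.call(rbind, c(rows, make.row.names = FALSE))
      else data.frame(group = character(0), compartment = character(0),
                      key = character(0))
      write.table(shared_tab, file.path(outDir, "share", "shared_sets.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ec <- exclusiveAndCommon(sets[[paste0(groups[1], "_PB")]],
                               sets[[paste0(groups[2], "_PB")]])
      summary <- list(
        pb = setNames(list(length(sets[[paste0(groups[1], "_PB")]]),
                           length(sets[[paste0(groups[2], "_PB")]]),
                           ec$common, ec$a_only, ec$b_only),
                      c(groups[1], groups[2], "common",
                        paste0(groups[1], "_only"),
                        paste0(groups[2], "_only"))),
        csf = setNames(list(length(sets[[paste0(groups[1], "_CSF")]]),
                            length(sets[[paste0(groups[2], "_CSF")]])),
                       groups))
      jsonlite::write_json(summary, file.path(outDir, "share",
                                              "sharing_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      cc <- crossCompartmentTable(reps, config$hyperThreshold)
      write.table(cc, file.path(outDir, "share", "cross_compartment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE, na = "")
      invisible(summary)
    },
    motif = {
      .needs(outDir, file.path("share", "shared_sets.tsv"), "share", "motif")
      shared <- read.delim(file.path(outDir, "share", "shared_sets.tsv"))
      groups <- unique(shared$group)
      dir.create(file.path(outDir, "motif"), showWarnings = FALSE)
      cdr3Of <- function(keys) {
        if (config$keyMode == "cdr3_aa") keys
        else vapply(strsplit(keys, "|", fixed = TRUE), `[[`, character(1), 2L)
      }
      pbsets <- lapply(groups, function(g)
        shared$key[shared$group == g & shared$compartment == "PB"])
      names(pbsets) <- groups
      ec <- exclusiveAndCommon(pbsets[[1]], pbsets[[2]])
      excl <- list(cdr3Of(ec$a_only_keys), cdr3Of(ec$b_only_keys))
      names(excl) <- groups
      out <- list()
      for (g in groups) {
        seqs <- unique(excl[[g]])
        if (length(seqs) < 3L) next
        tree <- buildTree(seqs)
        treeNewick(tree, file.path(outDir, "motif",
                                   paste0(g, "_pb_tree.nwk")))
        clusters <- cutClusters(tree, height = config$clusterHeight,
                                minSize = config$clusterMinSize)
        memb <- do.call(rbind, lapply(clusters, function(cl)
          data.frame(cluster_id = cl$cluster_id, member = cl$members,
                     consensus = cl$consensus)))
        if (!is.null(memb))
          write.table(memb, file.path(outDir, "motif",
                                      paste0(g, "_pb_clusters.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        out[[g]] <- list(n_sequences = length(seqs),
                         n_clusters = length(clusters))
      }
      if (all(lengths(excl) > 0)) {
        cmp <- groupConsensusComparison(excl[[1]], excl[[2]])
        jsonlite::write_json(
          list(length = cmp$length, consensusA = cmp$consensusA,
               consensusB = cmp$consensusB,
               differing_positions = cmp$differing_positions,
               groupA = groups[1], groupB = groups[2]),
          file.path(outDir, "motif", "consensus_comparison.json"),
          auto_unbox = TRUE, digits = NA)
        out$consensus_comparison <- cmp[c("length", "consensusA",
                                          "consensusB",
                                          "differing_positions")]
      }
      jsonlite::write_json(out, file.path(outDir, "motif",
                                          "motif_summary.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      invisible(out)
    },
    report = buildReport(outDir, config))
}

#' Run the full pipeline
#'
#' Runs all stages in order against \code{outDir}. Fully deterministic for
#' a fixed simulator seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir run directory.
#' @param stages stages to run (default all, in order).
#' @param germline germline reference.
#' @return the report list, invisibly (when the report stage runs).
#' @export
runStudy <- function(config = runConfig(), outDir,
                     stages = .STAGES, germline = builtinGermline()) {
  res <- NULL
  for (s in stages) res <- runStage(s, outDir, config, germline)
  invisible(res)
}

#' Assemble the study report
#'
#' Merges the stage outputs of a run directory into one machine-readable
#' report: per-sample metrics, PB-vs-CSF and group diversity comparisons
#' with exact Wilcoxon p-values and leave-one-out ranges, expansion bin
#' counts, the cross-compartment hyperexpanded table and the clonotype
#' sharing counts. Every number is read from a stage output file.
#'
#' @param outDir run directory with completed stages.
#' @param config a \code{\link{runConfig}}.
#' @return the report list (also written to \code{report.json}); sections
#'   whose stage has not run are marked unavailable.
#' @export
buildReport <- function(outDir, config = runConfig()) {
  report <- list()
  divFile <- file.path(outDir, "diversity", "metrics.tsv")
  if (file.exists(divFile)) {
    div <- read.delim(divFile)
    report$diversity <- div
    groups <- unique(div$group)
    pb <- div[div$compartment == "PB", ]
    csf <- div[div$compartment == "CSF", ]
    ord <- match(pb$subject, csf$subject)
    stats <- list()
    ## paired PB vs CSF, all subjects (richness and normalized entropy)
    for (metric in c("richness", "normalized_entropy")) {
      w <- suppressWarnings(wilcoxonSignedRank(pb[[metric]],
                                               csf[[metric]][ord]))
      loo <- suppressWarnings(leaveOneOutPvalues(pb[[metric]],
                                                 csf[[metric]][ord],
                                                 test = "paired"))
      stats[[paste0("pb_vs_csf_", metric)]] <-
        list(test = "paired_wilcoxon", statistic = w$statistic,
             p_value = w$p_value, loo_p_min = loo$p_min,
             loo_p_max = loo$p_max)
    }
    ## unpaired group comparison per compartment (normalized entropy)
    for (comp in c("PB", "CSF")) {
      d <- div[div$compartment == comp, ]
      a <- d$normalized_entropy[d$group == groups[1]]
      b <- d$normalized_entropy[d$group == groups[2]]
      w <- suppressWarnings(wilcoxonRankSum(a, b))
      loo <- suppressWarnings(leaveOneOutPvalues(a, b, test = "unpaired"))
      stats[[paste0(tolower(comp), "_group_diversity")]] <-
        list(test = "unpaired_wilcoxon", statistic = w$statistic,
             p_value = w$p_value, loo_p_min = loo$p_min,
             loo_p_max = loo$p_max)
    }
    report$stats <- stats
  } else report$diversity <- "unavailable"

  binFile <- file.path(outDir, "expansion", "bins.tsv")
  report$expansion_bins <- if (file.exists(binFile))
    read.delim(binFile) else "unavailable"

  shareFile <- file.path(outDir, "share", "sharing_summary.json")
  report$sharing <- if (file.exists(shareFile))
    jsonlite::read_json(shareFile) else "unavailable"

  ccFile <- file.path(outDir, "share", "cross_compartment.tsv")
  report$cross_compartment <- if (file.exists(ccFile))
    read.delim(ccFile) else "unavailable"

  motifFile <- file.path(outDir, "motif", "motif_summary.json")
  report$motifs <- if (file.exists(motifFile))
    jsonlite::read_json(motifFile) else "unavailable"

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       force = TRUE)
  invisible(report)
}
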