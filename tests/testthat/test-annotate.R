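test_that("segment assignment handles identity, reverse complement and noise", {
  g <- builtinGermline()
  vIds <- segmentIds(g)[segmentClass(g) == "V"]
  vSub <- g[vIds]
  refSeq <- as.character(segmentSequences(g))[["TRBV7-2"]]

  # verbatim reference -> that segment, full-length score
  call <- assignSegment(refSeq, vSub)
  expect_equal(call$segment_id, "TRBV7-2")
  expect_equal(call$score, nchar(refSeq))
  expect_equal(call$strand, "forward")

  # reverse complement of a J -> that segment, reverse strand
  jSeq <- as.character(segmentSequences(g))[["TRBJ2-3"]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(jSeq)))
  jSub <- g[segmentIds(g)[segmentClass(g) == "J"]]
  call2 <- assignSegment(rc, jSub)
  expect_equal(call2$segment_id, "TRBJ2-3")
  expect_equal(call2$strand, "reverse")

  # 2 substitutions vs the true V still win over all other references
  mut <- refSeq
  substr(mut, 10, 10) <- "A"
  substr(mut, 40, 40) <- "C"
  call3 <- assignSegment(mut, vSub)
  expect_equal(call3$segment_id, "TRBV7-2")

  # a read unrelated to any reference yields no call
  set.seed(21)
  junk <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  call4 <- assignSegment(junk, vSub, minScore = 30)
  expect_true(is.na(call4$segment_id))
})

test_that("segment assignment agrees with exhaustive per-reference scoring", {
  g <- builtinGermline()
  cfg <- simulationConfig(perBaseErrorRate = 0.02)
  set.seed(22)
  vIds <- segmentIds(g)[segmentClass(g) == "V"]
  jIds <- segmentIds(g)[segmentClass(g) == "J"]
  reads <- unlist(lapply(1:40, function(i) {
    cl <- recombineClonotype(sample(vIds, 1), sample(jIds, 1), g)
    emitReads(cl$amplicon, 1L, cfg)$sequence
  }))
  vSub <- g[vIds]
  calls <- assignSegment(reads, vSub)

  # independent oracle: score every read against every reference on both
  # strands with plain pairwiseAlignment calls, pick the best
  mat <- matrix(-1, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                          c("A","C","G","T","N")))
  diag(mat) <- 1; mat["N", ] <- 0; mat[, "N"] <- 0
  for (k in seq_along(reads)) {
    best <- -Inf; bestId <- NA
    for (id in sort(vIds)) {
      for (strand in c("f", "r")) {
        rd <- if (strand == "f") reads[[k]] else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(reads[[k]])))
        sc <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(rd),
          segmentSequences(g)[[id]], type = "local",
          substitutionMatrix = mat, gapOpening = 3, gapExtension = 1,
          scoreOnly = TRUE)
        if (sc > best) { best <- sc; bestId <- id }
      }
    }
    expect_equal(calls$segment_id[k], bestId)
    expect_equal(calls$score[k], best)
  }
})

test_that("productivity classification covers all reasons", {
  res <- classifyProductive(c("TGTGCCTTT", "TGTGCCTTTA", "TGTTAATTT",
                              "TGTGCNTTT"))
  expect_equal(res$productive, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$reason, c("ok", "frameshift", "stop", "ambiguous"))
})

test_that("CDR3 extraction recovers the planted junction", {
  g <- builtinGermline()
  set.seed(23)
  cl <- recombineClonotype("TRBV20-1", "TRBJ1-3", g)
  em <- emitReads(cl$amplicon, 1L)
  res <- extractCDR3(em$sequence[1], "TRBV20-1", "TRBJ1-3", g)
  expect_equal(res$cdr3_nt, cl$cdr3_nt)
  expect_equal(res$cdr3_aa, cl$cdr3_aa)

  # a read truncated before the J anchor yields no junction
  short <- substr(em$sequence[1], 1, cl$cdr3_start + 2)
  res2 <- extractCDR3(short, "TRBV20-1", "TRBJ1-3", g)
  expect_true(is.na(res2$cdr3_nt))
})

test_that("clonotype collapsing conserves productive read counts", {
  g <- builtinGermline()
  set.seed(24)
  vIds <- segmentIds(g)[segmentClass(g) == "V"]
  jIds <- segmentIds(g)[segmentClass(g) == "J"]
  clones <- lapply(1:30, function(i)
    recombineClonotype(sample(vIds, 1), sample(jIds, 1), g,
                       productive = i %% 5 != 0))
  counts <- sample(1:6, 30, replace = TRUE)
  reads <- unlist(lapply(seq_along(clones), function(i)
    emitReads(clones[[i]]$amplicon, counts[i])$sequence))
  ann <- annotateReads(reads, g)
  rep <- collapseClonotypes(ann, "S1", "MS", "PB", 1e5)
  expect_equal(totalReads(rep), sum(ann$productive))
  # per-clone counts match the emitted multiplicities (2 reads per count)
  truthKeys <- vapply(clones, function(cl)
    paste(cl$v_call, cl$cdr3_aa, cl$j_call, sep = "|"), character(1))
  prodIdx <- which(vapply(clones, `[[`, logical(1), "productive"))
  cl <- clonotypes(rep)
  recovered <- setNames(cl$count, paste(cl$v_call, cl$cdr3_aa, cl$j_call,
                                        sep = "|"))
  expect_equal(unname(recovered[truthKeys[prodIdx]]), 2L * counts[prodIdx])

  # no productive annotations -> empty repertoire with warning
  npAnn <- ann[ann$productive %in% FALSE, ]
  expect_warning(empty <- collapseClonotypes(npAnn, "S1", "MS", "PB", 10),
                 "productive")
  expect_equal(richness(empty), 0L)
})

test_that("germline contribution decomposition matches brute force", {
  g <- tinyGermline()
  # wholly V+J explained junction: no D, no additions
  seqs <- as.character(segmentSequences(g))
  vTail <- substr(seqs[["TRBV1"]], 21, 26)   # TGTGCA
  jHead <- substr(seqs[["TRBJ1"]], 8, 13)    # from before anchor through TTC
  cdr3 <- paste0(vTail, jHead)
  r <- Repertoire(data.frame(v_call = "TRBV1", j_call = "TRBJ1",
                             cdr3_nt = cdr3,
                             cdr3_aa = as.character(Biostrings::translate(
                               Biostrings::DNAString(cdr3))),
                             count = 1L),
                  "S", "MS", "PB", 10)
  out <- clonotypes(germlineContributions(r, g))
  expect_equal(out$n_additions, 0L)
  expect_equal(out$n_from_v + out$n_from_j, nchar(cdr3))
  expect_equal(out$n_from_d, 0L)

  # D detection: core GGGACAGGGGGC against a D containing ACAGGGG
  g2 <- GermlineSet(
    c(TRBV1 = paste0(strrep("A", 20), "TGT"),
      TRBJ1 = paste0("CCCCCCCCC", "TTC"),
      TRBD9 = "TACAGGGGT"),
    segmentClass = c("V", "J", "D"), anchorIndex = c(20L, 9L, NA))
  core <- "GGGACAGGGGGC"
  cdr3b <- paste0("TGT", core, "CCCCCCCCCTTC")
  r2 <- Repertoire(data.frame(v_call = "TRBV1", j_call = "TRBJ1",
                              cdr3_nt = cdr3b,
                              cdr3_aa = as.character(Biostrings::translate(
                                Biostrings::DNAString(cdr3b))),
                              count = 1L),
                   "S", "MS", "PB", 10)
  out2 <- clonotypes(germlineContributions(r2, g2))
  expect_equal(out2$n_from_d, 7L)  # ACAGGGG
  expect_equal(out2$d_call, "TRBD9")

  # brute-force oracle on random cores: longest substring present in any D
  set.seed(25)
  g3 <- builtinGermline()
  dSeqs <- as.character(segmentSequences(g3))[segmentClass(g3) == "D"]
  for (i in 1:25) {
    core <- paste(sample(c("A", "C", "G", "T"), 3L * sample(2:4, 1),
                         replace = TRUE), collapse = "")
    cdr3c <- paste0("TGC", core, "TTC")
    vSeq <- as.character(segmentSequences(g3))[["TRBV2"]]
    jSeq <- as.character(segmentSequences(g3))[["TRBJ1-1"]]
    aV <- anchorIndex(g3)[["TRBV2"]]; aJ <- anchorIndex(g3)[["TRBJ1-1"]]
    # oracle: recompute the V/J extensions and scan all substrings
    vt <- substr(vSeq, aV + 1, nchar(vSeq))
    jh <- substr(jSeq, 1, aJ + 3)
    pre <- 0L
    while (pre < min(nchar(cdr3c), nchar(vt)) &&
           substr(cdr3c, pre + 1, pre + 1) == substr(vt, pre + 1, pre + 1))
      pre <- pre + 1L
    suf <- 0L
    while (suf < min(nchar(cdr3c) - pre, nchar(jh)) &&
           substr(cdr3c, nchar(cdr3c) - suf, nchar(cdr3c) - suf) ==
           substr(jh, nchar(jh) - suf, nchar(jh) - suf))
      suf <- suf + 1L
    mid <- substr(cdr3c, pre + 1, nchar(cdr3c) - suf)
    bestD <- 0L
    if (nchar(mid) > 0) {
      for (L in seq_len(nchar(mid))) {
        for (st in 1:(nchar(mid) - L + 1)) {
          if (any(vapply(dSeqs, function(d)
            grepl(substr(mid, st, st + L - 1), d, fixed = TRUE), logical(1))))
            bestD <- max(bestD, L)
        }
      }
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cdr3c)))
    rr <- Repertoire(data.frame(v_call = "TRBV2", j_call = "TRBJ1-1",
                                cdr3_nt = cdr3c, cdr3_aa = aa,
                                count = 1L),
                     "S", "MS", "PB", 10)
    # only the D component is compared against the oracle here
    outc <- clonotypes(germlineContributions(rr, g3))
    expect_equal(outc$n_from_d, bestD)
  }
})

test_that("repertoire summaries are normalized distributions", {
  r <- tinyRepertoire(counts = c(2L, 2L))
  s <- repertoireSummaries(r)
  expect_equal(sum(s$lengthDistribution), 1)
  expect_equal(sum(s$vjPairing), 100)
  # two clonotypes, equal counts, different J: 50/50 cells
  expect_true(all(s$vjPairing[s$vjPairing > 0] == 50))
  for (m in s$aaComposition) expect_equal(unname(colSums(m)), rep(1, ncol(m)))
  # position 1 is always the conserved C
  expect_equal(unname(s$aaComposition[[1]]["C", 1]), 1)
})
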