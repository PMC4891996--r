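test_that("clone abundance sampling honours model and spikes", {
  cfg <- simulationConfig(abundanceModel = "uniform", uniformCount = 10L)
  set.seed(1)
  expect_equal(sampleCloneAbundances(10L, cfg), rep(10L, 10))

  cfg2 <- simulationConfig(spikeReadCount = 12000L)
  set.seed(2)
  counts <- sampleCloneAbundances(1000L, cfg2, nSpikes = 2L)
  expect_equal(sum(counts == 12000L), 2L)
  expect_true(all(counts >= 1L))

  # a spike count at or below the hyperexpansion threshold warns
  cfg3 <- simulationConfig(spikeReadCount = 9000L)
  expect_warning(sampleCloneAbundances(100L, cfg3, nSpikes = 1L),
                 "hyperexpanded")
})

test_that("power-law abundances have the expected rank-abundance shape", {
  # P(k) ~ k^-a with a = 1.5 gives a log-log rank-abundance slope near
  # -1/(a-1) = -2
  # truncation must not bind: expected top counts are (n/rank)^2, so the
  # cap is set well above them and central ranks are fitted (extreme order
  # statistics are noisy, deep ranks discreteness-flattened)
  cfg <- simulationConfig(abundanceModel = "power_law", powerExponent = 1.5,
                          abundanceMax = 1000000L)
  set.seed(3)
  counts <- sampleCloneAbundances(10000L, cfg)
  sorted <- sort(counts, decreasing = TRUE)
  keep <- 30:3000
  fit <- lm(log(sorted[keep]) ~ log(keep))
  expect_lt(abs(unname(coef(fit)[2]) - (-2)), 0.2)
})

test_that("recombined productive clonotypes satisfy the CDR3 contract", {
  g <- builtinGermline()
  set.seed(4)
  vIds <- segmentIds(g)[segmentClass(g) == "V"]
  jIds <- segmentIds(g)[segmentClass(g) == "J"]
  for (i in 1:150) {
    cl <- recombineClonotype(sample(vIds, 1), sample(jIds, 1), g)
    expect_equal(nchar(cl$cdr3_nt) %% 3L, 0L)
    expect_match(cl$cdr3_aa, "^C")
    expect_match(cl$cdr3_aa, "F$")
    expect_false(grepl("*", cl$cdr3_aa, fixed = TRUE))
    expect_equal(cl$n_from_v + cl$n_from_d + cl$n_from_j + cl$n_additions,
                 nchar(cl$cdr3_nt))
    # the amplicon embeds the CDR3 at the recorded coordinate
    expect_equal(substr(cl$amplicon, cl$cdr3_start,
                        cl$cdr3_start + nchar(cl$cdr3_nt) - 1L), cl$cdr3_nt)
  }
  # nonproductive clones are frameshifted or contain a stop
  set.seed(5)
  for (i in 1:40) {
    cl <- recombineClonotype(sample(vIds, 1), sample(jIds, 1), g,
                             productive = FALSE)
    bad <- nchar(cl$cdr3_nt) %% 3L != 0L ||
      grepl("*", cl$cdr3_aa, fixed = TRUE)
    expect_true(bad)
  }
})

test_that("productive recombinations all pass the annotator's classifier", {
  g <- builtinGermline()
  set.seed(6)
  vIds <- segmentIds(g)[segmentClass(g) == "V"]
  jIds <- segmentIds(g)[segmentClass(g) == "J"]
  nt <- vapply(1:300, function(i)
    recombineClonotype(sample(vIds, 1), sample(jIds, 1), g)$cdr3_nt,
    character(1))
  cls <- classifyProductive(nt)
  expect_true(all(cls$productive))
})

test_that("read emission is exact at error rate 0 and calibrated at 1%", {
  g <- builtinGermline()
  set.seed(7)
  cl <- recombineClonotype("TRBV9", "TRBJ1-5", g)
  em <- emitReads(cl$amplicon, 5L)
  expect_equal(length(em$sequence), 10L)
  expect_equal(sum(em$orientation == "forward"), 5L)
  # error rate 0: every read is an exact substring of the amplicon (forward)
  # or of its reverse complement (reverse)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cl$amplicon)))
  for (i in seq_along(em$sequence)) {
    hay <- if (em$orientation[i] == "forward") cl$amplicon else rc
    expect_true(grepl(em$sequence[i], hay, fixed = TRUE))
  }

  # 1% errors: observed mismatch fraction within the binomial 99% CI
  cfg <- simulationConfig(perBaseErrorRate = 0.01)
  set.seed(8)
  n <- 100L
  em2 <- emitReads(cl$amplicon, n, cfg)
  truthFwd <- substr(cl$amplicon, 1, 150)
  mism <- sum(vapply(em2$sequence[em2$orientation == "forward"], function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(truthFwd, "")[[1]])
  }, numeric(1)))
  bases <- n * 150L
  ci <- qbinom(c(0.005, 0.995), bases, 0.01)
  expect_gte(mism, ci[1])
  expect_lte(mism, ci[2])
})

test_that("study generation is deterministic and conserves reads", {
  cfg <- smallStudyConfig(seed = 33L)
  s1 <- generateStudy(cfg)
  s2 <- generateStudy(cfg)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(lapply(s1$reads, as.character),
                   lapply(s2$reads, as.character))
  # conservation: reads per sample equal twice the summed manifest counts
  for (nm in names(s1$reads)) {
    man <- s1$manifest[paste(s1$manifest$subject, s1$manifest$compartment,
                             sep = "_") == nm, ]
    expect_equal(length(s1$reads[[nm]]), 2L * sum(man$count))
  }
})

test_that("planted sharing structure is exact by construction", {
  cfg <- smallStudyConfig(seed = 12L)
  study <- generateStudy(cfg)
  man <- study$manifest
  # PB/CSF sharing per subject: round(fraction * nClonesCSF) clone keys
  nShared <- round(0.2 * 10)
  for (s in unique(man$subject)) {
    pb <- man[man$subject == s & man$compartment == "PB" & man$productive, ]
    csf <- man[man$subject == s & man$compartment == "CSF" & man$productive, ]
    keyOf <- function(d) paste(d$v_call, d$cdr3_aa, d$j_call)
    expect_equal(length(intersect(keyOf(pb), keyOf(csf))),
                 nShared + cfg@nSharedHyper)
  }
  # sharing fraction 0 with no shared spikes gives disjoint compartments
  cfg0 <- smallStudyConfig(seed = 13L)
  cfg0@pbCsfSharingFraction <- 0
  cfg0@nSharedHyper <- 0L
  study0 <- generateStudy(cfg0)
  man0 <- study0$manifest
  for (s in unique(man0$subject)) {
    pb <- man0[man0$subject == s & man0$compartment == "PB" & man0$productive, ]
    csf <- man0[man0$subject == s & man0$compartment == "CSF" & man0$productive, ]
    expect_equal(intersect(paste(pb$v_call, pb$cdr3_aa, pb$j_call),
                           paste(csf$v_call, csf$cdr3_aa, csf$j_call)),
                 character(0))
  }
})
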