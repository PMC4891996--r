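test_that("expansion binning uses strict boundary semantics", {
  b <- binExpansion(c(99, 100, 10000, 10001))
  expect_equal(unname(b), c(1L, 2L, 1L))
  expect_equal(names(b), c("small", "intermediate", "hyperexpanded"))
  # all singletons are small; bins always partition the richness
  expect_equal(unname(binExpansion(rep(1, 7))), c(7L, 0L, 0L))
  set.seed(41)
  for (i in 1:20) {
    counts <- sample(c(1:200, 9990:10010, 12000), sample(5:50, 1),
                     replace = TRUE)
    expect_equal(sum(binExpansion(counts)), length(counts))
  }
})

test_that("frequency window selection is inclusive on the log2 scale", {
  # clone exactly at the window edge is included
  counts <- c(round(2^-5.1 / 100 * 1e7), 1e7)
  prof <- expansionProfile(counts)
  # construct exact edge case instead: percent = 2^-5.1
  prof <- data.frame(key = c("a", "b"), count = c(1, 1),
                     percent_total_frequency = c(2^-5.1, 25),
                     log2_frequency = c(-5.1, log2(25)))
  expect_equal(frequencyWindowFilter(prof, -9.9, -5.1), "a")
  # a uniform 1000-clone repertoire sits at log2(0.1) = -3.32, outside the
  # [-9.9, -5.1] window
  prof2 <- expansionProfile(rep(1, 1000))
  expect_equal(length(frequencyWindowFilter(prof2, -9.9, -5.1)), 0L)
  expect_equal(length(frequencyWindowFilter(prof2, -4, -3)), 1000L)
})

test_that("shared clonotypes are the intersection over all subjects", {
  r1 <- tinyRepertoire(counts = c(1L, 2L, 3L), subject = "A")
  r2 <- tinyRepertoire(counts = c(9L, 9L, 9L), subject = "B")
  shared <- sharedClonotypes(list(r1, r2))
  expect_setequal(shared, clonotypeKeys(r1))
  # disjoint repertoires share nothing
  cl <- clonotypes(r2)
  cl$cdr3_aa <- sub("^CASS", "CAST", cl$cdr3_aa)
  cl$cdr3_nt <- sub("^TGTGCTAGTAGT", "TGTGCTAGTACT", cl$cdr3_nt)
  r3 <- Repertoire(cl, "C", "MS", "PB", 1000)
  expect_equal(sharedClonotypes(list(r1, r3)), character(0))
  # every shared key is findable in every member repertoire
  s <- sharedClonotypes(list(r1, r2, r1))
  for (k in s) {
    expect_true(k %in% clonotypeKeys(r1))
    expect_true(k %in% clonotypeKeys(r2))
  }
})

test_that("v_cdr3_j sharing is never larger than cdr3_aa sharing", {
  set.seed(42)
  g <- builtinGermline()
  study <- generateStudy(smallStudyConfig(seed = 44L))
  reps <- filterSamples(study$truth, group = "MS", compartment = "PB")
  strict <- sharedClonotypes(reps, keyMode = "v_cdr3_j")
  loose <- sharedClonotypes(reps, keyMode = "cdr3_aa")
  expect_lte(length(strict), length(loose))
})

test_that("exclusive/common partition matches brute-force set operations", {
  # identical sets: no exclusive keys
  ec0 <- exclusiveAndCommon(c("a", "b"), c("a", "b"))
  expect_equal(ec0$a_only, 0L)
  expect_equal(ec0$b_only, 0L)
  expect_equal(ec0$common, 2L)
  set.seed(43)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    ec <- exclusiveAndCommon(a, b)
    expect_equal(ec$a_only, length(setdiff(a, b)))
    expect_equal(ec$b_only, length(setdiff(b, a)))
    expect_equal(ec$common, length(intersect(a, b)))
    # partition arithmetic
    expect_equal(ec$a_only + ec$common, length(unique(a)))
    expect_equal(ec$a_only + ec$b_only + 2 * ec$common,
                 length(unique(a)) + length(unique(b)))
  }
})

test_that("cross-compartment hyperexpanded sharing arithmetic is exact", {
  # one planted shared hyperexpanded clone carrying 30,000 of 3,000,000 CSF
  # reads: ratio 1/n and exactly 1%
  csfCl <- clonotypes(tinyRepertoire(counts = c(30000L, 20000L, 2950000L)))
  csf <- Repertoire(csfCl, "S1", "MS", "CSF", 1e5)
  pbCl <- clonotypes(tinyRepertoire(counts = c(10L)))  # first clone only
  pb <- Repertoire(pbCl, "S1", "MS", "PB", 1e6)
  cc <- crossCompartmentHyperexpanded(csf, pb)
  expect_equal(cc$n_hyper, 3L)
  expect_equal(cc$n_shared, 1L)
  expect_equal(cc$percent_csf, 100 * 30000 / 3000000)
  # no overlap
  cl2 <- pbCl
  cl2$cdr3_aa <- sub("^CASS", "CASG", cl2$cdr3_aa)
  pb2 <- Repertoire(cl2, "S1", "MS", "PB", 1e6)
  cc2 <- crossCompartmentHyperexpanded(csf, pb2)
  expect_equal(cc2$n_shared, 0L)
  expect_equal(cc2$percent_csf, 0)
  # all hyper clones shared: percent equals their summed CSF frequency
  cc3 <- crossCompartmentHyperexpanded(csf, csf)
  expect_equal(cc3$n_shared, 3L)
  expect_equal(cc3$percent_csf, 100)
  # zero hyperexpanded CSF clones: absent ratio (dash convention)
  csfSmall <- Repertoire(clonotypes(tinyRepertoire(c(5L, 5L))),
                         "S1", "MS", "CSF", 1e5)
  cc4 <- crossCompartmentHyperexpanded(csfSmall, pb)
  expect_equal(cc4$n_hyper, 0L)
  expect_true(is.na(cc4$percent_csf))
})
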