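# Independent Gotoh (affine-gap global alignment) oracle for the CDR3
# distance, reimplemented from scratch in test code.
gotohScore <- function(a, b, open = 10, ext = 1) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

test_that("CDR3 distance is a normalized alignment premetric", {
  expect_equal(cdr3Distance("CASSF", "CASSF"), 0)
  set.seed(71)
  aas <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")
  for (i in 1:10) {
    a <- paste(sample(aas, sample(6:14, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(6:14, 1), replace = TRUE), collapse = "")
    dab <- cdr3Distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, cdr3Distance(b, a))
    expect_equal(cdr3Distance(a, a), 0)
  }
  expect_error(cdr3Distance("CASSF", "CAS1F"), "non-amino-acid")
})

test_that("CDR3 distances match an independent affine-gap oracle", {
  fixture <- c("CASSQRLAGSTDTQYF", "CASSQRLAGNTDTQYF", "CASSLEPGRNEKLF",
               "CASQQGSGSYEQYF", "CASSF")
  for (i in 1:4) for (j in (i + 1):5) {
    a <- fixture[i]; b <- fixture[j]
    expected <- 1 - gotohScore(a, b) /
      max(gotohScore(a, a), gotohScore(b, b))
    expect_equal(cdr3Distance(a, b), max(0, expected), tolerance = 1e-12)
  }
})

test_that("similarity trees are deterministic with faithful leaves", {
  seqs <- c("CASSLAPGATNEKLF", "CASSLAPGATNEKLW"  , "CAWWWWWWF",
            "CASSLAPGATNEKLY", "CAIIIIIIF")
  tr <- buildTree(seqs)
  expect_setequal(tr$phylo$tip.label, seqs)
  expect_equal(treeNewick(tr), treeNewick(buildTree(seqs)))
  # the near-identical pair are siblings in the 3-leaf case
  tr3 <- buildTree(c("CASSLAPGATNEKLF", "CASSLAPGATNEKLW", "CAWWWWWWF"))
  h <- tr3$hclust
  expect_equal(sort(h$merge[1, ]), c(-2, -1))  # first merge joins seqs 1+2
  # duplicates collapse with multiplicity
  trDup <- buildTree(c(seqs, seqs[1]))
  expect_equal(length(trDup$labels), 5L)
  expect_equal(trDup$multiplicity[trDup$labels == seqs[1]], 2L)
})

test_that("average-linkage merge heights match a brute-force UPGMA", {
  set.seed(72)
  fam <- simulateMotifFamilies(2, 3)
  seqs <- fam$sequence
  tr <- buildTree(seqs)
  D <- cdr3DistanceMatrix(seqs)
  # naive average linkage: repeatedly merge the closest pair of clusters,
  # scoring cluster distance as the mean over all original member pairs
  clusters <- as.list(seq_along(seqs))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sort(tr$hclust$height), sort(heights), tolerance = 1e-12)
})

test_that("cluster cutting respects height and minimum size", {
  seqs <- c("CASSAPF", "CASSAPF", "CASSAPF", "CAWWWTF", "CAYYYYF")
  tr <- buildTree(seqs)
  # height 0: only exact-duplicate groups survive
  cl0 <- cutClusters(tr, height = 0)
  expect_equal(length(cl0), 1L)
  expect_equal(cl0[[1]]$members, rep("CASSAPF", 3))
  # height above the maximum merge: one cluster holding everything
  clAll <- cutClusters(tr, height = max(tr$hclust$height) + 1)
  expect_equal(length(clAll), 1L)
  expect_equal(length(clAll[[1]]$members), 5L)
  # clusters are disjoint
  cl <- cutClusters(tr, height = 0.4)
  expect_equal(anyDuplicated(unlist(lapply(cl, function(x)
    unique(x$members)))), 0L)
})

test_that("position frequency matrices are normalized with correct IC", {
  p1 <- positionFrequencyMatrix(c("CASSF", "CASSF"))
  expect_equal(p1$consensus, "CASSF")
  expect_equal(unname(p1$information_content), rep(log2(20), 5))
  expect_equal(unname(colSums(p1$pfm)), rep(1, 5))

  p2 <- positionFrequencyMatrix(c("CAAAF", "CAGAF"))
  expect_equal(unname(p2$pfm["A", 3]), 0.5)
  expect_equal(unname(p2$pfm["G", 3]), 0.5)

  # a uniform column over all 20 residues has zero information content
  aas <- rownames(p1$pfm)
  seqs <- paste0("CA", aas, "TF")
  p3 <- positionFrequencyMatrix(seqs)
  expect_equal(unname(p3$information_content[3]), 0)
  expect_gte(min(p3$information_content), 0)
  expect_lte(max(p3$information_content), log2(20))

  # PFM columns sum to 1 for every cluster of a planted simulation
  set.seed(73)
  fam <- simulateMotifFamilies(3, 6)
  cls <- cutClusters(buildTree(fam$sequence))
  for (cl in cls)
    expect_equal(unname(colSums(cl$pfm)), rep(1, ncol(cl$pfm)),
                 tolerance = 1e-9)
})

test_that("planted motif families are recovered with high purity", {
  set.seed(74)
  fam <- simulateMotifFamilies(4, 8)
  tree <- buildTree(fam$sequence)
  cls <- cutClusters(tree)
  expect_gte(length(cls), 3L)
  recovered <- 0L
  for (f in sort(unique(fam$family))) {
    hit <- vapply(cls, function(cl) {
      members <- fam$family[match(cl$members, fam$sequence)]
      sum(members == f) >= length(fam$family[fam$family == f]) / 2 &&
        max(table(members)) / length(members) >= 0.8
    }, logical(1))
    recovered <- recovered + any(hit)
  }
  expect_gte(recovered, 3L)
})

test_that("group consensus comparison flags planted divergent positions", {
  # identical groups: nothing differs
  same <- c("CASSLGGADTQYF", "CASSLGGADTQYF", "CASSLGRADTQYF")
  cmp0 <- groupConsensusComparison(same, same)
  expect_equal(cmp0$differing_positions, integer(0))
  # planted glycine vs serine at positions 8 and 9
  set.seed(75)
  gr <- simulateConsensusGroups(nPerGroup = 30, divergentPos = c(8L, 9L),
                                residueA = "G", residueB = "S")
  cmp <- groupConsensusComparison(gr$A, gr$B)
  expect_equal(cmp$differing_positions, c(8L, 9L))
  expect_equal(substr(cmp$consensusA, 8, 9), "GG")
  expect_equal(substr(cmp$consensusB, 8, 9), "SS")
  # single-sequence groups fall back to those sequences
  cmp1 <- groupConsensusComparison("CASSF", "CASTF")
  expect_equal(cmp1$consensusA, "CASSF")
  expect_equal(cmp1$differing_positions, 4L)
})
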