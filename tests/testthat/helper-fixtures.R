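# Shared fixtures, all built in code.

# A tiny hand-written germline set with known anchors, for controlled tests.
tinyGermline <- function() {
  v1 <- paste0(strrep("A", 20), "TGT", "GCAGCA")      # anchor 20, Cys
  v2 <- paste0(strrep("G", 20), "TGC", "TTGTTG")      # anchor 20, Cys
  j1 <- paste0("ACGTACGTAC", "TTC", "GG", strrep("T", 15))  # anchor 10, Phe
  j2 <- paste0("GTCAGTCAGT", "TTT", "GG", strrep("C", 15))  # anchor 10, Phe
  d1 <- "GGGACAGGGGGC"
  GermlineSet(c(TRBV1 = v1, TRBV2 = v2, TRBJ1 = j1, TRBJ2 = j2, TRBD1 = d1),
              segmentClass = c("V", "V", "J", "J", "D"),
              anchorIndex = c(20L, 20L, 10L, 10L, NA))
}

# A small valid repertoire for IO / metric tests.
tinyRepertoire <- function(counts = c(5L, 3L, 2L), subject = "S1",
                           group = "MS", compartment = "PB",
                           cellCount = 1000) {
  n <- length(counts)
  # unique keys via distinct middle residues
  mid <- c("A", "D", "E", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R",
           "S", "T", "V", "W", "Y")
  aa <- vapply(seq_len(n), function(i)
    paste0("CASS", mid[1 + (i - 1) %% 18], mid[1 + ((i - 1) %/% 18) %% 18], "F"),
    character(1))
  nt <- vapply(aa, function(a) {
    codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "AGT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
    paste(codons[strsplit(a, "")[[1]]], collapse = "")
  }, character(1))
  Repertoire(data.frame(v_call = rep(c("TRBV1", "TRBV2"), length.out = n),
                        j_call = rep(c("TRBJ1", "TRBJ2"), length.out = n),
                        cdr3_nt = unname(nt), cdr3_aa = aa,
                        count = as.integer(counts)),
             subject = subject, group = group, compartment = compartment,
             cellCount = cellCount)
}

# Reduced-size study config for fast pipeline tests.
smallStudyConfig <- function(seed = 11L) {
  simulationConfig(seed = seed, nSubjectsPerGroup = 2L, nClonesPB = 25L,
                   nClonesCSF = 10L, publicExclusive = c(MS = 6, IIH = 4),
                   publicCommon = 3L, nSpikesCSF = 1L, nSharedHyper = 1L,
                   spikeReadCount = 10050L, pbCsfSharingFraction = 0.2,
                   nonproductiveRate = 0.1)
}

# The packaged study conditions, run once through the whole pipeline and
# cached for every test that needs them (this is the expensive fixture).
.studyCache <- new.env(parent = emptyenv())

packagedStudyRun <- function() {
  if (is.null(.studyCache$run)) {
    outDir <- file.path(tempdir(), "tcrbrep_packaged_study")
    cfg <- runConfig(sim = simulationConfig(seed = 20160420L))
    report <- runStudy(cfg, outDir)
    .studyCache$run <- list(outDir = outDir, config = cfg, report = report)
  }
  .studyCache$run
}
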