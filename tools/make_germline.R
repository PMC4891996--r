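# One-off generator for the frozen synthetic TRB germline fixture.
# Run once; outputs are committed under inst/extdata/ and never regenerated.
set.seed(20160420)

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

v_names <- c("TRBV2", "TRBV4-1", "TRBV4-3", "TRBV5-1", "TRBV6-5", "TRBV7-2",
             "TRBV7-6", "TRBV9", "TRBV12-3", "TRBV19", "TRBV20-1", "TRBV28")
j_names <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

# V: 57 nt, conserved Cys codon at 0-based position 45, 9 nt of germline
# sequence 3' of the codon (room for V-side junction template). The 45-nt
# 5' region keeps the junction inside both 150-base read windows with full
# alignable flanks for every achievable junction length.
v_seqs <- vapply(seq_along(v_names), function(i) {
  cys <- if (i %% 2 == 0) "TGT" else "TGC"
  paste0(rand_nt(45), cys, rand_nt(9))
}, character(1))

# J: 50 nt, conserved Phe codon at 0-based position 12 followed by the
# canonical GG of the FGxG motif.
j_seqs <- vapply(seq_along(j_names), function(i) {
  phe <- if (i %% 2 == 0) "TTT" else "TTC"
  paste0(rand_nt(12), phe, "GG", rand_nt(33))
}, character(1))

d_names <- c("TRBD1", "TRBD2")
d_seqs <- c("GGGACAGGGGGC", "GGGACTAGCGGGAGGG")

ids <- c(v_names, d_names, j_names)
seqs <- c(v_seqs, d_seqs, j_seqs)
fa <- file("inst/extdata/synthetic_trb_germline.fasta", "w")
for (i in seq_along(ids)) {
  cat(">", ids[i], "\n", seqs[i], "\n", sep = "", file = fa)
}
close(fa)

anchors <- data.frame(
  segment_id = c(v_names, j_names),
  anchor_index = c(rep(45L, length(v_names)), rep(12L, length(j_names)))
)
write.table(anchors, "inst/extdata/synthetic_trb_anchors.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", length(ids), "segments\n")
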