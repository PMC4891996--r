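---
title: "Methods: simulated TCRβ repertoires, annotation, diversity and sharing"
author: "tcrbrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated TCRB repertoires, annotation, diversity and sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbrep)
```

# Scope and model

`tcrbrep` analyses T-cell receptor β-chain (TCRβ) repertoires from paired
peripheral-blood (PB) and cerebrospinal-fluid (CSF) libraries of two subject
groups (a disease group, MS, and a control group, IIH). A TCRβ clonotype is
keyed by its V gene, its CDR3 amino-acid sequence — the junction running from
the conserved cysteine at the 3' end of the V gene through the conserved
phenylalanine in the J gene, both residues included — and its J gene. The
pipeline covers:

1. a seeded synthetic study generator (repertoires plus raw 150-base reads),
2. read annotation (V/J assignment, CDR3 extraction, productivity,
   clonotype collapsing, germline-contribution breakdown),
3. diversity metrics normalized by input cell count,
4. clonal-expansion profiling, binning and clonotype sharing,
5. exact small-sample Wilcoxon statistics with a leave-one-out range, and
6. CDR3 motif clustering with position frequency matrices.

Because no real sequencing data ships with the package, every quantitative
claim the test suite makes is a statement about recovery of structure planted
by the simulator, not about real repertoires. What a passing suite shows is
that the analysis code is exact on data whose truth is known; it does not
show that real PB/CSF libraries satisfy the generative assumptions below.

# The synthetic study generator

`generateStudy()` emulates a template-switch (5' RACE-style) TCRβ amplicon
library: each clone's amplicon is `anchor + V + junction + J + constant-stub`,
sequenced as one 150-base forward read (5' end) and one 150-base reverse read
(3' end) per in-frame read count. Defaults (`simulationConfig()`) define the
packaged study conditions:

* **Design**: 5 + 5 subjects, paired PB/CSF per subject. Input cell counts
  10^6 (PB) and 10^5 (CSF), the magnitudes typical of PBMC preparations and
  lumbar-puncture CSF yields; these drive the diversity normalization.
* **Clone abundances**: discrete power law P(count = k) ∝ k^-a with a = 2.5
  truncated at 3,000, giving the heavily skewed rank-abundance curves that
  repertoire data show. The law is configurable (log-normal, uniform); no
  published abundance law is assumed, and nothing downstream depends on the
  choice — recovery is asserted for planted structure only.
* **Junctions**: the V contributes its conserved Cys codon plus 0–6 templated
  nucleotides, the J its conserved Phe codon plus 0–8; an optionally trimmed
  D fragment is used in 85% of clones; non-templated N additions are drawn
  geometric(p = 0.25), truncated at 12 nt per side. Productive junctions are
  resampled until in-frame and stop-free; nonproductive clones (10% of
  private clones) carry a frameshift or an in-frame stop planted in the
  non-templated region.
* **Planted structure**: public PB clonotypes inserted into every subject of
  a group — 204 MS-exclusive, 158 IIH-exclusive, 94 common; a PB→CSF sharing
  fraction of 0.1 within each subject; 2 hyperexpanded CSF spike-in clones
  per subject at 12,000 reads (one of which is also planted in the paired
  PB). A study-wide key registry guarantees that no two independently
  generated clones collide on (V, CDR3aa, J), so planted sharing counts are
  exact by construction.
* **Errors**: independent per-base substitutions (default rate 0); indels
  are not simulated.

The synthetic germline reference (`builtinGermline()`, 12 V, 2 D, 13 J
segments with IMGT-style names) is a frozen, clearly-labelled synthetic
stand-in: segment bodies are random sequences with correct conserved anchor
codons, not database alleles. The V 5' region is 45 nt so that every emitted
read — forward and reverse — contains the complete junction with at least
20 nt of alignable V and J context for every achievable junction length;
consequently each planted clone of count c is expected to yield exactly 2c
annotated in-frame reads, which is what the end-to-end tests assert. Features
of real data that the generator does not emulate: allele-level germline
variation, PCR amplification bias, chimeric reads, quality-score structure,
indel errors, and realistic (longer, possibly non-spanning) V regions.

# Read annotation

V and J genes are assigned per read by local alignment against every
reference (match +1, mismatch −1, gap open −3, gap extend −1), on both
strands; the strand maximizing the combined best V + best J score wins, and
a best score below 20 yields no call. Ties on score go to the
lexicographically smallest segment id, deterministically. Identical read
sequences are collapsed before alignment and the results expanded afterwards,
which makes deep samples with highly clonal structure cheap to annotate.

The CDR3 is the read interval aligned from the V anchor codon through the J
anchor codon, both included. Anchor positions are projected through the
alignment; for the rare alignments containing indels the projection walks
the gapped alignment explicitly. Reads in which an anchor falls outside the
aligned region, or the anchors are ordered inconsistently, are tallied as
`no_junction`. A junction is productive when its length is divisible by
three and its translation contains no stop; codons containing N translate to
X and disqualify productivity. Unique productive (V, CDR3aa, J) combinations
are collapsed into counted clonotypes.

One deliberate choice: the junction is reported verbatim from the read. We
prototyped "correcting" germline-templated CDR3 positions from the called
reference (defensible in principle, since TCRs carry no somatic
hypermutation) and rejected it: local alignments frequently over-extend past
the true germline boundary through chance matches in the N region, so the
substitution corrupted a substantial fraction of error-free junctions. The
consequence is an honest error model: a read's clonotype is recovered
exactly if and only if its CDR3 contains no non-synonymous sequencing error.
With a mean CDR3 of ~26 nt, the expected exact-recovery rate at a 1%
per-base substitution rate is (1 − 0.01·0.76)^26 ≈ 0.82 — a ceiling of the
per-read approach itself, not of this implementation; raising it would
require clustering near-identical CDR3s for error correction, which is out
of scope. At error rate 0 recovery of junction-spanning reads is exact.

**Germline contributions.** For each clonotype, `n_from_v` is the longest
exact extension of the called V germline from its anchor into the CDR3,
`n_from_j` the symmetric extension from the 3' side (capped so the two do
not overlap, V taking precedence), `n_from_d` the longest substring of the
remaining core found in any D reference (ties: longer D segment, then
smaller id, leftmost match), and `n_additions` the remainder. Because chance
matches can extend a templated region past its generative boundary, these
annotations are maximal-parsimony estimates; simulator truth is only asserted
for junctions constructed to be unambiguous.

# Diversity metrics

Richness is the number of unique clonotypes. Shannon entropy is
H = −Σ p_i log p_i over clone frequencies, natural log by default (the
ecology convention; base 2 is a parameter). Evenness is Pielou's
J = H / log(richness), zero for a single clone. Normalization uses the cell
count of the library: a repertoire generated from N cells can contain at
most N clones, so maximum richness is N and maximum entropy log N (the
uniform repertoire over N cells); normalized values are observed / maximum,
clamped to [0, 1], with a warning when richness exceeds the recorded cell
count (a metadata error). This "uniform over input cells" maximum is the
minimal consistent reading of cell-count normalization; both the entropy
base and the maximum model are parameters, not hidden constants.

Expansion is measured per clone as percent total frequency,
100·c_i / Σc, and its log2 transform; profiles are sorted by decreasing
frequency for cumulative-curve views. Expansion bins use strict thresholds:
fewer than 100 in-frame reads is a "small" expansion, more than 10,000 is
"hyperexpanded", and boundary counts of exactly 100 or 10,000 fall in the
intermediate bin.

# Sharing and statistics

A clonotype is *shared* (public) within a group and compartment when present
in every subject's repertoire; keys are either (V, CDR3aa, J) — the default,
matching the notation used for cross-compartment tables — or CDR3 amino acid
alone, since published analyses use both granularities. An optional closed
log2-frequency window restricts each repertoire before intersecting (the
differential-expansion windows [−9.9, −5.1] for PB and [−5.7, −3.2] for CSF
are carried as defaults in `runConfig()`). The exclusive/common partition of
two shared sets is plain set arithmetic, tested against brute force. The
cross-compartment table intersects each subject's hyperexpanded CSF
clonotypes with the full PB repertoire and reports the percentage of all CSF
in-frame reads carried by the shared clones; a CSF sample with no
hyperexpanded clonotype reports an absent ratio rather than zero.

The unpaired group comparison is the Wilcoxon rank-sum (Mann–Whitney) test
and the paired compartment comparison the Wilcoxon signed-rank test — the
standard reading of a "nonparametric unpaired/paired Wilcoxon" prescription.
Exact two-sided p-values are computed by complete enumeration of the
permutation distribution of the observed mid-ranks (a subset-sum counting
recursion, so ties are exact too) for group sizes up to 10, with the
tie-corrected normal approximation above. The leave-one-out (LOO) range
recomputes the test omitting one subject at a time — every subject of both
groups for the unpaired test — and reports the min and max p, the
small-cohort robustness summary reported alongside each comparison. No
multiple-testing correction is applied, matching the analysis design this
package mirrors.

# Motif clustering

CDR3 amino-acid relatedness uses a normalized global-alignment distance
d(a,b) = 1 − S(a,b) / max(S(a,a), S(b,b)) under BLOSUM62 with affine gaps
(open 10, extend 1) — defaults chosen because the upstream analysis names
only a GUI product without parameters. d is symmetric with zero diagonal;
the triangle inequality is not guaranteed and not assumed. Trees are
agglomerative (average linkage by default) via `stats::hclust`, exportable
as Newick through `ape`; duplicate sequences are collapsed with multiplicity.
Clusters are subtrees below a height cut with at least 2 members. The
default cut height of 0.6 was calibrated once on pilot simulations of the
planted-family generator, where within-family merge heights fall around
0.35–0.58 and between-family merges above 0.6; it is a config parameter, and
no attempt is made to auto-tune it to reproduce any particular published
cluster count, which is data-dependent and not reproducible without the
original sequences.

Position frequency matrices stack equal-length members directly; unequal
lengths are aligned globally to the longest member and projected onto its
coordinates, with gap frequencies tracked separately so that every PFM
column sums to 1 over the 20 residues. The consensus takes the per-column
majority (alphabetical on ties) and information content is log2(20) minus
column entropy, in bits. The group-consensus comparison pools member
sequences per group, picks the dominant common length stratum, and flags
1-based positions (counted from the conserved C) whose dominant residues
differ — the machinery used to ask whether one group's shared clonotypes
carry a distinctive residue at particular CDR3 positions. Logo rendering is
left to the user's plotting stack; the PFM and IC are the tested artifact.

# Numerical and engineering choices

* Problem sizes: the packaged study uses 5+5 subjects with ~600 PB / ~120
  CSF clones per subject and ~510,000 reads in total, sized so the full
  pipeline (simulation through report) completes in about three minutes on
  one CPU; the per-stage file interface (TSV/JSON) makes each stage
  independently testable and a rerun byte-identical under a fixed seed.
* Degenerate inputs: empty count vectors error; single-clone repertoires
  have zero entropy and evenness; all-tied test inputs return p = 1 with a
  warning; zero paired differences are dropped with a warning; an empty
  productive annotation set collapses to an empty repertoire with a warning.
* Translation uses the standard genetic code via a direct codon-table
  lookup (the table itself comes from Biostrings); X (from N-containing
  codons) disqualifies productivity.
* All coordinates are 0-based half-open internally for anchors (reported
  1-based in R's string conventions); CDR3s include both conserved anchors.

# Known limitations

* The annotation error model is per-read; no consensus building or error
  clustering is performed, so exact clonotype recovery degrades multiplica-
  tively with junction length at nonzero substitution rates (see above).
* The synthetic germline reference is not IMGT; analyses of real reads
  require supplying a real reference FASTA plus anchor table to
  `readGermlineSegments()`.
* D-segment assignment by longest exact substring is a parsimony heuristic;
  short cores make `d_call` unreliable, which is why D is excluded from the
  clonotype key.
* Sharing analyses assume subjects' repertoires are comparable as sets;
  no abundance weighting is applied when intersecting.
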