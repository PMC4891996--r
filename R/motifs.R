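## CDR3 amino-acid motif clustering: alignment-based normalized distances,
## agglomerative trees, motif clusters with position frequency matrices and
## information content, and group consensus comparison.

.aaCheck <- function(x) {
  bad <- grepl(sprintf("[^%s]", paste(.AA20, collapse = "")), x)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(unique(x[bad]), collapse = ", "))
}

.aaScore <- function(a, b, matrix_name = "BLOSUM62", gapOpening = 10,
                     gapExtension = 1, vectorized = FALSE) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix_name, gapOpening = gapOpening,
    gapExtension = gapExtension, scoreOnly = TRUE)
}

#' Normalized CDR3 amino-acid distance
#'
#' Global alignment score S under a published substitution matrix (default
#' BLOSUM62, affine gaps 10/1), converted to the normalized distance
#' d = 1 - S(a, b) / max(S(a, a), S(b, b)). Identity gives 0 and the
#' distance is symmetric; the triangle inequality is not guaranteed.
#'
#' @param a,b CDR3 amino-acid strings.
#' @param matrix_name substitution matrix name (passed to Biostrings).
#' @param gapOpening,gapExtension affine gap penalties.
#' @return non-negative distance.
#' @export
cdr3Distance <- function(a, b, matrix_name = "BLOSUM62", gapOpening = 10,
                         gapExtension = 1) {
  .aaCheck(c(a, b))
  sab <- .aaScore(a, b, matrix_name, gapOpening, gapExtension)
  saa <- .aaScore(a, a, matrix_name, gapOpening, gapExtension)
  sbb <- .aaScore(b, b, matrix_name, gapOpening, gapExtension)
  max(0, 1 - sab / max(saa, sbb))
}

#' Pairwise CDR3 distance matrix
#'
#' @param sequences character vector of CDR3 amino-acid strings.
#' @inheritParams cdr3Distance
#' @return symmetric distance matrix with zero diagonal.
#' @export
cdr3DistanceMatrix <- function(sequences, matrix_name = "BLOSUM62",
                               gapOpening = 10, gapExtension = 1) {
  .aaCheck(sequences)
  n <- length(sequences)
  self <- vapply(sequences, function(s)
    .aaScore(s, s, matrix_name, gapOpening, gapExtension), numeric(1))
  D <- matrix(0, n, n, dimnames = list(sequences, sequences))
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    s <- .aaScore(sequences[idx], sequences[i], matrix_name, gapOpening,
                  gapExtension)
    d <- pmax(0, 1 - s / pmax(self[idx], self[i]))
    D[i, idx] <- d
    D[idx, i] <- d
  }
  D
}

#' Hierarchical similarity tree of CDR3 sequences
#'
#' Agglomerative clustering (default average linkage / UPGMA-style) of the
#' pairwise normalized alignment distances. Duplicate sequences are
#' collapsed with their multiplicity recorded. The tree is deterministic for
#' a given input order.
#'
#' @param sequences character vector of CDR3 amino-acid strings (>= 3
#'   unique).
#' @param linkage linkage method for \code{\link[stats]{hclust}}.
#' @inheritParams cdr3Distance
#' @return list of class \code{"cdr3_tree"}: \code{hclust}, \code{phylo}
#'   (an \code{ape} tree), \code{labels}, \code{multiplicity}.
#' @export
buildTree <- function(sequences, matrix_name = "BLOSUM62",
                      linkage = "average", gapOpening = 10,
                      gapExtension = 1) {
  tab <- table(sequences)[unique(sequences)]  # keep input order
  uniq <- names(tab)
  if (length(uniq) < 3L) stop("need at least 3 unique sequences")
  D <- cdr3DistanceMatrix(uniq, matrix_name, gapOpening, gapExtension)
  hc <- hclust(as.dist(D), method = linkage)
  structure(list(hclust = hc, phylo = ape::as.phylo(hc), labels = uniq,
                 multiplicity = as.integer(tab)),
            class = "cdr3_tree")
}

#' @rdname buildTree
#' @param tree a \code{"cdr3_tree"}.
#' @param path optional file path; when omitted the Newick string is
#'   returned.
#' @export
treeNewick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree$phylo)
  else { ape::write.tree(tree$phylo, file = path); invisible(path) }
}

#' Cut a similarity tree into motif clusters
#'
#' Subtrees merged below \code{height} with at least \code{minSize} member
#' sequences (duplicates counted with their multiplicity) become motif
#' clusters; smaller groups are discarded. Each cluster carries a position
#' frequency matrix, consensus and per-position information content from
#' \code{\link{positionFrequencyMatrix}}.
#'
#' @param tree a \code{"cdr3_tree"} from \code{\link{buildTree}}.
#' @param height cut height on the distance scale.
#' @param minSize minimum member count per cluster.
#' @return list of motif clusters, each a list with \code{cluster_id},
#'   \code{members}, \code{pfm}, \code{consensus},
#'   \code{information_content}.
#' @export
cutClusters <- function(tree, height = 0.6, minSize = 2L) {
  stopifnot(height >= 0)
  grp <- cutree(tree$hclust, h = height)
  out <- list()
  for (g in sort(unique(grp))) {
    members <- rep(tree$labels[grp == g], tree$multiplicity[grp == g])
    if (length(members) < minSize) next
    pfm <- positionFrequencyMatrix(members)
    out[[length(out) + 1L]] <- c(list(cluster_id = length(out) + 1L,
                                      members = members), pfm)
  }
  out
}

#' Position frequency matrix, consensus and information content
#'
#' Stacks the member CDR3 sequences into a 20 x L position frequency matrix.
#' Members of equal length are stacked directly; unequal lengths are aligned
#' globally to the longest member and placed by its coordinates, with gap
#' frequencies tracked separately (PFM columns are normalized over residues
#' only, so every column sums to 1). The consensus is the per-column
#' majority residue (ties alphabetical) and the information content is
#' log2(20) minus the column entropy, in bits.
#'
#' @param members character vector of CDR3 amino-acid sequences (>= 2).
#' @return list: \code{pfm} (20 x L), \code{consensus},
#'   \code{information_content} (length L, bits), \code{gap_frequency}.
#' @export
positionFrequencyMatrix <- function(members) {
  stopifnot(length(members) >= 2L)
  .aaCheck(members)
  L <- max(nchar(members))
  anchor <- members[which.max(nchar(members))]
  rows <- lapply(members, function(s) {
    if (nchar(s) == L) return(strsplit(s, "")[[1]])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(anchor), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ap[as != "-"][seq_len(L)]  # project onto anchor coordinates
  })
  M <- do.call(rbind, rows)
  M[is.na(M)] <- "-"
  pfm <- matrix(0, nrow = length(.AA20), ncol = L,
                dimnames = list(.AA20, seq_len(L)))
  gap <- numeric(L)
  for (p in seq_len(L)) {
    col <- M[, p]
    gap[p] <- mean(col == "-")
    res <- col[col != "-"]
    if (length(res) > 0) {
      tabp <- table(factor(res, levels = .AA20))
      pfm[, p] <- as.numeric(tabp) / length(res)
    }
  }
  consensus <- paste(vapply(seq_len(L), function(p) {
    .AA20[which.max(pfm[, p])]  # which.max takes the first (alphabetical) tie
  }, character(1)), collapse = "")
  ic <- vapply(seq_len(L), function(p) {
    q <- pfm[, p][pfm[, p] > 0]
    log2(20) + sum(q * log2(q))
  }, numeric(1))
  list(pfm = pfm, consensus = consensus, information_content = ic,
       gap_frequency = gap)
}

#' Compare pooled consensus motifs between two groups
#'
#' Pools the member sequences of each group (cluster lists or plain
#' character vectors), stratifies by CDR3 length, builds a pooled PFM per
#' group for the dominant common length stratum and reports the 1-based
#' positions (counted from the conserved C) where the dominant residues
#' differ. When the groups share no length stratum, per-stratum consensus
#' strings are reported instead.
#'
#' @param groupA,groupB cluster lists from \code{\link{cutClusters}} or
#'   character vectors of CDR3 sequences.
#' @return list: \code{length} (dominant common stratum), \code{consensusA},
#'   \code{consensusB}, \code{differing_positions}, \code{pfmA},
#'   \code{pfmB}; or, with no common stratum, \code{per_stratum} consensus
#'   tables.
#' @export
groupConsensusComparison <- function(groupA, groupB) {
  pool <- function(g) {
    if (is.character(g)) g else unlist(lapply(g, `[[`, "members"))
  }
  a <- pool(groupA); b <- pool(groupB)
  stopifnot(length(a) > 0L, length(b) > 0L)
  commonLens <- intersect(unique(nchar(a)), unique(nchar(b)))
  if (length(commonLens) == 0L) {
    strat <- function(x) vapply(split(x, nchar(x)), function(s)
      if (length(s) >= 2L) positionFrequencyMatrix(s)$consensus else s[1],
      character(1))
    return(list(length = NA_integer_,
                per_stratum = list(A = strat(a), B = strat(b))))
  }
  weight <- vapply(commonLens, function(L)
    sum(nchar(a) == L) + sum(nchar(b) == L), numeric(1))
  L <- commonLens[which.max(weight)]
  pfmOf <- function(x) {
    s <- x[nchar(x) == L]
    if (length(s) >= 2L) positionFrequencyMatrix(s)
    else list(pfm = NULL, consensus = s[1])
  }
  pa <- pfmOf(a); pb <- pfmOf(b)
  diffPos <- which(strsplit(pa$consensus, "")[[1]] !=
                     strsplit(pb$consensus, "")[[1]])
  list(length = L, consensusA = pa$consensus, consensusB = pb$consensus,
       differing_positions = diffPos, pfmA = pa$pfm, pfmB = pb$pfm)
}
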