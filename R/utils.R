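## Internal helpers shared across modules.

#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats hclust as.dist cutree rbinom rgeom rlnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.NT4 <- c("A", "C", "G", "T")

## 5' template-switch anchor and TCRB constant-region primer site defining the
## amplicon termini of the library structure emulated by the simulator.
.SMARTER_ANCHOR <- "AAGCAGTGGTATCAACGCAGAGTAC"
.CONST_STUB <- "AGGTCGCTGTGTTTGAGCCATCAGAAGCA"

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Translate nucleotide strings (length divisible by 3, ACGTN alphabet).
## Codon lookup against the standard genetic code (Biostrings table); any
## codon containing N or other ambiguity translates to X. Direct table
## lookup: this is called once per junction throughout the simulator and
## annotator, where XStringSet construction overhead would dominate.
.CODON_TABLE <- Biostrings::GENETIC_CODE

.translate <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  stopifnot(all(nchar(nt) %% 3L == 0L))
  vapply(nt, function(s) {
    n <- nchar(s)
    aa <- .CODON_TABLE[substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Length of the longest common prefix / suffix of two strings.
.commonPrefixLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

.commonSuffixLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(strsplit(substr(a, nchar(a) - n + 1L, nchar(a)), "")[[1]])
  bv <- rev(strsplit(substr(b, nchar(b) - n + 1L, nchar(b)), "")[[1]])
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' Build clonotype keys
#'
#' Forms the string key identifying a clonotype, either the full
#' V gene / CDR3 amino-acid / J gene triple (the notation used for
#' cross-compartment tables, e.g. \code{"TRBV4-3|CASSQRLAGSTDTQYF|TRBJ2-3"})
#' or the CDR3 amino-acid sequence alone.
#'
#' @param v_call,j_call character vectors of gene-level segment calls.
#' @param cdr3_aa character vector of CDR3 amino-acid sequences (conserved C
#'   through conserved F inclusive).
#' @param mode \code{"v_cdr3_j"} (default) or \code{"cdr3_aa"}.
#' @return character vector of keys.
#' @export
clonotypeKey <- function(v_call, cdr3_aa, j_call, mode = c("v_cdr3_j", "cdr3_aa")) {
  mode <- match.arg(mode)
  if (mode == "cdr3_aa") cdr3_aa else paste(v_call, cdr3_aa, j_call, sep = "|")
}

## Nucleotide substitution matrix: match +1, mismatch -1, N neutral (0).
.dnaSubMat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5L, 5L, dimnames = list(letters, letters))
      diag(mm) <- 1
      mm["N", ] <- 0
      mm[, "N"] <- 0
      m <<- mm
    }
    m
  }
})
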