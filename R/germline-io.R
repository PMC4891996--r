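## File IO: germline references, raw reads, AIRR-style clonotype tables.

#' Read germline segment references
#'
#' Loads a germline TRB segment FASTA plus a tab-separated anchor table
#' mapping every V and J segment id to the 0-based position of its conserved
#' anchor codon (cysteine for V, phenylalanine for J). Segment class is
#' derived from the id (\code{TRBV*}, \code{TRBD*}, \code{TRBJ*}). Validation
#' fails hard if an anchor is missing for a V/J segment or if an anchor codon
#' does not translate to the expected conserved residue.
#'
#' @param fastaPath path to the germline FASTA.
#' @param anchorPath path to a TSV with columns \code{segment_id},
#'   \code{anchor_index}.
#' @return a \code{\link{GermlineSet}}.
#' @export
readGermlineSegments <- function(fastaPath, anchorPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anchors <- read.delim(anchorPath, stringsAsFactors = FALSE)
  if (!all(c("segment_id", "anchor_index") %in% names(anchors)))
    stop("anchor table must have columns segment_id, anchor_index")
  cls <- ifelse(grepl("^TRBV", names(seqs)), "V",
                ifelse(grepl("^TRBD", names(seqs)), "D",
                       ifelse(grepl("^TRBJ", names(seqs)), "J", NA_character_)))
  if (anyNA(cls))
    stop("cannot infer segment class for: ",
         paste(names(seqs)[is.na(cls)], collapse = ", "))
  idx <- match(names(seqs), anchors$segment_id)
  missing_anchor <- cls %in% c("V", "J") & is.na(idx)
  if (any(missing_anchor))
    stop("missing anchor_index for segment(s): ",
         paste(names(seqs)[missing_anchor], collapse = ", "))
  anchor <- ifelse(is.na(idx), NA_integer_, anchors$anchor_index[idx])
  GermlineSet(seqs, cls, anchor)
}

#' Packaged synthetic germline reference
#'
#' Returns the frozen synthetic TRB germline reference shipped with the
#' package (12 V, 2 D, 13 J segments with IMGT-style names). These sequences
#' are synthetic stand-ins generated once with correct conserved anchors; they
#' are not IMGT germline alleles.
#'
#' @return a \code{\link{GermlineSet}}.
#' @export
builtinGermline <- function() {
  readGermlineSegments(
    system.file("extdata", "synthetic_trb_germline.fasta", package = "tcrbrep"),
    system.file("extdata", "synthetic_trb_anchors.tsv", package = "tcrbrep"))
}

#' Read raw sequencing reads
#'
#' Reads a FASTQ or FASTA file (gz-compressed accepted; format inferred from
#' the extension) into an uppercase \code{DNAStringSet}, one entry per record.
#'
#' @param path input file path.
#' @return a named \code{DNAStringSet}.
#' @export
readSequencingReads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("malformed ", fmt, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  nm <- names(reads)
  chars <- as.character(reads)
  if (any(grepl("[acgtn]", chars))) {
    reads <- Biostrings::DNAStringSet(toupper(chars))
    names(reads) <- nm
  }
  reads
}

#' Write / read clonotype tables
#'
#' Serializes a \code{Repertoire} as an AIRR-style rearrangement TSV with
#' columns \code{v_call}, \code{d_call}, \code{j_call}, \code{junction},
#' \code{junction_aa}, \code{duplicate_count} plus the germline-contribution
#' columns, preceded by \code{#}-prefixed header lines carrying the sample
#' metadata (subject, group, compartment, cell count). The junction includes
#' the conserved C and F. \code{readClonotypeTable} is the exact inverse:
#' a written table reads back field-for-field identical.
#'
#' @param repertoire a \code{\link{Repertoire}}.
#' @param path output (input) TSV path.
#' @return \code{readClonotypeTable} returns a \code{Repertoire};
#'   \code{writeClonotypeTable} returns \code{path} invisibly.
#' @export
writeClonotypeTable <- function(repertoire, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# subject_id=%s\n# group=%s\n# compartment=%s\n# cell_count=%s\n",
              subjectId(repertoire), groupLabel(repertoire),
              compartment(repertoire),
              format(cellCount(repertoire), scientific = FALSE)),
      file = con)
  cl <- clonotypes(repertoire)
  out <- data.frame(v_call = cl$v_call, d_call = cl$d_call, j_call = cl$j_call,
                    junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
                    duplicate_count = cl$count, n_from_v = cl$n_from_v,
                    n_from_d = cl$n_from_d, n_from_j = cl$n_from_j,
                    n_additions = cl$n_additions)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}

#' @rdname writeClonotypeTable
#' @export
readClonotypeTable <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  need_meta <- c("subject_id", "group", "compartment", "cell_count")
  if (!all(need_meta %in% names(meta)))
    stop("clonotype table '", path, "' lacks header metadata: ",
         paste(setdiff(need_meta, names(meta)), collapse = ", "))
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "")
  need <- c("v_call", "j_call", "junction", "junction_aa", "duplicate_count")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("clonotype table '", path, "' missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) > 0) {
    bad <- substr(tab$junction_aa, 1L, 1L) != "C" |
      substr(tab$junction_aa, nchar(tab$junction_aa), nchar(tab$junction_aa)) != "F"
    if (any(bad))
      stop("junction_aa must start with C and end with F; offending row(s): ",
           paste(which(bad), collapse = ", "))
  }
  cl <- data.frame(
    v_call = as.character(tab$v_call),
    d_call = if ("d_call" %in% names(tab)) as.character(tab$d_call) else NA_character_,
    j_call = as.character(tab$j_call),
    cdr3_nt = as.character(tab$junction),
    cdr3_aa = as.character(tab$junction_aa),
    count = as.integer(tab$duplicate_count),
    n_from_v = if ("n_from_v" %in% names(tab)) as.integer(tab$n_from_v) else NA_integer_,
    n_from_d = if ("n_from_d" %in% names(tab)) as.integer(tab$n_from_d) else NA_integer_,
    n_from_j = if ("n_from_j" %in% names(tab)) as.integer(tab$n_from_j) else NA_integer_,
    n_additions = if ("n_additions" %in% names(tab)) as.integer(tab$n_additions) else NA_integer_,
    stringsAsFactors = FALSE)
  Repertoire(cl, subject = meta$subject_id, group = meta$group,
             compartment = meta$compartment,
             cellCount = as.numeric(meta$cell_count))
}
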