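#' @rdname GermlineSet-class
#' @export
setGeneric("segmentIds", function(x) standardGeneric("segmentIds"))

#' @rdname GermlineSet-class
#' @export
setGeneric("segmentClass", function(x) standardGeneric("segmentClass"))

#' @rdname GermlineSet-class
#' @export
setGeneric("anchorIndex", function(x) standardGeneric("anchorIndex"))

#' @rdname GermlineSet-class
#' @export
setGeneric("segmentSequences", function(x) standardGeneric("segmentSequences"))

#' @rdname Repertoire-class
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))

#' @rdname Repertoire-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname Repertoire-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname Repertoire-class
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))

#' @rdname Repertoire-class
#' @export
setGeneric("cellCount", function(x) standardGeneric("cellCount"))

#' @rdname Repertoire-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Repertoire richness
#'
#' Number of unique clonotypes. For a numeric vector of per-clonotype counts
#' this is the number of strictly positive entries.
#'
#' @param x a \code{Repertoire} or a numeric vector of clone counts.
#' @return integer richness.
#' @export
setGeneric("richness", function(x) standardGeneric("richness"))

#' @rdname Repertoire-class
#' @export
setGeneric("clonotypeKeys", function(x, mode = "v_cdr3_j") standardGeneric("clonotypeKeys"))

#' @rdname RepertoireSet-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
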