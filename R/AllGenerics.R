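#' Accessors for dmsfunc objects
#'
#' `variantTable()` returns the codon-level variant table of a
#' [DmsLibrary-class]; `orfSequence()` and `nResidues()` return the reference
#' ORF nucleotide sequence and its residue count. `scoreTable()`,
#' `replicateZ()` and `meanZ()` access per-variant results of a
#' [FunctionalScores-class] object; `baselineStats()` returns the rolling
#' silent-baseline table of a [SilentBaseline-class] (or of the scores object
#' that carries one). `simCounts()` and `simTruth()` access the counts and the
#' ground-truth effect table of a [DmsSimulation-class].
#'
#' @param x the object.
#' @param ... unused.
#' @return A `DataFrame`, character scalar, integer, matrix or S4 object as
#'   appropriate for the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x, ...) standardGeneric("variantTable"))

#' @rdname accessors
#' @export
setGeneric("orfSequence", function(x, ...) standardGeneric("orfSequence"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x, ...) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("replicateZ", function(x, ...) standardGeneric("replicateZ"))

#' @rdname accessors
#' @export
setGeneric("meanZ", function(x, ...) standardGeneric("meanZ"))

#' @rdname accessors
#' @export
setGeneric("baselineStats", function(x, ...) standardGeneric("baselineStats"))

#' @rdname accessors
#' @export
setGeneric("simCounts", function(x, ...) standardGeneric("simCounts"))

#' @rdname accessors
#' @export
setGeneric("simTruth", function(x, ...) standardGeneric("simTruth"))
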