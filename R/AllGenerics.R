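#' @rdname GenomeAssembly-class
#' @param x,object a `GenomeAssembly` (or other class as documented).
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("hasSequence", function(x) standardGeneric("hasSequence"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("gapMask", function(x) standardGeneric("gapMask"))

#' @rdname PermTestResult-class
#' @export
setGeneric("observedOverlap", function(x) standardGeneric("observedOverlap"))

#' @rdname PermTestResult-class
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname PermTestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname PermTestResult-class
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

# consensusString / consensusMatrix methods are defined on the Biostrings
# generics (see consensus.R), keeping the accessor vocabulary of the field.
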