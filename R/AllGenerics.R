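#' @name hzascreen-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the classes in this
#'   package. Each has methods documented with the corresponding class.
#' @param x an object
#' @return the slot value (see the class documentation)
NULL

#' @rdname hzascreen-generics
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname hzascreen-generics
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname hzascreen-generics
#' @export
setGeneric("pseudocount", function(x) standardGeneric("pseudocount"))

#' @rdname hzascreen-generics
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @rdname hzascreen-generics
#' @export
setGeneric("regionSeqs", function(x) standardGeneric("regionSeqs"))

#' @rdname hzascreen-generics
#' @export
setGeneric("regionInfo", function(x) standardGeneric("regionInfo"))

#' @rdname hzascreen-generics
#' @export
setGeneric("exceedance", function(x) standardGeneric("exceedance"))

#' @rdname hzascreen-generics
#' @export
setGeneric("occurrences", function(x) standardGeneric("occurrences"))

#' @rdname hzascreen-generics
#' @export
setGeneric("significance", function(x) standardGeneric("significance"))

#' @rdname hzascreen-generics
#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))

#' @rdname hzascreen-generics
#' @export
setGeneric("candidateTable", function(x) standardGeneric("candidateTable"))

#' @rdname hzascreen-generics
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname hzascreen-generics
#' @export
setGeneric("studyGenome", function(x) standardGeneric("studyGenome"))

#' @rdname hzascreen-generics
#' @export
setGeneric("studyGenes", function(x) standardGeneric("studyGenes"))
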