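#' @title Generics for chronoq classes
#' @description Accessor generics shared by the core classes. Each has a
#'   method for the class(es) listed in its own documentation page.
#' @name chronoq-generics
#' @keywords internal
NULL

#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setGeneric("similarityMatrix", function(object) standardGeneric("similarityMatrix"))

#' @export
setGeneric("constructionConstant", function(object) standardGeneric("constructionConstant"))

#' @export
setGeneric("orderingIndices", function(object) standardGeneric("orderingIndices"))

#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @export
setGeneric("qTable", function(object) standardGeneric("qTable"))

#' @export
setGeneric("bestSimilarity", function(object) standardGeneric("bestSimilarity"))

#' @export
setGeneric("optimalOrderings", function(object) standardGeneric("optimalOrderings"))

#' @export
setGeneric("smdValue", function(object) standardGeneric("smdValue"))

#' @export
setGeneric("misplacedSamples", function(object) standardGeneric("misplacedSamples"))
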