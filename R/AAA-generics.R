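#' @import methods
NULL

#' @export
setGeneric("exprsMatrix", function(x, ...) standardGeneric("exprsMatrix"))

#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @export
setGeneric("classNames", function(x, ...) standardGeneric("classNames"))

#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @export
setGeneric("rankOrder", function(x) standardGeneric("rankOrder"))

#' @export
setGeneric("bestMask", function(x) standardGeneric("bestMask"))

#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))

#' @export
setGeneric("fitnessHistory", function(x) standardGeneric("fitnessHistory"))
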