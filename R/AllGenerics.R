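#' @import methods
NULL

#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @export
setGeneric("missingMask", function(x, ...) standardGeneric("missingMask"))

#' @export
setGeneric("ionMode", function(x, ...) standardGeneric("ionMode"))

#' @export
setGeneric("sampleGroups", function(x, ...) standardGeneric("sampleGroups"))

#' @export
setGeneric("isQC", function(x, ...) standardGeneric("isQC"))

#' @export
setGeneric("vipScores", function(object, ...) standardGeneric("vipScores"))

#' @export
setGeneric("pathwaySets", function(x, ...) standardGeneric("pathwaySets"))

#' @export
setGeneric("pathwayLabels", function(x, ...) standardGeneric("pathwayLabels"))
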