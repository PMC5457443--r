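#' @rdname PlateSet-class
#' @export
setGeneric("screenMode", function(x) standardGeneric("screenMode"))

#' @rdname PlateSet-class
#' @export
setGeneric("plateLayout", function(x) standardGeneric("plateLayout"))

#' @rdname PlateSet-class
#' @export
setGeneric("plateIds", function(x) standardGeneric("plateIds"))

#' @rdname PlateSet-class
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueUpGenes", function(x) standardGeneric("trueUpGenes"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueDownGenes", function(x) standardGeneric("trueDownGenes"))

#' @rdname GroundTruth-class
#' @export
setGeneric("toxicGenes", function(x) standardGeneric("toxicGenes"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueInteractors", function(x) standardGeneric("trueInteractors"))

#' @rdname GroundTruth-class
#' @export
setGeneric("enhancedInteractors",
           function(x) standardGeneric("enhancedInteractors"))

#' @rdname SpectralCountMatrix-class
#' @export
setGeneric("runInfo", function(x) standardGeneric("runInfo"))
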