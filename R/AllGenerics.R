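#' @rdname fovs
#' @export
setGeneric("fovs", function(x) standardGeneric("fovs"))

#' @rdname spatialCoords
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname cellLabels
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname cellLabels
#' @export
setGeneric("cellLabels<-", function(x, value) standardGeneric("cellLabels<-"))

#' @rdname fovOffsets
#' @export
setGeneric("fovOffsets", function(x) standardGeneric("fovOffsets"))
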