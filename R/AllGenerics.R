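#' @name stmli-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname stmli-generics
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname stmli-generics
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname stmli-generics
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname stmli-generics
#' @export
setGeneric("referenceType", function(x) standardGeneric("referenceType"))

#' @rdname stmli-generics
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname stmli-generics
#' @export
setGeneric("artifactEvents", function(x) standardGeneric("artifactEvents"))

#' @rdname stmli-generics
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))

#' @rdname stmli-generics
#' @export
setGeneric("recording", function(x) standardGeneric("recording"))

#' @rdname stmli-generics
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname stmli-generics
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname stmli-generics
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname stmli-generics
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname stmli-generics
#' @export
setGeneric("cohortMatrix", function(x) standardGeneric("cohortMatrix"))

#' @rdname stmli-generics
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
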