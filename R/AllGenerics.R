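#' @title Accessor generics
#' @description Generics for the core data classes: waveform containers,
#'   cochlear states, neurograms and fits. Accessors are the supported way to
#'   reach slot data.
#' @name dinoise-generics
#' @keywords internal
NULL

#' @rdname dinoise-generics
#' @param x An object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname dinoise-generics
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname dinoise-generics
#' @export
setGeneric("digitLabel", function(x) standardGeneric("digitLabel"))

#' @rdname dinoise-generics
#' @export
setGeneric("talkerId", function(x) standardGeneric("talkerId"))

#' @rdname dinoise-generics
#' @export
setGeneric("snrDb", function(x) standardGeneric("snrDb"))

#' @rdname dinoise-generics
#' @export
setGeneric("cfs", function(x) standardGeneric("cfs"))

#' @rdname dinoise-generics
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname dinoise-generics
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname dinoise-generics
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname dinoise-generics
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname dinoise-generics
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @rdname dinoise-generics
#' @export
setGeneric("stateId", function(x) standardGeneric("stateId"))
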