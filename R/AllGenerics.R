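#' @name neutroquant-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers. Slot access via
#'   `@` is considered internal; these are the supported surface.
#' @param x an object
#' @param marker a marker name present in the channel map
#' @keywords internal
NULL

#' @rdname neutroquant-generics
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname neutroquant-generics
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname neutroquant-generics
#' @export
setGeneric("getChannel", function(x, marker) standardGeneric("getChannel"))

#' @rdname neutroquant-generics
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname neutroquant-generics
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname neutroquant-generics
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname neutroquant-generics
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @rdname neutroquant-generics
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname neutroquant-generics
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname neutroquant-generics
#' @export
setGeneric("overlapSummary", function(x) standardGeneric("overlapSummary"))

#' @rdname neutroquant-generics
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname neutroquant-generics
#' @export
setGeneric("vascularShare", function(x) standardGeneric("vascularShare"))

#' @rdname neutroquant-generics
#' @export
setGeneric("tidyReport", function(x) standardGeneric("tidyReport"))
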