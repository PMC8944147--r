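# Accessors and show methods for the core containers.

#' @rdname neutroquant-generics
#' @export
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSize)

#' @rdname neutroquant-generics
#' @export
setMethod("pixelSize", "BinaryMask", function(x) x@pixelSize)

#' @rdname neutroquant-generics
#' @export
setMethod("pixelSize", "LabeledObjects", function(x) x@pixelSize)

#' @rdname neutroquant-generics
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) names(x@channelMap))

#' @rdname neutroquant-generics
#' @export
setMethod("getChannel", "MultiChannelImage", function(x, marker) {
  if (!marker %in% names(x@channelMap))
    stop("marker '", marker, "' not in channel map (have: ",
         paste(names(x@channelMap), collapse = ", "), ")")
  x@pixels[, , x@channelMap[[marker]]]
})

#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@pixels))

#' @rdname neutroquant-generics
#' @export
setMethod("maskArray", "BinaryMask", function(x) x@mask)

#' @rdname neutroquant-generics
#' @export
setMethod("provenance", "BinaryMask", function(x) x@provenance)

#' @rdname neutroquant-generics
#' @export
setMethod("labelImage", "LabeledObjects", function(x) x@labels)

#' @rdname neutroquant-generics
#' @export
setMethod("objectTable", "LabeledObjects", function(x) x@table)

#' @rdname neutroquant-generics
#' @export
setMethod("nObjects", "LabeledObjects", function(x) nrow(x@table))

#' @rdname neutroquant-generics
#' @export
setMethod("cellTable", "CellSet", function(x) x@cells)

#' @rdname neutroquant-generics
#' @export
setMethod("labelImage", "CellSet", function(x) x@objects@labels)

#' @rdname neutroquant-generics
#' @export
setMethod("objectTable", "CellSet", function(x) x@objects@table)

#' @rdname neutroquant-generics
#' @export
setMethod("overlapSummary", "CellSet", function(x) x@overlap)

#' @rdname neutroquant-generics
#' @export
setMethod("pairTable", "ColocalisationResult", function(x) x@pairs)

#' @rdname neutroquant-generics
#' @export
setMethod("overlapSummary", "ColocalisationResult", function(x) {
  data.frame(a_only = x@aOnly, b_only = x@bOnly, co_labelled = x@coLabelled,
             fraction_a_colabelled =
               if (x@nA > 0) x@coLabelled / x@nA else NA_real_)
})

#' @rdname neutroquant-generics
#' @export
setMethod("vascularShare", "MpoLoadResult", function(x) {
  if (x@total <= 0) NA_real_ else x@vascular / x@total
})

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@pixels)
  cat("MultiChannelImage:", d[1], "x", d[2], "px,", d[3], "channels at",
      object@pixelSize, "um/px\n")
  cat("  markers:", paste(names(object@channelMap), collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", nrow(object@mask), "x", ncol(object@mask), "px,",
      sum(object@mask), "foreground px\n")
  pv <- object@provenance
  if (length(pv))
    cat("  provenance:", paste(names(pv), vapply(pv, function(v)
      paste(format(v), collapse = "/"), ""), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LabeledObjects", function(object) {
  cat("LabeledObjects:", nrow(object@table), "objects in",
      nrow(object@labels), "x", ncol(object@labels), "px frame\n")
  if (nrow(object@table))
    cat("  area range:", round(min(object@table$area_um2), 1), "-",
        round(max(object@table$area_um2), 1), "um^2\n")
})

setMethod("show", "ColocalisationResult", function(object) {
  cat("ColocalisationResult:", object@markerA, "vs", object@markerB, "\n")
  cat("  ", object@markerA, "-only: ", object@aOnly, ", ", object@markerB,
      "-only: ", object@bOnly, ", co-labelled: ", object@coLabelled, "\n",
      sep = "")
})

setMethod("show", "CellSet", function(object) {
  cat("CellSet:", nrow(object@cells), "cells\n")
  if (nrow(object@cells)) print(table(object@cells$class))
})

setMethod("show", "MpoLoadResult", function(object) {
  cat("MpoLoadResult (", object@measure, "): total ", signif(object@total, 4),
      "\n", sep = "")
  if (object@total > 0)
    cat("  vascular ", round(100 * object@vascular / object@total, 1),
        "%, extravascular ",
        round(100 * object@extravascular / object@total, 1), "%\n", sep = "")
})

setMethod("show", "StatReport", function(object) {
  cat("StatReport:", object@test, "\n")
  if (length(object@estimate))
    cat("  estimates:", paste(names(object@estimate),
        signif(object@estimate, 4), sep = "=", collapse = ", "), "\n")
  if (length(object@statistic))
    cat("  statistic:", paste(names(object@statistic),
        signif(object@statistic, 4), sep = "=", collapse = ", "),
        " df:", paste(signif(object@df, 4), collapse = ","), "\n")
  cat("  p:", paste(signif(object@pValue, 4), collapse = ", "), "\n")
  if (!is.null(object@posthoc) && is.data.frame(object@posthoc) &&
      nrow(object@posthoc)) {
    cat("  post-hoc:\n")
    print(utils::head(object@posthoc, 10))
  }
})
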