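# Accessors and show methods for the core containers.

#' @describeIn VolumeImage-accessors voxel data array
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @describeIn VolumeImage-accessors voxel-to-world affine
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))
#' @describeIn VolumeImage-accessors unit tag
#' @export
setGeneric("imgUnits", function(x) standardGeneric("imgUnits"))
#' @describeIn VolumeImage-accessors map name
#' @export
setGeneric("imgName", function(x) standardGeneric("imgName"))
#' @describeIn VolumeImage-accessors echo times (s) of an [EchoSeries]
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' Accessors for image containers
#'
#' @param x a [VolumeImage], [EchoSeries] or [DynamicSeries].
#' @name VolumeImage-accessors
NULL

#' @export
setMethod("imgData", "VolumeImage", function(x) x@data)
#' @export
setMethod("imgData", "EchoSeries", function(x) x@data)
#' @export
setMethod("imgData", "DynamicSeries", function(x) x@data)
#' @export
setMethod("imgAffine", "VolumeImage", function(x) x@affine)
#' @export
setMethod("imgAffine", "EchoSeries", function(x) x@affine)
#' @export
setMethod("imgAffine", "DynamicSeries", function(x) x@affine)
#' @export
setMethod("imgUnits", "VolumeImage", function(x) x@units)
#' @export
setMethod("imgName", "VolumeImage", function(x) x@name)
#' @export
setMethod("echoTimes", "EchoSeries", function(x) x@echoTimes)

#' @describeIn DynamicSeries-accessors repetition time in seconds
#' @export
setGeneric("trS", function(x) standardGeneric("trS"))
#' @describeIn DynamicSeries-accessors echo time in seconds
#' @export
setGeneric("teS", function(x) standardGeneric("teS"))
#' @describeIn DynamicSeries-accessors number of pre-bolus baseline volumes
#' @export
setGeneric("nBaseline", function(x) standardGeneric("nBaseline"))

#' Accessors for dynamic series
#'
#' @param x a [DynamicSeries].
#' @name DynamicSeries-accessors
NULL

#' @export
setMethod("trS", "DynamicSeries", function(x) x@trS)
#' @export
setMethod("teS", "DynamicSeries", function(x) x@teS)
#' @export
setMethod("nBaseline", "DynamicSeries", function(x) x@nBaseline)

#' @describeIn TMEMap-accessors label volume of a [TMEMap]
#' @export
setGeneric("tmeLabels", function(x) standardGeneric("tmeLabels"))
#' @describeIn TMEMap-accessors legend (label/class/color) of a [TMEMap]
#' @export
setGeneric("tmeLegend", function(x) standardGeneric("tmeLegend"))

#' Accessors for TME maps
#'
#' @param x a [TMEMap].
#' @name TMEMap-accessors
NULL

#' @export
setMethod("tmeLabels", "TMEMap", function(x) x@labels)
#' @export
setMethod("tmeLegend", "TMEMap", function(x) x@legend)

#' @describeIn CompartmentSummary-accessors compartment percentages
#' @export
setGeneric("compartmentPercent", function(x) standardGeneric("compartmentPercent"))
#' @describeIn CompartmentSummary-accessors derived aggregates
#' @export
setGeneric("derivedPercent", function(x) standardGeneric("derivedPercent"))

#' Accessors for compartment summaries
#'
#' @param x a [CompartmentSummary].
#' @name CompartmentSummary-accessors
NULL

#' @export
setMethod("compartmentPercent", "CompartmentSummary", function(x) x@percent)
#' @export
setMethod("derivedPercent", "CompartmentSummary", function(x) x@derived)

#' @export
setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  v <- object@data[is.finite(object@data)]
  cat(sprintf("VolumeImage '%s' [%s] %s\n", object@name,
              paste(d, collapse = "x"), object@units))
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g  (%d invalid voxels)\n",
                min(v), max(v), sum(!is.finite(object@data))))
  invisible(object)
})

#' @export
setMethod("show", "EchoSeries", function(object) {
  cat(sprintf("EchoSeries [%s], %d echoes, TE %.1f..%.1f ms\n",
              paste(dim(object@data)[1:3], collapse = "x"),
              length(object@echoTimes),
              1000 * min(object@echoTimes), 1000 * max(object@echoTimes)))
  invisible(object)
})

#' @export
setMethod("show", "DynamicSeries", function(object) {
  cat(sprintf("DynamicSeries [%s], %d time points, TR %.2f s, TE %.1f ms, %d baseline\n",
              paste(dim(object@data)[1:3], collapse = "x"),
              dim(object@data)[4], object@trS, 1000 * object@teS,
              object@nBaseline))
  invisible(object)
})

#' @export
setMethod("show", "TMEMap", function(object) {
  lab <- object@labels@data
  tab <- table(factor(lab[lab > 0], levels = 1:5))
  cat("TMEMap:", sum(lab > 0, na.rm = TRUE), "classified voxels\n")
  for (i in 1:5)
    cat(sprintf("  %-14s (%s): %d\n", object@legend$class[i + 1],
                object@legend$color[i + 1], tab[[i]]))
  invisible(object)
})

#' @export
setMethod("show", "CompartmentSummary", function(object) {
  cat("CompartmentSummary over", object@nVoxels, "ROI voxels\n")
  p <- object@percent
  for (nm in names(p)) cat(sprintf("  %-14s %6.2f %%\n", nm, p[[nm]]))
  d <- object@derived
  for (nm in names(d)) cat(sprintf("  %-14s %6.2f %%  (derived)\n", nm, d[[nm]]))
  invisible(object)
})

#' Convert a compartment summary to a one-row data.frame
#'
#' @param x a [CompartmentSummary].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return one-row data.frame with class percentages and derived aggregates.
#' @export
as.data.frame.CompartmentSummary <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  as.data.frame(c(as.list(x@percent), as.list(x@derived),
                  list(n_voxels = x@nVoxels)), row.names = row.names)
}
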