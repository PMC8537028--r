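#' @import methods
NULL

#' VolumeImage: a 3D scalar field on a voxel grid
#'
#' Carrier for every biomarker map in the pipeline. Holds the voxel data,
#' the 4x4 voxel-to-world affine, a unit tag and a name. Invalid voxels
#' (outside the brain, failed fits) carry `NA` and propagate downstream.
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-to-world transform (RAS convention, 0-based voxel
#'   indices).
#' @slot units free-text unit tag, e.g. `"1/s"`, `"mm^2/s"`, `"mmHg"`.
#' @slot name identifier used for file names and provenance.
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix",
                 units = "character", name = "character"),
  prototype(units = "a.u.", name = "volume"))

setValidity("VolumeImage", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (!nzchar(object@units))
    msg <- c(msg, "units must be non-empty")
  if (length(msg)) msg else TRUE
})

#' EchoSeries: 4D multi-echo acquisition
#'
#' A stack of volumes acquired at increasing echo times, used for
#' voxelwise monoexponential R2*/R2 relaxometry.
#'
#' @slot data 4D numeric array (x, y, z, echo).
#' @slot echoTimes strictly increasing, positive echo times in seconds.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("EchoSeries",
  representation(data = "array", echoTimes = "numeric", affine = "matrix"))

setValidity("EchoSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array (x,y,z,echo)")
  else if (d[4] != length(object@echoTimes))
    msg <- c(msg, "echo count must match the 4th data dimension")
  if (any(object@echoTimes <= 0) || any(diff(object@echoTimes) <= 0))
    msg <- c(msg, "echoTimes must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' DynamicSeries: 4D dynamic susceptibility contrast acquisition
#'
#' A bolus-passage time series (gradient-echo or spin-echo DSC), with the
#' repetition time, echo time and the number of pre-bolus baseline volumes.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot trS repetition time in seconds (time between dynamic volumes).
#' @slot teS echo time in seconds.
#' @slot nBaseline number of pre-bolus time points (>= 3).
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("DynamicSeries",
  representation(data = "array", trS = "numeric", teS = "numeric",
                 nBaseline = "integer", affine = "matrix"))

setValidity("DynamicSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array (x,y,z,t)")
  if (object@trS <= 0 || object@teS <= 0)
    msg <- c(msg, "trS and teS must be positive")
  if (object@nBaseline < 3L)
    msg <- c(msg, "nBaseline must be >= 3")
  if (length(d) == 4L && object@nBaseline >= d[4])
    msg <- c(msg, "nBaseline must be smaller than the number of time points")
  if (length(msg)) msg else TRUE
})

#' TMEMap: integer-labeled tumor microenvironment compartment map
#'
#' Voxel labels: 0 unclassified/invalid, 1 glycolysis, 2 OxPhos,
#' 3 necrosis, 4 hypoxia with neovascularization, 5 hypoxia without
#' neovascularization. The legend carries the conventional display colors
#' (blue, green, black, yellow, red).
#'
#' @slot labels [VolumeImage] of integer labels (only nonzero inside the ROI).
#' @slot legend data.frame with columns label, class, color.
#' @export
setClass("TMEMap",
  representation(labels = "VolumeImage", legend = "data.frame"))

setValidity("TMEMap", function(object) {
  lab <- object@labels@data
  ok <- lab[is.finite(lab)]
  if (length(ok) && !all(ok %in% 0:5))
    "labels must be integers in 0..5" else TRUE
})

#' CompartmentSummary: per-ROI compartment percentages
#'
#' Percentages of the five TME classes plus unclassified voxels over the
#' enhancing-tumor ROI, with the derived aggregates: vital (= active) tumor
#' as glycolysis + OxPhos and total hypoxia as the sum of the two hypoxia
#' classes.
#'
#' @slot percent named numeric: glycolysis, oxphos, necrosis, hypoxia_nv,
#'   hypoxia_nonv, unclassified (sums to 100).
#' @slot derived named numeric: vital_tumor, active_tumor, total_hypoxia.
#' @slot counts named integer voxel counts per class.
#' @slot nVoxels total ROI voxel count.
#' @export
setClass("CompartmentSummary",
  representation(percent = "numeric", derived = "numeric",
                 counts = "integer", nVoxels = "integer"))

setValidity("CompartmentSummary", function(object) {
  if (abs(sum(object@percent) - 100) > 0.01)
    "class percentages plus unclassified must sum to 100" else TRUE
})
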