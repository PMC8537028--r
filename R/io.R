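# NIfTI I/O and container constructors.

#' Construct a VolumeImage
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix; default scales by `voxel_mm`.
#' @param units unit tag (non-empty).
#' @param name identifier.
#' @param voxel_mm voxel size used for the default affine.
#' @return a [VolumeImage].
#' @export
volumeImage <- function(data, affine = NULL, units = "a.u.", name = "volume",
                        voxel_mm = c(1.8, 1.8, 4)) {
  if (is.null(affine)) affine <- diag(c(voxel_mm, 1))
  new("VolumeImage", data = data, affine = affine, units = units, name = name)
}

#' Construct an EchoSeries
#'
#' @param data 4D array (x,y,z,echo).
#' @param echo_times_s strictly increasing echo times in seconds.
#' @param affine 4x4 matrix.
#' @return an [EchoSeries].
#' @export
echoSeries <- function(data, echo_times_s, affine = diag(c(1.8, 1.8, 4, 1))) {
  new("EchoSeries", data = data, echoTimes = as.numeric(echo_times_s),
      affine = affine)
}

#' Construct a DynamicSeries
#'
#' @param data 4D array (x,y,z,t).
#' @param tr_s repetition time (s).
#' @param te_s echo time (s).
#' @param n_baseline number of pre-bolus volumes.
#' @param affine 4x4 matrix.
#' @return a [DynamicSeries].
#' @export
dynamicSeries <- function(data, tr_s, te_s, n_baseline,
                          affine = diag(c(1.8, 1.8, 4, 1))) {
  new("DynamicSeries", data = data, trS = tr_s, teS = te_s,
      nBaseline = as.integer(n_baseline), affine = affine)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file.
#' @param expect_dims expected number of dimensions (3 or 4); a mismatch is
#'   an error so callers fail early on wrong inputs.
#' @param units,name metadata attached to the returned object.
#' @return a [VolumeImage] for 3D files, or a plain array (with `affine`
#'   attribute) for 4D files.
#' @export
readVolume <- function(path, expect_dims = 3L, units = "a.u.",
                       name = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(as.array(img)), dim(img))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  if (length(dim(arr)) != expect_dims)
    stop(sprintf("%s: expected %dD data, found %dD", path, expect_dims,
                 length(dim(arr))))
  if (expect_dims == 3L)
    volumeImage(arr, affine = affine, units = units, name = name)
  else
    structure(arr, affine = affine)
}

.write_nifti <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume or series to NIfTI
#'
#' @param x a [VolumeImage], [EchoSeries], [DynamicSeries], or array with an
#'   `affine` attribute.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "VolumeImage")) .write_nifti(x@data, x@affine, path)
  else if (is(x, "EchoSeries") || is(x, "DynamicSeries"))
    .write_nifti(x@data, x@affine, path)
  else if (is.array(x)) {
    aff <- attr(x, "affine")
    if (is.null(aff)) aff <- diag(c(1.8, 1.8, 4, 1))
    .write_nifti(unclass(x), aff, path)
  } else stop("cannot write object of class ", class(x)[1])
}

.same_grid <- function(a, b) {
  identical(dim(imgData(a))[1:3], dim(imgData(b))[1:3])
}
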