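# NIfTI-1 input/output, delegated to RNifti. Volumes are 3-D images; velocity
# and deformation fields are 4-D with the last axis holding the 3 vector
# components (voxel units). Data round-trip at float32 precision.

.niftiSpacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[1:3])
}

#' Read a scalar intensity volume from NIfTI
#'
#' @param path Path to a 3-D NIfTI-1 file (optionally gzipped).
#' @return A \linkS4class{ScalarVolume}.
#' @export
readScalarVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is rank %d; expected a 3-D volume", path, length(d)),
         call. = FALSE)
  ScalarVolume(array(as.numeric(img), dim(img)), spacing = .niftiSpacing(img))
}

#' Read a segmentation label volume from NIfTI
#'
#' @param path Path to a 3-D integer-valued NIfTI-1 file.
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is rank %d; expected a 3-D volume", path, length(d)),
         call. = FALSE)
  LabelVolume(array(round(as.numeric(img)), dim(img)),
              spacing = .niftiSpacing(img))
}

#' Write a volume to NIfTI
#'
#' Intensities are written as float32, labels as int32.
#'
#' @param vol A \linkS4class{ScalarVolume} or \linkS4class{LabelVolume}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  dtype <- if (is(vol, "LabelVolume")) "int32" else "float"
  a <- vol@data
  attr(a, "pixdim") <- vol@spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = dtype), path)
  invisible(path)
}

#' Load an externally computed stationary velocity field
#'
#' Validates and ingests a 4-D NIfTI SVF (e.g. the output of a learned
#' registration network), checking rank, component count and, optionally,
#' grid shape against the working template.
#'
#' @param path Path to a 4-D NIfTI with 3 components on the last axis.
#' @param grid Optional integer length-3 expected spatial shape (e.g.
#'   \code{gridDim(template)}); a mismatch is rejected with both shapes named.
#' @return A \linkS4class{VelocityField}.
#' @export
loadExternalSVF <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is rank %d; an SVF must be 4-D (grid x components)",
                 path, length(d)), call. = FALSE)
  if (d[4L] != 3L)
    stop(sprintf("'%s' has %d components on axis 4; an SVF needs 3",
                 path, d[4L]), call. = FALSE)
  if (!is.null(grid) && !identical(as.integer(d[1:3]), as.integer(grid)))
    stop(sprintf("SVF grid %s does not match working grid %s",
                 paste(d[1:3], collapse = "x"),
                 paste(grid, collapse = "x")), call. = FALSE)
  VelocityField(array(as.numeric(img), d), spacing = .niftiSpacing(img))
}

#' Write a velocity field to NIfTI
#'
#' @param v A \linkS4class{VelocityField}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
writeVelocityField <- function(v, path) {
  a <- v@data
  attr(a, "pixdim") <- c(v@spacing, 1)
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "float"), path)
  invisible(path)
}
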