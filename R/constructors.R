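#' Construct a ScalarVolume
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing Voxel size per axis in mm (default isotropic 1 mm).
#' @return A \linkS4class{ScalarVolume}.
#' @examples
#' vol <- ScalarVolume(array(runif(8^3), c(8, 8, 8)))
#' gridDim(vol)
#' @export
ScalarVolume <- function(data, spacing = c(1, 1, 1)) {
  new("ScalarVolume", data = data, spacing = as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param data 3-D array of non-negative integer labels.
#' @param spacing Voxel size per axis in mm.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1)) {
  storage.mode(data) <- "double"
  new("LabelVolume", data = data, spacing = as.numeric(spacing))
}

#' Construct a VelocityField
#'
#' @param data 4-D numeric array, last axis the 3 vector components in voxel
#'   units per unit time, component order matching the array axes.
#' @param spacing Voxel size per axis in mm (metadata only).
#' @return A \linkS4class{VelocityField}.
#' @export
VelocityField <- function(data, spacing = c(1, 1, 1)) {
  new("VelocityField", data = data, spacing = as.numeric(spacing))
}

#' Zero velocity field on a grid
#'
#' @param dims Integer length-3 grid size.
#' @param spacing Voxel size per axis in mm.
#' @return A \linkS4class{VelocityField} of zeros.
#' @export
zeroVelocityField <- function(dims, spacing = c(1, 1, 1)) {
  VelocityField(array(0, c(dims, 3L)), spacing = spacing)
}

#' Construct a DeformationField from a coordinate map
#'
#' @param data 4-D array of 0-based target voxel coordinates.
#' @param spacing Voxel size per axis in mm.
#' @param steps Squaring steps used to build it, if any.
#' @return A \linkS4class{DeformationField}.
#' @export
DeformationField <- function(data, spacing = c(1, 1, 1), steps = NA_integer_) {
  new("DeformationField", data = data, spacing = as.numeric(spacing),
      steps = as.integer(steps))
}

#' Identity deformation on a grid
#'
#' @param dims Integer length-3 grid size.
#' @param spacing Voxel size per axis in mm.
#' @return The identity \linkS4class{DeformationField} (maps every voxel to
#'   itself).
#' @export
identityDeformation <- function(dims, spacing = c(1, 1, 1)) {
  DeformationField(.identityGrid(dims), spacing = spacing, steps = 0L)
}

#' Displacement view of a deformation
#'
#' Deformations are stored as coordinate maps; this returns the displacement
#' field \eqn{u(x) = \phi(x) - x} (voxel units), the conventional form for
#' NIfTI I/O and visualization.
#'
#' @param phi A \linkS4class{DeformationField}.
#' @return A 4-D numeric array of displacements.
#' @export
displacementField <- function(phi) {
  stopifnot(is(phi, "DeformationField"))
  phi@data - .identityGrid(dim(phi@data)[1:3])
}
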