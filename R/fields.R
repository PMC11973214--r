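#' Integrate a stationary velocity field to a diffeomorphic deformation
#'
#' Computes the unit-time flow \eqn{\phi = \exp(v)} of a stationary velocity
#' field by scaling and squaring: the field is scaled by \eqn{2^{-steps}},
#' the identity is added to form a small coordinate map, and the map is
#' composed with itself \code{steps} times. For a zero field the result is the
#' identity map exactly; for a spatially constant field it is a translation.
#'
#' @param v A \linkS4class{VelocityField} (voxel units per unit time).
#' @param steps Number of squaring steps (default 7, a standard accuracy/cost
#'   trade-off for fields of up to a few voxels magnitude).
#' @return A \linkS4class{DeformationField} coordinate map.
#' @examples
#' v <- zeroVelocityField(c(8, 8, 8))
#' phi <- integrateSVF(v)
#' max(abs(displacementField(phi)))  # 0: identity
#' @export
integrateSVF <- function(v, steps = 7L) {
  stopifnot(is(v, "VelocityField"))
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  phi <- .integrateArray(v@data, steps)
  DeformationField(phi, spacing = v@spacing, steps = steps)
}

# Scaling-and-squaring on the displacement view: u <- u + u(x + u(x)).
.integrateArray <- function(vArr, steps) {
  d <- dim(vArr)[1:3]
  id <- .identityGrid(d)
  u <- vArr / 2^steps
  for (s in seq_len(steps)) {
    uu <- .sampleField4(u,
                        as.vector(id[, , , 1L] + u[, , , 1L]),
                        as.vector(id[, , , 2L] + u[, , , 2L]),
                        as.vector(id[, , , 3L] + u[, , , 3L]))
    u <- u + array(uu, c(d, 3L))
  }
  id + u
}

# Composition resamples the outer map at the inner map's coordinates; it is
# carried out on the displacement view (phi(x) = x + u(x)), which behaves far
# better under edge clamping than resampling raw coordinates: displacements
# are smooth and small at the faces where clamped coordinates would be biased.
.composeArray <- function(outerMap, innerMap) {
  d <- dim(outerMap)
  uOuter <- outerMap - .identityGrid(d[1:3])
  uu <- .sampleField4(uOuter,
                      as.vector(innerMap[, , , 1L]),
                      as.vector(innerMap[, , , 2L]),
                      as.vector(innerMap[, , , 3L]))
  innerMap + array(uu, d)
}

#' Compose two deformation fields
#'
#' Returns the coordinate map of \eqn{\phi_{outer} \circ \phi_{inner}}, i.e.
#' \eqn{x \mapsto \phi_{outer}(\phi_{inner}(x))}, by trilinear resampling of
#' the outer coordinate map at the inner map's coordinates (edge-clamped).
#'
#' @param phiOuter,phiInner \linkS4class{DeformationField}s on the same grid.
#' @return A \linkS4class{DeformationField}.
#' @export
composeFields <- function(phiOuter, phiInner) {
  stopifnot(is(phiOuter, "DeformationField"), is(phiInner, "DeformationField"))
  .stopIfShapeMismatch(phiOuter@data, phiInner@data, "deformation fields")
  DeformationField(.composeArray(phiOuter@data, phiInner@data),
                   spacing = phiOuter@spacing)
}

#' Warp a volume through a deformation field
#'
#' Resamples the image at the deformation's mapped coordinates (the
#' spatial-transformer / pullback convention: \code{warped(x) = image(phi(x))}).
#' Out-of-domain coordinates are edge-clamped. Label volumes are always
#' resampled with nearest-neighbour interpolation.
#'
#' @param image A \linkS4class{ScalarVolume} or \linkS4class{LabelVolume}.
#' @param phi A \linkS4class{DeformationField} on the same grid.
#' @param interpolation \code{"trilinear"} (default for intensities) or
#'   \code{"nearest"}; ignored (forced to nearest) for label volumes.
#' @return A warped volume of the same class as \code{image}.
#' @export
warpVolume <- function(image, phi,
                       interpolation = c("trilinear", "nearest")) {
  stopifnot(is(phi, "DeformationField"))
  isLabel <- is(image, "LabelVolume")
  if (!isLabel && !is(image, "ScalarVolume"))
    stop("image must be a ScalarVolume or LabelVolume", call. = FALSE)
  interpolation <- if (isLabel) "nearest" else match.arg(interpolation)
  .stopIfShapeMismatch(image@data, phi@data, "image and deformation")
  d <- dim(image@data)
  x <- as.vector(phi@data[, , , 1L])
  y <- as.vector(phi@data[, , , 2L])
  z <- as.vector(phi@data[, , , 3L])
  out <- if (interpolation == "trilinear")
    .sampleTrilinear(image@data, x, y, z)
  else
    .sampleNearest(image@data, x, y, z)
  out <- array(out, d)
  if (isLabel) LabelVolume(out, spacing = image@spacing)
  else ScalarVolume(out, spacing = image@spacing)
}

#' Invert a stationary velocity field
#'
#' In the SVF parameterization the inverse deformation is the flow of the
#' negated field, \eqn{\exp(v)^{-1} = \exp(-v)}, so inversion is a sign flip.
#'
#' @param v A \linkS4class{VelocityField}.
#' @return The negated \linkS4class{VelocityField}.
#' @export
invertSVF <- function(v) {
  stopifnot(is(v, "VelocityField"))
  VelocityField(-v@data, spacing = v@spacing)
}
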