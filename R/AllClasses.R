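#' @import methods
#' @importFrom stats lm coef quantile rnorm runif sd t.test var setNames pt
#' @importFrom utils read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib dbmaging, .registration = TRUE
NULL

.checkGrid3 <- function(data, what) {
  if (!is.array(data) || length(dim(data)) != 3L)
    return(sprintf("%s must be a 3-D array (got %s dims)", what,
                   length(dim(data))))
  if (!all(is.finite(data)))
    return(sprintf("%s contains non-finite values", what))
  NULL
}

.checkField4 <- function(data, what) {
  d <- dim(data)
  if (!is.array(data) || length(d) != 4L)
    return(sprintf("%s must be a 4-D array (grid x 3 components)", what))
  if (d[4L] != 3L)
    return(sprintf("%s must have 3 vector components, got %d", what, d[4L]))
  if (!all(is.finite(data)))
    return(sprintf("%s contains non-finite values", what))
  NULL
}

#' Scalar intensity volume
#'
#' A dense 3-D intensity grid with voxel spacing (mm) carried as metadata.
#' Intensities are expected in \[0, 1\] after preprocessing but this is not
#' enforced; finiteness is.
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing Numeric length-3 voxel size per axis (mm).
#'
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- .checkGrid3(object@data, "ScalarVolume data")
    if (is.null(msg) && length(object@spacing) != 3L)
      msg <- "spacing must have length 3"
    if (is.null(msg)) TRUE else msg
  })

#' Integer label volume
#'
#' A segmentation volume of non-negative integer labels (FreeSurfer/SynthSeg
#' label convention), sharing the grid of its companion \linkS4class{ScalarVolume}.
#'
#' @slot data 3-D array of non-negative integers (stored as numeric).
#' @slot spacing Numeric length-3 voxel size per axis (mm).
#'
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- .checkGrid3(object@data, "LabelVolume data")
    if (is.null(msg) && any(object@data < 0))
      msg <- "labels must be non-negative"
    if (is.null(msg) && any(object@data != round(object@data)))
      msg <- "labels must be integer-valued"
    if (is.null(msg)) TRUE else msg
  })

#' Stationary velocity field (SVF)
#'
#' A 3-D grid of 3-vectors in voxel units per unit time, the Lie-algebra
#' parameterization of a diffeomorphic deformation: the unit-time flow of the
#' field (see \code{\link{integrateSVF}}) is the deformation it encodes.
#'
#' @slot data 4-D numeric array; last axis indexes the vector component,
#'   ordered as the array axes.
#' @slot spacing Numeric length-3 voxel size per axis (mm), metadata only —
#'   all field algebra is in voxel units.
#'
#' @exportClass VelocityField
setClass("VelocityField",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- .checkField4(object@data, "VelocityField data")
    if (is.null(msg)) TRUE else msg
  })

#' Diffeomorphic deformation field
#'
#' A 3-D grid of mapped target coordinates (voxel units, 0-based), i.e. a
#' coordinate map \eqn{\phi}. Built from a zero velocity field it reduces to
#' the identity map. Stored as coordinates (not displacements) so that
#' composition is a pure resample; \code{\link{displacementField}} gives the
#' displacement view for I/O.
#'
#' @slot data 4-D numeric array of target coordinates; last axis = component.
#' @slot spacing Numeric length-3 voxel size (mm), metadata.
#' @slot steps Integer, number of squaring steps used in construction
#'   (\code{NA} for maps not built by scaling-and-squaring).
#'
#' @exportClass DeformationField
setClass("DeformationField",
  representation(data = "array", spacing = "numeric", steps = "integer"),
  validity = function(object) {
    msg <- .checkField4(object@data, "DeformationField data")
    if (is.null(msg)) TRUE else msg
  })

#' Result of SVF registration
#'
#' @slot svf Moving-to-fixed \linkS4class{VelocityField} over unit time.
#' @slot similarityTrace Numeric vector, the masked sum-of-squared-differences
#'   data term per accepted iteration (all multiresolution levels concatenated).
#' @slot levelIndex Integer vector parallel to \code{similarityTrace} giving the
#'   multiresolution level of each entry.
#' @slot converged Logical flag.
#' @slot settings List of settings actually used.
#'
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(svf = "VelocityField", similarityTrace = "numeric",
                 levelIndex = "integer", converged = "logical",
                 settings = "list"))

#' One-year normal-aging velocity field
#'
#' The template-pair SVF divided by the template age gap, giving the expected
#' deformation per year of normal aging, together with the ages involved.
#'
#' @slot v0 \linkS4class{VelocityField}, voxels per year.
#' @slot ageYoung,ageOld Template ages (years); \code{ageOld > ageYoung}.
#' @slot referenceAge Age (years) of the template all subjects register to.
#'
#' @exportClass NormalAgingField
setClass("NormalAgingField",
  representation(v0 = "VelocityField", ageYoung = "numeric",
                 ageOld = "numeric", referenceAge = "numeric"),
  validity = function(object) {
    if (object@ageOld <= object@ageYoung)
      return("ageOld must exceed ageYoung")
    TRUE
  })

#' Entropy focus criterion result
#'
#' @slot rawEFC Shannon-entropy sharpness value (nats); 0 when all in-mask
#'   energy sits in a single voxel.
#' @slot normalizedEFC \code{rawEFC} divided by the maximum attainable value
#'   for the in-mask voxel count (the uniform-image entropy); in \[0, 1\].
#' @slot nVoxels Number of in-mask voxels.
#' @slot bMax Root-sum-of-squares brightness normalizer.
#'
#' @exportClass EFCResult
setClass("EFCResult",
  representation(rawEFC = "numeric", normalizedEFC = "numeric",
                 nVoxels = "integer", bMax = "numeric"),
  validity = function(object) {
    if (object@normalizedEFC < -1e-12 || object@normalizedEFC > 1 + 1e-12)
      return("normalizedEFC must lie in [0, 1]")
    TRUE
  })

#' Voxel-wise aging / disease-specific score maps
#'
#' Per-voxel aging score (AS, years, signed) and disease-specific residual
#' magnitude (ADS, voxels, non-negative), defined only where \code{validMask}
#' is \code{TRUE} (inside the analysis region and where the normal-aging field
#' magnitude exceeds the rejection threshold).
#'
#' @slot asMap,adsMap 3-D numeric arrays; \code{NA} outside the valid mask.
#' @slot validMask 3-D logical array.
#'
#' @exportClass ScoreMap
setClass("ScoreMap",
  representation(asMap = "array", adsMap = "array", validMask = "array"),
  validity = function(object) {
    if (!identical(dim(object@asMap), dim(object@adsMap)) ||
        !identical(dim(object@asMap), dim(object@validMask)))
      return("asMap, adsMap and validMask must share one grid")
    v <- object@validMask
    if (any(object@adsMap[v] < 0))
      return("adsMap must be non-negative on valid voxels")
    TRUE
  })

#' Quantile-threshold selection record
#'
#' The R-squared of the AS-versus-age fit in the cognitively normal group,
#' per candidate quantile of the normal-aging-field magnitude used as an
#' outlier-rejection threshold, and the chosen (R-squared-maximizing) quantile.
#'
#' @slot quantileGrid,r2PerQuantile Numeric vectors, parallel.
#' @slot nVoxelsPerQuantile Integer vector of retained voxel counts (mean over
#'   scans, rounded), non-increasing in the quantile.
#' @slot chosenQuantile The argmax quantile; ties resolved to the smallest.
#'
#' @exportClass QuantileSelection
setClass("QuantileSelection",
  representation(quantileGrid = "numeric", r2PerQuantile = "numeric",
                 nVoxelsPerQuantile = "integer", chosenQuantile = "numeric"),
  validity = function(object) {
    if (length(object@quantileGrid) != length(object@r2PerQuantile))
      return("quantileGrid and r2PerQuantile lengths differ")
    if (is.unsorted(rev(object@nVoxelsPerQuantile)))
      return("retained voxel counts must be non-increasing in the quantile")
    TRUE
  })

#' Analysis region specification
#'
#' Names either a set of segmentation label ids or the derived
#' ventricle-edge map (the set difference between the ventricle segmentations
#' of the old and young templates).
#'
#' @slot name Region name.
#' @slot labelIds Integer label ids; empty for the whole-brain (foreground)
#'   and edge-map regions.
#' @slot edgeMap Logical; \code{TRUE} for the ventricle-edge region.
#'
#' @exportClass RegionSpec
setClass("RegionSpec",
  representation(name = "character", labelIds = "integer", edgeMap = "logical"),
  validity = function(object) {
    if (!object@edgeMap && length(object@labelIds) == 0L &&
        !identical(object@name, "whole-brain"))
      return("labelIds must be non-empty for a labelled region")
    TRUE
  })
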