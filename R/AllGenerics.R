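#' Extract the dense numeric array behind a volume or field object
#'
#' @param x A \linkS4class{ScalarVolume}, \linkS4class{LabelVolume},
#'   \linkS4class{VelocityField} or \linkS4class{DeformationField}.
#' @return The underlying numeric array (3-D for volumes, 4-D for fields).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing of a volume or field
#'
#' @param x A volume or field object.
#' @return Numeric length-3 voxel size per axis (mm).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Grid dimensions of a volume or field
#'
#' @param x A volume or field object.
#' @return Integer length-3 spatial grid size.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "VelocityField", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "DeformationField", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VelocityField", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DeformationField", function(x) x@spacing)

#' @rdname gridDim
#' @export
setMethod("gridDim", "ScalarVolume", function(x) dim(x@data))
#' @rdname gridDim
#' @export
setMethod("gridDim", "LabelVolume", function(x) dim(x@data))
#' @rdname gridDim
#' @export
setMethod("gridDim", "VelocityField", function(x) dim(x@data)[1:3])
#' @rdname gridDim
#' @export
setMethod("gridDim", "DeformationField", function(x) dim(x@data)[1:3])

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScalarVolume %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(object@spacing, collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  labs <- sort(unique(as.vector(object@data)))
  labs <- labs[labs != 0]
  cat(sprintf("LabelVolume %dx%dx%d, %d non-zero labels: %s\n",
              d[1], d[2], d[3], length(labs),
              paste(utils::head(labs, 12), collapse = ", ")))
})

setMethod("show", "VelocityField", function(object) {
  d <- dim(object@data)
  mag <- sqrt(rowSums(matrix(object@data, ncol = 3L)^2))
  cat(sprintf("VelocityField %dx%dx%d, |v| max %.4g, mean %.4g voxels/unit time\n",
              d[1], d[2], d[3], max(mag), mean(mag)))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@data)
  cat(sprintf("DeformationField %dx%dx%d (coordinate map, %s squaring steps)\n",
              d[1], d[2], d[3],
              if (is.na(object@steps)) "n/a" else object@steps))
})

setMethod("show", "RegistrationResult", function(object) {
  tr <- object@similarityTrace
  cat(sprintf("RegistrationResult: %d iterations over %d levels, SSD %.6g -> %.6g, %s\n",
              length(tr), length(unique(object@levelIndex)),
              tr[1], tr[length(tr)],
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "NormalAgingField", function(object) {
  cat(sprintf("NormalAgingField: v0 over ages %g-%g (reference %g), ",
              object@ageYoung, object@ageOld, object@referenceAge))
  show(object@v0)
})

setMethod("show", "EFCResult", function(object) {
  cat(sprintf("EFC: raw %.6g nats, normalized %.6g (N = %d in-mask voxels)\n",
              object@rawEFC, object@normalizedEFC, object@nVoxels))
})

setMethod("show", "ScoreMap", function(object) {
  n <- sum(object@validMask)
  cat(sprintf("ScoreMap: %d valid voxels", n))
  if (n > 0)
    cat(sprintf("; mean AS %.4g years, mean ADS %.4g voxels",
                mean(object@asMap[object@validMask]),
                mean(object@adsMap[object@validMask])))
  cat("\n")
})

setMethod("show", "QuantileSelection", function(object) {
  cat(sprintf("QuantileSelection: chosen quantile %.1f (R^2 = %.4f) over grid {%s}\n",
              object@chosenQuantile,
              object@r2PerQuantile[which(object@quantileGrid ==
                                           object@chosenQuantile)[1]],
              paste(object@quantileGrid, collapse = ", ")))
})

setMethod("show", "RegionSpec", function(object) {
  if (object@edgeMap)
    cat(sprintf("RegionSpec '%s' (ventricle-edge map)\n", object@name))
  else
    cat(sprintf("RegionSpec '%s' labels {%s}\n", object@name,
                paste(object@labelIds, collapse = ", ")))
})
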