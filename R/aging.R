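#' Built-in analysis regions
#'
#' The four regions analysed throughout: the whole brain, the ventricles
#' (segmentation labels 4, 14, 15, 43), the hippocampi & amygdala (labels
#' 17, 53, 18, 54) and the ventricle-edge map (the set difference between the
#' ventricle segmentations of the old and young templates, the rim where
#' registration of the homogeneous ventricle interior is least informative).
#'
#' @param name One of \code{"whole-brain"}, \code{"ventricles"},
#'   \code{"hippocampi-amygdala"}, \code{"ventricle-edge"}.
#' @return A \linkS4class{RegionSpec}.
#' @examples
#' regionSpec("ventricles")
#' @export
regionSpec <- function(name = c("whole-brain", "ventricles",
                                "hippocampi-amygdala", "ventricle-edge")) {
  name <- match.arg(name)
  switch(name,
    "whole-brain" = new("RegionSpec", name = name, labelIds = integer(0),
                        edgeMap = FALSE),
    "ventricles" = new("RegionSpec", name = name,
                       labelIds = c(4L, 14L, 15L, 43L), edgeMap = FALSE),
    "hippocampi-amygdala" = new("RegionSpec", name = name,
                                labelIds = c(17L, 53L, 18L, 54L),
                                edgeMap = FALSE),
    "ventricle-edge" = new("RegionSpec", name = name, labelIds = integer(0),
                           edgeMap = TRUE))
}

.VENTRICLE_LABELS <- c(4L, 14L, 15L, 43L)

#' Build the one-year normal-aging velocity field
#'
#' Divides the SVF registering the young template to the old one by the age
#' gap, giving the expected deformation per year of normal aging (linear
#' aging is assumed: the per-year field is constant across ages). With the
#' default 60- and 90-year templates this is the pair SVF divided by 30.
#'
#' @param pairSVF \linkS4class{VelocityField} from the young-to-old template
#'   registration (young template moving, old fixed).
#' @param ageYoung,ageOld Template ages in years; \code{ageOld > ageYoung}.
#' @param referenceAge Age of the template subjects are registered to
#'   (default \code{ageYoung}).
#' @return A \linkS4class{NormalAgingField}.
#' @export
buildAgingField <- function(pairSVF, ageYoung = 60, ageOld = 90,
                            referenceAge = ageYoung) {
  stopifnot(is(pairSVF, "VelocityField"))
  if (ageOld <= ageYoung)
    stop(sprintf("ageOld (%g) must exceed ageYoung (%g)", ageOld, ageYoung),
         call. = FALSE)
  v0 <- VelocityField(pairSVF@data / (ageOld - ageYoung),
                      spacing = pairSVF@spacing)
  new("NormalAgingField", v0 = v0, ageYoung = ageYoung, ageOld = ageOld,
      referenceAge = referenceAge)
}

#' Binary analysis mask for a region
#'
#' Whole-brain is the brain foreground; labelled regions are the union of the
#' region's segmentation labels intersected with the brain foreground; the
#' ventricle-edge map is the set difference between the old- and
#' young-template ventricle segmentations (by default the symmetric
#' difference; \code{growthOnly = TRUE} restricts to the enlargement shell
#' old-minus-young, the dominant direction since ventricles enlarge with age).
#'
#' @param region A \linkS4class{RegionSpec} or region name accepted by
#'   \code{\link{regionSpec}}.
#' @param segRef \linkS4class{LabelVolume} segmentation of the reference
#'   (young) template.
#' @param segOld Segmentation of the old template; required for the edge map.
#' @param brainMask Optional \linkS4class{LabelVolume} brain foreground;
#'   defaults to \code{segRef != 0}.
#' @param growthOnly Edge map only: keep only voxels ventricular in the old
#'   template but not the young one.
#' @return A 3-D logical array.
#' @export
regionMask <- function(region, segRef, segOld = NULL, brainMask = NULL,
                       growthOnly = FALSE) {
  if (is.character(region)) region <- regionSpec(region)
  stopifnot(is(region, "RegionSpec"), is(segRef, "LabelVolume"))
  brain <- if (is.null(brainMask)) segRef@data != 0 else {
    .stopIfShapeMismatch(segRef@data, brainMask@data, "segmentation and brain mask")
    brainMask@data != 0
  }
  if (region@edgeMap) {
    if (is.null(segOld))
      stop("the ventricle-edge region requires segOld", call. = FALSE)
    .stopIfShapeMismatch(segRef@data, segOld@data, "young and old segmentations")
    vy <- array(segRef@data %in% .VENTRICLE_LABELS, dim(segRef@data))
    vo <- array(segOld@data %in% .VENTRICLE_LABELS, dim(segOld@data))
    m <- if (growthOnly) vo & !vy else xor(vy, vo)
    return(m)
  }
  if (region@name == "whole-brain") return(brain)
  present <- region@labelIds %in% unique(as.vector(segRef@data))
  if (!any(present))
    stop(sprintf("none of the labels {%s} for region '%s' are present in the segmentation",
                 paste(region@labelIds, collapse = ", "), region@name),
         call. = FALSE)
  array(segRef@data %in% region@labelIds, dim(segRef@data)) & brain
}
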