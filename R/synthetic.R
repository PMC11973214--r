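# Synthetic brain phantoms, ground-truth aging/disease velocity fields and
# full cohorts with known AS/ADS structure. These stand in for the learned
# age-conditioned templates and their segmentations, so the whole pipeline is
# exercisable with zero downloads. All geometry is synthetic and labelled as
# such; label ids reuse the FreeSurfer/SynthSeg convention so the built-in
# region definitions apply unchanged.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# Ellipsoidal "radius" (1 on the surface) of grid points around a center.
.ellipsoidRho <- function(dims, center, radii) {
  g <- .identityGrid(dims) + 1  # 1-based coordinates
  sqrt(((g[, , , 1L] - center[1]) / radii[1])^2 +
       ((g[, , , 2L] - center[2]) / radii[2])^2 +
       ((g[, , , 3L] - center[3]) / radii[3])^2)
}

#' Phantom geometry specification
#'
#' Describes a brain-like phantom: an outer "brain" ellipsoid, two
#' "ventricle" ellipsoids (labels 4/43) and two "hippocampus" blobs (labels
#' 17/53; the amygdala labels are merged into these blobs, so the built-in
#' hippocampi-amygdala region applies). Geometry scales with the grid so any
#' shape up to full scan size works.
#'
#' @param shape Integer length-3 grid size (default 48 cubed, which keeps
#'   every downstream experiment fast while leaving room for multi-voxel
#'   deformations).
#' @param intensities Named intensity levels in \[0, 1\] for tissue,
#'   ventricle (dark, CSF-like) and hippocampus.
#' @param smoothSigma Edge-softening Gaussian sigma (voxels) for the
#'   intensity image (labels stay crisp).
#' @return A list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(shape = c(48L, 48L, 48L),
                        intensities = c(tissue = 0.6, ventricle = 0.1,
                                        hippocampus = 0.4),
                        smoothSigma = 0.8) {
  shape <- as.integer(rep(shape, length.out = 3L))
  c0 <- (shape + 1) / 2
  s <- min(shape)
  structure(list(
    shape = shape,
    brain = list(center = c0, radii = 0.40 * shape),
    ventricles = list(
      list(label = 4L, center = c0 + c(-0.115, -0.030, 0.020) * s,
           radii = c(0.070, 0.110, 0.080) * s),
      list(label = 43L, center = c0 + c(0.115, -0.030, 0.020) * s,
           radii = c(0.070, 0.110, 0.080) * s)),
    hippocampi = list(
      list(label = 17L, center = c0 + c(-0.170, 0.120, -0.100) * s,
           radii = c(0.060, 0.075, 0.060) * s),
      list(label = 53L, center = c0 + c(0.170, 0.120, -0.100) * s,
           radii = c(0.060, 0.075, 0.060) * s)),
    intensities = intensities,
    smoothSigma = smoothSigma), class = "phantomSpec")
}

#' Generate a brain-like phantom template and segmentation
#'
#' @param spec A \code{\link{phantomSpec}}.
#' @return A list with \code{template} (\linkS4class{ScalarVolume},
#'   intensities in \[0, 1\]) and \code{seg} (\linkS4class{LabelVolume} with
#'   labels 2 = tissue, 4/43 = ventricles, 17/53 = hippocampi).
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(24, 24, 24)))
#' sort(unique(as.vector(voxelData(ph$seg))))
#' @export
makePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "phantomSpec"))
  d <- spec$shape
  brain <- .ellipsoidRho(d, spec$brain$center, spec$brain$radii) <= 1
  seg <- array(0, d)
  img <- array(0, d)
  seg[brain] <- 2
  img[brain] <- spec$intensities[["tissue"]]
  inner <- c(spec$ventricles, spec$hippocampi)
  masks <- lapply(inner, function(st)
    .ellipsoidRho(d, st$center, st$radii) <= 1)
  for (i in seq_along(inner)) {
    if (!all(brain[masks[[i]]]))
      stop(sprintf("structure with label %d is not nested inside the brain",
                   inner[[i]]$label), call. = FALSE)
    for (j in seq_len(i - 1L))
      if (any(masks[[i]] & masks[[j]]))
        stop(sprintf("structures with labels %d and %d overlap",
                     inner[[j]]$label, inner[[i]]$label), call. = FALSE)
    seg[masks[[i]]] <- inner[[i]]$label
    lvl <- if (inner[[i]]$label %in% c(4L, 43L)) "ventricle" else "hippocampus"
    img[masks[[i]]] <- spec$intensities[[lvl]]
  }
  img <- .smooth3(img, spec$smoothSigma)
  list(template = ScalarVolume(img), seg = LabelVolume(seg))
}

#' Ground-truth one-year aging velocity field for a phantom
#'
#' Builds a smooth field that enlarges the ventricles and shrinks the
#' hippocampal blobs when the phantom is warped through its flow — the two
#' cardinal macroscopic signatures of normal brain aging. The field peaks at
#' \code{rate} voxels/year on each structure's boundary (a Gaussian shell of
#' width \code{width} voxels around the surface, radially oriented) and is
#' exactly zero outside the brain. Doubling \code{rate} doubles the field
#' exactly. Deformations act by pullback resampling, so "enlarging" means the
#' field points toward the ventricle centers.
#'
#' @param template Phantom \linkS4class{ScalarVolume} (grid/spacing carrier).
#' @param seg Phantom \linkS4class{LabelVolume}.
#' @param spec The \code{\link{phantomSpec}} used to build them.
#' @param rate Peak field magnitude, voxels per year (default 0.05, i.e.
#'   1.5 voxels of boundary motion over a 30-year gap).
#' @param width Shell width in voxels.
#' @return A \linkS4class{VelocityField} (the ground-truth one-year field).
#' @export
makeAgingField <- function(template, seg, spec = phantomSpec(),
                           rate = 0.05, width = 1.6) {
  stopifnot(is(template, "ScalarVolume"), is(seg, "LabelVolume"))
  d <- dim(template@data)
  field <- array(0, c(d, 3L))
  if (rate == 0) return(VelocityField(field, spacing = template@spacing))
  g <- .identityGrid(d) + 1
  addStructure <- function(st, sign) {
    rho <- .ellipsoidRho(d, st$center, st$radii)
    rbar <- prod(st$radii)^(1 / 3)
    amp <- rate * exp(-((rho - 1) * rbar)^2 / (2 * width^2))
    dx <- g[, , , 1L] - st$center[1]
    dy <- g[, , , 2L] - st$center[2]
    dz <- g[, , , 3L] - st$center[3]
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    nrm[nrm == 0] <- 1
    field[, , , 1L] <<- field[, , , 1L] + sign * amp * dx / nrm
    field[, , , 2L] <<- field[, , , 2L] + sign * amp * dy / nrm
    field[, , , 3L] <<- field[, , , 3L] + sign * amp * dz / nrm
  }
  # pullback convention: inward field grows a structure, outward shrinks it
  for (st in spec$ventricles) addStructure(st, -1)
  for (st in spec$hippocampi) addStructure(st, +1)
  brain <- seg@data != 0
  field <- field * as.vector(brain)
  VelocityField(field, spacing = template@spacing)
}

#' Synthesize one subject with known aging and disease components
#'
#' Constructs the ground-truth subject-to-template SVF as
#' \deqn{v_{true} = AS_{true} \cdot v_{age} + ADS_{true} \cdot w + noise,}
#' where \eqn{w} is a smooth random unit field made voxel-wise orthogonal to
#' \eqn{v_{age}} by per-voxel Gram-Schmidt (zero where \eqn{v_{age}} is), so
#' the voxel-wise decomposition recovers \code{asTrue} and \code{adsTrue}
#' exactly in the noiseless case. The noise is a smoothed Gaussian vector
#' field (per-component standard deviation \code{noiseSigma} voxels),
#' emulating registration error.
#'
#' @param template Phantom \linkS4class{ScalarVolume}.
#' @param vAge One-year aging \linkS4class{VelocityField} (ground truth).
#' @param asTrue Planted aging score (years; signed).
#' @param adsTrue Planted disease-specific magnitude (voxels; >= 0).
#' @param noiseSigma Per-component noise SD (voxels); 0 for noiseless.
#' @param seed RNG seed for the disease direction and noise.
#' @param steps Squaring steps for the image warp.
#' @param warpImage Set \code{FALSE} to skip the (comparatively costly)
#'   image synthesis and return only the SVF.
#' @return A list with \code{svfTrue} (\linkS4class{VelocityField}),
#'   \code{image} (warped \linkS4class{ScalarVolume}, or \code{NULL}), and
#'   \code{w} (the unit disease-direction field).
#' @export
makeSubject <- function(template, vAge, asTrue, adsTrue, noiseSigma = 0,
                        seed = 1L, steps = 7L, warpImage = TRUE) {
  stopifnot(is(template, "ScalarVolume"), is(vAge, "VelocityField"),
            is.finite(asTrue), adsTrue >= 0)
  .stopIfShapeMismatch(template@data, vAge@data, "template and aging field")
  d <- dim(template@data)
  res <- .withSeed(seed, {
    w <- .orthogonalUnitField(vAge@data, sigma = 2)
    noise <- array(0, c(d, 3L))
    if (noiseSigma > 0) {
      noise <- array(rnorm(prod(d) * 3L), c(d, 3L))
      noise <- .smooth4(noise, 1.5)
      noise <- noise * (noiseSigma / stats::sd(as.vector(noise)))
    }
    list(w = w, noise = noise)
  })
  svf <- asTrue * vAge@data + adsTrue * res$w + res$noise
  svfTrue <- VelocityField(svf, spacing = template@spacing)
  image <- NULL
  if (warpImage)
    image <- warpVolume(template, integrateSVF(svfTrue, steps = steps))
  list(svfTrue = svfTrue, image = image,
       w = VelocityField(res$w, spacing = template@spacing))
}

# Smooth random unit vector field, voxel-wise orthogonalized against vAge by
# Gram-Schmidt; zero where ||vAge|| <= eps (those voxels are invalid for
# scoring anyway).
.orthogonalUnitField <- function(vAgeArr, sigma = 2, eps = 1e-8) {
  d <- dim(vAgeArr)[1:3]
  raw <- array(rnorm(prod(d) * 3L), c(d, 3L))
  raw <- .smooth4(raw, sigma)
  va <- matrix(vAgeArr, ncol = 3L)
  wm <- matrix(raw, ncol = 3L)
  n0sq <- rowSums(va^2)
  act <- sqrt(n0sq) > eps
  proj <- rowSums(wm * va) / pmax(n0sq, eps^2)
  wm <- wm - proj * va
  wn <- sqrt(rowSums(wm^2))
  ok <- act & wn > eps
  wm[ok, ] <- wm[ok, , drop = FALSE] / wn[ok]
  wm[!ok, ] <- 0
  array(wm, c(d, 3L))
}

#' Cohort simulation specification
#'
#' Study-scale defaults for a synthetic cohort emulating a cross-sectional
#' neurodegeneration dataset: a cognitively normal (CN) group plus clinical
#' stages CDR 0 / 0.5 / 1 / 2 (the CDR 2 stage has only a handful of scans,
#' matching its scarcity in such cohorts, and is excluded from testing by
#' default downstream). CN aging follows the planted slope
#' \code{asSlope} years of morphological age per chronological year relative
#' to \code{referenceAge}; disease groups add an aging acceleration
#' (\code{asOffsets}, years) and a disease-specific orthogonal component
#' (\code{adsOffsets}, voxels) increasing with stage.
#'
#' @param nPerGroup Named integer vector of scans per group.
#' @param ageRange Named list of \code{c(min, max)} scan-age ranges (years).
#' @param asSlope Planted AS-per-year slope in CN (default 1).
#' @param asJitterSD Between-scan SD of the planted AS (years).
#' @param asOffsets Named per-group AS offsets (years).
#' @param adsOffsets Named per-group planted ADS magnitudes (voxels).
#' @param adsJitterSD Between-scan SD of the planted ADS (voxels).
#' @param noiseSigma Per-component SVF measurement noise SD (voxels).
#' @param referenceAge Reference template age (years).
#' @param seed Master RNG seed; everything downstream derives from it.
#' @return A list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nPerGroup = c(CN = 40L, CDR0 = 25L, `CDR0.5` = 25L,
                                     CDR1 = 20L, CDR2 = 4L),
                       ageRange = list(CN = c(60, 90), CDR0 = c(62, 88),
                                       `CDR0.5` = c(64, 88), CDR1 = c(65, 88),
                                       CDR2 = c(66, 86)),
                       asSlope = 1.0, asJitterSD = 1.0,
                       asOffsets = c(CN = 0, CDR0 = 2, `CDR0.5` = 4,
                                     CDR1 = 6, CDR2 = 8),
                       adsOffsets = c(CN = 0.05, CDR0 = 0.15, `CDR0.5` = 0.25,
                                      CDR1 = 0.40, CDR2 = 0.55),
                       adsJitterSD = 0.02, noiseSigma = 0.05,
                       referenceAge = 60, seed = 1L) {
  groups <- names(nPerGroup)
  bad <- setdiff(groups, .GROUP_LEVELS)
  if (length(bad))
    stop(sprintf("unknown groups: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  structure(list(nPerGroup = nPerGroup, ageRange = ageRange,
                 asSlope = asSlope, asJitterSD = asJitterSD,
                 asOffsets = asOffsets, adsOffsets = adsOffsets,
                 adsJitterSD = adsJitterSD, noiseSigma = noiseSigma,
                 referenceAge = referenceAge, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Simulate a full cohort to disk
#'
#' Builds the phantom template pair (young, and old = young warped through
#' the 30-year aging flow), the ground-truth pair SVF and aging field, and
#' one scan per cohort row (subject SVF, optionally the warped image), plus
#' a demographics table and a ground-truth table for recovery experiments.
#' Fully deterministic under the spec's seed.
#'
#' @param spec A \code{\link{cohortSpec}}.
#' @param dir Output directory (created if needed).
#' @param shape Phantom grid size.
#' @param rate Peak one-year aging-field magnitude (voxels/year).
#' @param ageGap Template-pair age gap in years (old = reference + gap).
#' @param images Also write warped subject images (slower).
#' @param steps Squaring steps for warps.
#' @return A list: \code{dir}, \code{demographics} (data.frame),
#'   \code{truth} (data.frame), \code{files} (named paths for templates,
#'   segmentations, pair SVF and aging field).
#' @export
makeCohort <- function(spec = cohortSpec(), dir = tempfile("cohort"),
                       shape = c(48L, 48L, 48L), rate = 0.05, ageGap = 30,
                       images = TRUE, steps = 7L) {
  stopifnot(inherits(spec, "cohortSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "svf"), showWarnings = FALSE)
  if (images) dir.create(file.path(dir, "img"), showWarnings = FALSE)

  pspec <- phantomSpec(shape = shape)
  ph <- makePhantom(pspec)
  vAge <- makeAgingField(ph$template, ph$seg, pspec, rate = rate)
  pairSVF <- VelocityField(ageGap * vAge@data, spacing = vAge@spacing)
  phiPair <- integrateSVF(pairSVF, steps = steps)
  templateOld <- warpVolume(ph$template, phiPair)
  segOld <- warpVolume(ph$seg, phiPair)

  files <- list(template = file.path(dir, "template.nii.gz"),
                seg = file.path(dir, "seg.nii.gz"),
                templateOld = file.path(dir, "template_old.nii.gz"),
                segOld = file.path(dir, "seg_old.nii.gz"),
                pairSVF = file.path(dir, "pair_svf.nii.gz"),
                agingField = file.path(dir, "aging_field.nii.gz"))
  writeVolume(ph$template, files$template)
  writeVolume(ph$seg, files$seg)
  writeVolume(templateOld, files$templateOld)
  writeVolume(segOld, files$segOld)
  writeVelocityField(pairSVF, files$pairSVF)
  writeVelocityField(vAge, files$agingField)

  rows <- list()
  scanIdx <- 0L
  for (grp in names(spec$nPerGroup)) {
    n <- spec$nPerGroup[[grp]]
    if (n == 0L) next
    draws <- .withSeed(as.integer((as.numeric(spec$seed) * 1009 +
                                   match(grp, .GROUP_LEVELS)) %% 2147483647), {
      rng <- spec$ageRange[[grp]]
      data.frame(age = runif(n, rng[1], rng[2]),
                 asJit = rnorm(n, 0, spec$asJitterSD),
                 adsJit = rnorm(n, 0, spec$adsJitterSD))
    })
    for (i in seq_len(n)) {
      scanIdx <- scanIdx + 1L
      id <- sprintf("scan%03d", scanIdx)
      age <- draws$age[i]
      asTrue <- spec$asSlope * (age - spec$referenceAge) +
        spec$asOffsets[[grp]] + draws$asJit[i]
      adsTrue <- max(0, spec$adsOffsets[[grp]] + draws$adsJit[i])
      subj <- makeSubject(ph$template, vAge, asTrue = asTrue,
                          adsTrue = adsTrue, noiseSigma = spec$noiseSigma,
                          seed = as.integer((as.numeric(spec$seed) * 7919 +
                                             scanIdx) %% 2147483647),
                          steps = steps, warpImage = images)
      writeVelocityField(subj$svfTrue,
                         file.path(dir, "svf", paste0(id, ".nii.gz")))
      if (images)
        writeVolume(subj$image, file.path(dir, "img", paste0(id, ".nii.gz")))
      rows[[scanIdx]] <- data.frame(scan_id = id, subject_id = id,
                                    age = age, group = grp,
                                    as_true = asTrue, ads_true = adsTrue,
                                    stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth))
    truth <- data.frame(scan_id = character(0), subject_id = character(0),
                        age = numeric(0), group = character(0),
                        as_true = numeric(0), ads_true = numeric(0))
  demographics <- truth[, c("scan_id", "subject_id", "age", "group")]
  write.csv(demographics, file.path(dir, "demographics.csv"),
            row.names = FALSE)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(nPerGroup = as.list(spec$nPerGroup), asSlope = spec$asSlope,
         asJitterSD = spec$asJitterSD, asOffsets = as.list(spec$asOffsets),
         adsOffsets = as.list(spec$adsOffsets),
         adsJitterSD = spec$adsJitterSD, noiseSigma = spec$noiseSigma,
         referenceAge = spec$referenceAge, seed = spec$seed,
         shape = shape, rate = rate, ageGap = ageGap),
    file.path(dir, "cohort_spec.json"), auto_unbox = TRUE, digits = NA)
  list(dir = dir, demographics = demographics, truth = truth, files = files)
}
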