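#' Voxel-wise decomposition of a subject SVF into aging and residual parts
#'
#' At every voxel where the normal-aging field has magnitude above
#' \code{eps}, the subject-to-template SVF is orthogonally projected onto the
#' one-year normal-aging field \eqn{v_0}:
#' \deqn{AS = \frac{\langle v_{subject}, v_0\rangle}{\|v_0\|^2}, \qquad
#'       ADS = \|v_{subject} - AS \cdot v_0\|.}
#' AS (years) measures alignment with the normal-aging direction — negative
#' values mean slower-than-normal aging; ADS (voxels) is the magnitude of the
#' residual orthogonal to it. Voxels with \eqn{\|v_0\| \le eps} are marked
#' invalid (the quantile outlier-rejection stage is the real guard against
#' near-zero \eqn{\|v_0\|}; \code{eps} only prevents division blow-ups).
#'
#' @param vSubject Subject-to-template \linkS4class{VelocityField}.
#' @param v0 One-year normal-aging \linkS4class{VelocityField} (or a
#'   \linkS4class{NormalAgingField}) on the same grid.
#' @param eps Magnitude guard for \eqn{\|v_0\|}, voxels.
#' @return A \linkS4class{ScoreMap}.
#' @export
decomposeVoxelwise <- function(vSubject, v0, eps = 1e-8) {
  if (is(v0, "NormalAgingField")) v0 <- v0@v0
  stopifnot(is(vSubject, "VelocityField"), is(v0, "VelocityField"), eps > 0)
  .stopIfShapeMismatch(vSubject@data, v0@data, "subject SVF and v0")
  d <- dim(v0@data)[1:3]
  vs <- matrix(vSubject@data, ncol = 3L)
  va <- matrix(v0@data, ncol = 3L)
  n0sq <- rowSums(va^2)
  valid <- sqrt(n0sq) > eps
  as_ <- rep(NA_real_, nrow(vs))
  ads <- rep(NA_real_, nrow(vs))
  as_[valid] <- rowSums(vs[valid, , drop = FALSE] *
                        va[valid, , drop = FALSE]) / n0sq[valid]
  resid <- vs[valid, , drop = FALSE] - as_[valid] * va[valid, , drop = FALSE]
  ads[valid] <- sqrt(rowSums(resid^2))
  new("ScoreMap", asMap = array(as_, d), adsMap = array(ads, d),
      validMask = array(valid, d))
}

#' Quantile-based outlier rejection on the normal-aging-field magnitude
#'
#' Voxels with small \eqn{\|v_0\|} produce disproportionately large score
#' values; this retains the in-region valid voxels whose \eqn{\|v_0\|} is at
#' least the quantile-\code{q} value of \eqn{\|v_0\|} over the region's valid
#' voxels (linear-interpolation quantile, computed per region). Quantile 0
#' retains every in-region valid voxel.
#'
#' @param scoreMap A \linkS4class{ScoreMap} from
#'   \code{\link{decomposeVoxelwise}}.
#' @param v0 The \linkS4class{VelocityField} (or
#'   \linkS4class{NormalAgingField}) the map was computed against.
#' @param regionMask 3-D logical array, e.g. from \code{\link{regionMask}}.
#' @param quantile Threshold quantile in \[0, 1).
#' @return A \linkS4class{ScoreMap} restricted to the retained voxels.
#' @export
rejectOutliers <- function(scoreMap, v0, regionMask, quantile = 0) {
  if (is(v0, "NormalAgingField")) v0 <- v0@v0
  stopifnot(is(scoreMap, "ScoreMap"), is(v0, "VelocityField"))
  if (quantile < 0 || quantile >= 1)
    stop("quantile must lie in [0, 1)", call. = FALSE)
  .stopIfShapeMismatch(scoreMap@asMap, v0@data, "score map and v0")
  .stopIfShapeMismatch(scoreMap@asMap, regionMask, "score map and region mask")
  norms <- .fieldNorm(v0@data)
  base <- scoreMap@validMask & regionMask
  if (!any(base))
    stop(sprintf("no valid voxels in region at quantile %g", quantile),
         call. = FALSE)
  keep <- base
  if (quantile > 0) {
    thr <- stats::quantile(norms[base], probs = quantile, names = FALSE,
                           type = 7)
    keep <- base & norms >= thr
  }
  if (!any(keep))
    stop(sprintf("outlier rejection retained no voxels (quantile %g)",
                 quantile), call. = FALSE)
  as_ <- scoreMap@asMap; ads <- scoreMap@adsMap
  as_[!keep] <- NA_real_; ads[!keep] <- NA_real_
  new("ScoreMap", asMap = as_, adsMap = ads, validMask = keep)
}

#' Regional aggregation of voxel-wise scores
#'
#' The regional aging score and disease-specific score are the arithmetic
#' means of the voxel-wise values over the retained voxels (for ADS, the mean
#' of the voxel-wise residual norms).
#'
#' @param scoreMap A \linkS4class{ScoreMap} (usually after
#'   \code{\link{rejectOutliers}}).
#' @return A list with \code{AS} (years), \code{ADS} (voxels) and
#'   \code{nVoxels}.
#' @export
aggregateRegion <- function(scoreMap) {
  stopifnot(is(scoreMap, "ScoreMap"))
  v <- scoreMap@validMask
  if (!any(v)) stop("no valid voxels to aggregate", call. = FALSE)
  list(AS = mean(scoreMap@asMap[v]), ADS = mean(scoreMap@adsMap[v]),
       nVoxels = sum(v))
}

#' Score one scan over a set of regions
#'
#' Runs the voxel-wise decomposition once and aggregates it over each
#' requested region at the given quantile(s), returning one row per
#' (region, quantile).
#'
#' @param vSubject Subject-to-template \linkS4class{VelocityField}.
#' @param aging A \linkS4class{NormalAgingField} or plain
#'   \linkS4class{VelocityField} \eqn{v_0}.
#' @param segRef,segOld Young/old template segmentations (see
#'   \code{\link{regionMask}}).
#' @param regions Character vector of region names or list of
#'   \linkS4class{RegionSpec}s.
#' @param quantiles Numeric vector of rejection quantiles, or a single value.
#' @param eps Magnitude guard passed to \code{\link{decomposeVoxelwise}}.
#' @return A data.frame with columns \code{region}, \code{quantile},
#'   \code{AS}, \code{ADS}, \code{nVoxels}.
#' @export
scoreScan <- function(vSubject, aging, segRef, segOld = NULL,
                      regions = c("whole-brain", "ventricles",
                                  "hippocampi-amygdala", "ventricle-edge"),
                      quantiles = 0, eps = 1e-8) {
  v0 <- if (is(aging, "NormalAgingField")) aging@v0 else aging
  sm <- decomposeVoxelwise(vSubject, v0, eps = eps)
  if (is.character(regions)) regions <- lapply(regions, regionSpec)
  out <- list()
  for (rg in regions) {
    mask <- regionMask(rg, segRef = segRef, segOld = segOld)
    for (q in quantiles) {
      agg <- aggregateRegion(rejectOutliers(sm, v0, mask, quantile = q))
      out[[length(out) + 1L]] <- data.frame(
        region = rg@name, quantile = q, AS = agg$AS, ADS = agg$ADS,
        nVoxels = agg$nVoxels, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Select the outlier-rejection quantile maximizing the AS-age fit
#'
#' For each candidate quantile, fits ordinary least squares of the regional
#' aging score on chronological age over the cognitively normal scans and
#' records the coefficient of determination; the chosen quantile maximizes
#' R-squared, with ties resolved to the smallest quantile (least data
#' discarded).
#'
#' @param cnRecords Data.frame with columns \code{quantile}, \code{AS},
#'   \code{age} (one row per CN scan per quantile), and optionally
#'   \code{nVoxels}.
#' @param grid Candidate quantiles (default 0, 0.1, ..., 0.9).
#' @return A \linkS4class{QuantileSelection}.
#' @export
selectQuantile <- function(cnRecords, grid = seq(0, 0.9, by = 0.1)) {
  stopifnot(all(c("quantile", "AS", "age") %in% names(cnRecords)))
  r2 <- numeric(length(grid))
  nv <- integer(length(grid))
  for (i in seq_along(grid)) {
    sub <- cnRecords[abs(cnRecords$quantile - grid[i]) < 1e-9, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop(sprintf("need >= 3 CN scans at quantile %g, got %d",
                   grid[i], nrow(sub)), call. = FALSE)
    if (stats::var(sub$age) == 0)
      stop("ages have zero variance; the AS-age fit is degenerate",
           call. = FALSE)
    fit <- stats::lm(AS ~ age, data = sub)
    r2[i] <- suppressWarnings(summary(fit))$r.squared
    nv[i] <- if ("nVoxels" %in% names(sub)) as.integer(round(mean(sub$nVoxels)))
             else NA_integer_
  }
  if (all(is.na(nv))) nv <- rep(0L, length(grid))
  chosen <- grid[which.max(r2)]   # which.max takes the first (smallest) tie
  new("QuantileSelection", quantileGrid = grid, r2PerQuantile = r2,
      nVoxelsPerQuantile = nv, chosenQuantile = chosen)
}
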