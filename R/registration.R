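#' Diffeomorphic SVF registration by multiresolution gradient descent
#'
#' Estimates the stationary velocity field whose unit-time flow warps
#' \code{moving} onto \code{fixed}, by minimizing the (optionally masked)
#' sum-of-squared-differences data term plus implicit smoothness from
#' Gaussian (fluid-like) smoothing of every velocity update — the classical
#' log-domain demons scheme. The optimization is fully deterministic: given
#' identical inputs and settings the result is bit-identical.
#'
#' A Gaussian image pyramid (default 3 levels at scale factors 4, 2, 1) is
#' descended coarse-to-fine; at each level the update direction is the
#' masked residual times the warped-image gradient, smoothed with
#' \code{sigmaFluid}, and the step size is set by backtracking line search on
#' the data term. If the data term cannot be reduced for
#' \code{maxFailures} consecutive attempts the level stops and the best
#' iterate is kept; the result is flagged unconverged only when this happens
#' at the finest level before the relative-improvement tolerance is met.
#'
#' @param fixed,moving \linkS4class{ScalarVolume}s on the same grid,
#'   intensities expected in \[0, 1\].
#' @param mask Optional \linkS4class{LabelVolume}; non-zero voxels (dilated by
#'   \code{maskDilate}) restrict the data term, counteracting background
#'   errors, and the returned field is zeroed outside the dilated mask.
#' @param levels Number of multiresolution levels (factors \eqn{2^{l-1}}).
#' @param sigmaFluid Gaussian sigma (voxels) applied to each velocity update.
#' @param iterations Per-level iteration caps, coarse to fine; recycled.
#' @param steps Scaling-and-squaring steps for each integration.
#' @param maxStep Largest allowed per-iteration displacement update (voxels).
#' @param tol Relative data-term improvement below which a level is declared
#'   settled.
#' @param maxFailures Consecutive failed line searches tolerated per level.
#' @param maskDilate Dilation radius (voxels, full resolution) for the mask.
#' @return A \linkS4class{RegistrationResult}.
#' @export
registerSVF <- function(fixed, moving, mask = NULL, levels = 3L,
                        sigmaFluid = 2, iterations = c(150L, 120L, 80L),
                        steps = 7L, maxStep = 1.0, tol = 1e-7,
                        maxFailures = 4L, maskDilate = 3L) {
  stopifnot(is(fixed, "ScalarVolume"), is(moving, "ScalarVolume"))
  .stopIfShapeMismatch(fixed@data, moving@data, "fixed and moving")
  d <- dim(fixed@data)
  iterations <- rep(as.integer(iterations), length.out = levels)
  maskFull <- NULL
  if (!is.null(mask)) {
    stopifnot(is(mask, "LabelVolume"))
    .stopIfShapeMismatch(fixed@data, mask@data, "fixed and mask")
    maskFull <- .dilateMask(mask@data != 0, maskDilate)
  }

  trace <- numeric(0)
  levelIdx <- integer(0)
  converged <- FALSE
  v <- NULL
  prevDims <- NULL

  for (lev in seq_len(levels)) {
    f <- 2^(levels - lev)
    nd <- as.integer(pmax(ceiling(d / f), 4L))
    fixArr <- fixed@data
    movArr <- moving@data
    if (f > 1) {
      fixArr <- .resampleArray3(.smooth3(fixArr, f / 2), nd)
      movArr <- .resampleArray3(.smooth3(movArr, f / 2), nd)
    }
    w <- NULL
    if (!is.null(maskFull)) {
      w <- if (f > 1) .resampleArray3(maskFull * 1, nd, nearest = TRUE)
           else maskFull * 1
    }
    if (is.null(v)) {
      v <- array(0, c(nd, 3L))
    } else if (!identical(prevDims, nd)) {
      vUp <- array(0, c(nd, 3L))
      for (c in 1:3) {
        scale <- if (prevDims[c] > 1L) (nd[c] - 1) / (prevDims[c] - 1) else 1
        vUp[, , , c] <- .resampleArray3(v[, , , c], nd) * scale
      }
      v <- vUp
    }
    prevDims <- nd

    dataCost <- function(vArr) {
      phi <- .integrateArray(vArr, steps)
      warped <- array(.sampleTrilinear(movArr,
                                       as.vector(phi[, , , 1L]),
                                       as.vector(phi[, , , 2L]),
                                       as.vector(phi[, , , 3L])), nd)
      r <- fixArr - warped
      if (!is.null(w)) r <- r * w
      list(ssd = sum(r^2), resid = r, warped = warped)
    }

    cur <- dataCost(v)
    stepSize <- maxStep
    failures <- 0L
    settled <- FALSE
    for (it in seq_len(iterations[lev])) {
      g <- .gradient3(cur$warped)
      force <- g * as.vector(cur$resid)   # recycles resid over components
      update <- .smooth4(force, sigmaFluid)
      m <- max(.fieldNorm(update))
      if (m < 1e-12) { settled <- TRUE; break }
      update <- update / m
      accepted <- FALSE
      s <- stepSize
      for (try in 1:5) {
        vTry <- v + s * update
        new <- dataCost(vTry)
        if (new$ssd < cur$ssd) {
          rel <- (cur$ssd - new$ssd) / max(cur$ssd, .Machine$double.eps)
          v <- vTry
          cur <- new
          trace <- c(trace, new$ssd)
          levelIdx <- c(levelIdx, lev)
          stepSize <- min(maxStep, s * 1.2)
          accepted <- TRUE
          if (rel < tol) settled <- TRUE
          break
        }
        s <- s / 2
      }
      if (!accepted) {
        failures <- failures + 1L
        stepSize <- max(stepSize / 2, 1e-4)
        if (failures >= maxFailures) break
      } else failures <- 0L
      if (settled) break
    }
    if (lev == levels) converged <- settled || failures < maxFailures
  }

  if (!is.null(maskFull))
    v <- v * as.vector(maskFull)

  new("RegistrationResult",
      svf = VelocityField(v, spacing = fixed@spacing),
      similarityTrace = trace, levelIndex = levelIdx,
      converged = converged,
      settings = list(levels = levels, sigmaFluid = sigmaFluid,
                      iterations = iterations, steps = steps,
                      maxStep = maxStep, tol = tol,
                      maxFailures = maxFailures, maskDilate = maskDilate,
                      masked = !is.null(maskFull)))
}
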