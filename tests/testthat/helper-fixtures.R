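# Shared fixtures and independent oracles. The Euler integrator and the
# trilinear sampler here are deliberately written in plain R, independent of
# the package's compiled resampling kernels, so they can serve as oracles.

# Pure-R edge-clamped trilinear sampling (oracle; slow but simple).
refTrilinear <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- pmin(pmax(x, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  z <- pmin(pmax(z, 0), d[3] - 1)
  i0 <- pmin(floor(x), d[1] - 2); j0 <- pmin(floor(y), d[2] - 2)
  k0 <- pmin(floor(z), d[3] - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  idx <- function(i, j, k) 1 + i + j * d[1] + k * d[1] * d[2]
  v <- arr[idx(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[idx(i0 + 1, j0, k0)] * fx * (1 - fy) * (1 - fz) +
       arr[idx(i0, j0 + 1, k0)] * (1 - fx) * fy * (1 - fz) +
       arr[idx(i0 + 1, j0 + 1, k0)] * fx * fy * (1 - fz) +
       arr[idx(i0, j0, k0 + 1)] * (1 - fx) * (1 - fy) * fz +
       arr[idx(i0 + 1, j0, k0 + 1)] * fx * (1 - fy) * fz +
       arr[idx(i0, j0 + 1, k0 + 1)] * (1 - fx) * fy * fz +
       arr[idx(i0 + 1, j0 + 1, k0 + 1)] * fx * fy * fz
  v
}

# Explicit forward-Euler flow of a stationary velocity field (oracle for the
# scaling-and-squaring integrator). Returns the coordinate map as a 4-D array.
eulerFlow <- function(vArr, nSteps = 1024) {
  d <- dim(vArr)[1:3]
  grids <- list(
    array(rep(0:(d[1] - 1), times = d[2] * d[3]), d),
    array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d),
    array(rep(0:(d[3] - 1), each = d[1] * d[2]), d))
  pos <- array(c(grids[[1]], grids[[2]], grids[[3]]), c(d, 3))
  for (s in seq_len(nSteps)) {
    x <- as.vector(pos[, , , 1]); y <- as.vector(pos[, , , 2])
    z <- as.vector(pos[, , , 3])
    step <- array(c(refTrilinear(vArr[, , , 1], x, y, z),
                    refTrilinear(vArr[, , , 2], x, y, z),
                    refTrilinear(vArr[, , , 3], x, y, z)), c(d, 3))
    pos <- pos + step / nSteps
  }
  pos
}

# Smooth random velocity field with a prescribed maximum vector magnitude.
smoothRandomField <- function(dims, sigma = 2.5, maxMag = 0.5, seed = 1) {
  set.seed(seed)
  raw <- array(rnorm(prod(dims) * 3), c(dims, 3))
  for (c in 1:3) raw[, , , c] <- dbmaging:::.smooth3(raw[, , , c], sigma)
  mag <- sqrt(apply(raw^2, 1:3, sum))
  raw / max(mag) * maxMag
}

# Logical interior mask with the given margin from every face.
interiorMask <- function(dims, margin = 2) {
  m <- array(FALSE, dims)
  m[(1 + margin):(dims[1] - margin), (1 + margin):(dims[2] - margin),
    (1 + margin):(dims[3] - margin)] <- TRUE
  m
}

maxInteriorErr <- function(a, b, margin = 2) {
  msk <- interiorMask(dim(a)[1:3], margin)
  e <- abs(a - b)
  max(e[, , , 1][msk], e[, , , 2][msk], e[, , , 3][msk])
}

# Small phantom shared across tests (built once per test run).
testPhantom <- local({
  cache <- NULL
  function(shape = c(24L, 24L, 24L)) {
    key <- paste(shape, collapse = "x")
    if (is.null(cache[[key]])) {
      sp <- phantomSpec(shape = shape)
      cache[[key]] <<- c(makePhantom(sp), list(spec = sp))
    }
    cache[[key]]
  }
})
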