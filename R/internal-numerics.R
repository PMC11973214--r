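# Internal dense-grid numerics shared by the field algebra, registration and
# synthetic modules. All coordinates are 0-based voxel indices; arrays are
# 1-based R arrays, so sampling shifts by one internally. Out-of-domain
# coordinates are edge-clamped everywhere.

.identityGrid <- function(dims) {
  d <- as.integer(dims)
  g <- array(0, c(d, 3L))
  g[, , , 1L] <- array(rep(0:(d[1] - 1L), times = d[2] * d[3]), d)
  g[, , , 2L] <- array(rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]), d)
  g[, , , 3L] <- array(rep(0:(d[3] - 1L), each = d[1] * d[2]), d)
  g
}

# Trilinear sampling of one 3-D array at 0-based coordinates (vectors x, y, z).
.sampleTrilinear <- function(arr, x, y, z) {
  .sampleTrilinearCpp(arr, dim(arr), as.numeric(x), as.numeric(y),
                      as.numeric(z))
}

# Trilinear sampling of all 3 components of a 4-D field at shared 0-based
# coordinates; corner indices and weights computed once. Returns n x 3.
.sampleField4 <- function(field, x, y, z) {
  .sampleField4Cpp(field, dim(field)[1:3], as.numeric(x), as.numeric(y),
                   as.numeric(z))
}

.sampleNearest <- function(arr, x, y, z) {
  d <- dim(arr)
  i <- pmin(pmax(round(x), 0), d[1] - 1L)
  j <- pmin(pmax(round(y), 0), d[2] - 1L)
  k <- pmin(pmax(round(z), 0), d[3] - 1L)
  arr[1 + i + j * d[1] + k * d[1] * d[2]]
}

# Truncated, row-renormalized Gaussian convolution matrix for one axis; the
# renormalization keeps constants exactly invariant at the boundary.
.gaussKernelMatrix <- function(n, sigma) {
  i <- seq_len(n)
  M <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  M[abs(outer(i, i, "-")) > ceiling(3.5 * sigma)] <- 0
  M / rowSums(M)
}

# Separable Gaussian smoothing of a 3-D array (sigma in voxels, scalar or
# per-axis length 3).
.smooth3 <- function(arr, sigma) {
  if (all(sigma <= 0)) return(arr)
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(arr)
  if (sigma[1] > 0) {
    M <- .gaussKernelMatrix(d[1], sigma[1])
    arr <- array(M %*% matrix(arr, d[1], d[2] * d[3]), d)
  }
  if (sigma[2] > 0) {
    M <- .gaussKernelMatrix(d[2], sigma[2])
    a <- aperm(arr, c(2L, 1L, 3L))
    a <- array(M %*% matrix(a, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2L, 1L, 3L))
  }
  if (sigma[3] > 0) {
    M <- .gaussKernelMatrix(d[3], sigma[3])
    arr <- array(matrix(arr, d[1] * d[2], d[3]) %*% t(M), d)
  }
  arr
}

.smooth4 <- function(field, sigma) {
  for (c in 1:3) field[, , , c] <- .smooth3(field[, , , c], sigma)
  field
}

# Central-difference spatial gradient of a 3-D array; one-sided at the faces.
# Returns a 4-D array (gradient component per last axis), voxel units.
.gradient3 <- function(arr) {
  d <- dim(arr)
  g <- array(0, c(d, 3L))
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    ip <- c(2:n, n)       # forward neighbour (clamped)
    im <- c(1L, 1:(n - 1L))  # backward neighbour (clamped)
    den <- array(rep(ifelse(ip - im == 0L, 1L, ip - im),
                     each = prod(d[seq_len(ax - 1L)])), d)
    if (ax == 1L) g[, , , 1L] <- (arr[ip, , , drop = FALSE] -
                                  arr[im, , , drop = FALSE]) / den
    if (ax == 2L) g[, , , 2L] <- (arr[, ip, , drop = FALSE] -
                                  arr[, im, , drop = FALSE]) / den
    if (ax == 3L) g[, , , 3L] <- (arr[, , ip, drop = FALSE] -
                                  arr[, , im, drop = FALSE]) / den
  }
  g
}

# Align-corners trilinear resampling of a 3-D array onto a new grid size.
.resampleArray3 <- function(arr, newDims, nearest = FALSE) {
  d <- dim(arr); nd <- as.integer(newDims)
  co <- lapply(1:3, function(ax) {
    if (nd[ax] == 1L) 0 else (0:(nd[ax] - 1L)) * (d[ax] - 1) / (nd[ax] - 1)
  })
  g <- .identityGrid(nd)
  x <- co[[1]][g[, , , 1L] + 1L]
  y <- co[[2]][g[, , , 2L] + 1L]
  z <- co[[3]][g[, , , 3L] + 1L]
  out <- if (nearest) .sampleNearest(arr, x, y, z)
         else .sampleTrilinear(arr, x, y, z)
  array(out, nd)
}

# Morphological dilation of a logical mask by r voxels (6-neighbourhood).
.dilateMask <- function(mask, r) {
  m <- mask * 1
  d <- dim(m)
  for (pass in seq_len(r)) {
    shifted <- m
    shifted <- pmax(shifted, m[c(1L, 1:(d[1] - 1L)), , ])
    shifted <- pmax(shifted, m[c(2:d[1], d[1]), , ])
    shifted <- pmax(shifted, m[, c(1L, 1:(d[2] - 1L)), ])
    shifted <- pmax(shifted, m[, c(2:d[2], d[2]), ])
    shifted <- pmax(shifted, m[, , c(1L, 1:(d[3] - 1L))])
    shifted <- pmax(shifted, m[, , c(2:d[3], d[3])])
    m <- shifted
  }
  array(m > 0, d)
}

# Per-voxel Euclidean norm of a 4-D vector field, returned as a 3-D array.
.fieldNorm <- function(field) {
  d <- dim(field)
  array(sqrt(rowSums(matrix(field, ncol = 3L)^2)), d[1:3])
}

.stopIfShapeMismatch <- function(a, b, what = "operands") {
  da <- if (length(dim(a)) == 4L) dim(a)[1:3] else dim(a)
  db <- if (length(dim(b)) == 4L) dim(b)[1:3] else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("grid shape mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}
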