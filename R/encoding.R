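#' @useDynLib flowrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Array conventions used throughout the package (column-major R arrays,
# spatial axes first for locality):
#   image series x      : complex (NY, NZ, NT, NV)
#   coil maps S         : complex (NY, NZ, NC), attr "support" logical (NY, NZ)
#   sampling mask D     : 0/1    (NY, NZ, NT, NV)
#   multicoil k-space y : complex (NY, NZ, NC, NT, NV)
#   velocity field v    : double (NY, NZ, NT, 3) in cm/s
# NV velocity encodings (reference first), NT cardiac frames, NC coils.

.check_mask_binary <- function(mask) {
  if (!all(mask == 0 | mask == 1)) stop("sampling mask must be binary (0/1)")
  invisible(TRUE)
}

# slice one index off the last dimension(s) without dropping earlier dims
.slice_last <- function(a, ...) {
  idx <- c(...)
  d <- dim(a)
  nkeep <- length(d) - length(idx)
  args <- c(list(a), rep(list(quote(expr = )), nkeep), as.list(idx),
            list(drop = FALSE))
  s <- do.call(`[`, args)
  dim(s) <- d[seq_len(nkeep)]
  s
}

.dim_or_stop <- function(x, n, what) {
  d <- dim(x)
  if (is.null(d) || length(d) != n)
    stop(sprintf("%s must be a %d-dimensional array", what, n))
  d
}

#' Multicoil Cartesian encoding operator E = D F S
#'
#' Applies the SENSE forward model per coil, frame and velocity encoding:
#' the image is weighted by the coil sensitivity, transformed with the
#' centered unitary 2D FFT over (y, z), and masked with the binary sampling
#' pattern.  Output k-space is exactly zero at unsampled locations.
#'
#' @param x complex image array `(NY, NZ, NT, NV)`.
#' @param smaps complex coil sensitivities `(NY, NZ, NC)`, normalized so the
#'   coil-combined operator has unit gain on the support
#'   (see [normalize_coil_maps()]).
#' @param mask binary sampling mask `(NY, NZ, NT, NV)`.
#' @return complex k-space array `(NY, NZ, NC, NT, NV)`.
#' @seealso [adjoint_op()]
#' @export
#' @examples
#' S <- normalize_coil_maps(array(1 + 0i, c(4, 4, 1)))
#' x <- array(1 + 0i, c(4, 4, 1, 1))
#' D <- array(1, c(4, 4, 1, 1))
#' y <- forward_op(x, S, D)  # single DC peak of height sqrt(16)
forward_op <- function(x, smaps, mask) {
  dx <- .dim_or_stop(x, 4L, "x")
  ds <- .dim_or_stop(smaps, 3L, "smaps")
  dm <- .dim_or_stop(mask, 4L, "mask")
  if (!all(dx[1:2] == ds[1:2]) || !all(dx == dm))
    stop("shape mismatch between image, coil maps and mask")
  .check_mask_binary(mask)
  ny <- dx[1]; nz <- dx[2]; nt <- dx[3]; nv <- dx[4]; nc <- ds[3]
  y <- array(0i, c(ny, nz, nc, nt, nv))
  for (v in seq_len(nv)) for (t in seq_len(nt)) {
    sx <- smaps * as.vector(x[, , t, v])      # (NY,NZ,NC): broadcast over coils
    k <- fft2c(sx)
    m <- mask[, , t, v]
    for (c in seq_len(nc)) y[, , c, t, v] <- k[, , c] * m
  }
  y
}

#' Adjoint of the encoding operator (zero-filled reconstruction)
#'
#' Computes the coil-combined adjoint `sum_i conj(S_i) * F^{-1}(y_i)` per
#' frame and encoding.  For fully sampled data and unit-gain maps this
#' inverts [forward_op()]; for undersampled data it is the zero-filled
#' reconstruction used to initialize the unrolled network.
#'
#' @param y complex k-space `(NY, NZ, NC, NT, NV)`, zero off the mask.
#' @param smaps complex coil sensitivities `(NY, NZ, NC)`.
#' @return complex image array `(NY, NZ, NT, NV)`.
#' @export
adjoint_op <- function(y, smaps) {
  dy <- .dim_or_stop(y, 5L, "y")
  ds <- .dim_or_stop(smaps, 3L, "smaps")
  if (!all(dy[1:2] == ds[1:2]) || dy[3] != ds[3])
    stop("shape mismatch between k-space and coil maps")
  ny <- dy[1]; nz <- dy[2]; nc <- dy[3]; nt <- dy[4]; nv <- dy[5]
  x <- array(0i, c(ny, nz, nt, nv))
  cs <- Conj(smaps)
  for (v in seq_len(nv)) for (t in seq_len(nt)) {
    img <- ifft2c(.slice_last(y, t, v))
    acc <- array(0i, c(ny, nz))
    for (c in seq_len(nc)) acc <- acc + cs[, , c] * img[, , c]
    x[, , t, v] <- acc
  }
  x
}

#' Normalize coil sensitivity maps to unit coil-combined gain
#'
#' Divides raw sensitivities by their root-sum-of-squares over coils on the
#' signal support and zeroes voxels whose root-sum-of-squares falls below
#' `support_threshold` times its maximum.  After normalization
#' `sum_i |S_i|^2 = 1` on the support, which makes `E^H E` the identity for
#' full sampling and lets the data-consistency algebra use plain weighted
#' averages.
#'
#' @param raw complex array `(NY, NZ, NC)`.
#' @param support_threshold fraction of the maximum root-sum-of-squares below
#'   which a voxel is treated as background (default 0.05).
#' @return complex array `(NY, NZ, NC)` with attribute `support`
#'   (logical `(NY, NZ)`).
#' @export
normalize_coil_maps <- function(raw, support_threshold = 0.05) {
  ds <- .dim_or_stop(raw, 3L, "raw")
  if (!all(is.finite(Re(raw))) || !all(is.finite(Im(raw))))
    stop("raw coil maps must be finite")
  rss <- sqrt(apply(abs(raw)^2, c(1, 2), sum))
  mx <- max(rss)
  if (mx == 0) stop("all-zero coil maps")
  support <- rss >= support_threshold * mx
  denom <- ifelse(support, rss, 1)
  out <- raw / as.vector(denom)
  for (c in seq_len(ds[3])) out[, , c] <- out[, , c] * support
  attr(out, "support") <- support
  out
}

#' SVD-based coil compression to virtual coils
#'
#' Forms the (coil x sample) matrix of the time-and-encoding-averaged
#' k-space, takes its singular value decomposition, and projects all frames
#' and encodings onto the leading `n_virtual` left singular vectors.  The
#' same linear combination is applied everywhere, so the compressed data
#' remain consistent across the dynamic and velocity-encoding dimensions.
#'
#' @param y complex k-space `(NY, NZ, NC, NT, NV)`.
#' @param n_virtual number of virtual coils to keep (`1 <= n_virtual <= NC`).
#' @return compressed k-space `(NY, NZ, n_virtual, NT, NV)` with attribute
#'   `compression`: the `(n_virtual x NC)` mixing matrix `A` such that
#'   `y_virtual = A y_physical` per k-space location.
#' @export
compress_coils <- function(y, n_virtual) {
  dy <- .dim_or_stop(y, 5L, "y")
  nc <- dy[3]
  if (n_virtual < 1) stop("n_virtual must be >= 1")
  if (n_virtual > nc) stop("n_virtual must not exceed the number of coils")
  ny <- dy[1]; nz <- dy[2]; nt <- dy[4]; nv <- dy[5]
  avg <- array(0i, c(ny, nz, nc))
  for (v in seq_len(nv)) for (t in seq_len(nt))
    avg <- avg + .slice_last(y, t, v)
  avg <- avg / (nt * nv)
  m <- t(matrix(avg, ny * nz, nc))          # (NC x samples)
  sv <- svd(m, nu = nc, nv = 0)
  A <- Conj(t(sv$u[, seq_len(n_virtual), drop = FALSE]))  # (r x NC)
  out <- array(0i, c(ny, nz, n_virtual, nt, nv))
  for (v in seq_len(nv)) for (t in seq_len(nt)) {
    sl <- matrix(y[, , , t, v, drop = FALSE], ny * nz, nc)
    out[, , , t, v] <- array(sl %*% t(A), c(ny, nz, n_virtual))
  }
  attr(out, "compression") <- A
  out
}

#' Apply a coil-compression matrix to a coil-indexed array
#'
#' @param arr complex array with the coil axis third, e.g. coil maps
#'   `(NY, NZ, NC)` or k-space `(NY, NZ, NC, ...)`.
#' @param compression `(r x NC)` matrix from [compress_coils()].
#' @return array with the coil axis reduced to `r`.
#' @export
apply_coil_compression <- function(arr, compression) {
  d <- dim(arr)
  if (is.null(d) || length(d) < 3L) stop("arr must have a third (coil) axis")
  nc <- d[3]
  if (ncol(compression) != nc) stop("compression matrix does not match coil count")
  r <- nrow(compression)
  rest <- if (length(d) > 3L) prod(d[-(1:3)]) else 1L
  a <- arr
  dim(a) <- c(d[1] * d[2], nc, rest)
  out <- array(0i, c(d[1] * d[2], r, rest))
  for (j in seq_len(rest)) out[, , j] <- a[, , j] %*% t(compression)
  dim(out) <- c(d[1], d[2], r, if (length(d) > 3L) d[-(1:3)] else NULL)
  out
}

#' Split a 3D Cartesian acquisition into independent 2D+t subproblems
#'
#' The readout dimension of a Cartesian acquisition is fully sampled, so an
#' inverse unitary FFT along readout decouples the volume into `NX`
#' independent `(NY, NZ)` phase-encode subproblems that share the same
#' (ky, kz) sampling mask.
#'
#' @param k3d complex array `(NX, NY, NZ, NC, NT, NV)` with readout first.
#' @param readout_mask optional 0/1 vector of length `NX`; anything other
#'   than all-ones is an error, since the decomposition requires a fully
#'   sampled readout.
#' @return list of `NX` complex k-space arrays `(NY, NZ, NC, NT, NV)`.
#' @export
split_readout <- function(k3d, readout_mask = NULL) {
  d <- .dim_or_stop(k3d, 6L, "k3d")
  nx <- d[1]
  if (!is.null(readout_mask)) {
    if (length(readout_mask) != nx || !all(readout_mask == 1))
      stop("readout dimension is not fully sampled")
  }
  rest <- prod(d[-1])
  m <- matrix(k3d, nx, rest)
  # centered unitary inverse FFT along readout
  idx_i <- c((ceiling(nx / 2) + 1L):nx, seq_len(ceiling(nx / 2)))
  idx_f <- c((floor(nx / 2) + 1L):nx, seq_len(floor(nx / 2)))
  if (nx > 1L) {
    m <- stats::mvfft(m[idx_i, , drop = FALSE], inverse = TRUE) / sqrt(nx)
    m <- m[idx_f, , drop = FALSE]
  }
  lapply(seq_len(nx), function(j) {
    sl <- m[j, ]
    dim(sl) <- d[-1]
    sl
  })
}

#' Low-resolution coil sensitivity estimation from central k-space
#'
#' Averages the acquired k-space over frames and encodings (weighted by how
#' often each location was sampled), keeps a smoothly windowed central disc,
#' reconstructs low-resolution coil images and normalizes them by their
#' root-sum-of-squares.  This is a simple auto-calibration estimator for
#' smooth coil profiles; the phantom simulator also provides ground-truth
#' maps.
#'
#' @param y complex k-space `(NY, NZ, NC, NT, NV)`.
#' @param mask binary sampling mask `(NY, NZ, NT, NV)`.
#' @param center_radius radius (in k-space samples) of the calibration disc.
#' @param support_threshold passed to [normalize_coil_maps()].
#' @return normalized coil maps `(NY, NZ, NC)`.
#' @export
estimate_coil_maps <- function(y, mask, center_radius = 6,
                               support_threshold = 0.05) {
  dy <- .dim_or_stop(y, 5L, "y")
  ny <- dy[1]; nz <- dy[2]; nc <- dy[3]; nt <- dy[4]; nv <- dy[5]
  counts <- array(0, c(ny, nz))
  acc <- array(0i, c(ny, nz, nc))
  for (v in seq_len(nv)) for (t in seq_len(nt)) {
    m <- mask[, , t, v]
    counts <- counts + m
    for (c in seq_len(nc)) acc[, , c] <- acc[, , c] + y[, , c, t, v]
  }
  w <- ifelse(counts > 0, 1 / pmax(counts, 1), 0)
  rad <- .center_distance(ny, nz)
  taper <- 0.5 * (1 + cos(pi * pmin(rad / center_radius, 1)))  # raised cosine
  for (c in seq_len(nc)) acc[, , c] <- acc[, , c] * w * taper
  lowres <- ifft2c(acc)
  normalize_coil_maps(lowres, support_threshold = support_threshold)
}

# Euclidean distance (in samples) from the centered k-space origin
.center_distance <- function(ny, nz) {
  cy <- floor(ny / 2) + 1L
  cz <- floor(nz / 2) + 1L
  outer(seq_len(ny) - cy, seq_len(nz) - cz, function(a, b) sqrt(a^2 + b^2))
}
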