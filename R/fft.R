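#' Centered unitary 2D Fourier transforms
#'
#' k-space and image space are related by the orthonormal (unitary) discrete
#' Fourier transform with the zero-frequency sample stored at index
#' `floor(N/2) + 1` along each transformed axis (the usual "centered"
#' convention).  With a unitary transform the adjoint of the encoding
#' operator is its conjugate transpose, so SENSE adjoint/normal-equation
#' algebra holds without extra scaling factors.
#'
#' `fft2c()` / `ifft2c()` transform the first two dimensions of an array of
#' any rank; trailing dimensions (coils, frames, encodings) are carried along
#' unchanged.
#'
#' @param x complex array with at least 2 dimensions `(NY, NZ, ...)`.
#' @return complex array of the same shape.
#' @keywords internal
fft2c <- function(x) {
  .fft2_apply(x, inverse = FALSE)
}

#' @rdname fft2c
#' @keywords internal
ifft2c <- function(x) {
  .fft2_apply(x, inverse = TRUE)
}

.fft2_apply <- function(x, inverse) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("fft2c expects an array with >= 2 dims")
  ny <- d[1L]; nz <- d[2L]
  rest <- if (length(d) > 2L) prod(d[-c(1L, 2L)]) else 1L
  xm <- x
  dim(xm) <- c(ny, nz, rest)
  out <- array(0i, dim = c(ny, nz, rest))
  sc <- sqrt(ny * nz)
  for (j in seq_len(rest)) {
    sl <- xm[, , j]
    dim(sl) <- c(ny, nz)
    f <- stats::fft(ifftshift2(sl), inverse = inverse)
    out[, , j] <- fftshift2(f) / sc
  }
  dim(out) <- d
  out
}

#' Shift the zero-frequency sample to the array center (first two dims)
#' @param x matrix
#' @keywords internal
fftshift2 <- function(x) {
  idx <- function(n) if (n == 1L) 1L else
    c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
  x[idx(nrow(x)), idx(ncol(x)), drop = FALSE]
}

#' Inverse of [fftshift2()]
#' @param x matrix
#' @keywords internal
ifftshift2 <- function(x) {
  idx <- function(n) if (n == 1L) 1L else
    c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))
  x[idx(nrow(x)), idx(ncol(x)), drop = FALSE]
}

# 1D variants used for the readout dimension
fftshift1 <- function(x) {
  n <- length(x)
  x[c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))]
}
ifftshift1 <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  x[c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))]
}
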