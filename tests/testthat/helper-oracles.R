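# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own FFT/conv code paths: the DFT
# matrix is built from the exponential definition plus explicit index
# permutations, and the convolution oracle is a brute-force loop.

rcplx <- function(n, sd = 1) {
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}

rand_image <- function(ny, nz, nt, nv) {
  array(rcplx(ny * nz * nt * nv), c(ny, nz, nt, nv))
}

rand_smaps <- function(ny, nz, nc, full_support = TRUE) {
  raw <- array(rcplx(ny * nz * nc), c(ny, nz, nc))
  normalize_coil_maps(raw, support_threshold = if (full_support) 0 else 0.05)
}

# centered unitary 1D DFT matrix: permute the plain DFT by fftshift on the
# output and ifftshift on the input
dense_dft1 <- function(N) {
  W <- outer(0:(N - 1), 0:(N - 1),
             function(k, n) exp(-2i * pi * k * n / N)) / sqrt(N)
  pf <- c((floor(N / 2) + 1):N, seq_len(floor(N / 2)))       # fftshift
  pi_ <- c((ceiling(N / 2) + 1):N, seq_len(ceiling(N / 2)))  # ifftshift
  Pf <- diag(N)[pf, , drop = FALSE]
  Pi <- diag(N)[pi_, , drop = FALSE]
  Pf %*% W %*% Pi
}

# 2D centered unitary DFT as a dense matrix over the vectorized (ny x nz)
# image (column-major)
dense_dft2 <- function(ny, nz) {
  kronecker(dense_dft1(nz), dense_dft1(ny))
}

# dense encoding matrix: rows stack coils; D and S supplied per coil
dense_encoding <- function(smaps, mask2d) {
  ny <- dim(smaps)[1]; nz <- dim(smaps)[2]; nc <- dim(smaps)[3]
  F2 <- dense_dft2(ny, nz)
  do.call(rbind, lapply(seq_len(nc), function(c) {
    diag(as.numeric(mask2d)) %*% F2 %*% diag(as.complex(smaps[, , c]))
  }))
}

# brute-force complex 2D convolution ("same" zero padding, correlation
# orientation matching complex_conv)
conv_oracle <- function(input, W, bias = NULL) {
  d <- dim(input); k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  if (is.null(bias)) bias <- rep(0i, cout)
  o <- (k - 1) / 2
  out <- array(0i, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    acc <- array(bias[co], c(d[1], d[2]))
    for (ci in seq_len(cin)) for (dz in seq_len(k)) for (dy in seq_len(k)) {
      w <- W[dy, dz, ci, co]
      for (z in seq_len(d[2])) for (y in seq_len(d[1])) {
        yy <- y + dy - 1 - o; zz <- z + dz - 1 - o
        if (yy >= 1 && yy <= d[1] && zz >= 1 && zz <= d[2])
          acc[y, z] <- acc[y, z] + w * input[yy, zz, ci]
      }
    }
    out[, , co] <- acc
  }
  out
}

# small phantom training set matching the scaled-down study conditions
make_phantom_set <- function(n = 8, grid = c(24, 24), nt = 4, nc = 3, R = 8,
                             noise = 0.02, base_seed = 100) {
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(grid = grid, n_frames = nt, n_coils = nc, venc = 150,
                       peak_velocity = 120, vessel_radius = 4, peak_frame = 2,
                       noise_sigma = noise)
    sp$seed <- base_seed + i
    ms <- mask_spec(kind = "uniform_random", R = R, seed = base_seed + 100 + i)
    simulate_phantom(sp, ms)
  })
}

# restrict multicoil k-space to a (NY,NZ,NT,NV) mask without tripping R's
# dimension dropping on singleton axes
apply_mask_y <- function(y, D) {
  for (c in seq_len(dim(y)[3]))
    y[, , c, , ] <- as.vector(y[, , c, , ]) * as.vector(D)
  y
}

rand_omega <- function(ny, nz, nt, nv, density = 0.3, center_radius = 3) {
  omega <- array(rbinom(ny * nz * nt * nv, 1, density), c(ny, nz, nt, nv))
  cy <- floor(ny / 2) + 1; cz <- floor(nz / 2) + 1
  for (y in 1:ny) for (z in 1:nz)
    if ((y - cy)^2 + (z - cz)^2 <= center_radius^2) omega[y, z, , ] <- 1
  omega
}
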