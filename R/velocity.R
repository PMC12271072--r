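# Velocity decoding from four-point reconstructions, eddy-current
# background-phase correction, quantitative error metrics and peak-velocity
# curve extraction.

#' Decode velocities from a four-point reconstruction
#'
#' `v_d = (venc / pi) * Arg(x_d * conj(x_ref))` per voxel and frame, using
#' the principal branch of the complex argument (no unwrapping; velocities
#' at exactly +/-venc map to +/-venc).  Voxels with zero magnitude decode to
#' 0 by convention; their count is attached as attribute `n_zero_magnitude`.
#'
#' @param x complex image series `(NY, NZ, NT, 4)`, reference encoding
#'   first.
#' @param venc velocity-encoding value (cm/s), positive.
#' @return numeric velocity array `(NY, NZ, NT, 3)` in cm/s.
#' @export
decode_velocity <- function(x, venc) {
  d <- .dim_or_stop(x, 4L, "x")
  if (d[4] != 4L) stop("decode_velocity expects NV = 4 encodings")
  if (venc <= 0) stop("venc must be positive")
  v <- array(0, c(d[1], d[2], d[3], 3))
  nzero <- 0L
  for (t in seq_len(d[3])) {
    ref <- x[, , t, 1]
    for (comp in 1:3) {
      prod <- x[, , t, comp + 1] * Conj(ref)
      zero <- Mod(prod) == 0
      nzero <- nzero + sum(zero)
      ph <- Arg(prod)
      ph[zero] <- 0
      v[, , t, comp] <- venc / pi * ph
    }
  }
  attr(v, "n_zero_magnitude") <- nzero
  v
}

#' Third-order polynomial background-phase (eddy-current) correction
#'
#' Fits a third-order 2D polynomial (10 monomials over normalized in-plane
#' coordinates) to the time-averaged velocity of stationary-tissue voxels,
#' separately per velocity component, by ordinary least squares, and
#' subtracts the fitted field from every frame.  With `trim > 0` the fit is
#' repeated once after discarding the stationary voxels with the largest
#' absolute residuals (a lightweight robust consensus refit).
#'
#' @param v numeric velocity array `(NY, NZ, NT, 3)` (cm/s).
#' @param stationary logical/binary `(NY, NZ)` mask of stationary tissue;
#'   needs at least 10 voxels (more for a stable fit).
#' @param trim fraction of worst-residual voxels to discard before the
#'   refit (default 0: plain least squares).
#' @return corrected velocity array, with attribute `background_coeffs`
#'   (`10 x 3` fitted coefficients, cm/s per basis monomial).
#' @export
correct_background_phase <- function(v, stationary, trim = 0) {
  d <- .dim_or_stop(v, 4L, "v")
  stat_idx <- which(stationary != 0)
  basis <- poly_basis_2d(d[1], d[2])
  if (length(stat_idx) < ncol(basis))
    stop("stationary mask too small for a third-order polynomial fit")
  vbar <- apply(v, c(1, 2, 4), mean)        # time-averaged, (NY, NZ, 3)
  coeffs <- matrix(0, ncol(basis), 3)
  out <- v
  for (comp in 1:3) {
    yv <- vbar[, , comp][stat_idx]
    X <- basis[stat_idx, , drop = FALSE]
    fit <- stats::lm.fit(X, yv)
    if (any(is.na(fit$coefficients)))
      stop("rank-deficient stationary mask for polynomial fit")
    if (trim > 0) {
      res <- abs(fit$residuals)
      keep <- res <= stats::quantile(res, 1 - trim)
      if (sum(keep) >= ncol(basis)) {
        fit <- stats::lm.fit(X[keep, , drop = FALSE], yv[keep])
        if (any(is.na(fit$coefficients)))
          stop("rank-deficient stationary mask after trimming")
      }
    }
    coeffs[, comp] <- fit$coefficients
    field <- matrix(basis %*% fit$coefficients, d[1], d[2])
    for (t in seq_len(d[3]))
      out[, , t, comp] <- v[, , t, comp] - field
  }
  attr(out, "background_coeffs") <- coeffs
  out
}

#' Normalized root-mean-square error of image magnitudes
#'
#' `sqrt( sum (a - a_ref)^2 / sum a_ref^2 )` over all supplied voxels.
#'
#' @param a,a_ref numeric magnitude arrays of equal shape.
#' @return nonnegative scalar.
#' @export
nrmse_m <- function(a, a_ref) {
  if (!all(dim(a) == dim(a_ref))) stop("shape mismatch")
  sqrt(sum((a - a_ref)^2) / sum(a_ref^2))
}

#' Vectorial normalized RMSE of velocities inside a region of interest
#'
#' `sqrt( sum_ROI ||u_i - v_i||^2 / sum_ROI ||v_i||^2 )` with the Euclidean
#' norm over the three velocity components; the sum runs over ROI voxels
#' and, for a time-resolved field, over frames.
#'
#' @param u estimated velocity array `(NY, NZ, NT, 3)`.
#' @param v_ref reference velocity array of the same shape.
#' @param roi logical/binary `(NY, NZ)` or `(NY, NZ, NT)` region of
#'   interest.
#' @return nonnegative scalar.
#' @export
nrmse_v <- function(u, v_ref, roi) {
  d <- .dim_or_stop(u, 4L, "u")
  if (!all(d == dim(v_ref))) stop("shape mismatch")
  m <- .roi_per_frame(roi, d)
  num <- 0; den <- 0
  for (t in seq_len(d[3])) {
    idx <- which(m[, , t] != 0)
    for (comp in 1:3) {
      du <- u[, , t, comp][idx] - v_ref[, , t, comp][idx]
      num <- num + sum(du^2)
      den <- den + sum(v_ref[, , t, comp][idx]^2)
    }
  }
  if (den == 0) stop("reference velocity is zero inside the ROI")
  sqrt(num / den)
}

#' Mean directional error of velocity vectors inside a region of interest
#'
#' `mean over ROI of (1 - u.v / (|u| |v|))`; 0 for aligned fields, 1 for
#' orthogonal, 2 for anti-parallel.  Voxels where either vector has zero
#' magnitude are excluded; their count is attached as attribute
#' `n_excluded`.
#'
#' @inheritParams nrmse_v
#' @return scalar in `[0, 2]`.
#' @export
mdirerr <- function(u, v_ref, roi) {
  d <- .dim_or_stop(u, 4L, "u")
  if (!all(d == dim(v_ref))) stop("shape mismatch")
  m <- .roi_per_frame(roi, d)
  total <- 0; count <- 0L; excluded <- 0L
  for (t in seq_len(d[3])) {
    idx <- which(m[, , t] != 0)
    if (length(idx) == 0L) next
    um <- sapply(1:3, function(c) u[, , t, c][idx])
    vm <- sapply(1:3, function(c) v_ref[, , t, c][idx])
    if (length(idx) == 1L) { um <- matrix(um, 1); vm <- matrix(vm, 1) }
    nu <- sqrt(rowSums(um^2)); nv <- sqrt(rowSums(vm^2))
    ok <- nu > 0 & nv > 0
    excluded <- excluded + sum(!ok)
    total <- total + sum(1 - rowSums(um * vm)[ok] / (nu[ok] * nv[ok]))
    count <- count + sum(ok)
  }
  if (count == 0L) stop("no usable voxels in the ROI")
  structure(total / count, n_excluded = excluded)
}

.roi_per_frame <- function(roi, d) {
  dr <- dim(roi)
  if (length(dr) == 2L) {
    m <- array(0, d[1:3])
    for (t in seq_len(d[3])) m[, , t] <- roi
    m
  } else if (length(dr) == 3L) {
    roi
  } else stop("roi must be (NY, NZ) or (NY, NZ, NT)")
}

#' Patch-based signal-to-noise ratio in dB
#'
#' `20 log10(mean(a_patch) / sd(a_patch))` with the sample standard
#' deviation, assuming Gaussian noise in a homogeneous patch.
#'
#' @param a numeric magnitude image.
#' @param patch logical/binary mask of the homogeneous patch.
#' @return scalar in dB.
#' @export
snr_patch <- function(a, patch) {
  vals <- a[patch != 0]
  if (length(vals) < 2L) stop("patch must contain at least two voxels")
  s <- stats::sd(vals)
  if (s == 0) stop("constant patch: SNR undefined")
  20 * log10(mean(vals) / s)
}

# binary erosion with the 4-neighborhood cross
.erode1 <- function(m) {
  ny <- nrow(m); nz <- ncol(m)
  p <- matrix(FALSE, ny + 2, nz + 2)
  p[2:(ny + 1), 2:(nz + 1)] <- m != 0
  ctr <- p[2:(ny + 1), 2:(nz + 1)]
  ctr & p[1:ny, 2:(nz + 1)] & p[3:(ny + 2), 2:(nz + 1)] &
    p[2:(ny + 1), 1:nz] & p[2:(ny + 1), 3:(nz + 2)]
}

#' Peak-velocity curve at the fastest voxel of an ROI
#'
#' Erodes the ROI by one voxel (guarding against wall/partial-volume
#' voxels), locates the voxel whose chosen velocity component attains the
#' largest absolute value over all frames, and returns the time courses of
#' all three components at that voxel.  No temporal interpolation is
#' applied.
#'
#' @param v numeric velocity array `(NY, NZ, NT, 3)`.
#' @param roi logical/binary `(NY, NZ)` vessel mask.
#' @param component component (1-3) defining "peak velocity" (through-plane
#'   for the phantom).
#' @return data frame with columns `frame`, `v1`, `v2`, `v3` (cm/s) and
#'   attribute `voxel` (the `(y, z)` index of the selected voxel).
#' @export
peak_velocity_curve <- function(v, roi, component = 1L) {
  d <- .dim_or_stop(v, 4L, "v")
  er <- .erode1(roi)
  if (!any(er)) er <- roi != 0   # tiny ROI: fall back to the full mask
  idx <- which(er)
  if (length(idx) == 0L) stop("empty ROI")
  peak <- rep(0, length(idx))
  for (t in seq_len(d[3]))
    peak <- pmax(peak, abs(v[, , t, component][idx]))
  best <- idx[which.max(peak)]
  yz <- arrayInd(best, d[1:2])
  out <- data.frame(frame = seq_len(d[3]),
                    v1 = v[yz[1], yz[2], , 1],
                    v2 = v[yz[1], yz[2], , 2],
                    v3 = v[yz[1], yz[2], , 3])
  attr(out, "voxel") <- c(y = yz[1], z = yz[2])
  out
}

#' Export magnitude and velocity volumes to NIfTI
#'
#' Writes the reference-encoding magnitude and the three velocity components
#' as 3D+t NIfTI volumes (y, z, frame) using the container's voxel size.
#'
#' @param x complex image series `(NY, NZ, NT, NV)`.
#' @param v numeric velocity array `(NY, NZ, NT, 3)`.
#' @param dir output directory.
#' @param voxel_mm voxel size `(dy, dz, dt-as-1)` metadata.
#' @return invisibly, the written file paths.
#' @export
export_nifti <- function(x, v, dir, voxel_mm = c(2.5, 2.5, 2.5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  mag <- abs(x[, , , 1])
  p <- file.path(dir, "magnitude.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mag, pixdim = voxel_mm), p)
  paths <- c(paths, p)
  for (comp in 1:3) {
    p <- file.path(dir, sprintf("velocity_%d.nii.gz", comp))
    RNifti::writeNifti(RNifti::asNifti(v[, , , comp], pixdim = voxel_mm), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
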