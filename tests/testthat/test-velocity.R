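test_that("velocity decoding implements the phase-difference relation", {
  set.seed(20)
  x <- rand_image(6, 6, 2, 4)
  x[, , , 2] <- x[, , , 1]
  v <- decode_velocity(x, venc = 150)
  expect_true(all(v[, , , 1] == 0))
  # phase difference of pi maps to exactly venc
  xx <- array(1 + 0i, c(4, 4, 1, 4))
  xx[2, 2, 1, 2] <- exp(1i * pi) * (1 + 1e-16)
  v2 <- decode_velocity(xx, venc = 150)
  expect_equal(abs(v2[2, 2, 1, 1]), 150)
  # zero-magnitude voxels decode to zero and are counted
  x0 <- x; x0[1, 1, 1, 1] <- 0
  v0 <- decode_velocity(x0, venc = 150)
  expect_equal(v0[1, 1, 1, ], rep(0, 3))
  expect_gte(attr(v0, "n_zero_magnitude"), 3)
  expect_error(decode_velocity(x[, , , 1:3, drop = FALSE], 150), "NV = 4")
})

test_that("background-phase correction recovers planted polynomial offsets", {
  set.seed(21)
  ny <- 32; nz <- 32; nt <- 3
  coeffs <- c(0.8, 0.4, -0.3, 0.25, -0.15, 0.2, -0.1, 0.08, -0.05, 0.06)
  basis <- poly_basis_2d(ny, nz)
  offset <- matrix(basis %*% coeffs, ny, nz)      # cm/s offset field
  vessel <- outer(1:ny, 1:nz, function(y, z) (y - 16)^2 + (z - 16)^2 < 16)
  vtrue <- array(0, c(ny, nz, nt, 3))
  for (t in 1:nt) vtrue[, , t, 1] <- 100 * vessel * exp(-(t - 2)^2)
  v <- vtrue
  for (t in 1:nt) for (comp in 1:3) v[, , t, comp] <- v[, , t, comp] + offset
  stationary <- !vessel
  vc <- correct_background_phase(v, stationary)
  fit <- attr(vc, "background_coeffs")
  for (comp in 1:3)
    expect_lt(max(abs(fit[, comp] - coeffs)) / max(abs(coeffs)), 0.01)
  expect_lt(max(abs(vc - vtrue)), 0.1)
  # residual stationary velocity is tiny and the correction is idempotent
  expect_lt(max(abs(vc[, , 1, 1][stationary])), 0.1)
  vcc <- correct_background_phase(vc, stationary)
  expect_lt(max(abs(vcc - vc)), 1e-6)
  # a constant offset is absorbed by the intercept
  vconst <- vtrue + 5
  vc2 <- correct_background_phase(vconst, stationary)
  expect_lt(abs(mean(vc2[, , 1, 1][stationary])), 1e-6)
  # zero-offset input passes through unchanged
  vc3 <- correct_background_phase(vtrue, stationary)
  expect_lt(max(abs(vc3 - vtrue)), 1e-6)
  expect_error(correct_background_phase(v, stationary * 0), "stationary mask")
})

test_that("trimmed refit tolerates contaminated stationary voxels", {
  set.seed(22)
  ny <- 24; nz <- 24
  coeffs <- c(1, 0.5, -0.5, 0.3, 0.1, -0.2, 0.05, -0.04, 0.03, 0.02)
  offset <- matrix(poly_basis_2d(ny, nz) %*% coeffs, ny, nz)
  v <- array(0, c(ny, nz, 2, 3))
  for (t in 1:2) for (comp in 1:3) v[, , t, comp] <- offset
  stationary <- matrix(TRUE, ny, nz)
  # contaminate 5% of stationary voxels with large spikes
  bad <- sample(ny * nz, round(0.05 * ny * nz))
  for (t in 1:2) { sl <- v[, , t, 1]; sl[bad] <- sl[bad] + 40; v[, , t, 1] <- sl }
  plain <- correct_background_phase(v, stationary)
  robust <- correct_background_phase(v, stationary, trim = 0.1)
  good <- setdiff(seq_len(ny * nz), bad)
  res_plain <- abs(plain[, , 1, 1][good])
  res_robust <- abs(robust[, , 1, 1][good])
  expect_lt(mean(res_robust), mean(res_plain))
})

test_that("error metrics reproduce direct formula evaluation", {
  set.seed(23)
  a <- array(abs(rnorm(60)), c(5, 4, 3)); b <- array(abs(rnorm(60)), c(5, 4, 3))
  expect_equal(nrmse_m(a, a), 0)
  expect_equal(nrmse_m(a * 0, a), 1)
  expect_equal(nrmse_m(a, b), sqrt(sum((a - b)^2) / sum(b^2)), tolerance = 1e-12)

  u <- array(rnorm(5 * 4 * 2 * 3), c(5, 4, 2, 3))
  vr <- array(rnorm(5 * 4 * 2 * 3), c(5, 4, 2, 3))
  roi <- matrix(runif(20) > 0.4, 5, 4)
  expect_equal(nrmse_v(vr, vr, roi), 0)
  expect_equal(nrmse_v(vr * 0, vr, roi), 1)
  expect_equal(nrmse_v(2 * vr, vr, roi), 1)       # homogeneity
  # independent direct evaluation
  num <- 0; den <- 0
  for (t in 1:2) for (y in 1:5) for (z in 1:4) if (roi[y, z]) {
    num <- num + sum((u[y, z, t, ] - vr[y, z, t, ])^2)
    den <- den + sum(vr[y, z, t, ]^2)
  }
  expect_equal(nrmse_v(u, vr, roi), sqrt(num / den), tolerance = 1e-12)
  # permutation invariance over voxels
  perm <- sample(5 * 4)
  up <- u; vp <- vr; rp <- roi
  for (t in 1:2) for (comp in 1:3) {
    up[, , t, comp] <- matrix(u[, , t, comp][perm], 5, 4)
    vp[, , t, comp] <- matrix(vr[, , t, comp][perm], 5, 4)
  }
  rp <- matrix(roi[perm], 5, 4)
  expect_equal(nrmse_v(up, vp, rp), nrmse_v(u, vr, roi), tolerance = 1e-12)
})

test_that("directional error has the prescribed geometry", {
  set.seed(24)
  vr <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  roi <- matrix(TRUE, 4, 4)
  expect_equal(as.numeric(mdirerr(vr, vr, roi)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(mdirerr(-vr, vr, roi)), 2, tolerance = 1e-12)
  # orthogonal fields: error exactly 1
  u <- vr * 0; u[, , , 1] <- vr[, , , 2]; u[, , , 2] <- -vr[, , , 1]
  expect_equal(as.numeric(mdirerr(u, vr, roi)), 1, tolerance = 1e-12)
  # zero-magnitude voxels are excluded and counted
  vz <- vr; vz[1, 1, , ] <- 0
  m <- mdirerr(vr, vz, roi)
  expect_equal(attr(m, "n_excluded"), 2L)
})

test_that("patch SNR follows its definition and scale invariance", {
  set.seed(25)
  a <- matrix(rnorm(10000, mean = 10, sd = 1), 100, 100)
  patch <- matrix(TRUE, 100, 100)
  expect_equal(snr_patch(a, patch), 20, tolerance = 0.5)
  expect_equal(snr_patch(3.7 * a, patch), snr_patch(a, patch), tolerance = 1e-12)
  expect_error(snr_patch(matrix(5, 4, 4), matrix(TRUE, 4, 4)), "constant")
})

test_that("peak-velocity extraction finds the vessel center of the phantom", {
  sp <- phantom_spec(grid = c(32, 32), n_frames = 5, n_coils = 2,
                     vessel_radius = 6, peak_frame = 3, peak_velocity = 110,
                     noise_sigma = 0, seed = 8)
  ct <- simulate_phantom(sp, mask_spec(R = 1, seed = 8))
  v <- decode_velocity(adjoint_op(ct$kspace, ct$smaps), ct$venc_cm_s)
  v <- correct_background_phase(v, stationary_mask(ct))
  pv <- peak_velocity_curve(v, ct$vessel_roi, component = 1)
  vox <- attr(pv, "voxel")
  expect_lt(max(abs(vox - sp$vessel_center)), 1.5)
  expect_equal(max(pv$v1), 110, tolerance = 0.5)
  expect_equal(nrow(pv), 5)
  # single-voxel ROI returns that voxel's time course
  roi1 <- matrix(FALSE, 32, 32); roi1[10, 12] <- TRUE
  pv1 <- peak_velocity_curve(v, roi1, component = 1)
  expect_equal(unname(attr(pv1, "voxel")), c(10, 12))
  expect_equal(pv1$v1, v[10, 12, , 1])
})

test_that("NIfTI export writes readable volumes", {
  dirn <- withr::local_tempdir()
  x <- rand_image(8, 8, 2, 4)
  v <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  export_nifti(x, v, dirn)
  f <- file.path(dirn, "magnitude.nii.gz")
  expect_true(file.exists(f))
  img <- RNifti::readNifti(f)
  expect_equal(dim(img), c(8, 8, 2))
  expect_equal(as.numeric(img[, , 1]), as.numeric(abs(x[, , 1, 1])),
               tolerance = 1e-6)
})
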