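test_that("partition invariants hold across random sampling masks", {
  set.seed(10)
  for (i in 1:25) {
    ny <- sample(12:20, 1); nz <- sample(12:20, 1)
    nt <- sample(1:3, 1); nv <- sample(2:4, 1)
    omega <- rand_omega(ny, nz, nt, nv, density = runif(1, 0.2, 0.6))
    p <- partition_mask(omega, ratio = 0.2, center_radius = 3)
    # disjoint and exhaustive
    expect_true(all(p$theta * p$lambda == 0))
    expect_equal(p$theta + p$lambda, omega)
    # protected center per frame and encoding
    cy <- floor(ny / 2) + 1; cz <- floor(nz / 2) + 1
    for (dy in -3:3) for (dz in -3:3)
      if (dy^2 + dz^2 <= 9)
        expect_true(all(p$lambda[cy + dy, cz + dz, , ] == 0))
    # sibling closure: every Lambda sample's sampled encoding-siblings are
    # also in Lambda
    hit <- apply(p$lambda, c(1, 2, 3), max)
    for (v in seq_len(nv)) {
      om_v <- array(omega[, , , v], dim(omega)[1:3])
      la_v <- array(p$lambda[, , , v], dim(omega)[1:3])
      expect_false(any(om_v == 1 & hit == 1 & la_v == 0))
    }
  }
})

test_that("partitioning errors when only the protected center is sampled", {
  omega <- array(0, c(12, 12, 1, 2))
  cy <- 7; cz <- 7
  for (dy in -3:3) for (dz in -3:3)
    if (dy^2 + dz^2 <= 9) omega[cy + dy, cz + dz, , ] <- 1
  expect_error(partition_mask(omega), "Lambda")
})

test_that("independent per-encoding masks give the requested Lambda ratio", {
  set.seed(12)
  # large sparse mask without cross-encoding overlap outside the center
  omega <- array(0, c(80, 80, 2, 2))
  pool0 <- which(flowrecon:::.center_distance(80, 80) > 3)
  picks <- matrix(sample(pool0, 4 * 1500), ncol = 4)
  for (v in 1:2) for (t in 1:2) {
    m <- matrix(0, 80, 80)
    m[picks[, (v - 1) * 2 + t]] <- 1
    m[flowrecon:::.center_distance(80, 80) <= 3] <- 1
    omega[, , t, v] <- m
  }
  p <- partition_mask(omega, ratio = 0.2, center_radius = 3)
  pool_n <- sum(omega) - sum(flowrecon:::.center_distance(80, 80) <= 3) * 4
  expect_lt(abs(sum(p$lambda) / pool_n - 0.2), 0.02)
})

test_that("applying a partition splits the measured data exactly", {
  set.seed(13)
  omega <- rand_omega(12, 12, 2, 4)
  y <- apply_mask_y(array(rcplx(12 * 12 * 3 * 2 * 4), c(12, 12, 3, 2, 4)), omega)
  p <- partition_mask(omega)
  ys <- apply_partition(y, p)
  expect_equal(ys$y_theta + ys$y_lambda, y)
  expect_equal(sum(Mod(ys$y_theta)^2) + sum(Mod(ys$y_lambda)^2),
               sum(Mod(y)^2))
  # fresh draws differ
  p2 <- partition_mask(omega)
  expect_false(identical(p$lambda, p2$lambda))
})

test_that("the normalized L1-L2 loss satisfies its identities", {
  set.seed(14)
  y <- array(rcplx(200), c(10, 10, 2, 1, 1))
  expect_equal(ssdu_loss(y, y), 0)
  expect_equal(ssdu_loss(y, y * 0), 2)
  yh <- y + array(rcplx(200, 0.3), dim(y))
  l <- ssdu_loss(y, yh)
  expect_gt(l, 0)
  for (cc in c(2 + 0i, -0.7i, 0.3 - 0.4i))
    expect_equal(ssdu_loss(cc * y, cc * yh), l, tolerance = 1e-12)
  expect_error(ssdu_loss(y * 0, y), "zero-norm")
})

test_that("analytic gradients match finite differences on a small problem", {
  set.seed(15)
  ny <- 4; nz <- 4; nt <- 2; nv <- 4; nc <- 1
  S <- rand_smaps(ny, nz, nc)
  cfg <- unroll_config(n_units = 2, n_filters = 2, kernel = 3,
                       n_bcrnn_layers = 1, n_venc = nv)
  params <- init_network_params(cfg, seed = 5)
  params$out$W <- array(rcplx(prod(dim(params$out$W)), 0.1), dim(params$out$W))
  params$layers[[1]]$b_mod <- rnorm(2, sd = 0.2)
  omega <- rand_omega(ny, nz, nt, nv, density = 0.5, center_radius = 1)
  y <- forward_op(rand_image(ny, nz, nt, nv), S, omega)
  p <- partition_mask(omega, ratio = 0.3, center_radius = 1)
  ys <- apply_partition(y, p)
  st <- flowrecon:::.ssdu_step(ys$y_theta, p$theta, ys$y_lambda, p$lambda, S, params)
  g <- flowrecon:::.flatten_params(st$grads)
  v0 <- flowrecon:::.flatten_params(params)
  lossfun <- function(vec) {
    pp <- flowrecon:::.unflatten_params(vec, params)
    x <- unrolled_forward(ys$y_theta, S, p$theta, pp)
    ssdu_loss(ys$y_lambda, forward_op(x, S, p$lambda))
  }
  idx <- unique(c(sample(length(v0), 12), length(v0) - 0:3))
  h <- 1e-5
  for (i in idx) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    fd <- (lossfun(vp) - lossfun(vm)) / (2 * h)
    if (abs(fd) > 1e-7) expect_lt(abs(fd - g[i]) / abs(fd), 1e-3)
  }
})

test_that("checkpointed recomputation reproduces stored-activation gradients exactly", {
  set.seed(16)
  S <- rand_smaps(6, 6, 2)
  cfg <- unroll_config(n_units = 3, n_filters = 3, n_bcrnn_layers = 2,
                       n_venc = 4)
  params <- init_network_params(cfg, seed = 2)
  params$out$W <- array(rcplx(prod(dim(params$out$W)), 0.05), dim(params$out$W))
  omega <- rand_omega(6, 6, 2, 4, density = 0.5)
  y <- forward_op(rand_image(6, 6, 2, 4), S, omega)
  p <- partition_mask(omega, center_radius = 2)
  ys <- apply_partition(y, p)
  a <- flowrecon:::.ssdu_step(ys$y_theta, p$theta, ys$y_lambda, p$lambda, S,
                              params, recompute = FALSE)
  b <- flowrecon:::.ssdu_step(ys$y_theta, p$theta, ys$y_lambda, p$lambda, S,
                              params, recompute = TRUE)
  expect_identical(flowrecon:::.flatten_params(a$grads),
                   flowrecon:::.flatten_params(b$grads))
  expect_identical(a$loss, b$loss)
})

test_that("training is seeded, reproducible, and a zero learning rate is inert", {
  containers <- make_phantom_set(n = 2, grid = c(16, 16), nt = 2, nc = 2,
                                 R = 4, noise = 0.01, base_seed = 50)
  ncfg <- unroll_config(n_units = 2, n_filters = 3, n_bcrnn_layers = 2,
                        n_venc = 4)
  # learning rate ~0: parameters unchanged after one epoch
  t0 <- train_config(learning_rate = 1e-300, epochs = 1, seed = 3)
  p0 <- init_network_params(ncfg, seed = 3)
  fit0 <- train_ssdu(containers, ncfg, t0, params = p0)
  expect_equal(flowrecon:::.flatten_params(fit0$params),
               flowrecon:::.flatten_params(p0), tolerance = 1e-250)
  # identical seeds give identical loss traces
  tc <- train_config(learning_rate = 5e-4, epochs = 3, seed = 9)
  f1 <- train_ssdu(containers, ncfg, tc)
  f2 <- train_ssdu(containers, ncfg, tc)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_length(f1$loss_trace, 6)
  expect_true(all(is.finite(f1$loss_trace)))
  expect_error(train_ssdu(list(), ncfg, tc), "empty")
})

test_that("self-supervised training at desk scale improves held-out reconstruction", {
  # package desk-scale recipe: 50 epochs over 7 slices at lr 2e-3; the
  # trained network must reconstruct the held-out slice with lower velocity
  # error than the zero-filled baseline
  containers <- make_phantom_set(n = 8)
  ncfg <- unroll_config(n_units = 4, n_filters = 8, kernel = 3,
                        n_bcrnn_layers = 4, n_venc = 4)
  tcfg <- train_config(learning_rate = 2e-3, epochs = 50, seed = 1)
  fit <- train_ssdu(containers[2:8], ncfg, tcfg)
  expect_lt(mean(utils::tail(fit$loss_trace, 10)),
            mean(utils::head(fit$loss_trace, 10)))
  ct <- containers[[1]]
  x_net <- reconstruct(ct$kspace, ct$smaps, ct$mask, fit$params)
  expect_identical(x_net,
                   unrolled_forward(ct$kspace, ct$smaps, ct$mask, fit$params))
  m_net <- evaluate_reconstruction(x_net, ct)
  m_zf <- evaluate_reconstruction(adjoint_op(ct$kspace, ct$smaps), ct)
  expect_lt(m_net$nrmse_v, m_zf$nrmse_v)
})
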