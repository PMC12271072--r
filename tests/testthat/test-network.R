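test_that("modReLU thresholds magnitude and preserves phase", {
  z <- 2 * exp(1i * pi / 3)
  expect_equal(modrelu(z, -1), exp(1i * pi / 3), tolerance = 1e-15)
  expect_equal(modrelu(1 + 0i, -2), 0 + 0i)
  set.seed(1)
  zz <- array(rcplx(4 * 4 * 3), c(4, 4, 3))
  expect_equal(modrelu(zz, 0), zz)                 # b = 0 is the identity
  out <- modrelu(zz, c(-0.5, 0.2, -4))
  nz <- Mod(out) > 0
  expect_lt(max(abs(Arg(out[nz]) - Arg(zz[nz]))), 1e-12)
  expect_true(all(out[, , 3] == 0))                # b << -|z| kills the map
})

test_that("complex convolution matches a brute-force oracle", {
  set.seed(2)
  inp <- array(rcplx(5 * 5 * 3), c(5, 5, 3))
  W <- array(rcplx(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  bias <- rcplx(2)
  expect_lt(max(Mod(complex_conv(inp, W, bias) - conv_oracle(inp, W, bias))),
            1e-12)
  # 1x1 kernel with a single weight is a pointwise product
  W1 <- array(0.7 - 0.2i, c(1, 1, 1, 1))
  i1 <- array(rcplx(16), c(4, 4, 1))
  expect_equal(complex_conv(i1, W1), i1 * (0.7 - 0.2i))
  # real weights and input give a real result
  Wr <- array(complex(real = rnorm(9)), c(3, 3, 1, 1))
  ir <- array(complex(real = rnorm(16)), c(4, 4, 1))
  expect_lt(max(abs(Im(complex_conv(ir, Wr)))), 1e-14)
})

test_that("bidirectional recurrent layer degenerates correctly and matches hand evaluation", {
  set.seed(3)
  f <- 2; cin <- 2
  lp <- list(W_in = array(rcplx(3 * 3 * cin * f, 0.3), c(3, 3, cin, f)),
             W_time = array(rcplx(3 * 3 * f * f, 0.3), c(3, 3, f, f)),
             W_iter = array(rcplx(3 * 3 * f * f, 0.3), c(3, 3, f, f)),
             b_in = rcplx(f, 0.1), b_time = rcplx(f, 0.1),
             b_iter = rcplx(f, 0.1), b_mod = rnorm(f, sd = 0.1))
  # NT = 1: both directions coincide, output is twice one pass
  inp1 <- array(rcplx(4 * 4 * cin), c(4, 4, cin, 1))
  h1 <- array(rcplx(4 * 4 * f), c(4, 4, f, 1))
  out1 <- bcrnn_layer(inp1, h1, lp)
  one <- modrelu(conv_oracle(inp1[, , , 1], lp$W_in, lp$b_in) +
                   conv_oracle(h1[, , , 1], lp$W_iter, lp$b_iter) +
                   array(rep(lp$b_time, each = 16), c(4, 4, f)),
                 lp$b_mod)
  expect_lt(max(Mod(out1[, , , 1] - 2 * one)), 1e-12)

  # NT = 2: explicit step-by-step recurrence on a tiny grid
  inp <- array(rcplx(3 * 3 * cin * 2), c(3, 3, cin, 2))
  h <- array(rcplx(3 * 3 * f * 2), c(3, 3, f, 2))
  out <- bcrnn_layer(inp, h, lp)
  step <- function(xt, hprev, hit) {
    modrelu(conv_oracle(xt, lp$W_in, lp$b_in) +
              conv_oracle(hprev, lp$W_time, lp$b_time) +
              conv_oracle(hit, lp$W_iter, lp$b_iter), lp$b_mod)
  }
  z3 <- array(0i, c(3, 3, f))
  f1 <- step(inp[, , , 1], z3, h[, , , 1]); f2 <- step(inp[, , , 2], f1, h[, , , 2])
  b2 <- step(inp[, , , 2], z3, h[, , , 2]); b1 <- step(inp[, , , 1], b2, h[, , , 1])
  expect_lt(max(Mod(out[, , , 1] - (f1 + b1))), 1e-12)
  expect_lt(max(Mod(out[, , , 2] - (f2 + b2))), 1e-12)
})

test_that("denoiser with zero output projection is the residual identity", {
  cfg <- unroll_config(n_units = 2, n_filters = 4, kernel = 3,
                       n_bcrnn_layers = 2, n_venc = 4)
  params <- init_network_params(cfg, seed = 1)   # output CNN zero-initialized
  set.seed(4)
  x <- rand_image(6, 6, 3, 4)
  r <- denoiser(x, NULL, params)
  expect_identical(r$z, x)
  expect_length(r$hidden, 2)
  # deterministic: same params, same input, same output
  params2 <- init_network_params(cfg, seed = 1)
  params2$out$W <- array(0.05 + 0.02i, dim(params2$out$W))
  r1 <- denoiser(x, NULL, params2)
  r2 <- denoiser(x, NULL, params2)
  expect_identical(r1$z, r2$z)
  expect_true(all(is.finite(Mod(r1$z))))
})

test_that("data-consistency block solves the per-coil quadratic subproblem", {
  # nu = 0 returns x for any mask under normalized full-support maps
  set.seed(5)
  S <- rand_smaps(4, 4, 2)
  x <- rand_image(4, 4, 1, 1)
  D <- array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))
  y <- forward_op(rand_image(4, 4, 1, 1), S, D)
  expect_lt(max(Mod(dc_block(x, y, S, D, 0) - x)), 1e-10)
  # nu = 1, full mask returns the zero-filled reconstruction of y
  Df <- array(1, c(4, 4, 1, 1))
  yf <- forward_op(rand_image(4, 4, 1, 1), S, Df)
  expect_lt(max(Mod(dc_block(x, yf, S, Df, 1) - adjoint_op(yf, S))), 1e-10)

  # oracle: normal-equation minimizer of lambda/2 ||D F w - y||^2 +
  # alpha/2 ||w - S x||^2 per coil, coil-combined, for random instances
  for (i in 1:25) {
    nc <- sample(1:2, 1)
    S2 <- rand_smaps(4, 4, nc)
    x2 <- rand_image(4, 4, 1, 1)
    m <- matrix(rbinom(16, 1, 0.5), 4, 4)
    D2 <- array(m, c(4, 4, 1, 1))
    yr <- array(0i, c(4, 4, nc, 1, 1))
    for (c in seq_len(nc)) yr[, , c, 1, 1] <- matrix(rcplx(16), 4, 4) * m
    nu <- runif(1, 0.05, 0.95)
    lambda <- nu; alpha <- 1 - nu    # nu = lambda / (lambda + alpha)
    F2 <- dense_dft2(4, 4)
    Dm <- diag(as.numeric(m))
    combined <- rep(0i, 16)
    for (c in seq_len(nc)) {
      Sc <- diag(as.complex(S2[, , c]))
      A <- lambda * Conj(t(F2)) %*% Dm %*% F2 + alpha * diag(16)
      b <- lambda * Conj(t(F2)) %*% Dm %*% as.vector(yr[, , c, 1, 1]) +
        alpha * Sc %*% as.vector(x2[, , 1, 1])
      w <- solve(A, b)
      combined <- combined + Conj(as.complex(S2[, , c])) * as.vector(w)
    }
    got <- as.vector(dc_block(x2, yr, S2, D2, nu)[, , 1, 1])
    expect_lt(sqrt(sum(Mod(got - combined)^2) / sum(Mod(combined)^2)), 1e-6)
  }
})

test_that("weighted-averaging block solves the image consensus subproblem", {
  set.seed(6)
  x_dc <- rand_image(4, 4, 2, 2); z <- rand_image(4, 4, 2, 2)
  expect_equal(wa_block(x_dc, z, 1), x_dc)
  expect_equal(wa_block(x_dc, z, 0), z)
  # oracle: (alpha sum S^H S + beta I)^{-1} (alpha sum S^H w + beta z)
  # with normalized full-support maps, where x_dc = sum S^H w
  for (i in 1:25) {
    nc <- sample(1:3, 1)
    S <- rand_smaps(4, 4, nc)
    w <- array(rcplx(16 * nc), c(4, 4, nc))     # per-coil auxiliary images
    zz <- array(rcplx(16), c(4, 4))
    mu <- runif(1, 0.05, 0.95)
    alpha <- mu; beta <- 1 - mu                 # mu = alpha / (alpha + beta)
    SHS <- rowSums(sapply(seq_len(nc), function(c) Mod(as.complex(S[, , c]))^2))
    SHw <- rowSums(sapply(seq_len(nc), function(c)
      Conj(as.complex(S[, , c])) * as.complex(w[, , c])))
    if (nc == 1) { SHS <- Mod(as.complex(S[, , 1]))^2
                   SHw <- Conj(as.complex(S[, , 1])) * as.complex(w[, , 1]) }
    oracle <- (alpha * SHw + beta * as.complex(zz)) / (alpha * SHS + beta)
    xdc <- array(SHw, c(4, 4, 1, 1))
    got <- as.vector(wa_block(xdc, array(zz, c(4, 4, 1, 1)), mu)[, , 1, 1])
    expect_lt(sqrt(sum(Mod(got - oracle)^2) / sum(Mod(oracle)^2)), 1e-6)
  }
})

test_that("parameter count reproduces the documented convention", {
  expect_equal(as.numeric(count_parameters(unroll_config())), 64099)
  n <- count_parameters(unroll_config(n_units = 3, n_filters = 2, kernel = 1,
                                      n_bcrnn_layers = 1, n_venc = 1))
  expect_equal(as.numeric(n), 27)
  expect_equal(unname(attr(n, "breakdown")), c(19, 8))
  # weight sharing: doubling N adds exactly 2 * dN scalars
  n10 <- count_parameters(unroll_config(n_units = 10))
  n20 <- count_parameters(unroll_config(n_units = 20))
  expect_equal(as.numeric(n20 - n10), 20)
})

test_that("unrolled forward pass has the prescribed degenerate behaviors", {
  set.seed(7)
  S <- rand_smaps(6, 6, 2)
  cfg0 <- unroll_config(n_units = 0, n_filters = 3, n_bcrnn_layers = 2,
                        n_venc = 4)
  p0 <- init_network_params(cfg0, seed = 1)
  D <- array(rbinom(6 * 6 * 2 * 4, 1, 0.6), c(6, 6, 2, 4))
  y <- forward_op(rand_image(6, 6, 2, 4), S, D)
  # N = 0: the zero-filled reconstruction
  expect_equal(unrolled_forward(y, S, D, p0), adjoint_op(y, S))

  # zero output CNN, nu -> 0, mu -> 1: every unit is a passthrough
  cfg <- unroll_config(n_units = 3, n_filters = 3, n_bcrnn_layers = 2,
                       n_venc = 4)
  p <- init_network_params(cfg, seed = 1)
  p$nu_raw <- rep(-40, 3)   # sigmoid ~ 0
  p$mu_raw <- rep(40, 3)    # sigmoid ~ 1
  x0 <- adjoint_op(y, S)
  xn <- unrolled_forward(y, S, D, p)
  expect_lt(max(Mod(xn - x0)), 1e-8)

  # with identity denoiser and nu = 1 the fully sampled reconstruction is a
  # fixed point of every unit
  Df <- array(1, c(6, 6, 2, 4))
  yf <- forward_op(rand_image(6, 6, 2, 4), S, Df)
  pf <- init_network_params(unroll_config(n_units = 4, n_filters = 3,
                                          n_bcrnn_layers = 2, n_venc = 4),
                            seed = 2)
  pf$nu_raw <- rep(40, 4); pf$mu_raw <- rep(40, 4)
  expect_lt(max(Mod(unrolled_forward(yf, S, Df, pf) - adjoint_op(yf, S))), 1e-6)

  # bounded output across random parameter draws
  for (i in 1:10) {
    pr <- init_network_params(cfg, seed = 100 + i)
    pr$out$W <- array(rcplx(prod(dim(pr$out$W)), sd = 0.05), dim(pr$out$W))
    xr <- unrolled_forward(y, S, D, pr)
    expect_true(all(is.finite(Mod(xr))))
  }
})
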