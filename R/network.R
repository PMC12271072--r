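# The unrolled reconstruction network: a complex-valued bidirectional
# convolutional recurrent denoiser (the learned proximal operator of the
# regularizer), a closed-form k-space data-consistency block, and a
# weighted-averaging block, repeated for N units with shared weights.
# Per-unit scalars nu_n (data-consistency noise level) and mu_n (averaging
# weight) are stored as raw reals and passed through a sigmoid.

#' Unrolled network configuration
#'
#' @param n_units number of unrolling units N (weights shared across units).
#' @param n_filters number of complex feature maps f per recurrent layer.
#' @param kernel odd spatial kernel size k of all convolutions.
#' @param n_bcrnn_layers number of bidirectional convolutional recurrent
#'   layers in the denoiser.
#' @param n_venc number of velocity encodings NV; the encodings are the
#'   feature channels of the network input, so their redundancy is exploited
#'   jointly.
#' @return object of class `unroll_config`.
#' @export
unroll_config <- function(n_units = 10L, n_filters = 25L, kernel = 3L,
                          n_bcrnn_layers = 4L, n_venc = 4L) {
  if (kernel %% 2 == 0) stop("kernel size must be odd")
  if (n_units < 0) stop("n_units must be >= 0")
  structure(list(n_units = as.integer(n_units),
                 n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel),
                 n_bcrnn_layers = as.integer(n_bcrnn_layers),
                 n_venc = as.integer(n_venc),
                 weight_sharing = TRUE),
            class = "unroll_config")
}

#' Count learnable parameters
#'
#' Complex parameters are counted once each (not as two reals).  Per
#' recurrent layer with input width `C_in`: `(C_in f + 2 f^2) k^2` complex
#' convolution weights, `3 f` complex biases, and `f` real modReLU biases.
#' The output projection adds `f NV k^2 + NV` complex parameters, and each
#' unrolling unit contributes two real scalars (`nu_raw`, `mu_raw`).  For the
#' default configuration this totals 64,099.
#'
#' @param config an [unroll_config()].
#' @return total parameter count, with attribute `breakdown`
#'   (complex and real counts).
#' @export
count_parameters <- function(config) {
  f <- config$n_filters; k <- config$kernel; nv <- config$n_venc
  L <- config$n_bcrnn_layers; N <- config$n_units
  n_complex <- 0
  for (l in seq_len(L)) {
    cin <- if (l == 1L) nv else f
    n_complex <- n_complex + (cin * f + 2 * f^2) * k^2 + 3 * f
  }
  n_complex <- n_complex + f * nv * k^2 + nv
  n_real <- L * f + 2 * N
  structure(n_complex + n_real,
            breakdown = c(complex = n_complex, real = n_real))
}

# complex Glorot-style init: independent real/imaginary parts with the
# per-component variance halved so |w| matches real-network fan-in scaling.
# `gain` rescales the standard deviation; the recurrent layers use
# 1/sqrt(6) because each pre-activation sums three convolution terms and the
# layer output sums two directional passes, keeping the activation variance
# roughly unity through the stack instead of compounding across units.
.cx_init <- function(dims, fan_in, gain = 1) {
  sd <- gain * sqrt(1 / (2 * fan_in))
  n <- prod(dims)
  w <- complex(real = stats::rnorm(n, sd = sd),
               imaginary = stats::rnorm(n, sd = sd))
  dim(w) <- dims
  w
}

#' Initialize network parameters
#'
#' @param config an [unroll_config()].
#' @param seed integer seed.
#' @return object of class `flow_params`: nested list with per-layer complex
#'   convolution weights/biases and real modReLU biases, the output
#'   projection, and raw per-unit scalars `nu_raw`, `mu_raw` (initialized to
#'   0, i.e. sigmoid 0.5).
#' @export
init_network_params <- function(config, seed = 1L) {
  f <- config$n_filters; k <- config$kernel; nv <- config$n_venc
  L <- config$n_bcrnn_layers; N <- config$n_units
  .with_seed(seed, {
    layers <- vector("list", L)
    g <- 1 / sqrt(6)
    for (l in seq_len(L)) {
      cin <- if (l == 1L) nv else f
      layers[[l]] <- list(
        W_in = .cx_init(c(k, k, cin, f), cin * k^2, gain = g),
        W_time = .cx_init(c(k, k, f, f), f * k^2, gain = g),
        W_iter = .cx_init(c(k, k, f, f), f * k^2, gain = g),
        b_in = array(0i, f), b_time = array(0i, f), b_iter = array(0i, f),
        b_mod = numeric(f))
    }
    # zero-initialized output projection: the denoiser starts as the exact
    # identity (residual passthrough), so the untrained unrolled network is a
    # pure alternating data-consistency scheme and training departs from it
    # only as the self-supervised loss accumulates evidence
    out <- list(W = array(0i, c(k, k, f, nv)), b = array(0i, nv))
    p <- structure(list(layers = layers, out = out,
                        nu_raw = numeric(N), mu_raw = numeric(N)),
                   class = "flow_params")
    attr(p, "config") <- config
    p
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' modReLU activation
#'
#' Magnitude-thresholding, phase-preserving activation for complex-valued
#' networks: `(|z| + b) z / |z|` where `|z| + b >= 0`, else 0.  The learnable
#' bias `b` is real, one per feature map.
#'
#' @param z complex array; if `b` has length > 1, the last dimension of `z`
#'   (or the third of a `(NY, NZ, f, ...)` array) indexes features.
#' @param b real bias, scalar or one per feature map.
#' @return complex array of the same shape, with the phase of `z` wherever
#'   the output is nonzero.
#' @export
modrelu <- function(z, b) {
  r <- Mod(z)
  bfull <- .expand_feature(b, z)
  scale <- ifelse(r > 0 & (r + bfull) >= 0, 1 + bfull / pmax(r, .Machine$double.xmin), 0)
  z * scale
}

# broadcast a per-feature vector over a (NY, NZ, f[, ...]) complex array;
# a scalar bias applies everywhere (and keeps scalar inputs dimensionless)
.expand_feature <- function(b, z) {
  if (length(b) == 1L) return(b)
  d <- dim(z)
  if (is.null(d)) stop("per-feature bias requires an array input")
  if (d[3] != length(b)) stop("feature count mismatch in modrelu")
  arr <- array(rep(b, each = d[1] * d[2]), d)
  arr
}

# backward pass of modrelu under the real-pair gradient convention
# g = dL/dRe + i dL/dIm; returns gradient wrt z and the per-feature real
# bias gradient
.modrelu_bwd <- function(g, z, b) {
  r <- Mod(z)
  bfull <- .expand_feature(b, z)
  active <- r > 0 & (r + bfull) >= 0
  rs <- pmax(r, .Machine$double.xmin)
  gz <- ifelse(active,
               g * (1 + bfull / (2 * rs)) - Conj(g) * bfull * z^2 / (2 * rs^3),
               0i)
  gb_full <- ifelse(active, Re(g * Conj(z)) / rs, 0)
  d <- dim(z)
  if (length(b) == 1L) {
    gb <- sum(gb_full)
  } else {
    dim(gb_full) <- c(d[1] * d[2], d[3], prod(d[-(1:3)]))
    gb <- rowSums(colSums(gb_full))
    dim(gb) <- NULL
  }
  list(g = gz, g_b = gb)
}

#' Complex-valued 2D convolution
#'
#' Full complex multiply-accumulate convolution with "same" zero padding.
#'
#' @param input complex array `(NY, NZ, C_in)`.
#' @param W complex weights `(k, k, C_in, C_out)`, `k` odd.
#' @param bias complex bias of length `C_out` (default zeros).
#' @return complex array `(NY, NZ, C_out)`.
#' @export
complex_conv <- function(input, W, bias = NULL) {
  if (is.null(bias)) bias <- array(0i, dim(W)[4])
  storage.mode(input) <- "complex"
  storage.mode(W) <- "complex"
  storage.mode(bias) <- "complex"
  .cx_conv2d(input, W, bias)
}

# one bidirectional convolutional recurrent layer
# inp: (NY, NZ, Cin, NT); h_iter: (NY, NZ, f, NT) hidden state of this layer
# at the previous unrolling unit (zeros at the first unit).  Directional
# weights are shared; the layer output is the sum of the two directional
# hidden sequences.
.bcrnn_forward <- function(inp, h_iter, lp, tape = FALSE) {
  d <- dim(inp)
  nt <- d[4]
  f <- dim(lp$W_in)[4]
  out <- array(0i, c(d[1], d[2], f, nt))
  pre_store <- if (tape) array(0i, c(d[1], d[2], f, nt, 2)) else NULL
  h_store <- if (tape) array(0i, c(d[1], d[2], f, nt, 2)) else NULL
  for (dir in 1:2) {
    ord <- if (dir == 1) seq_len(nt) else rev(seq_len(nt))
    hprev <- array(0i, c(d[1], d[2], f))
    for (t in ord) {
      pre <- complex_conv(.slice_last(inp, t), lp$W_in, lp$b_in) +
        complex_conv(hprev, lp$W_time, lp$b_time) +
        complex_conv(.slice_last(h_iter, t), lp$W_iter, lp$b_iter)
      h <- modrelu(pre, lp$b_mod)
      if (tape) { pre_store[, , , t, dir] <- pre; h_store[, , , t, dir] <- h }
      out[, , , t] <- out[, , , t] + h
      hprev <- h
    }
  }
  list(out = out, tape = if (tape) list(pre = pre_store, H = h_store) else NULL)
}

#' Bidirectional convolutional recurrent layer
#'
#' Evolves a convolutional recurrence over the cardiac frames in both
#' temporal directions with shared weights and zero initial states, adding a
#' recurrent connection over the unrolling-iteration dimension through the
#' layer's hidden state at the previous unit.  The output is the sum of the
#' two directional hidden sequences after the modReLU activation.
#'
#' @param inp complex array `(NY, NZ, C_in, NT)`.
#' @param h_iter complex array `(NY, NZ, f, NT)`: this layer's hidden state
#'   from the previous unrolling unit (zeros at the first unit).
#' @param layer_params list with `W_in`, `W_time`, `W_iter` complex weights,
#'   `b_in`, `b_time`, `b_iter` complex biases and `b_mod` real modReLU bias.
#' @return complex array `(NY, NZ, f, NT)`.
#' @export
bcrnn_layer <- function(inp, h_iter, layer_params) {
  .bcrnn_forward(inp, h_iter, layer_params, tape = FALSE)$out
}

# denoiser: BCRNN stack + output CNN + residual connection around the whole
# block.  x: (NY, NZ, NT, NV); hidden: list over layers of (NY, NZ, f, NT).
.denoiser_forward <- function(x, hidden, params, tape = FALSE) {
  cfg <- attr(params, "config")
  d <- dim(x)
  ny <- d[1]; nz <- d[2]; nt <- d[3]; nv <- d[4]
  f <- cfg$n_filters
  L <- cfg$n_bcrnn_layers
  if (is.null(hidden))
    hidden <- replicate(L, array(0i, c(ny, nz, f, nt)), simplify = FALSE)
  inp <- aperm(x, c(1, 2, 4, 3))           # (NY, NZ, NV, NT): channels third
  layer_inputs <- if (tape) vector("list", L) else NULL
  layer_tapes <- if (tape) vector("list", L) else NULL
  new_hidden <- vector("list", L)
  for (l in seq_len(L)) {
    if (tape) layer_inputs[[l]] <- inp
    r <- .bcrnn_forward(inp, hidden[[l]], params$layers[[l]], tape = tape)
    new_hidden[[l]] <- r$out
    if (tape) layer_tapes[[l]] <- r$tape
    inp <- r$out
  }
  cnn <- array(0i, c(ny, nz, nv, nt))
  for (t in seq_len(nt))
    cnn[, , , t] <- complex_conv(.slice_last(inp, t),
                                 params$out$W, params$out$b)
  z <- x + aperm(cnn, c(1, 2, 4, 3))
  list(z = z, hidden = new_hidden,
       tape = if (tape) list(layer_inputs = layer_inputs,
                             layer_tapes = layer_tapes,
                             cnn_in = inp, hidden_in = hidden) else NULL)
}

#' Learned denoising block
#'
#' Passes the image series (velocity encodings as feature channels) through
#' the bidirectional recurrent stack and the output projection, then adds the
#' input through a residual connection.
#'
#' @param x complex image series `(NY, NZ, NT, NV)`.
#' @param hidden list over layers of complex hidden states
#'   `(NY, NZ, f, NT)` from the previous unrolling unit, or `NULL` for zeros.
#' @param params a `flow_params` object.
#' @return list with `z` (denoised image series) and `hidden` (states to pass
#'   to the next unit).
#' @export
denoiser <- function(x, hidden, params) {
  r <- .denoiser_forward(x, hidden, params, tape = FALSE)
  list(z = r$z, hidden = r$hidden)
}

#' Data-consistency block
#'
#' Closed-form minimizer of the per-coil data-fidelity subproblem: in
#' k-space, sampled locations are replaced by the convex combination
#' `nu * y + (1 - nu) * F S x` while unsampled locations keep the predicted
#' value; the result is coil-combined back to image space.  `nu` is the
#' learned noise level `lambda / (lambda + alpha)` of the quadratic
#' splitting.
#'
#' @param x complex image series `(NY, NZ, NT, NV)`.
#' @param y measured complex k-space `(NY, NZ, NC, NT, NV)`.
#' @param smaps normalized coil maps `(NY, NZ, NC)`.
#' @param mask binary sampling mask `(NY, NZ, NT, NV)`.
#' @param nu scalar in `[0, 1]`.
#' @return complex image series `(NY, NZ, NT, NV)`.
#' @export
dc_block <- function(x, y, smaps, mask, nu) {
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]")
  d <- dim(x)
  dy <- dim(y)
  if (!all(d[1:2] == dy[1:2]) || !all(d[3:4] == dy[4:5]))
    stop("shape mismatch between image and k-space")
  ny <- d[1]; nz <- d[2]; nt <- d[3]; nv <- d[4]; nc <- dy[3]
  out <- array(0i, d)
  cs <- Conj(smaps)
  for (v in seq_len(nv)) for (t in seq_len(nt)) {
    m <- mask[, , t, v]
    k <- fft2c(smaps * as.vector(x[, , t, v]))
    for (c in seq_len(nc))
      k[, , c] <- m * (nu * y[, , c, t, v] + (1 - nu) * k[, , c]) +
        (1 - m) * k[, , c]
    img <- ifft2c(k)
    acc <- array(0i, c(ny, nz))
    for (c in seq_len(nc)) acc <- acc + cs[, , c] * img[, , c]
    out[, , t, v] <- acc
  }
  out
}

#' Weighted-averaging block
#'
#' Convex combination `mu * x_dc + (1 - mu) * z` of the coil-combined
#' data-consistency output and the denoiser output — the closed-form
#' minimizer of the image-consensus subproblem under unit-gain coil maps,
#' with `mu = alpha / (alpha + beta)`.
#'
#' @param x_dc data-consistency output `(NY, NZ, NT, NV)`.
#' @param z denoiser output `(NY, NZ, NT, NV)`.
#' @param mu scalar in `[0, 1]`.
#' @return complex image series `(NY, NZ, NT, NV)`.
#' @export
wa_block <- function(x_dc, z, mu) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  mu * x_dc + (1 - mu) * z
}

#' Unrolled network forward pass
#'
#' Starting from the zero-filled reconstruction `x0 = E^H y`, applies
#' `n_units` iterations of denoising, data consistency and weighted
#' averaging with shared weights; per-unit `nu_n = sigmoid(nu_raw[n])` and
#' `mu_n = sigmoid(mu_raw[n])`.
#'
#' @param y complex k-space `(NY, NZ, NC, NT, NV)` (zero off the mask).
#' @param smaps normalized coil maps `(NY, NZ, NC)`.
#' @param mask binary sampling mask `(NY, NZ, NT, NV)` matching `y`.
#' @param params a `flow_params` object (configuration attached).
#' @param keep_tape keep intermediate activations for backpropagation
#'   (`"all"`), only per-unit inputs for recomputation-based memory saving
#'   (`"checkpoint"`), or nothing (`"none"`, default).
#' @return reconstructed complex image series `(NY, NZ, NT, NV)`; when a tape
#'   is kept it is attached as attribute `tape`.
#' @export
unrolled_forward <- function(y, smaps, mask, params,
                             keep_tape = c("none", "all", "checkpoint")) {
  keep_tape <- match.arg(keep_tape)
  cfg <- attr(params, "config")
  N <- cfg$n_units
  x <- adjoint_op(y, smaps)
  hidden <- NULL
  units <- if (keep_tape != "none") vector("list", N) else NULL
  for (n in seq_len(N)) {
    nu <- sigmoid(params$nu_raw[n])
    mu <- sigmoid(params$mu_raw[n])
    den <- .denoiser_forward(x, hidden, params, tape = (keep_tape == "all"))
    xdc <- dc_block(x, y, smaps, mask, nu)
    xn <- wa_block(xdc, den$z, mu)
    if (keep_tape != "none")
      units[[n]] <- list(x_in = x, hidden_in = hidden, z = den$z, xdc = xdc,
                         den_tape = if (keep_tape == "all") den$tape else NULL)
    x <- xn
    hidden <- den$hidden
  }
  if (keep_tape != "none")
    attr(x, "tape") <- list(units = units, mode = keep_tape)
  x
}
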