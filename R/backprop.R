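# Reverse-mode gradients through the unrolled network, written against the
# real-pair convention g = dL/d(Re .) + i dL/d(Im .) (= 2 dL/d conj(.)) so
# finite differences on the real and imaginary parts match the propagated
# gradients directly.  All operators here are small enough that the
# activations of a whole forward pass fit comfortably in memory; an optional
# checkpointing mode stores only per-unit inputs and recomputes activations
# during the backward sweep (bit-identical results, lower memory).

.zero_like_params <- function(params) {
  z <- params
  for (l in seq_along(z$layers))
    for (nm in names(z$layers[[l]]))
      z$layers[[l]][[nm]] <- z$layers[[l]][[nm]] * 0
  z$out$W <- z$out$W * 0
  z$out$b <- z$out$b * 0
  z$nu_raw <- z$nu_raw * 0
  z$mu_raw <- z$mu_raw * 0
  z
}

# backward through one bidirectional recurrent layer
.bcrnn_backward <- function(g_out, inp, h_iter, tape, lp) {
  d <- dim(inp)
  nt <- d[4]
  f <- dim(lp$W_in)[4]
  k <- dim(lp$W_in)[1]
  gW_in <- lp$W_in * 0; gW_time <- lp$W_time * 0; gW_iter <- lp$W_iter * 0
  gb <- array(0i, f)
  g_bmod <- numeric(f)
  g_inp <- array(0i, d)
  g_hiter <- array(0i, c(d[1], d[2], f, nt))
  zerosf <- array(0i, c(d[1], d[2], f))
  for (dir in 1:2) {
    ord <- if (dir == 1) seq_len(nt) else rev(seq_len(nt))
    carry <- zerosf
    for (j in rev(seq_len(nt))) {
      t <- ord[j]
      g_h <- .slice_last(g_out, t) + carry
      mb <- .modrelu_bwd(g_h, .slice_last(tape$pre, t, dir), lp$b_mod)
      g_pre <- mb$g
      g_bmod <- g_bmod + mb$g_b
      hprev <- if (j == 1) zerosf else .slice_last(tape$H, ord[j - 1], dir)
      r1 <- .cx_conv2d_bwd_weights(.slice_last(inp, t), g_pre, k)
      r2 <- .cx_conv2d_bwd_weights(hprev, g_pre, k)
      r3 <- .cx_conv2d_bwd_weights(.slice_last(h_iter, t), g_pre, k)
      gW_in <- gW_in + r1$W; gW_time <- gW_time + r2$W; gW_iter <- gW_iter + r3$W
      gb <- gb + r1$bias
      g_inp[, , , t] <- .slice_last(g_inp, t) + .cx_conv2d_bwd_input(g_pre, lp$W_in)
      g_hiter[, , , t] <- .slice_last(g_hiter, t) +
        .cx_conv2d_bwd_input(g_pre, lp$W_iter)
      carry <- .cx_conv2d_bwd_input(g_pre, lp$W_time)
    }
  }
  # the three biases enter the pre-activation additively, so they share one
  # gradient
  list(W_in = gW_in, W_time = gW_time, W_iter = gW_iter,
       b_in = gb, b_time = gb, b_iter = gb, b_mod = g_bmod,
       g_inp = g_inp, g_hiter = g_hiter)
}

# backward through the denoiser (BCRNN stack + output CNN + residual)
.denoiser_backward <- function(g_z, g_hidden, tape, params, grads) {
  cfg <- attr(params, "config")
  L <- cfg$n_bcrnn_layers
  k <- cfg$kernel
  d <- dim(g_z)
  nt <- d[3]
  g_x <- g_z                                  # residual path
  g_cnn <- aperm(g_z, c(1, 2, 4, 3))          # (NY, NZ, NV, NT)
  g_feat <- array(0i, dim(tape$cnn_in))
  for (t in seq_len(nt)) {
    gt <- .slice_last(g_cnn, t)
    r <- .cx_conv2d_bwd_weights(.slice_last(tape$cnn_in, t), gt, k)
    grads$out$W <- grads$out$W + r$W
    grads$out$b <- grads$out$b + r$bias
    g_feat[, , , t] <- .cx_conv2d_bwd_input(gt, params$out$W)
  }
  g_out_l <- g_feat
  if (!is.null(g_hidden)) g_out_l <- g_out_l + g_hidden[[L]]
  g_hidden_prev <- vector("list", L)
  for (l in seq.int(L, 1)) {
    gb <- .bcrnn_backward(g_out_l, tape$layer_inputs[[l]],
                          tape$hidden_in[[l]], tape$layer_tapes[[l]],
                          params$layers[[l]])
    for (nm in c("W_in", "W_time", "W_iter", "b_in", "b_time", "b_iter", "b_mod"))
      grads$layers[[l]][[nm]] <- grads$layers[[l]][[nm]] + gb[[nm]]
    g_hidden_prev[[l]] <- gb$g_hiter
    if (l > 1) {
      g_out_l <- gb$g_inp
      if (!is.null(g_hidden)) g_out_l <- g_out_l + g_hidden[[l - 1]]
    } else {
      g_x <- g_x + aperm(gb$g_inp, c(1, 2, 4, 3))
    }
  }
  list(g_x = g_x, g_hidden_prev = g_hidden_prev, grads = grads)
}

# derivative of the data-consistency output with respect to nu:
# sum_i S_i^H F^{-1}[ D (y_i - F S_i x) ]
.dc_dnu <- function(x, y, smaps, mask) {
  d <- dim(x)
  nc <- dim(y)[3]
  out <- array(0i, d)
  cs <- Conj(smaps)
  for (v in seq_len(d[4])) for (t in seq_len(d[3])) {
    m <- mask[, , t, v]
    k <- fft2c(smaps * as.vector(x[, , t, v]))
    for (c in seq_len(nc)) k[, , c] <- m * (y[, , c, t, v] - k[, , c])
    img <- ifft2c(k)
    acc <- array(0i, c(d[1], d[2]))
    for (c in seq_len(nc)) acc <- acc + cs[, , c] * img[, , c]
    out[, , t, v] <- acc
  }
  out
}

# full backward sweep through the unrolled network.  `tape` is the attribute
# attached by unrolled_forward(); g_xN is the gradient of the loss with
# respect to the network output.
.network_backward <- function(tape, g_xN, params, y, smaps, mask) {
  cfg <- attr(params, "config")
  N <- cfg$n_units
  grads <- .zero_like_params(params)
  zero_y <- y * 0
  g_x <- g_xN
  g_hidden <- NULL
  for (n in rev(seq_len(N))) {
    u <- tape$units[[n]]
    den_tape <- u$den_tape
    if (is.null(den_tape))  # checkpointing: recompute this unit's activations
      den_tape <- .denoiser_forward(u$x_in, u$hidden_in, params, tape = TRUE)$tape
    nu <- sigmoid(params$nu_raw[n])
    mu <- sigmoid(params$mu_raw[n])
    # weighted averaging: x_n = mu * xdc + (1 - mu) * z
    grads$mu_raw[n] <- grads$mu_raw[n] +
      sum(Re(g_x * Conj(u$xdc - u$z))) * mu * (1 - mu)
    g_dc <- mu * g_x
    g_z <- (1 - mu) * g_x
    # data consistency: self-adjoint linear map in x (apply it to the
    # gradient with the measured k-space zeroed), plus the nu sensitivity
    grads$nu_raw[n] <- grads$nu_raw[n] +
      sum(Re(g_dc * Conj(.dc_dnu(u$x_in, y, smaps, mask)))) * nu * (1 - nu)
    g_x_dc <- dc_block(g_dc, zero_y, smaps, mask, nu)
    db <- .denoiser_backward(g_z, g_hidden, den_tape, params, grads)
    grads <- db$grads
    g_x <- g_x_dc + db$g_x
    g_hidden <- db$g_hidden_prev
  }
  grads
}

# ---- flattening utilities (optimizer state lives on one real vector) ----

.flatten_params <- function(p) {
  out <- vector("list", 0)
  push <- function(x) {
    if (is.complex(x)) c(as.numeric(Re(x)), as.numeric(Im(x))) else as.numeric(x)
  }
  for (lp in p$layers)
    for (nm in c("W_in", "W_time", "W_iter", "b_in", "b_time", "b_iter", "b_mod"))
      out[[length(out) + 1L]] <- push(lp[[nm]])
  out[[length(out) + 1L]] <- push(p$out$W)
  out[[length(out) + 1L]] <- push(p$out$b)
  out[[length(out) + 1L]] <- push(p$nu_raw)
  out[[length(out) + 1L]] <- push(p$mu_raw)
  unlist(out, use.names = FALSE)
}

.unflatten_params <- function(vec, template) {
  pos <- 0L
  take <- function(proto) {
    n <- length(proto)
    if (is.complex(proto)) {
      re <- vec[(pos + 1L):(pos + n)]
      im <- vec[(pos + n + 1L):(pos + 2L * n)]
      pos <<- pos + 2L * n
      z <- complex(real = re, imaginary = im)
      dim(z) <- dim(proto)
      z
    } else {
      v <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      dim(v) <- dim(proto)
      v
    }
  }
  p <- template
  for (l in seq_along(p$layers))
    for (nm in c("W_in", "W_time", "W_iter", "b_in", "b_time", "b_iter", "b_mod"))
      p$layers[[l]][[nm]] <- take(template$layers[[l]][[nm]])
  p$out$W <- take(template$out$W)
  p$out$b <- take(template$out$b)
  p$nu_raw <- take(template$nu_raw)
  p$mu_raw <- take(template$mu_raw)
  if (pos != length(vec)) stop("parameter vector length mismatch")
  p
}
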