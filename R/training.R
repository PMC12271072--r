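# Self-supervised training on the acquired undersampled k-space: the
# sampled locations Omega are split per step into a network-input /
# data-consistency set Theta and a held-out loss set Lambda, the network
# reconstructs from Theta alone, and the reconstruction is compared to the
# measured samples on Lambda through the encoding operator.

.expand_mask <- function(mask, nc) {
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], nc, d[3], d[4]))
  for (c in seq_len(nc)) out[, , c, , ] <- mask
  out
}

#' Partition the sampled k-space locations into Theta and Lambda
#'
#' Draws a uniform random `ratio` fraction of the sampled locations outside
#' the protected k-space center into the loss set Lambda, then closes Lambda
#' under velocity-encoding siblings: every sampled location that differs from
#' a Lambda member only in its encoding index is moved into Lambda as well.
#' The remainder (including the fully protected center disc of every frame
#' and encoding) forms the network-input set Theta.  Theta and Lambda are
#' disjoint and their union is the sampling mask.  Uses the current R random
#' number generator state; seed the generator for reproducibility.
#'
#' @param omega binary sampling mask `(NY, NZ, NT, NV)`.
#' @param ratio target fraction of the candidate pool assigned to Lambda
#'   before sibling closure (default 0.2); the effective Lambda fraction
#'   after closure is reported in the result.
#' @param center_radius radius (samples) of the protected central disc
#'   around the centered k-space origin, per frame and encoding (default 3).
#' @return list with binary arrays `theta` and `lambda`, the settings, and
#'   `lambda_fraction` (share of sampled locations in Lambda after closure).
#' @export
partition_mask <- function(omega, ratio = 0.2, center_radius = 3) {
  d <- dim(omega)
  .check_mask_binary(omega)
  rad <- .center_distance(d[1], d[2])
  center2d <- rad <= center_radius
  center <- array(0, d)
  for (v in seq_len(d[4])) for (t in seq_len(d[3]))
    center[, , t, v] <- center2d
  pool <- which(omega == 1 & center == 0)
  if (length(pool) == 0L)
    stop("no candidate samples outside the protected center: Lambda would be empty")
  n_draw <- max(1L, round(ratio * length(pool)))
  lam0 <- array(FALSE, d)
  lam0[sample(pool, n_draw, replace = FALSE)] <- TRUE
  # sibling closure over the encoding axis: any (ky, kz, t) hit by Lambda
  # claims all its sampled encodings
  hit <- apply(lam0, c(1, 2, 3), any)
  lambda <- array(0, d)
  for (v in seq_len(d[4])) lambda[, , , v] <- hit
  lambda <- lambda * omega
  theta <- omega - lambda
  if (sum(lambda) == 0L) stop("empty Lambda partition")
  list(theta = theta, lambda = lambda, ratio = ratio,
       center_radius = center_radius,
       lambda_fraction = sum(lambda) / sum(omega))
}

#' Split measured k-space along a partition
#'
#' @param y complex k-space `(NY, NZ, NC, NT, NV)`.
#' @param partition result of [partition_mask()].
#' @return list with `y_theta` and `y_lambda`; their sum reconstitutes `y`.
#' @export
apply_partition <- function(y, partition) {
  nc <- dim(y)[3]
  mt <- .expand_mask(partition$theta, nc)
  ml <- .expand_mask(partition$lambda, nc)
  list(y_theta = y * mt, y_lambda = y * ml)
}

#' Normalized L1-L2 k-space loss
#'
#' `||y - yhat||_2 / ||y||_2 + ||y - yhat||_1 / ||y||_1` over complex
#' entries (the L1 norm sums moduli).  Scale-invariant under global complex
#' scaling of both arguments; equals 0 iff the prediction matches on Lambda
#' and 2 for an all-zero prediction.
#'
#' @param y_lambda measured k-space restricted to the loss set.
#' @param y_pred_lambda predicted k-space restricted to the same set.
#' @return nonnegative scalar.
#' @export
ssdu_loss <- function(y_lambda, y_pred_lambda) {
  n2 <- sqrt(sum(Mod(y_lambda)^2))
  n1 <- sum(Mod(y_lambda))
  if (n2 == 0) stop("zero-norm reference in ssdu_loss")
  r <- y_lambda - y_pred_lambda
  sqrt(sum(Mod(r)^2)) / n2 + sum(Mod(r)) / n1
}

# gradient of ssdu_loss wrt the prediction, real-pair convention
.ssdu_loss_grad <- function(y_lambda, y_pred_lambda) {
  n2 <- sqrt(sum(Mod(y_lambda)^2))
  n1 <- sum(Mod(y_lambda))
  r <- y_lambda - y_pred_lambda
  rn <- sqrt(sum(Mod(r)^2))
  g <- array(0i, dim(r))
  if (rn > 0) g <- g - r / (rn * n2)
  m <- Mod(r)
  phase <- ifelse(m > 0, r / pmax(m, .Machine$double.xmin), 0i)
  g - phase / n1
}

# loss and parameter gradients for one training example
.ssdu_step <- function(y_theta, theta, y_lambda, lambda, smaps, params,
                       recompute = FALSE) {
  x <- unrolled_forward(y_theta, smaps, theta, params,
                        keep_tape = if (recompute) "checkpoint" else "all")
  tape <- attr(x, "tape")
  attr(x, "tape") <- NULL
  yhat <- forward_op(x, smaps, lambda)
  loss <- ssdu_loss(y_lambda, yhat)
  g_yhat <- .ssdu_loss_grad(y_lambda, yhat)
  nc <- dim(y_lambda)[3]
  g_yhat <- g_yhat * .expand_mask(lambda, nc)
  g_x <- adjoint_op(g_yhat, smaps)
  grads <- .network_backward(tape, g_x, params, y_theta, smaps, theta)
  list(loss = loss, grads = grads, x = x)
}

#' Training configuration
#'
#' @param learning_rate initial Adam learning rate (default 5e-4).
#' @param epochs passes over the training slices; with `batch_size = 1` each
#'   slice contributes one gradient step per epoch, with a fresh random
#'   partition every step.
#' @param batch_size gradient updates use this many slices' averaged
#'   gradients (default 1, as in standard SSDU practice).
#' @param ratio,center_radius partition settings, see [partition_mask()].
#' @param checkpoint_recompute recompute per-unit activations during the
#'   backward pass instead of storing them (same results, less memory).
#' @param seed integer seed for partition draws and slice order.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 15L, batch_size = 1L,
                         ratio = 0.2, center_radius = 3,
                         checkpoint_recompute = FALSE, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), ratio = ratio,
                 center_radius = center_radius,
                 checkpoint_recompute = checkpoint_recompute,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Self-supervised training loop
#'
#' Adam with a cosine-annealed learning rate (annealed to 0 over the run).
#' Each step draws a fresh Theta/Lambda partition of one slice's sampling
#' mask, reconstructs from Theta, and minimizes the normalized L1-L2 loss of
#' the predicted k-space against the held-out Lambda samples.  Fully seeded:
#' identical seeds give identical loss traces in single-threaded use.
#'
#' @param containers list of `flow_container` slices (see
#'   [simulate_phantom()] / [read_container()]).
#' @param net_config an [unroll_config()].
#' @param tcfg a [train_config()].
#' @param params optional initial `flow_params` (default: seeded
#'   initialization from `tcfg$seed`).
#' @param verbose print per-epoch mean loss.
#' @return list with `params` (trained), `loss_trace` (per step),
#'   `lambda_fractions` (effective Lambda share per step) and `lr_trace`.
#' @export
train_ssdu <- function(containers, net_config, tcfg, params = NULL,
                       verbose = FALSE) {
  if (length(containers) == 0L) stop("empty training dataset")
  if (is.null(params)) params <- init_network_params(net_config, seed = tcfg$seed)
  n_slices <- length(containers)
  n_steps <- tcfg$epochs * ceiling(n_slices / tcfg$batch_size)
  vec <- .flatten_params(params)
  m <- numeric(length(vec)); v <- numeric(length(vec))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(n_steps)
  lam_trace <- numeric(n_steps)
  lr_trace <- numeric(n_steps)
  set.seed(tcfg$seed)
  step <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    order_ep <- sample(n_slices)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / tcfg$batch_size))
    for (bt in batches) {
      step <- step + 1L
      lr <- tcfg$learning_rate * 0.5 * (1 + cos(pi * (step - 1) / n_steps))
      gsum <- NULL
      lsum <- 0
      lfrac <- 0
      for (idx in bt) {
        ct <- containers[[idx]]
        p <- partition_mask(ct$mask, ratio = tcfg$ratio,
                            center_radius = tcfg$center_radius)
        ys <- apply_partition(ct$kspace, p)
        st <- .ssdu_step(ys$y_theta, p$theta, ys$y_lambda, p$lambda,
                         ct$smaps, params,
                         recompute = tcfg$checkpoint_recompute)
        if (!is.finite(st$loss))
          stop(sprintf("loss became non-finite at step %d (slice %d)", step, idx))
        g <- .flatten_params(st$grads)
        gsum <- if (is.null(gsum)) g else gsum + g
        lsum <- lsum + st$loss
        lfrac <- lfrac + p$lambda_fraction
      }
      g <- gsum / length(bt)
      loss_trace[step] <- lsum / length(bt)
      lam_trace[step] <- lfrac / length(bt)
      lr_trace[step] <- lr
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      vec <- vec - lr * mhat / (sqrt(vhat) + eps)
      params <- .unflatten_params(vec, params)
    }
    if (verbose)
      message(sprintf("epoch %d/%d  mean loss %.4f", ep, tcfg$epochs,
                      mean(loss_trace[(step - length(batches) + 1):step])))
  }
  list(params = params, loss_trace = loss_trace,
       lambda_fractions = lam_trace, lr_trace = lr_trace)
}

#' Reconstruct from the full sampled k-space
#'
#' At inference no partitioning is needed: the full sampling mask drives the
#' data-consistency blocks and the network input is the zero-filled
#' reconstruction of all acquired samples.
#'
#' @param y complex k-space `(NY, NZ, NC, NT, NV)`.
#' @param smaps normalized coil maps.
#' @param mask binary sampling mask `(NY, NZ, NT, NV)`.
#' @param params trained `flow_params`.
#' @return reconstructed complex image series `(NY, NZ, NT, NV)`.
#' @export
reconstruct <- function(y, smaps, mask, params) {
  unrolled_forward(y, smaps, mask, params, keep_tape = "none")
}

#' Save / load a network checkpoint
#'
#' Single-file archive holding the parameter arrays, the network
#' configuration and free-form metadata (e.g. the undersampling factor the
#' network was trained for), with a format version for forward
#' compatibility.
#'
#' @param params a `flow_params` object.
#' @param path file path.
#' @param metadata named list stored alongside the parameters.
#' @return `load_checkpoint` returns the `flow_params` with attribute
#'   `metadata`.
#' @export
save_checkpoint <- function(params, path, metadata = list()) {
  obj <- list(format = "flowrecon-checkpoint", version = 1L,
              config = unclass(attr(params, "config")),
              params = unclass(params), metadata = metadata)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "flowrecon-checkpoint"))
    stop("not a flowrecon checkpoint")
  p <- structure(obj$params, class = "flow_params")
  attr(p, "config") <- structure(obj$config, class = "unroll_config")
  attr(p, "metadata") <- obj$metadata
  p
}
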