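# End-to-end orchestration: simulate -> filter -> train -> reconstruct ->
# evaluate, with a manifest that makes every artifact regenerable from the
# run configuration and seed alone.

.dilate1 <- function(m) {
  ny <- nrow(m); nz <- ncol(m)
  p <- matrix(FALSE, ny + 2, nz + 2)
  p[2:(ny + 1), 2:(nz + 1)] <- m != 0
  p[2:(ny + 1), 2:(nz + 1)] | p[1:ny, 2:(nz + 1)] | p[3:(ny + 2), 2:(nz + 1)] |
    p[2:(ny + 1), 1:nz] | p[2:(ny + 1), 3:(nz + 2)]
}

#' Stationary-tissue mask of a phantom container
#'
#' Body voxels (nonzero truth magnitude) excluding the vessel dilated by two
#' voxels; used for background-phase fitting and SNR patches.
#'
#' @param container a `flow_container`.
#' @return logical `(NY, NZ)`.
#' @export
stationary_mask <- function(container) {
  body <- abs(container$truth_image[, , 1, 1]) > 0
  ves <- .dilate1(.dilate1(container$vessel_roi))
  body & !ves
}

#' Evaluate a reconstruction against the container's ground truth
#'
#' Decodes velocities from the reconstructed four-point series, applies the
#' third-order background-phase correction on the stationary tissue, and
#' computes the magnitude nRMSE, vectorial velocity nRMSE and mean
#' directional error inside the vessel ROI, plus the stationary-patch SNR of
#' the magnitude image.
#'
#' @param x complex reconstructed image series `(NY, NZ, NT, 4)`.
#' @param container the `flow_container` holding the ground truth.
#' @param correct_background apply [correct_background_phase()] first.
#' @return one-row data frame with `nrmse_m`, `nrmse_v`, `mdirerr`,
#'   `snr_db`.
#' @export
evaluate_reconstruction <- function(x, container, correct_background = TRUE) {
  v <- decode_velocity(x, container$venc_cm_s)
  stat <- stationary_mask(container)
  if (correct_background) v <- correct_background_phase(v, stat)
  vt <- container$truth_velocity
  roi <- container$vessel_roi
  mag <- abs(x[, , , 1])
  mag_t <- abs(container$truth_image[, , , 1])
  data.frame(
    nrmse_m = nrmse_m(mag, mag_t),
    nrmse_v = nrmse_v(v, vt, roi),
    mdirerr = as.numeric(mdirerr(v, vt, roi)),
    snr_db = snr_patch(apply(mag, c(1, 2), mean), stat))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param phantom a [phantom_spec()].
#' @param mask a [mask_spec()].
#' @param network an [unroll_config()].
#' @param training a [train_config()].
#' @param n_slices number of phantom slices to simulate.
#' @param heldout index of the slice reserved for evaluation.
#' @param seed global seed; per-slice and training seeds derive from it.
#' @param out_dir output directory.
#' @return validated `run_config` list.
#' @export
run_config <- function(phantom, mask, network, training, n_slices = 8L,
                       heldout = 1L, seed = 1L, out_dir) {
  cfg <- list(phantom = phantom, mask = mask, network = network,
              training = training, n_slices = as.integer(n_slices),
              heldout = as.integer(heldout), seed = as.integer(seed),
              out_dir = out_dir)
  required <- c("phantom", "mask", "network", "training", "n_slices",
                "heldout", "seed", "out_dir")
  for (key in required)
    if (is.null(cfg[[key]]))
      stop(sprintf("run_config: missing mandatory key '%s'", key))
  stopifnot(inherits(phantom, "phantom_spec"), inherits(mask, "mask_spec"),
            inherits(network, "unroll_config"), inherits(training, "train_config"))
  if (cfg$heldout < 1 || cfg$heldout > cfg$n_slices)
    stop("heldout slice index out of range")
  structure(cfg, class = "run_config")
}

#' Run the full simulate / train / reconstruct / evaluate pipeline
#'
#' Executes all stages into `config$out_dir`: simulated slice containers, a
#' trained checkpoint, the reconstruction of the held-out slice with its
#' zero-filled baseline, a metrics CSV, the per-step loss CSV, NIfTI exports
#' and a JSON manifest with file hashes and per-stage timings.  Identical
#' configurations and seeds reproduce identical metrics.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "containers"), showWarnings = FALSE)
  timings <- list()
  note <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    if (verbose) message(sprintf("[%s] done in %.1fs", stage, timings[[stage]]))
    r
  }

  containers <- note("simulate", {
    lapply(seq_len(config$n_slices), function(i) {
      sp <- config$phantom; sp$seed <- config$seed + i
      ms <- config$mask; ms$seed <- config$seed + 100L + i
      ct <- simulate_phantom(sp, ms)
      write_container(ct, file.path(out, "containers",
                                    sprintf("slice_%02d.rds", i)))
      ct
    })
  })

  kept <- note("filter", vessel_content_filter(containers))
  train_idx <- setdiff(kept, config$heldout)
  if (length(train_idx) == 0L) stop("no training slices left after filtering")

  fit <- note("train", {
    tcfg <- config$training
    tcfg$seed <- config$seed
    train_ssdu(containers[train_idx], config$network, tcfg)
  })
  ckpt <- file.path(out, "checkpoint.rds")
  save_checkpoint(fit$params, ckpt,
                  metadata = list(R = containers[[1]]$R, seed = config$seed))
  utils::write.csv(data.frame(step = seq_along(fit$loss_trace),
                              loss = fit$loss_trace,
                              lr = fit$lr_trace,
                              lambda_fraction = fit$lambda_fractions),
                   file.path(out, "loss.csv"), row.names = FALSE)

  recons <- note("reconstruct", {
    ct <- containers[[config$heldout]]
    x_net <- reconstruct(ct$kspace, ct$smaps, ct$mask, fit$params)
    x_zf <- adjoint_op(ct$kspace, ct$smaps)
    saveRDS(list(trained = x_net, zero_filled = x_zf),
            file.path(out, "reconstruction.rds"), version = 3)
    list(net = x_net, zf = x_zf, container = ct)
  })

  metrics <- note("evaluate", {
    ct <- recons$container
    m1 <- cbind(method = "trained", evaluate_reconstruction(recons$net, ct))
    m2 <- cbind(method = "zero_filled", evaluate_reconstruction(recons$zf, ct))
    m <- rbind(m1, m2)
    utils::write.csv(m, file.path(out, "metrics.csv"), row.names = FALSE)
    v <- correct_background_phase(decode_velocity(recons$net, ct$venc_cm_s),
                                  stationary_mask(ct))
    pv <- peak_velocity_curve(v, ct$vessel_roi, component = 1L)
    utils::write.csv(pv, file.path(out, "peak_velocity.csv"), row.names = FALSE)
    export_nifti(recons$net, v, file.path(out, "nifti"),
                 voxel_mm = ct$voxel_mm)
    m
  })

  cfg_serial <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(cfg_serial, file.path(out, "config.yaml"))
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("flowrecon")),
    seed = config$seed,
    timings = timings,
    kept_slices = kept,
    heldout = config$heldout,
    hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Render a human-readable run summary
#'
#' Writes `report.md` plus PNG figures into the run directory: the metric
#' table, the training-loss curve, the peak-velocity curves, and the learned
#' per-unit data-consistency noise levels `sigmoid(nu_n)` and averaging
#' weights `sigmoid(mu_n)`.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return invisibly, the report path.
#' @export
report <- function(run_dir) {
  mf <- file.path(run_dir, "metrics.csv")
  if (!file.exists(mf)) stop("no metrics found: not a completed run directory")
  metrics <- utils::read.csv(mf)
  loss <- utils::read.csv(file.path(run_dir, "loss.csv"))
  pv <- utils::read.csv(file.path(run_dir, "peak_velocity.csv"))
  params <- load_checkpoint(file.path(run_dir, "checkpoint.rds"))
  nu <- sigmoid(params$nu_raw); mu <- sigmoid(params$mu_raw)

  grDevices::png(file.path(run_dir, "loss.png"), 600, 400)
  graphics::plot(loss$step, loss$loss, type = "l", xlab = "step",
       ylab = "normalized L1-L2 loss", main = "Self-supervised training loss")
  grDevices::dev.off()

  grDevices::png(file.path(run_dir, "peak_velocity.png"), 600, 400)
  graphics::matplot(pv$frame, pv[, c("v1", "v2", "v3")], type = "b", pch = 1:3,
          xlab = "cardiac frame", ylab = "velocity (cm/s)",
          main = "Peak-voxel velocity curves")
  graphics::legend("topright", legend = c("through-plane", "in-plane 1", "in-plane 2"),
         pch = 1:3, col = 1:3)
  grDevices::dev.off()

  grDevices::png(file.path(run_dir, "nu_mu.png"), 600, 400)
  graphics::plot(seq_along(nu), nu, type = "b", col = "blue", ylim = c(0, 1),
       xlab = "unrolling unit n", ylab = "value",
       main = "Learned per-unit weights")
  graphics::lines(seq_along(mu), mu, type = "b", col = "red")
  graphics::legend("topright", legend = c("sigmoid(nu_n) [DC]", "sigmoid(mu_n) [WA]"),
         col = c("blue", "red"), lty = 1)
  grDevices::dev.off()

  lines_md <- c(
    "# Reconstruction run report", "",
    "## Metrics (held-out slice)", "",
    paste(utils::capture.output(print(metrics, row.names = FALSE)),
          collapse = "\n"),
    "",
    sprintf("Final training loss: %.4f (initial %.4f, %d steps)",
            utils::tail(loss$loss, 1), loss$loss[1], nrow(loss)),
    "",
    "![loss](loss.png)", "",
    "![peak velocity](peak_velocity.png)", "",
    "![learned unit weights](nu_mu.png)", "")
  writeLines(lines_md, file.path(run_dir, "report.md"))
  invisible(file.path(run_dir, "report.md"))
}
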