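# flowrecon

Self-supervised, physics-driven reconstruction of highly undersampled
multi-velocity-encoded dynamic (4D flow) MRI, in R.

4D flow MRI quantifies time-resolved three-component blood velocity fields,
but clinically feasible scan times require undersampling k-space by factors
of R = 8–24, far beyond what classical parallel imaging can invert on its
own. `flowrecon` implements an unrolled optimization network for this
inverse problem and trains it **on the undersampled measurements
themselves** — no fully sampled reference is ever needed.

## The method

The multicoil forward model per velocity encoding and cardiac frame is
`y_i = D F S_i x`, with coil sensitivities `S_i`, centered unitary 2D FFT
`F` and binary sampling mask `D`. Variable splitting with quadratic
penalties turns regularized least squares into `N` unrolled units, each
consisting of

* a **denoising block**: a complex-valued bidirectional convolutional
  recurrent network (4 layers, recurrence over cardiac frames and over the
  unrolling iterations, modReLU activations `(|z|+b) z/|z|`, velocity
  encodings as feature channels, residual connection),
* a **data-consistency block**: the closed-form k-space update
  `nu_n y + (1 - nu_n) F S x` at sampled locations,
* a **weighted-averaging block**: `mu_n x_dc + (1 - mu_n) z_n`,

with per-unit learnable scalars `nu_n, mu_n` kept in (0, 1) by a sigmoid
and all convolution weights shared across units (64,099 parameters at the
default `N = 10`, `f = 25`, `k = 3`, `NV = 4`).

Training uses self-supervision via data undersampling (SSDU): every step
splits the sampled set Ω into a network-input set Θ (always containing the
central k-space disc of radius 3) and a loss set Λ (closed under
velocity-encoding siblings), reconstructs from Θ alone and minimizes the
normalized L1–L2 loss of the re-encoded prediction against the held-out
samples. Gradients through the whole unrolled network (complex
convolutions, recurrences, modReLU, FFT-based DC blocks) are computed by a
hand-written reverse-mode engine validated against finite differences.

A synthetic four-point phase-contrast phantom (pulsatile Poiseuille vessel,
eddy-current-like encoded-channel phase, smooth coil maps, seeded masks and
noise) provides ground truth for every test, and the post-processing module
decodes velocities, removes third-order polynomial background phase, and
computes the standard error metrics (magnitude nRMSE, vectorial velocity
nRMSE, mean directional error, patch SNR) plus peak-velocity curves.

## Worked example

```r
library(flowrecon)

# eight phantom slices: 24 x 24, 4 frames, 3 coils, 4 encodings, R = 8
slices <- lapply(1:8, function(i) {
  sp <- phantom_spec(grid = c(24, 24), n_frames = 4, n_coils = 3,
                     venc = 150, peak_velocity = 120, vessel_radius = 4,
                     peak_frame = 2, noise_sigma = 0.02)
  sp$seed <- 100 + i
  simulate_phantom(sp, mask_spec(kind = "uniform_random", R = 8,
                                 seed = 200 + i))
})

net  <- unroll_config(n_units = 4, n_filters = 8, n_bcrnn_layers = 4)
fit  <- train_ssdu(slices[2:8], net,
                   train_config(learning_rate = 2e-3, epochs = 50, seed = 1))

ct    <- slices[[1]]                                   # held-out slice
x_net <- reconstruct(ct$kspace, ct$smaps, ct$mask, fit$params)
rbind(trained     = evaluate_reconstruction(x_net, ct),
      zero_filled = evaluate_reconstruction(adjoint_op(ct$kspace, ct$smaps), ct))
```

which prints (seeds as above):

```
              nrmse_m   nrmse_v     mdirerr   snr_db
trained     0.4839582 0.1698282 0.004818512 19.00677
zero_filled 0.2472725 0.3047930 0.002046907 14.01874
```

The trained network roughly halves the vectorial velocity error of the
zero-filled baseline on the held-out slice and raises the stationary-patch
SNR by 5 dB. Two columns deserve a caveat: the magnitude nRMSE of the
short-run network is higher than zero-filled (the denoiser is optimized
through the velocity-encoding phase structure, not the magnitude), and the
mean directional error stays near the baseline's, which is already ~1e-3
on this phantom because zero-filled aliasing mostly rescales the velocity
vector rather than rotating it.
`count_parameters(unroll_config())` reproduces the 64,099-parameter count
of the full-size architecture.

A thin CLI covering simulate / train / reconstruct / evaluate /
count-params / pipeline / report lives at `inst/cli/flowrecon`.

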