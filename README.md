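# lfdenoise

Self-supervised denoising for 4D spatial-angular (light-field) fluorescence
microscopy data, with a synthetic light-field simulator, a simplified
iterative-tomography reconstructor, and the image-quality and calcium-trace
metrics needed to evaluate it. No clean ground truth and no temporal
redundancy are required: the denoiser trains on a single noisy acquisition.

## Who this is for

Microscopists and computational imaging researchers working with scanning
light-field microscopy (sLFM, 13 × 13 angular views) or two-photon
synthetic-aperture microscopy (2pSAM, 13 scan angles) under photon-limited
conditions, and anyone studying self-supervised denoising that exploits
spatial-angular rather than temporal redundancy.

## The method

A light field `L(u, v, y, x)` contains each scene point once per angular
view, displaced by a depth-dependent disparity. In an epipolar-plane image
(EPI) — a slice mixing one spatial axis with the serialized angular axis —
3D points become lines whose slope encodes depth. Noise is independent
across EPI rows while signal is not, so splitting an EPI stack by row parity
yields two noisy observations of the same signal: a Noise2Noise training
pair that needs no clean reference.

Training minimizes, per patch,

```
loss = loss_xs + loss_yt + loss_fusion
loss(X, Y)   = 0.5‖X − Y‖₁ + 0.5‖X − Y‖₂²          (pixel means)
loss_fusion  = 0.4[0.5 loss(Y₁, Y_f) + 0.5 loss(Y₂, Y_f)]
             + 0.6[0.5 loss(Y_m1, Y_f) + 0.5 loss(Y_m2, Y_f)]
```

where the x-s and y-t sub-networks (3D U-net encoders, 16/32/64 channels →
128-feature temporal + spatial transformers → decoders, global residual)
produce `Y₁, Y₂` (gradients severed in the fusion term), and `Y_m1, Y_m2`
are half-resolution targets drawn per iteration from eight orthogonal
2-of-4 pixel masks, identical across views. An attention-based fusion
module (eight residual window-transformer blocks in one route, five
convolution-block-attention modules in the other, sharing a double
convolution that reduces `2A → A` channels) merges the two EPI routes into
the denoised spatial-angular output. The standard configuration totals
17.98 M trainable parameters. Optimization is Adam (β₁ = 0.9, β₂ = 0.999),
lr 1e-4 decaying ×0.3 every 5 epochs, 20–25 epochs over ~1000 EPI patches.

Reconstruction to a 3D volume uses iterative tomography: from a uniform
volume, each angular view in turn is forward-projected, compared with the
measurement, and the error back-projected as a multiplicative correction
(geometric shift projector; 10 sweeps by default).

See `vignettes/lf-denoising.Rmd` for the full model description, design
decisions and limitations.

## Worked example

Desk-scale end-to-end run (81 angular views, reduced-width network; about
ten minutes on one CPU):

```r
library(lfdenoise)

side <- 9                                   # 9 x 9 = 81 angular views
proj <- lf_projector(c(side, side), n_planes = 16, kappa = 0.3)
train_field <- simulate_lightfield("mixed", c(16, 64, 64), n_objects = 12,
  seed = 7, proj = proj, np = noise_params(100, gauss_var = 5, seed = 11))
heldout <- simulate_lightfield("mixed", c(16, 64, 64), n_objects = 12,
  seed = 8, proj = proj, np = noise_params(100, gauss_var = 5, seed = 12))

models <- build_lf_models(lf_network_config("tiny", angle_count = side^2), seed = 1)
tset <- build_training_set(list(train_field$noisy), n_patches = 1000,
                           patch_size = 32, seed = 2)
fit <- train_lf_denoiser(models, tset, optim_spec(lr0 = 1e-3, seed = 3),
                         epochs = 1, max_steps = 400)

den <- denoise_lightfield(models, heldout$noisy, patch_size = 32,
                          overlap = 8, quantize = FALSE)
clean <- heldout$clean_scaled$data
cat("SNR gain:", snr(clean, den$data) - snr(clean, heldout$noisy$data), "dB\n")
cat("RMSE noisy:", rmse(clean, heldout$noisy$data),
    "denoised:", rmse(clean, den$data), "\n")
```

Output from this exact script:

```
SNR gain: 4.597837 dB
RMSE noisy: 2.398293 denoised: 1.412571
```

The held-out field was never seen in training, and training never saw clean
data: the 4.6 dB SNR improvement and 41% RMSE reduction come purely from
spatial-angular self-supervision. (`snr()` is `10·log10(Σx²/Σ(x−y)²)`;
intensities are in camera digital numbers on the 100-photon scale.)

The same pipeline is scriptable from a shell:

```sh
inst/cli/lfdenoise simulate --out run/ --seed 1
inst/cli/lfdenoise train --data run/ --out run/ --epochs 2
inst/cli/lfdenoise denoise --input run/sim_noisy.tif \
    --checkpoint run/checkpoint.rds --output run/denoised.tif
inst/cli/lfdenoise evaluate --reference run/sim_clean.tif \
    --estimate run/denoised.tif --layout 9x9
inst/cli/lfdenoise model-info --preset standard --angles 81
```

`model-info` for the standard preset prints:

```
preset: standard
angular views: 81
sub-network parameters: 1920833 (x2)
fusion parameters: 14140451
total trainable parameters: 17982117 (17.98 M)
```

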