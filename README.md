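# anetsr

Super-resolution restoration of confocal images of filament-like
structures (microtubules and kin), for microscopists who have ordinary
confocal frames — 512 × 512 px, 16-bit, ~0.25 µm pixel pitch — and want
sub-PSF sketches of the filament network without special hardware or a
public training corpus.

## What it does

The package implements a hybrid classical/learned pipeline built on the
degradation model **L = H ∗ f + N** (observed image = high-resolution
scene convolved with the PSF, plus noise):

1. **Preprocessing** — hard threshold denoising, then two passes of 3D
   Gaussian interpolation with the confocal kernel
   `g = g₀ exp(−((x−x_c)² + (y−y_c)²)/2r⊥² − (z−z_c)²/2r∥²)`,
   `r⊥ = 0.61 λe/NA`, `r∥ = 4 n λe/(2 NA²)`, lifting 512 px / 1 µm-z
   stacks to 2048 px / 250 nm-z (display pitch 63 nm).
2. **DWDC label generation** — discrete-wavelet shrinkage (sym4,
   BayesShrink) + Lucy–Richardson deconvolution + binarization produce
   high-resolution binary labels from the originals.
3. **A-net** — a U-net variant with every valid convolution replaced by
   a same convolution (skip maps concatenate uncropped; output size =
   input size), trained with minibatch 1 under Adam on a pixel-wise
   softmax `P_i(x) = exp(a_i(x)) / Σ_j exp(a_j(x))` and the
   boundary-weighted cross-entropy
   `E = −Σ_x ω(x) log P_{g(x)}(x)`,
   `ω = w_class + w₀ exp(−d²/2σ_w²)` with d the distance to the nearest
   label boundary.
4. **Postprocessing & metrology** — tile-wise prediction and exact
   reassembly, binarization of the foreground probability, mask ×
   test-image multiplication, and resolution measurement as the FWHM of
   interpolated line profiles (plus SSIM/PSNR for completeness, and 3D
   restacking of result slices).

Because no imaging data are redistributable in this regime, the package
includes a first-class **synthetic filament phantom generator**: random
smooth curves rendered at 62.5 nm supersampling, blurred with the
Gaussian PSF (σ = r⊥ ≈ 279 nm, FWHM ≈ 657 nm), binned to the 250 nm
confocal pitch, and corrupted with Poisson shot noise, Gaussian read
noise and 16-bit quantization. Every stage of the pipeline is trained,
tested and benchmarked against these phantoms, whose ground truth is
known exactly.

## Worked example

```r
library(anetsr)

# the scaled study: 40 train / 10 test phantoms at 64 px, depth-2
# A-net with 16 base channels, 30 epochs (a few minutes on one CPU)
ex <- run_phantom_experiment(n_train = 40, n_test = 10,
                             net = anet_config(input_side = 64, depth = 2,
                                               base_channels = 16),
                             epochs = 30, lr = 1e-2, seed = 1)
round(c(iou = ex$mean_iou,
        fwhm_in = ex$mean_fwhm_degraded,
        fwhm_out = ex$mean_fwhm_result,
        gain = ex$fwhm_ratio), 3)
#>      iou  fwhm_in fwhm_out     gain
#>    0.534  726.521  347.014    2.094
```

Reading the numbers: the binarized network prediction overlaps the true
filament mask with IoU 0.53 on held-out phantoms; perpendicular cuts
across true centerlines measure a mean FWHM of ~727 nm on the degraded
inputs (the ~657 nm PSF plus 250 nm pixelation) versus ~347 nm on the
masked results — a 2.1× resolution gain, measured identically on input
and output. Individual stages are available as plain functions
(`threshold_denoise()`, `gaussian_interpolate_3d()`, `make_label()`,
`anet_train()`, `predict_full()`, `apply_mask()`, `fwhm()`, …), and
`inst/cli/anet-sr.R` wraps them as a command-line tool
(`simulate`, `convert`, `tile`, `preprocess`, `label`, `train`,
`predict`, `evaluate`).

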