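# cohsr — super-resolution for coherent holographic imaging

`cohsr` is an R toolkit for resolution enhancement of coherent (holographic)
imaging systems. It covers two configurations of in-line holographic
microscopy and the learning method that super-resolves their reconstructed
complex images:

* **Pixel-size-limited, lensfree on-chip** ("System A"): unit magnification
  puts the resolution at the sensor pitch (2.24 µm for one Bayer channel).
  Classical pixel super-resolution (PSR) synthesizes a finer grid from
  sub-pixel-shifted acquisitions; a trained network replaces the 36-image
  raster with a single shot.
* **Diffraction-limited, lens-based** ("System B"): a low-NA objective
  (4×/0.13) limits resolution to λ/NA ≈ 4.09 µm; the network output
  approaches the 10×/0.30 reference (1.773 µm).

The package implements the full classical chain that produces training
pairs, and the learning core itself:

* **Wave optics** — angular-spectrum free-space propagation (exact,
  non-paraxial, evanescent-suppressed) and the coherence calculators:
  temporal coherence length `√(2 ln 2/π)·λ²/(nΔλ)`, the coherence-limited
  effective aperture `n√(1−(z₂/(z₂+ΔL_c))²)`, and the resolution `λ/NA`.
* **Reconstruction** — Tamura-of-gradient (edge-sparsity) autofocusing with
  golden-section refinement, SVD fixed-pattern background subtraction, and
  iterative multi-height phase recovery (8 heights; phase kept, amplitude
  averaged toward `√I` at each height).
* **Pixel super-resolution** — sub-pixel shift-table estimation by upsampled
  phase correlation and shift-and-add synthesis with count-normalized
  gridding.
* **Registration** — bicubic upsampling, correlation-based rigid
  registration (rotation sweep + sub-pixel translation, 50 px border crop),
  tile stitching by masked normalized cross-correlation, and
  correlation-matrix field-of-view matching.
* **GAN** — U-Net generator and convolutional discriminator written
  in-package (im2col+GEMM convolutions with hand-derived backward passes,
  Adam), trained with the composite loss
  `L₁ + γ·TV + α·(1−D(G(x)))² [+ β·(1−SSIM)]`
  (α = 0.00275, γ = 0.015, β = 0.01 for the phase-channel system) at a 4:1
  generator:discriminator update ratio; tiled feathered inference.
* **Metrics** — SSIM (windowed and global) and radially averaged
  spatial-frequency spectra.
* **Synthetic data** — seeded generators for tissue-like complex objects,
  multi-height hologram stacks with fixed-pattern background and noise,
  sub-pixel raster acquisitions, and registered LR/HR patch sets.

## Worked example

Simulate an 8-height acquisition of a tissue-like object, refocus it, and
recover the complex field:

```r
library(cohsr)

spec <- synth_spec("tissue_blobs", size = 128, pixel_pitch = 1.12,
                   amplitude_range = c(0.7, 1), phase_range = c(0, 0),
                   seed = 5)
obj   <- make_object(spec)
stack <- simulate_stack(obj, heights = seq(300, 475, by = 25))

opt <- optical_params(0.55, 0.002, z2 = 300, pixel_pitch = 1.12)
af  <- autofocus(stack$intensities[[1]], 250, 350, 5, opt)
af$best_z
#> [1] 300.4102

rec <- multiheight_phase_recovery(stack, n_iter = 50)
mean(abs(Mod(rec$values) - Mod(obj$values))) / mean(Mod(obj$values))
#> [1] 0.002758131
```

The autofocused height lands within a fraction of a micrometre of the true
300 µm, and after 50 sweeps the recovered amplitude differs from the ground
truth by ~0.3% — the twin image has been suppressed by the height
diversity. The coherence calculators reproduce the system's operating
point:

```r
lc <- coherence_length(0.550, 0.002)   # 100.4727 um
na <- effective_na(300, lc)            # 0.6624403
resolution_limit(0.55, na)             # 0.8302635 um
```

Classical PSR from a 6×6 sub-pixel raster:

```r
hrspec <- synth_spec("tissue_blobs", size = 384, pixel_pitch = 0.3733, seed = 11)
sim <- simulate_subpixel_set(make_object(hrspec), raster = c(6, 6),
                             factor = 6, height = 300)
sr  <- shift_and_add(sim$lr, sim$table, 6, pitch = 2.24)
attr(sr, "pixel_pitch")
#> [1] 0.3733333
```

Training and evaluating a (small) network end to end:

```r
run_train(list(out_dir = "run1", mode = "pixel_sr", seed = 1,
               n_pairs = 200, patch = 64, steps = 2000,
               network = list(base_channels = 4, depth = 2)))
run_eval(list(model = "run1/model.rds", out_dir = "run1/eval", seed = 2))
```

A thin command-line front-end over the same functions ships in
`inst/cli/cohsr.R` (subcommands `synth`, `reconstruct`, `train`, `eval`).

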