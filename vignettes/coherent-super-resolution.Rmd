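---
title: "Methods: coherent-imaging super-resolution with cohsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherent-imaging super-resolution with cohsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohsr)
```

`cohsr` implements the computational chain of two in-line holographic
microscope configurations — a lensfree on-chip system whose resolution is
limited by the sensor pixel pitch, and a lens-based system limited by the
numerical aperture of its objective — together with a generative adversarial
network (GAN) that learns to super-resolve the reconstructed complex images.
This vignette explains the models, the tunable parameters, the numerical
conventions, and what the synthetic data do and do not demonstrate.

## Wave-optics core

Fields are scalar, monochromatic, sampled on square grids; all lengths are in
micrometres. Free-space propagation uses the exact angular-spectrum transfer
function

$$H(f_x, f_y) = \exp\!\Big(i \tfrac{2\pi n}{\lambda} \Delta z
\sqrt{1 - (\lambda f_x / n)^2 - (\lambda f_y / n)^2}\Big),$$

with evanescent components ($f_x^2 + f_y^2 > (n/\lambda)^2$) set to zero.
The sign convention is fixed so that backward propagation is the conjugate
transfer function; `propagate(propagate(f, z), -z)` returns `f` exactly for
band-limited fields. Frequencies live on the standard discrete grid
$[-1/(2\Delta x), 1/(2\Delta x))$.

**Padding.** `propagate()` zero-pads to twice the linear size by default
(`pad = 2`), which suppresses periodic wrap-around for isolated, apertured
fields. The reconstruction functions (`autofocus()`,
`multiheight_phase_recovery()`) default to `pad = 1` (periodic): a
multi-height stack is processed by dozens of consecutive propagations, and
with zero-padding each round trip irreversibly leaks energy out of the crop
window — with periodic boundaries the sweep is exactly unitary and
self-consistent with the periodic synthetic generator. For real apertured
acquisitions both accept `pad = 2`.

For a source of centre wavelength $\lambda$ and bandwidth $\Delta\lambda$ the
temporal coherence length is
$\Delta L_c = \sqrt{2\ln 2/\pi}\,\lambda^2/(n\,\Delta\lambda)$; it bounds the
largest fringe angle with appreciable modulation, giving the effective
aperture $\mathrm{NA} = n\sqrt{1 - (z_2/(z_2+\Delta L_c))^2}$ and the
coherence-limited resolution $\lambda/\mathrm{NA}$:

```{r calculators}
lc <- coherence_length(0.550, 0.002)   # 550 nm, 2 nm bandwidth
na <- effective_na(300, lc)            # sample-to-sensor 300 um
c(coherence_um = lc, effective_na = na,
  resolution_um = resolution_limit(0.55, na))
```

## Hologram reconstruction

**Autofocusing.** The sample-to-sensor distance is found by assigning zero
phase to the measured hologram amplitude, back-propagating over a coarse
grid of candidate heights, scoring the refocused amplitude with the Tamura
coefficient of the gradient ($\sqrt{\sigma_g/\mu_g}$ of the
central-difference gradient magnitude), and refining the best coarse height
by golden-section search down to 0.5 um. The edge-sparsity score peaks at
focus for absorption-dominant samples (stained smears and sections). For
objects with substantial phase contrast the defocus fringes themselves score
high on edge sparsity and bias the peak — the reason the metric is used on
stained tissue; the synthetic autofocus checks therefore use
amplitude-contrast objects. Residual bias from the twin image is of order
1 um at $z_2 \approx 300$ um, well inside the tolerance of the downstream
phase recovery.

**SVD background subtraction.** Dust and parasitic interference on the
optical surfaces of the lens-based system produce a diffraction pattern
independent of the sample position. Vectorizing the stack into a
pixels-by-heights matrix, this fixed pattern is the dominant rank-1
component shared across heights; removing the first singular triplet and
re-offsetting each image to its original mean isolates the sample signal.
Rank 1 is the right choice because the pattern is literally
sample-independent; higher ranks would begin to eat the sample term.

**Multi-height phase recovery.** Starting from $\sqrt{I_1}$ with zero phase,
each sweep propagates the field up through the (autofocused) heights and
back; at every height the phase is kept and the amplitude is replaced by the
average of the current amplitude and $\sqrt{I_k}$. The averaging weight of
1/2 is fixed; the update is applied on both passes by default
(`average_backward = FALSE` restricts it to the forward pass). The default
budget is 50 sweeps with early stop once the data fidelity (mean absolute
amplitude mismatch over heights) improves by less than `tol = 1e-6`; on
noise-free synthetic 8-height stacks the fidelity is non-increasing and the
recovered amplitude error is a few tenths of a percent. The twin image and
self-interference terms are suppressed because they are inconsistent across
heights. The recovered field is finally back-propagated to the sample plane
($z = 0$; heights are positive sensor-side distances).

## Pixel super-resolution

A raster of sub-pixel sensor displacements gives low-resolution images whose
sampling phases interleave. Shifts are estimated against the first image by
phase correlation with a local matrix-DFT refinement (100x upsampling around
the integer peak; ~0.02 px RMS on clean data). `shift_and_add()` places each
LR pixel at its displaced location on a `factor`-times denser grid, averages
by hit count, and interpolates unobserved sites by iterative neighbour
means. The grid convention puts output pixel `x` at the top-left corner of
the contributing LR footprint.

Shift-and-add does **not** deconvolve the sensor's pixel aperture: what the
raster scan measures, and what a full raster reconstructs exactly, is the
aperture-filtered intensity on the dense grid. Round-trip checks therefore
compare against the box-filtered high-resolution hologram; against that
target a full 6x6 raster is exact to floating point and the error decreases
strictly as the raster grows 1x1 &rarr; 2x2 &rarr; 3x3 &rarr; 6x6.

## Registration

Training pairs require pixel-wise alignment of the bicubically upsampled LR
image with its HR counterpart. `register_pair()` sweeps rotation
(+/-5 deg in 0.25 deg steps, parabolic refinement), estimates the residual
translation by phase correlation, applies the rigid transform to the HR
image, and crops 50 px from every side; pairs whose aligned correlation
falls below 0.5 are flagged invalid and excluded. The transform is
restricted to rotation + translation (the acquisitions share one
magnification); it is computed on the phase channel and applied to all
channels. For the lens-based system, `stitch_tiles()` builds the HR mosaic
first — neighbour offsets by masked (overlap-normalized) cross-correlation,
which stays reliable at ~15% overlaps where whitened phase correlation does
not — and `match_fov()` locates each LR tile in the mosaic by a
coarse-then-refined normalized-correlation scan.

## The GAN

The generator is an adapted U-Net: a convolution to `base_channels` (32 in
the reference configuration) with leaky-ReLU (slope 0.1), three down blocks
(two 3x3 convolutions, channels doubled at the second, plus a
parameter-free additive skip that duplicates the block input across
channels — the blocks are described as residual), average pooling of stride
2 between blocks, a 3x3 bottleneck convolution preserving the feature
count, and a mirrored up path (bilinear x2 upsampling, concatenation with
the skip, two convolutions), closed by a linear output convolution. The
discriminator stacks five blocks that double channels while halving both
lateral dimensions, pools each channel globally to a 1024-vector, and
applies two fully connected layers and a sigmoid.

The losses are
$$\ell_D = D(G(x))^2 + (1 - D(z))^2, \qquad
\ell_G = L_1\{z, G(x)\} + \gamma\,TV\{G(x)\}
       + \alpha\,(1 - D(G(x)))^2 \;[+\; \beta\,(1 - \mathrm{SSIM})],$$
with $\alpha = 0.00275$, $\gamma = 0.015$, and $\beta = 0.01$ for the
phase-channel (lens-based) system.

Two deliberate deviations from the literal formulas, both switchable:

* The total-variation term is defined as a per-channel *sum* of absolute
  forward differences. With $\gamma = 0.015$ a summed TV on a 128 px patch
  would exceed the $L_1$ term by orders of magnitude, contradicting the
  stated loss composition (data term ~60%, TV ~0.25%); training therefore
  uses the per-pixel-normalized form (`tv_reduction = "mean"`), while
  `tv_loss(..., "sum")` retains the literal definition.
* A positive SSIM summand would *penalize* similarity; the SSIM term enters
  as $\beta(1 - \mathrm{SSIM})$ by default (`ssim_literal_sign = TRUE`
  restores the literal sign).

Training uses Adam (generator lr $10^{-4}$, discriminator lr $10^{-5}$),
batch 10 (25 for validation), four generator updates per discriminator
update, and augmentation by random left-right flips (probability 0.5) and
uniformly drawn multiples of 90 deg, applied identically to input and
label. Inputs and labels are normalized per channel with the training-label
statistics, which are stored in the model and reapplied at inference.
Convolution weights are initialized from a truncated normal (+/-2 SD); the
scale defaults to the He fan-in value $\sqrt{2/\mathrm{fan\_in}}$ — with a
fixed small scale the stated learning rate cannot bring the weights to
identity-mapping magnitude within a scaled-down step budget. Biases start at
zero. The checkpoint with the lowest validation generator loss is kept
(validation every 250 generator updates). At equilibrium the discriminator
cannot separate generated from label patches and its mean output on
generated images approaches 0.5.

`gan_infer()` runs tiled inference with linear feathering; each tile's outer
margin (`trim`, default half the overlap) is discarded before blending
because the zero-padded convolutions distort predictions near tile borders.

## Synthetic data: what it emulates, and what it does not

`make_object()` produces seeded complex transmission fields:
`tissue_blobs` scatters absorbing, phase-shifting Gaussian bumps (shared
centres, independent weights) on a clear background — the sparse-edge
structure of a smear or thin section; `resolution_target` and
`phase_gratings` give line pairs and sinusoidal phase gratings of known
spacing. `feature_scale` (default 10 um, a cell-scale correlation length)
sets blob radii. `simulate_stack()` propagates to each height and adds a
shared smooth fixed-pattern background and additive Gaussian intensity noise
(a shot-noise proxy; a Poisson mode is available).
`simulate_subpixel_set()` emulates the mechanical raster with periodic
sub-pixel sampling and box binning.

`make_training_set()` degrades the *reconstructed field* directly —
factor-binning of the real and imaginary channels (pixel-size-limited
emulation) or a hard circular aperture at $\mathrm{NA}/\lambda$ in the field
spectrum (diffraction-limited emulation) — rather than re-running the full
hologram/phase-recovery chain per pair, which keeps generating hundreds of
pairs tractable; the full chain is exercised end-to-end by the
reconstruction tests and `run_reconstruct()`. Registration is run on each
synthetic pair (it finds the identity and performs the border crop); the
label is only resampled when the estimated transform exceeds the
estimator's own refinement noise (0.05 deg / 0.05 px), since warping an
already-aligned pair would merely inject interpolation error.

**Scaled-down training task.** The packaged study conditions for the
adversarial training checks use 200 pairs of 64 px patches with 3x binning,
taking the 0.3733 um super-resolved grid to the 1.12 um pitch of the 2x2
raster — one of the reported training configurations — with
`feature_scale = 2` um so the objects carry sub-cellular texture in the
frequency band the network must restore (with only cell-scale content the
band above the LR cutoff holds no signal and a spectral comparison measures
noise). Networks are width-reduced to `base_channels = 4` and depth 2
(discriminator: 5 blocks, base 4) so that 2000 generator updates run in
minutes on one CPU. At these conditions the validation $L_1$ drops more
than 3x from initialization, the mean discriminator output on generated
validation patches settles near 0.5, and the radially averaged output
spectrum is closer to the ground truth than the bicubic input's above the
LR Nyquist frequency.

Passing these checks demonstrates that the chain is implemented
consistently — propagation is unitary, phase retrieval converges, the PSR
grid bookkeeping is right, the losses match their definitions, adversarial
training is stable at the stated ratio — not that the network attains the
tissue-scale quality reported for the real systems: the synthetic objects
lack stain spectra, speckle from out-of-plane scatterers, sensor nonlinearity
and mechanical drift, and the scaled-down networks have ~1% of the reference
parameter count.

## Numerical conventions and degenerate inputs

* Coordinates are (row, col), 0-based internally for grids; pixel centres at
  integer coordinates. Bicubic resampling uses the Catmull-Rom kernel
  (a = -0.5) with edge clamping and top-left source mapping
  (`src = out / factor`), so aligned decimation inverts upsampling exactly.
* A constant image has zero Tamura-of-gradient by convention; constant
  inputs make registration pairs invalid rather than erroring.
* SSIM stabilizers default to $(0.01 L)^2$ and $(0.03 L)^2$ with $L$ the
  joint data range; reporting uses an 11 px Gaussian window (sigma 1.5),
  shrinking automatically for smaller images, with the global form retained
  for loss-term parity.
* All randomness flows from explicit seeds; the synthetic generators save
  and restore the caller's RNG state.

## Known limitations

* No partial-coherence or polarization modelling; the coherence calculators
  summarize bandwidth effects but propagation is monochromatic.
* Autofocusing assumes absorption-dominant samples (see above).
* Shift-and-add performs no aperture deconvolution and no iterative
  refinement of the shift table.
* Registration is rigid (rotation + translation); non-rigid deformation and
  illumination drift are out of scope.
* The training loop is single-threaded CPU R/C++; it is intended for the
  scaled-down regime, not for reproducing the reference networks at full
  width and 10^5 iterations.
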