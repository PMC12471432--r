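# dmsim

Spatial-domain super-resolution reconstruction for phase-shifted structured
illumination microscopy (SIM), with an integrated low-light enhancement stage
and a full simulation/evaluation harness.

## The problem

Linear SIM doubles (up to) the lateral resolution of a fluorescence
microscope by illuminating the specimen with sinusoidal fringes: sample
frequencies just above the OTF cutoff $k_c$ beat against the fringe frequency
$\mathbf k_0$ and appear inside the passband as moiré patterns. The standard
way to unmix them works in frequency space and needs careful band separation,
apodization and parameter estimation. This package implements a *spatial
domain* alternative for the fixed $\pi/2$ phase-step protocol: with nine raw
frames (3 fringe orientations × phases $\varphi_0, \varphi_0+\pi/2,
\varphi_0+\pi$), pairwise frame differences

$$d_{12} = D_1 - D_2,\qquad d_{23} = D_2 - D_3$$

cancel both the unmodulated widefield term and any out-of-focus background
$B_\mathrm{out}$ exactly (optical sectioning for free), and the complex
analytic signal $Z = d_{12} - i\,d_{23} = \sqrt2\,mI_0\,
e^{i(2\pi\mathbf k_0\cdot\mathbf r + \varphi_0 - \pi/4)}\,
[S \otimes (H e^{-i2\pi\mathbf k_0\cdot\mathbf r})]$ demodulates the moiré
content without any Fourier-domain surgery. Two demodulations are provided:
the phase-invariant modulus $|Z|$ (default) and carrier re-modulation
(`demod = "carrier"`), whose transfer function $[h(k\!-\!k_0)+h(k\!+\!k_0)]/2$
extends the passband to $k_c + k_0$ and therefore carries the lateral
resolution gain (see the methods vignette for why the modulus is exactly
FWHM-neutral on point sources).

Because reconstructed low-signal images are often dim and unevenly exposed,
a Retinex-style low-light enhancement stage (multi-scale block exposure
classification at the 0.65 threshold → attention map → dynamically truncated
illumination estimate → attention-weighted TV refinement → $R = I/L^{0.8}$)
is included, plus metrics (Gaussian-fit FWHM, SSIM, PSNR, RMSE, CII), an
independent frequency-domain Wiener reconstructor for cross-checking, TIFF
I/O, a reproducible pipeline, and a CLI (`inst/cli/dmsim.R`).

## Worked example

Simulate 200 nm beads at 30 nm/px with fringes at $0.66\,k_c$ and an
out-of-focus background, reconstruct, and measure the resolution:

```r
library(dmsim)

phantom <- make_phantom("beads", 192, 30,
                        list(n = 6L, margin_px = 24L, min_sep_px = 26), seed = 9)
psf   <- make_psf("gaussian", 470, 0.6, 30, 61)      # FWHM = 0.51*470/0.6 = 399.5 nm
cfg   <- illum_config(k0_cycles_per_px = 0.66 * psf$cutoff_cycles_per_px)
stack <- acquire_stack(phantom, psf, cfg, b_out = 0.4)
stack
#> <acquisition_stack> 192x192 px  3 orientations x 3 phases  noise=none

sr <- reconstruct(stack, demod = "carrier", normalize = TRUE)
sr
#> <sr_image> 192x192 px  pixel=30 nm  algorithm=dm-sim  range=[0, 1]

centers <- phantom$meta$centers
bead_resolution(stack$widefield, centers, 30, window_px = 12)
#> <resolution_report> 6 bead(s)  mean FWHM = 417.2 +- 1.4 nm
bead_resolution(sr$data, centers, 30, window_px = 12)
#> <resolution_report> 6 bead(s)  mean FWHM = 255.1 +- 0.8 nm
```

The measured gain is 417.2 / 255.1 = **1.635**, against a theoretical
`theoretical_gain(0.66)` = **1.66** — and the 0.4 background added above
changed nothing, because the phase-pair differences cancel it exactly.

Enhance a half-dark/half-saturated image and quantify the result:

```r
fx  <- lowlight_fixture(64, seed = 1)
out <- enhance(fx$image)
out
#> <llie_result> 64x64 px  100 refinement iterations  final loss 159.8

mean(out$data[fx$dark])   / mean(fx$image[fx$dark])    # dark half boosted
#> [1] 5.26
mean(out$data[fx$bright]) / mean(fx$image[fx$bright])  # saturated half spared
#> [1] 1.022

quality(out$data, fx$image)
#> <quality_report> SSIM=0.5778  PSNR=10.23 dB  RMSE=78.545 (0-255)  CII=1.911
```

The end-to-end pipeline (simulate → reconstruct → enhance → evaluate) with
full provenance:

```r
manifest <- run_pipeline(pipeline_config(output_dir = "run1", seed = 1))
# writes stack.tif (+ stack.yaml), sr.tif, sr_llie.tif, report.json, provenance.json
```

## Documentation

* `vignettes/dmsim-methods.Rmd` — the full model, the modulus-vs-carrier
  demodulation analysis, enhancement internals, and stated limitations.
* `inst/cli/dmsim.R` — CLI with `simulate`, `reconstruct`, `enhance`,
  `evaluate`, `resolution`, `demo` and `pipeline` subcommands.
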