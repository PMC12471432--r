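# Independent oracles and small fixtures used across the suite.

# Brute-force spatial-domain circular convolution: explicit sum over kernel
# taps with integer circular shifts.  Independent of the FFT route.
direct_convolve <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  cy <- (kr + 1L) %/% 2L; cx <- (kc + 1L) %/% 2L
  out <- matrix(0, n, m)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      dy <- a - cy; dx <- b - cx
      ri <- ((seq_len(n) - 1L - dy) %% n) + 1L
      ci <- ((seq_len(m) - 1L - dx) %% m) + 1L
      out <- out + w * img[ri, ci]
    }
  }
  out
}

# Frequency-domain evaluation of the demodulated envelope:
# sqrt(2) m I0 |IFFT[ s(k) * h(k - k0) ]| with the discrete system OTF
# shifted by the (grid-commensurate) fringe frequency.  k0 is given as
# integer cycle counts (cx, cy) over the field.
freq_oracle_modulus <- function(S, psf, m, i0, k0_cycles) {
  n <- nrow(S)
  otf <- stats::fft(dmsim_embed(psf$kernel, n))
  # h(k + k0): circular shift of the OTF grid by the integer cycle counts
  ri <- ((seq_len(n) - 1L + k0_cycles[2]) %% n) + 1L
  ci <- ((seq_len(n) - 1L + k0_cycles[1]) %% n) + 1L
  otf_shift <- otf[ri, ci]
  sqrt(2) * m * i0 *
    Mod(stats::fft(stats::fft(S) * otf_shift, inverse = TRUE)) / n^2
}

# Access the package-internal kernel embedding without relying on :::
dmsim_embed <- function(kernel, n) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  cy <- (kr + 1L) %/% 2L; cx <- (kc + 1L) %/% 2L
  out <- matrix(0, n, n)
  ri <- ((seq_len(kr) - cy) %% n) + 1L
  ci <- ((seq_len(kc) - cx) %% n) + 1L
  out[ri, ci] <- kernel
  out
}

# Compact PSF suited to 32 x 32 oracle fields (sigma ~2.1 px, >99.9% energy).
small_psf <- function() make_psf("gaussian", 470, 0.8, 60, 15)

# The package-default simulation scene (matches pipeline_config defaults),
# used by the cross-method agreement tests.
standard_bead_stack <- function(seed = 7L) {
  ph <- make_phantom("beads", 256, 30, list(n = 20L, diameter_nm = 200), seed = seed)
  psf <- make_psf("gaussian", 470, 0.6, 30, 61)
  cfg <- illum_config(k0_cycles_per_px = 0.66 * psf$cutoff_cycles_per_px)
  list(stack = acquire_stack(ph, psf, cfg), phantom = ph, psf = psf, cfg = cfg)
}

# Standard bead acquisition used by resolution and cross-method tests.
bead_stack <- function(size = 192L, n_beads = 6L, seed = 7L, b_out = 0,
                       boundary = "reflect", phi0 = 0) {
  ph <- make_phantom("beads", size, 30,
                     list(n = n_beads, margin_px = 24L, min_sep_px = 26),
                     seed = seed)
  psf <- make_psf("gaussian", 470, 0.6, 30, 61)
  cfg <- illum_config(k0_cycles_per_px = 0.66 * psf$cutoff_cycles_per_px,
                      phi0_rad = phi0)
  list(stack = acquire_stack(ph, psf, cfg, b_out = b_out, boundary = boundary),
       phantom = ph, psf = psf, cfg = cfg)
}
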