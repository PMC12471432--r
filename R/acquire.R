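#' Simulate a nine-frame structured-illumination acquisition
#'
#' Applies the SIM forward model `D = (I * S) (x) H + Bout` for every
#' orientation/phase combination (3 orientations x 3 phases with a pi/2 step
#' by default), plus a uniform-illumination wide-field reference
#' `(I0 * S) (x) H + Bout`.  Convolution is FFT-based; by default the field
#' is reflect-padded by the kernel half-width and cropped back, which avoids
#' wrap-around artifacts; `boundary = "periodic"` selects plain circular
#' convolution (exact for grid-periodic fringes, used by the analytic test
#' oracles).  Noise, when enabled, is applied last: Poisson on the
#' photon-scaled signal, then additive Gaussian read noise.
#'
#' @param phantom a [make_phantom()] object.
#' @param psf a [make_psf()] kernel with the same `pixel_size_nm`.
#' @param cfg an [illum_config()]; `k0` must not exceed the PSF cutoff.
#' @param b_out out-of-focus background: nonnegative scalar or a matrix the
#'   size of the phantom (a smooth map).
#' @param noise list: `model` one of `"none"`, `"gaussian"`,
#'   `"poisson_gaussian"`; for gaussian, `sd`; for poisson_gaussian,
#'   `photons_per_unit` (default 100) and `read_sd` (default 0).
#' @param seed RNG seed for the noise draw, or `NULL`.
#' @param boundary convolution boundary handling, `"reflect"` (default) or
#'   `"periodic"`.
#' @return an object of class `acquisition_stack`: list with `frames` (array
#'   `[row, col, orientation, phase]`), `widefield`, `b_out`, `noise`,
#'   `illumination` (the config), `pixel_size_nm`, `psf` and `boundary`.
#' @examples
#' ph <- make_phantom("beads", 64, 30, list(n = 2), seed = 1)
#' psf <- make_psf("gaussian", 470, 0.6, 30, 31)
#' cfg <- illum_config(k0_cycles_per_px = 0.66 * psf$cutoff_cycles_per_px)
#' st <- acquire_stack(ph, psf, cfg)
#' dim(st$frames)
#' @export
acquire_stack <- function(phantom, psf, cfg, b_out = 0,
                          noise = list(model = "none"), seed = NULL,
                          boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  if (!inherits(phantom, "phantom")) stopf("phantom must be a 'phantom'")
  if (!inherits(psf, "psf_kernel")) stopf("psf must be a 'psf_kernel'")
  if (!inherits(cfg, "illum_config")) stopf("cfg must be an 'illum_config'")
  if (!isTRUE(all.equal(phantom$pixel_size_nm, psf$pixel_size_nm)))
    stopf("phantom and psf pixel_size_nm differ (%g vs %g)",
          phantom$pixel_size_nm, psf$pixel_size_nm)
  if (cfg$k0_cycles_per_px > psf$cutoff_cycles_per_px + 1e-12)
    stopf("fringe frequency k0 = %.4g exceeds the PSF cutoff kc = %.4g; fringes cannot pass the system",
          cfg$k0_cycles_per_px, psf$cutoff_cycles_per_px)
  n <- nrow(phantom$density)
  if (is.matrix(b_out)) {
    if (!all(dim(b_out) == n)) stopf("b_out map must match the phantom grid")
    if (any(b_out < 0)) stopf("b_out must be nonnegative")
  } else {
    if (length(b_out) != 1L || b_out < 0) stopf("b_out must be a nonnegative scalar or matrix")
  }

  n_theta <- length(cfg$thetas_deg)
  n_phase <- length(cfg$phases_rad)
  frames <- array(0, dim = c(n, n, n_theta, n_phase))
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_phase)) {
      illum <- make_illumination(cfg$thetas_deg[i], cfg$phases_rad[j], cfg, n)
      frames[, , i, j] <- fft_convolve(illum * phantom$density, psf$kernel, boundary) + b_out
    }
  }
  widefield <- fft_convolve(cfg$i0 * phantom$density, psf$kernel, boundary) + b_out

  model <- noise$model %||% "none"
  if (!model %in% c("none", "gaussian", "poisson_gaussian"))
    stopf("unknown noise model '%s'", model)
  if (model != "none") {
    set_seed_if(seed)
    apply_noise <- function(img) {
      if (model == "gaussian") {
        img + stats::rnorm(length(img), sd = noise$sd %||% 0.01)
      } else {
        ppu <- noise$photons_per_unit %||% 100
        out <- stats::rpois(length(img), lambda = pmax(img, 0) * ppu) / ppu
        out + stats::rnorm(length(img), sd = noise$read_sd %||% 0)
      }
    }
    for (i in seq_len(n_theta)) for (j in seq_len(n_phase))
      frames[, , i, j] <- matrix(apply_noise(frames[, , i, j]), n, n)
    widefield <- matrix(apply_noise(widefield), n, n)
  }

  structure(
    list(frames = frames, widefield = widefield, b_out = b_out,
         noise = c(noise, list(seed = seed)), illumination = cfg,
         pixel_size_nm = phantom$pixel_size_nm, psf = psf, boundary = boundary),
    class = "acquisition_stack"
  )
}

#' @export
print.acquisition_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<acquisition_stack> %dx%d px  %d orientations x %d phases  noise=%s\n",
              d[1], d[2], d[3], d[4], x$noise$model %||% "none"))
  invisible(x)
}
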