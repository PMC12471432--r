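#' Sinusoidal illumination configuration
#'
#' Groups the fringe parameters of the structured-illumination forward model:
#' mean intensity `I0`, modulation depth `m`, fringe frequency `k0` (cycles
#' per pixel), fringe orientations, and the reference phase `phi0`.  The
#' phase step is fixed at pi/2: each orientation is acquired at phases
#' `phi0`, `phi0 + pi/2` and `phi0 + pi`.
#'
#' @param i0 mean illumination intensity (positive).
#' @param m modulation depth in \[0, 1\].
#' @param k0_cycles_per_px fringe spatial frequency in cycles per pixel.
#' @param thetas_deg fringe orientations in degrees (default 0, 60, 120).
#' @param phi0_rad reference fringe phase in radians.
#' @return an object of class `illum_config`.
#' @export
illum_config <- function(i0 = 1, m = 1, k0_cycles_per_px,
                         thetas_deg = c(0, 60, 120), phi0_rad = 0) {
  if (i0 <= 0) stopf("i0 must be positive")
  if (m < 0 || m > 1) stopf("modulation depth m must be in [0, 1] (negative intensities otherwise)")
  if (k0_cycles_per_px <= 0) stopf("k0_cycles_per_px must be positive")
  structure(
    list(i0 = i0, m = m, k0_cycles_per_px = k0_cycles_per_px,
         thetas_deg = thetas_deg, phi0_rad = phi0_rad, dphi_rad = pi / 2,
         phases_rad = phi0_rad + c(0, pi / 2, pi)),
    class = "illum_config"
  )
}

#' Evaluate the sinusoidal illumination pattern
#'
#' `I(r) = I0 * (1 + m cos(2 pi k0 (cos theta, sin theta) . r + phi))` with
#' `r` in 0-based pixel units, origin at the top-left pixel.
#'
#' @param theta_deg fringe orientation in degrees.
#' @param phase_rad absolute fringe phase in radians.
#' @param cfg an [illum_config()].
#' @param size_px grid side length (must match the phantom grid).
#' @return a `size_px` x `size_px` matrix of intensities.
#' @export
make_illumination <- function(theta_deg, phase_rad, cfg, size_px) {
  if (!inherits(cfg, "illum_config")) stopf("cfg must be an illum_config")
  g <- pixel_grid(size_px)
  th <- theta_deg * pi / 180
  arg <- 2 * pi * cfg$k0_cycles_per_px * (cos(th) * g$x + sin(th) * g$y) + phase_rad
  cfg$i0 * (1 + cfg$m * cos(arg))
}

#' @export
print.illum_config <- function(x, ...) {
  cat(sprintf("<illum_config> I0=%g  m=%g  k0=%.4g cyc/px  thetas=%s deg  phi0=%.3g rad  dphi=pi/2\n",
              x$i0, x$m, x$k0_cycles_per_px, paste(x$thetas_deg, collapse = "/"), x$phi0_rad))
  invisible(x)
}
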