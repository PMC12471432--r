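#' FWHM of a single-peak intensity profile by Gaussian fitting
#'
#' Least-squares fit of `A exp(-(x - mu)^2 / (2 sigma^2)) + c` with
#' moment-based initialization; the full width at half maximum is
#' `2 sqrt(2 ln 2) sigma` in pixels, scaled by the pixel size.
#'
#' @param profile numeric vector (>= 7 samples) with one dominant peak.
#' @param pixel_size_nm pixel size in nanometres.
#' @return FWHM in nm, with attributes `r_squared`, `mu_px` (0-based peak
#'   position) and `sigma_px`.
#' @export
fwhm_from_profile <- function(profile, pixel_size_nm) {
  profile <- as.numeric(profile)
  if (length(profile) < 7L) stopf("profile needs at least 7 samples")
  if (anyNA(profile)) stopf("profile must be finite")
  rng <- max(profile) - min(profile)
  if (rng <= 0 || rng < 1e-12 * max(abs(profile), 1))
    stopf("profile has no peak to fit")
  x <- seq_along(profile) - 1
  base <- min(profile)
  wt <- pmax(profile - base, 0)
  mu0 <- sum(x * wt) / sum(wt)
  s0 <- sqrt(max(sum((x - mu0)^2 * wt) / sum(wt), 0.25))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + c0,
      data = data.frame(x = x, y = profile),
      start = list(A = rng, mu = mu0, s = s0, c0 = base),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stopf("Gaussian fit did not converge: %s", conditionMessage(e))
  )
  p <- stats::coef(fit)
  resid <- profile - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((profile - mean(profile))^2)
  if (r2 < 0.5) stopf("Gaussian fit rejected (R^2 = %.2f < 0.5)", r2)
  fwhm <- 2 * sqrt(2 * log(2)) * abs(p[["s"]]) * pixel_size_nm
  structure(fwhm, r_squared = r2, mu_px = p[["mu"]], sigma_px = abs(p[["s"]]))
}

#' Per-bead FWHM resolution report
#'
#' For each bead, the peak is located as the local maximum near the given
#' center, horizontal and vertical line profiles through the peak are each
#' fitted with a Gaussian, and the two FWHM values are averaged.  Beads whose
#' analysis windows overlap are skipped with a warning; aggregate statistics
#' use only beads with fit `R^2 >= 0.9`.
#'
#' @param image 2-D image.
#' @param bead_centers n x 2 matrix of 0-based `(x, y)` pixel coordinates.
#' @param pixel_size_nm pixel size.
#' @param window_px half-width of the profile window (default 10).
#' @return an object of class `resolution_report`: list with
#'   `per_bead_fwhm_nm`, `fit_r2`, `mean_fwhm_nm`, `std_fwhm_nm`, `n_beads`.
#' @export
bead_resolution <- function(image, bead_centers, pixel_size_nm, window_px = 10L) {
  assert_matrix(image)
  empty <- structure(
    list(per_bead_fwhm_nm = numeric(0), fit_r2 = numeric(0),
         mean_fwhm_nm = NA_real_, std_fwhm_nm = NA_real_, n_beads = 0L),
    class = "resolution_report"
  )
  if (is.null(bead_centers) || length(bead_centers) == 0L || max(image) <= 0) return(empty)
  centers <- matrix(as.numeric(bead_centers), ncol = 2)
  w <- as.integer(window_px)
  n <- nrow(image)
  inside <- centers[, 1] >= w & centers[, 1] <= ncol(image) - 1 - w &
    centers[, 2] >= w & centers[, 2] <= n - 1 - w
  if (!all(inside)) stopf("bead centers must lie at least window_px from the image border")

  # drop beads whose windows overlap
  keep <- rep(TRUE, nrow(centers))
  if (nrow(centers) > 1L) {
    dmat <- as.matrix(stats::dist(centers))
    diag(dmat) <- Inf
    clash <- apply(dmat, 1, min) < 2 * w
    if (any(clash)) {
      warning(sprintf("skipping %d bead(s) with overlapping analysis windows", sum(clash)))
      keep <- !clash
    }
  }

  fwhm <- r2 <- numeric(0)
  for (b in which(keep)) {
    cx <- round(centers[b, 1]) + 1L
    cy <- round(centers[b, 2]) + 1L
    win <- image[(cy - w):(cy + w), (cx - w):(cx + w)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    py <- cy - w - 1L + pk[1]
    px <- cx - w - 1L + pk[2]
    res <- tryCatch({
      fh <- fwhm_from_profile(image[py, (px - w):(px + w)], pixel_size_nm)
      fv <- fwhm_from_profile(image[(py - w):(py + w), px], pixel_size_nm)
      c(mean(c(fh, fv)), min(attr(fh, "r_squared"), attr(fv, "r_squared")))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      fwhm <- c(fwhm, res[1]); r2 <- c(r2, res[2])
    }
  }
  good <- r2 >= 0.9
  structure(
    list(per_bead_fwhm_nm = fwhm, fit_r2 = r2,
         mean_fwhm_nm = if (any(good)) mean(fwhm[good]) else NA_real_,
         std_fwhm_nm = if (sum(good) > 1L) stats::sd(fwhm[good]) else NA_real_,
         n_beads = length(fwhm)),
    class = "resolution_report"
  )
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> %d bead(s)  mean FWHM = %.1f +- %.1f nm\n",
              x$n_beads, x$mean_fwhm_nm, x$std_fwhm_nm %||% NA))
  invisible(x)
}

#' Full-reference image quality metrics
#'
#' SSIM (11 x 11 Gaussian window, sigma 1.5, standard stabilizers on unit
#' dynamic range), PSNR (`10 log10(1 / MSE)` on \[0, 1\], capped at 100 dB for
#' identical images), RMSE reported on the 0--255 scale, and the contrast
#' improvement index CII: the ratio of mean local RMS contrast (3 x 3
#' windows) of the processed image to the reference.
#'
#' @param enhanced,reference equally shaped 2-D images; values outside
#'   \[0, 1\] are min-max rescaled.
#' @param cii_window odd window size of the local RMS contrast (default 3).
#' @return an object of class `quality_report`: list with `ssim`, `psnr_db`,
#'   `rmse`, `cii`.
#' @export
quality <- function(enhanced, reference, cii_window = 3L) {
  assert_matrix(enhanced); assert_matrix(reference)
  if (!all(dim(enhanced) == dim(reference))) stopf("shape mismatch")
  rescale <- function(x) {
    if (min(x) >= 0 && max(x) <= 1) return(x)
    r <- range(x); if (diff(r) == 0) return(x * 0)
    (x - r[1]) / diff(r)
  }
  e <- rescale(enhanced); r <- rescale(reference)
  mse <- mean((e - r)^2)
  psnr <- if (mse == 0) 100 else min(10 * log10(1 / mse), 100)
  structure(
    list(ssim = ssim(e, r),
         psnr_db = psnr,
         rmse = sqrt(mse) * 255,
         cii = local_rms_contrast(e, cii_window) /
           max(local_rms_contrast(r, cii_window), .Machine$double.eps)),
    class = "quality_report"
  )
}

#' Structural similarity index (mean SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian weighting window (sigma 1.5) and
#' stabilizers `C1 = (0.01)^2`, `C2 = (0.03)^2` for unit dynamic range.
#' Symmetric in its arguments.
#'
#' @param x,y images in \[0, 1\], same shape.
#' @param window_size,sigma Gaussian window parameters.
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y, window_size = 11L, sigma = 1.5) {
  assert_matrix(x); assert_matrix(y)
  if (!all(dim(x) == dim(y))) stopf("shape mismatch")
  w <- gaussian_window(window_size, sigma)
  f <- function(img) fft_convolve_reflect(img, w)
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2
  syy <- f(y * y) - my^2
  sxy <- f(x * y) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

# Mean local RMS contrast: population sd within sliding odd-sized windows.
local_rms_contrast <- function(img, window = 3L) {
  window <- as.integer(window)
  stopifnot(window %% 2L == 1L)
  box <- matrix(1 / window^2, window, window)
  m <- fft_convolve_reflect(img, box)
  v <- pmax(fft_convolve_reflect(img * img, box) - m^2, 0)
  mean(sqrt(v))
}

#' Lateral resolution gain
#'
#' Ratio of a wide-field FWHM to a super-resolved FWHM: values above 1 mean
#' the reconstruction resolves finer detail.
#'
#' @param fwhm_widefield_nm,fwhm_sr_nm FWHM values in nm.
#' @return the gain (dimensionless).
#' @export
resolution_gain <- function(fwhm_widefield_nm, fwhm_sr_nm) {
  if (fwhm_sr_nm <= 0) stopf("FWHM must be positive")
  fwhm_widefield_nm / fwhm_sr_nm
}

#' Theoretical SIM resolution gain
#'
#' For linear SIM the maximum observable frequency grows from `kc` to
#' `kc + k0`, so the expected lateral gain is `1 + k0/kc`.
#'
#' @param k0_over_kc fringe frequency as a fraction of the OTF cutoff.
#' @return the theoretical gain.
#' @export
theoretical_gain <- function(k0_over_kc) {
  if (k0_over_kc < 0 || k0_over_kc > 1) stopf("k0/kc must be in [0, 1]")
  1 + k0_over_kc
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> SSIM=%.4f  PSNR=%.2f dB  RMSE=%.3f (0-255)  CII=%.3f\n",
              x$ssim, x$psnr_db, x$rmse, x$cii))
  invisible(x)
}
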