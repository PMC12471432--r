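# TIFF + sidecar-metadata input/output.
#
# The tiff package stores unit-range float pages, so every file is written
# with a recorded `scale` factor (max absolute value across pages) and
# rescaled on read.

#' Write an acquisition stack as a multi-page TIFF with a YAML sidecar
#'
#' Pages are orientation-major (orientation 1 phases 1..3, then orientation 2,
#' ...), followed by nothing else; the wide-field image, illumination
#' parameters, background, noise record and the intensity scale are stored in
#' the sidecar.
#'
#' @param stack an [acquire_stack()] result.
#' @param path output TIFF path.
#' @param meta_path sidecar YAML path (default: `path` with `.yaml`).
#' @return invisibly, the two paths.
#' @export
write_stack <- function(stack, path, meta_path = paste0(tools::file_path_sans_ext(path), ".yaml")) {
  if (!inherits(stack, "acquisition_stack")) stopf("stack must be an 'acquisition_stack'")
  d <- dim(stack$frames)
  pages <- list()
  for (i in seq_len(d[3])) for (j in seq_len(d[4]))
    pages[[length(pages) + 1L]] <- stack$frames[, , i, j]
  scale <- max(abs(unlist(lapply(pages, range))), max(abs(stack$widefield)), 1e-12)
  pages <- lapply(pages, function(p) pmin(pmax(p / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  cfg <- stack$illumination
  meta <- list(
    pixel_size_nm = stack$pixel_size_nm,
    i0 = cfg$i0, m = cfg$m, k0_cycles_per_px = cfg$k0_cycles_per_px,
    thetas_deg = as.numeric(cfg$thetas_deg), phi0_rad = cfg$phi0_rad,
    phases_rad = as.numeric(cfg$phases_rad),
    b_out = if (is.matrix(stack$b_out)) "map" else stack$b_out,
    noise = stack$noise[!vapply(stack$noise, is.null, logical(1))],
    boundary = stack$boundary,
    scale = scale,
    n_orientations = d[3], n_phases = d[4],
    widefield = as.numeric(stack$widefield / scale)
  )
  yaml::write_yaml(meta, meta_path, precision = 15L)
  invisible(c(tiff = path, meta = meta_path))
}

#' Read an acquisition stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param meta_path sidecar YAML path (default: `path` with `.yaml`).
#' @return an `acquisition_stack` (without the PSF object, which is not
#'   serialized; `$psf` is `NULL`).
#' @export
read_stack <- function(path, meta_path = paste0(tools::file_path_sans_ext(path), ".yaml")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(meta_path)
  n_theta <- meta$n_orientations; n_phase <- meta$n_phases
  if (length(pages) != n_theta * n_phase)
    stopf("expected %d pages, found %d", n_theta * n_phase, length(pages))
  n <- nrow(pages[[1]])
  frames <- array(0, dim = c(n, ncol(pages[[1]]), n_theta, n_phase))
  k <- 1L
  for (i in seq_len(n_theta)) for (j in seq_len(n_phase)) {
    frames[, , i, j] <- pages[[k]] * meta$scale
    k <- k + 1L
  }
  cfg <- illum_config(i0 = meta$i0, m = meta$m,
                      k0_cycles_per_px = meta$k0_cycles_per_px,
                      thetas_deg = meta$thetas_deg, phi0_rad = meta$phi0_rad)
  wf <- matrix(meta$widefield, n, ncol(pages[[1]])) * meta$scale
  structure(
    list(frames = frames, widefield = wf,
         b_out = if (identical(meta$b_out, "map")) NA else meta$b_out,
         noise = meta$noise, illumination = cfg,
         pixel_size_nm = meta$pixel_size_nm, psf = NULL,
         boundary = meta$boundary %||% "reflect"),
    class = "acquisition_stack"
  )
}

#' Write a single 2-D image as 32-bit float TIFF
#'
#' Values are divided by their maximum (recorded in the TIFF description via a
#' sidecar-free convention: images are written pre-normalized to \[0, 1\]).
#'
#' @param image numeric matrix with values in \[0, 1\] (rescaled by its max if
#'   above 1).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_image <- function(image, path) {
  assert_matrix(image)
  mx <- max(image, 1)
  tiff::writeTIFF(pmin(pmax(image / mx, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a single-page TIFF as a matrix
#' @param path TIFF path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
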