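#' Generate a ground-truth fluorophore phantom
#'
#' Builds a synthetic fluorophore density map on a square pixel grid, used as
#' the object `S(r)` of the SIM forward model.  Beads emulate sub-diffraction
#' fluorescent microspheres (e.g. 200 nm calibration beads) rendered as
#' anti-aliased discs; line pairs provide a two-ridge resolution target;
#' textures give a smooth nonnegative random field.
#'
#' @param kind one of `"beads"`, `"line_pair"`, `"texture"`, `"custom"`.
#' @param size_px even grid side length in pixels (>= 32).
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param params kind-specific parameters:
#'   * beads: `n` (count), `diameter_nm` (default 200), `amplitude`
#'     (default 1), `margin_px` (default 16), `min_sep_px` (default 12).
#'   * line_pair: `separation_px`, `amplitude` (default 1).
#'   * texture: `correlation_px` (default 8), `mean` (default 1).
#'   * custom: `density` (a `size_px` x `size_px` nonnegative matrix).
#' @param seed integer seed for reproducible random placement, or `NULL`.
#' @return an object of class `phantom`: list with `density` (matrix),
#'   `pixel_size_nm`, `kind` and `meta` (the realized parameters).
#' @examples
#' ph <- make_phantom("beads", 64, 30, list(n = 3), seed = 1)
#' sum(ph$density > 0) > 0
#' @export
make_phantom <- function(kind = c("beads", "line_pair", "texture", "custom"),
                         size_px, pixel_size_nm, params = list(), seed = NULL) {
  kind <- match.arg(kind)
  size_px <- as.integer(size_px)
  if (size_px < 32L || size_px %% 2L != 0L)
    stopf("size_px must be even and >= 32, got %d", size_px)
  if (pixel_size_nm <= 0) stopf("pixel_size_nm must be positive")
  set_seed_if(seed)

  meta <- list(seed = seed)
  density <- switch(kind,
    beads = {
      n <- params$n %||% 10L
      diameter_nm <- params$diameter_nm %||% 200
      amplitude <- params$amplitude %||% 1
      margin <- params$margin_px %||% 16L
      min_sep <- params$min_sep_px %||% 12
      radius_px <- diameter_nm / (2 * pixel_size_nm)
      if (2 * radius_px < 1)
        stopf(paste("bead diameter (%.0f nm) is below one pixel at pixel_size_nm = %.0f;",
                    "use a finer pixel_size_nm"), diameter_nm, pixel_size_nm)
      centers <- if (!is.null(params$centers)) {
        as.matrix(params$centers)
      } else if (n > 0L) {
        place_beads(n, size_px, margin, min_sep)
      } else {
        matrix(numeric(0), 0, 2)
      }
      if (nrow(centers) > 0 &&
          (any(centers < radius_px) || any(centers > size_px - 1 - radius_px)))
        stopf("bead discs must fit inside the grid")
      meta$centers <- centers
      meta$radius_px <- radius_px
      meta$amplitude <- amplitude
      render_discs(size_px, centers, radius_px, amplitude)
    },
    line_pair = {
      sep <- params$separation_px %||% 8L
      amplitude <- params$amplitude %||% 1
      c1 <- (size_px - sep) %/% 2L
      c2 <- c1 + as.integer(sep)
      if (c1 < 1L || c2 > size_px - 2L) stopf("line separation does not fit the grid")
      d <- matrix(0, size_px, size_px)
      d[, c1 + 1L] <- amplitude
      d[, c2 + 1L] <- amplitude
      meta$columns_0based <- c(c1, c2)
      d
    },
    texture = {
      corr <- params$correlation_px %||% 8
      mu <- params$mean %||% 1
      raw <- matrix(stats::rnorm(size_px^2), size_px, size_px)
      win <- 2L * as.integer(ceiling(2 * corr)) + 1L
      if (win > size_px) win <- size_px - ((size_px + 1L) %% 2L)  # largest odd fit
      g <- gaussian_window(win, corr)
      sm <- fft_convolve_periodic(raw, g)
      sm <- (sm - min(sm)) / max(max(sm) - min(sm), .Machine$double.eps)
      meta$correlation_px <- corr
      mu * 2 * sm
    },
    custom = {
      d <- params$density
      if (is.null(d)) stopf("kind 'custom' requires params$density")
      assert_matrix(d, "params$density")
      if (!all(dim(d) == size_px)) stopf("custom density must be %d x %d", size_px, size_px)
      if (any(d < 0)) stopf("density must be nonnegative")
      d
    }
  )

  structure(
    list(density = density, pixel_size_nm = pixel_size_nm, kind = kind, meta = meta),
    class = "phantom"
  )
}

# Rejection-sample bead centers (0-based pixel coordinates, x then y) with a
# minimum pairwise separation; falls back to the best effort after many tries.
place_beads <- function(n, size_px, margin, min_sep) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n && tries < 5000L) {
    cand <- stats::runif(2, margin, size_px - 1 - margin)
    ok <- nrow(centers) == 0 ||
      min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2, byrow = TRUE))^2))) >= min_sep
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
  }
  if (nrow(centers) < n)
    stopf("could not place %d beads with min_sep_px = %.1f; reduce n or min_sep_px", n, min_sep)
  dimnames(centers) <- list(NULL, c("x", "y"))
  centers
}

# Anti-aliased discs: each pixel's value is the supersampled (8x8) area
# fraction covered by the disc, times the amplitude.  Only a local window
# around each bead is rasterized.
render_discs <- function(size_px, centers, radius_px, amplitude) {
  d <- matrix(0, size_px, size_px)
  if (nrow(centers) == 0) return(d)
  ss <- 8L
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  for (b in seq_len(nrow(centers))) {
    cx <- centers[b, 1]; cy <- centers[b, 2]
    r0 <- ceiling(radius_px) + 1L
    xs <- max(0L, floor(cx) - r0):min(size_px - 1L, ceiling(cx) + r0)
    ys <- max(0L, floor(cy) - r0):min(size_px - 1L, ceiling(cy) + r0)
    for (px in xs) for (py in ys) {
      sx <- px + off - cx
      sy <- py + off - cy
      frac <- mean(outer(sy^2, sx^2, `+`) < radius_px^2)
      if (frac > 0) d[py + 1L, px + 1L] <- d[py + 1L, px + 1L] + amplitude * frac
    }
  }
  d
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> kind=%s  %dx%d px  pixel=%.3g nm  total density=%.4g\n",
              x$kind, nrow(x$density), ncol(x$density), x$pixel_size_nm, sum(x$density)))
  invisible(x)
}
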