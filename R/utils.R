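# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("'%s' must be a numeric matrix", name)
  if (anyNA(x) || any(!is.finite(x))) stopf("'%s' must be finite", name)
  invisible(x)
}

# Pixel coordinate grids, 0-based, origin at the top-left pixel.
# Returns list(x, y) where x varies along columns and y along rows.
pixel_grid <- function(nrow, ncol = nrow) {
  list(
    x = matrix(rep(seq_len(ncol) - 1, each = nrow), nrow, ncol),
    y = matrix(rep(seq_len(nrow) - 1, times = ncol), nrow, ncol)
  )
}

# Embed a centered (odd-sized) kernel into an nr x nc field with its center
# at index [1, 1], wrapping negative offsets -- the layout expected by
# FFT-based circular convolution.
embed_kernel <- function(kernel, nr, nc) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nr || kc > nc) stopf("kernel (%dx%d) larger than field (%dx%d)", kr, kc, nr, nc)
  cy <- (kr + 1L) %/% 2L; cx <- (kc + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  ri <- ((seq_len(kr) - cy) %% nr) + 1L
  ci <- ((seq_len(kc) - cx) %% nc) + 1L
  out[ri, ci] <- kernel
  out
}

# Mirror (reflect) padding without repeating the edge sample.
reflect_pad <- function(img, pad) {
  if (pad == 0L) return(img)
  n <- nrow(img); m <- ncol(img)
  if (pad >= n || pad >= m) stopf("reflect pad %d too large for a %dx%d image", pad, n, m)
  ridx <- c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
  cidx <- c(rev(seq_len(pad) + 1L), seq_len(m), m - seq_len(pad))
  img[ridx, cidx]
}

# Circular (periodic) FFT convolution with a centered kernel.
fft_convolve_periodic <- function(img, kernel) {
  k <- embed_kernel(kernel, nrow(img), ncol(img))
  Re(stats::fft(stats::fft(img) * stats::fft(k), inverse = TRUE)) / length(img)
}

# FFT convolution on a reflect-padded grid (pad = kernel half-width),
# cropped back to the original extent.
fft_convolve_reflect <- function(img, kernel) {
  pad <- max(nrow(kernel), ncol(kernel)) %/% 2L
  padded <- reflect_pad(img, pad)
  full <- fft_convolve_periodic(padded, kernel)
  full[pad + seq_len(nrow(img)), pad + seq_len(ncol(img))]
}

fft_convolve <- function(img, kernel, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  if (boundary == "periodic") fft_convolve_periodic(img, kernel)
  else fft_convolve_reflect(img, kernel)
}

# DFT frequency grid in cycles/pixel, matching stats::fft ordering.
fft_freq <- function(n) {
  k <- c(seq(0L, n - ((n %/% 2L) + 1L)), seq(-(n %/% 2L), -1L))
  k / n
}

# Percentile on the 0-100 scale (quantile type 7).
percentile <- function(x, p) stats::quantile(x, p / 100, names = FALSE, type = 7)

pearson <- function(a, b) stats::cor(as.vector(a), as.vector(b))

# Gaussian weight matrix (odd size), normalized to sum 1.
gaussian_window <- function(size, sigma) {
  stopifnot(size %% 2L == 1L)
  r <- seq_len(size) - (size + 1L) / 2L
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# Per-pixel channel maximum; a plain matrix is returned unchanged.
channel_max <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) return(apply(img, c(1, 2), max))
  stopf("expected a matrix or an H x W x C array")
}

as_channels <- function(img) {
  if (is.matrix(img)) array(img, dim = c(dim(img), 1L)) else img
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
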