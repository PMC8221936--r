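#' Complex field containers and Fourier helpers
#'
#' A `field_map` is a complex scalar field sampled on the back-focal-plane
#' grid at one wavenumber; a `field_cube` stacks one map per spectral
#' sample. Maps record their illumination (kx, ky) and lens displacement
#' (xd, yd) metadata.
#'
#' @name field_map
NULL

new_field_map <- function(values, k, kx = 0, ky = 0, xd = 0, yd = 0,
                          windowed = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  f <- list(values = values, k = k, kx = kx, ky = ky, xd = xd, yd = yd,
            windowed = windowed)
  class(f) <- "field_map"
  f
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "<field_map> %dx%d, k = %.6g rad/m, (kx,ky) = (%.3g, %.3g), (xd,yd) = (%.3g, %.3g) um\n",
    nrow(x$values), ncol(x$values), x$k, x$kx, x$ky, 1e6 * x$xd, 1e6 * x$yd))
  invisible(x)
}

new_field_cube <- function(maps, spec, config) {
  stopifnot(length(maps) == length(spec$k))
  f <- list(maps = maps, spec = spec, config = config)
  class(f) <- "field_cube"
  f
}

#' @export
print.field_cube <- function(x, ...) {
  cat(sprintf("<field_cube> %d wavenumbers, %d^2 grid\n",
              length(x$maps), nrow(x$maps[[1]]$values)))
  invisible(x)
}

# Signed DFT frequencies (cycles/sample) for an even length n.
fft_freq <- function(n) c(0:(n / 2 - 1), -(n / 2):-1) / n

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Embed an N x N matrix centrally in a (pad*N) x (pad*N) zero matrix.
pad_matrix <- function(m, pad = 2L) {
  n <- nrow(m)
  np <- pad * n
  out <- matrix(0 + 0i, np, np)
  i0 <- (np - n) / 2
  out[i0 + seq_len(n), i0 + seq_len(n)] <- m
  out
}

crop_matrix <- function(m, n) {
  np <- nrow(m)
  i0 <- (np - n) / 2
  m[i0 + seq_len(n), i0 + seq_len(n)]
}

#' Fourier-shift resampling of a gridded field
#'
#' Evaluates the trigonometric interpolant of `g` at every grid point
#' displaced by `(sx, sy)` — i.e. returns samples of `g(x + sx, y + sy)`
#' — by phase multiplication in the discrete Fourier domain on a
#' zero-padded (factor `pad`) grid. Exact for band-limited, compactly
#' supported records such as guard-tapered back-focal-plane fields.
#'
#' @param g square complex matrix.
#' @param sx,sy shift (m); positive values sample the field at larger x/y.
#' @param dx grid spacing (m).
#' @param pad zero-padding factor (default 2).
#' @return matrix of the same size as `g`.
#' @export
fourier_shift <- function(g, sx, sy, dx, pad = 2L) {
  n <- nrow(g)
  gp <- pad_matrix(g, pad)
  np <- nrow(gp)
  fr <- fft_freq(np)
  px <- exp(2i * pi * fr * (sx / dx))
  py <- exp(2i * pi * fr * (sy / dx))
  out <- ifft2(fft2(gp) * outer(px, py))
  crop_matrix(out, n)
}

# Batched 2-D FFT of a stack of matrices given as columns of a matrix
# (each column one n x n field, column-major). Returns same layout.
fft2_stack <- function(cols, n, inverse = FALSE) {
  b <- ncol(cols)
  # FFT along dim 1 of each field: reshape to n x (n*b)
  m <- matrix(cols, n, n * b)
  m <- stats::mvfft(m, inverse = inverse)
  # transpose each field, FFT along the other axis
  a <- array(m, dim = c(n, n, b))
  a <- aperm(a, c(2, 1, 3))
  m <- stats::mvfft(matrix(a, n, n * b), inverse = inverse)
  a <- aperm(array(m, dim = c(n, n, b)), c(2, 1, 3))
  out <- matrix(a, n * n, b)
  if (inverse) out / (n * n) else out
}

rel_l2 <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}
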