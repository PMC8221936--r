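#' Define the optical system of a scanned spectral-domain OCT simulation
#'
#' Collects the lens, fiber, spectral and grid parameters shared by every
#' other function in the package. The model is a low-NA, scalar,
#' fiber-based spectral-domain OCT system: an objective of focal length
#' `f2` with a circular aperture of radius `Ra` collimates the scattered
#' field onto its back focal plane, where it is coupled into a single-mode
#' fiber whose (Gaussian) mode is also used to weight the illumination
#' angular spectrum.
#'
#' All quantities are SI (metres, rad/m). Wavenumbers are wavenumbers in
#' the background medium, `k = 2*pi*nb/lambda_vac`: phase accumulated over
#' a round trip to a scatterer at depth `zs` is `2*k*zs`, so the A-scan
#' depth axis is in physical sample depth.
#'
#' @param f2 objective focal length (m).
#' @param Ra aperture radius (m). The paraxial numerical aperture is
#'   `Ra/f2` and must stay below 0.3 (the synthesis assumes a low-NA,
#'   scalar regime).
#' @param lambda0 center vacuum wavelength (m).
#' @param bandwidth full sampled spectral width (m, in wavelength). The
#'   source envelope is Gaussian in k with FWHM equal to half the sampled
#'   k span (so the envelope has fallen to 2^-4 at the grid edges).
#' @param n_k number of spectral samples (uniform in k).
#' @param nb background refractive index of the sample medium.
#' @param fiber_mode_radius Gaussian mode field radius `w` of the fiber
#'   mode projected into the back focal plane (m): the mode amplitude is
#'   proportional to `exp(-r^2/w^2)` (1/e field radius, 1/e^2 intensity
#'   radius). Default `0.64*Ra`, filling the aperture without severe
#'   truncation.
#' @param bfp_extent half-extent of the recorded back-focal-plane grid (m).
#'   Default `1.5*Ra`: the outer 0.5*Ra is a guard band in which recorded
#'   fields are smoothly windowed to zero (see [guard_taper()]), so that
#'   Fourier-shift resampling of the record is spectrally accurate.
#' @param bfp_samples samples per axis of the (even-sized, origin-centered)
#'   back-focal-plane grid. Default 256.
#' @param n_angle samples per axis of the angular grid used to decompose
#'   the focussed beam, covering `[-k*NA, k*NA]`. Default 63.
#'
#' @return An object of class `oct_system` (a validated list with the
#'   above fields plus derived `NA_obj = Ra/f2`).
#' @examples
#' cfg <- oct_system()          # Telesto-II-like defaults
#' numerical_aperture(cfg)      # 0.0972
#' @export
oct_system <- function(f2 = 36e-3, Ra = 3.5e-3, lambda0 = 1.3e-6,
                       bandwidth = 170e-9, n_k = 1024L, nb = 1,
                       fiber_mode_radius = 0.64 * Ra,
                       bfp_extent = 1.5 * Ra, bfp_samples = 256L,
                       n_angle = 63L) {
  cfg <- list(f2 = f2, Ra = Ra, lambda0 = lambda0, bandwidth = bandwidth,
              n_k = as.integer(n_k), nb = nb,
              fiber_mode_radius = fiber_mode_radius,
              bfp_extent = bfp_extent, bfp_samples = as.integer(bfp_samples),
              n_angle = as.integer(n_angle))
  cfg$NA_obj <- Ra / f2
  class(cfg) <- "oct_system"
  validate_oct_system(cfg)
  cfg
}

validate_oct_system <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!(cfg$f2 > 0)) stop("invalid config: f2 must be > 0", call. = FALSE)
  if (!(cfg$Ra > 0)) stop("invalid config: Ra must be > 0", call. = FALSE)
  na <- cfg$Ra / cfg$f2
  if (!(na > 0 && na < 0.3))
    stop("invalid config: Ra/f2 = ", signif(na, 4),
         " outside the low-NA regime (0, 0.3)", call. = FALSE)
  if (!(cfg$lambda0 > 0)) stop("invalid config: lambda0 must be > 0", call. = FALSE)
  if (cfg$n_k < 1L) stop("invalid config: n_k must be >= 1", call. = FALSE)
  if (cfg$n_k > 1L && !(cfg$bandwidth > 0))
    stop("invalid config: bandwidth must be > 0 when n_k > 1", call. = FALSE)
  if (!(cfg$bandwidth < cfg$lambda0))
    stop("invalid config: bandwidth must be < lambda0", call. = FALSE)
  if (!(cfg$nb >= 1)) stop("invalid config: nb must be >= 1", call. = FALSE)
  if (!(cfg$fiber_mode_radius > 0))
    stop("invalid config: fiber_mode_radius must be > 0", call. = FALSE)
  if (cfg$bfp_samples < 8L || cfg$bfp_samples %% 2L != 0L)
    stop("invalid config: bfp_samples must be even and >= 8", call. = FALSE)
  if (!(cfg$bfp_extent > cfg$Ra))
    stop("invalid config: bfp_extent must exceed Ra (guard band required)",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.oct_system <- function(x, ...) {
  cat("<oct_system>\n")
  cat(sprintf("  f2 = %.3g mm, Ra = %.3g mm (NA = %.4f)\n",
              x$f2 * 1e3, x$Ra * 1e3, x$NA_obj))
  cat(sprintf("  lambda0 = %.4g um, bandwidth = %.3g nm, n_k = %d, nb = %.3f\n",
              x$lambda0 * 1e6, x$bandwidth * 1e9, x$n_k, x$nb))
  cat(sprintf("  BFP grid: %d^2 over +-%.3g mm; angular grid %d^2; mode radius %.3g mm\n",
              x$bfp_samples, x$bfp_extent * 1e3, x$n_angle,
              x$fiber_mode_radius * 1e3))
  invisible(x)
}

#' Paraxial numerical aperture of the objective
#'
#' @param config an [oct_system()] configuration.
#' @return `Ra/f2` (dimensionless).
#' @export
numerical_aperture <- function(config) config$Ra / config$f2

#' Uniform wavenumber grid and Gaussian source envelope
#'
#' Builds the spectral sampling used for A-scan formation: `n_k`
#' wavenumbers in the background medium, uniformly spaced in k over the
#' band `[2*pi*nb/(lambda0 + bw/2), 2*pi*nb/(lambda0 - bw/2)]`, with a
#' Gaussian field envelope whose FWHM (in k) is half the sampled span.
#' Uniform k spacing is required by the FFT-based A-scan reconstruction.
#'
#' @param config an [oct_system()] configuration.
#' @return An object of class `spectral_grid`: list with `k` (rad/m,
#'   strictly increasing), `weights` (unit peak), `dk`, `k0`.
#' @export
build_spectral_grid <- function(config) {
  n <- config$n_k
  k0 <- 2 * pi * config$nb / config$lambda0
  if (n == 1L) {
    g <- list(k = k0, weights = 1, dk = 0, k0 = k0)
    class(g) <- "spectral_grid"
    return(g)
  }
  if (!(config$bandwidth > 0))
    stop("invalid config: bandwidth must be > 0 when n_k > 1", call. = FALSE)
  lmin <- config$lambda0 - config$bandwidth / 2
  lmax <- config$lambda0 + config$bandwidth / 2
  kmin <- 2 * pi * config$nb / lmax
  kmax <- 2 * pi * config$nb / lmin
  k <- seq(kmin, kmax, length.out = n)
  kc <- (kmin + kmax) / 2
  fwhm <- (kmax - kmin) / 2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(k - kc)^2 / (2 * sigma^2))
  g <- list(k = k, weights = w, dk = k[2] - k[1], k0 = kc)
  class(g) <- "spectral_grid"
  g
}

#' Axial depth resolution of the spectral grid
#'
#' One depth bin of the FFT A-scan reconstruction, `pi/(n_k * dk)`.
#' @param spec a [build_spectral_grid()] result.
#' @return depth bin size (m).
#' @export
depth_bin <- function(spec) {
  if (length(spec$k) < 2L) stop("depth axis undefined for a single wavenumber")
  pi / (length(spec$k) * spec$dk)
}

#' Back-focal-plane sampling grid
#'
#' Regular, even-sized grid centered so that the origin is an exact
#' sample: `x_j = (j - 1 - N/2) * dx`, `j = 1..N`, spanning
#' `[-bfp_extent, bfp_extent)`.
#'
#' @param config an [oct_system()] configuration.
#' @return Object of class `aperture_grid`: list with vectors `x`, `y`,
#'   spacing `dx`, matrices `X`, `Y`, `R2 = X^2+Y^2`, logical aperture
#'   `mask` (`R2 < Ra^2`) and the guard `taper` matrix.
#' @export
aperture_grid <- function(config) {
  n <- config$bfp_samples
  dx <- 2 * config$bfp_extent / n
  x <- (seq_len(n) - 1 - n / 2) * dx
  X <- matrix(x, n, n)
  Y <- t(X)
  R2 <- X^2 + Y^2
  g <- list(x = x, y = x, dx = dx, X = X, Y = Y, R2 = R2,
            mask = R2 < config$Ra^2,
            taper = guard_taper(sqrt(R2), config),
            Ra = config$Ra, extent = config$bfp_extent)
  class(g) <- "aperture_grid"
  g
}

#' Guard-band window of the recorded back-focal-plane field
#'
#' Recorded fields are windowed to zero over the outer guard band of the
#' back-focal-plane grid with a smooth (C-infinity) Planck taper: 1 for
#' `r <= 1.02*Ra`, 0 for `r >= 1.45*Ra`. This keeps the stored field
#' effectively band-limited and compactly supported, so that the
#' Fourier-shift resampling used by the synthesis is spectrally accurate.
#' The taper only touches radii outside the aperture; the hard aperture
#' `x^2+y^2 < Ra^2` is enforced at the fiber-coupling step.
#'
#' @param r radius values (m), any shape.
#' @param config an [oct_system()] configuration.
#' @param r0,r1 inner (taper start) and outer (zero) radii; defaults
#'   `1.02*Ra` and `1.45*Ra`.
#' @return window values in `[0, 1]`, same shape as `r`.
#' @export
guard_taper <- function(r, config, r0 = 1.02 * config$Ra,
                        r1 = 1.45 * config$Ra) {
  t <- ifelse(r <= r0, 1, 0)
  mid <- r > r0 & r < r1
  if (any(mid)) {
    s <- (r[mid] - r0) / (r1 - r0)
    t[mid] <- 1 / (1 + exp(1 / (1 - s) - 1 / s))
  }
  t
}

#' Angular grid of the focussed beam's plane-wave decomposition
#'
#' Cell-centered (midpoint-rule) grid of transverse wavenumbers covering
#' `[-kNA, kNA]^2` with `n_angle` nodes per axis, where `kNA = k * NA`.
#' With odd `n_angle` the origin (normal incidence) is an exact node.
#' Quadrature weight per node is `dkx * dky`; nodes outside the disk
#' `kx^2 + ky^2 <= kNA^2` are masked out.
#'
#' @param k wavenumber in the background medium (rad/m).
#' @param config an [oct_system()] configuration.
#' @param n_angle override for `config$n_angle`.
#' @return Object of class `angular_grid`: list with node vectors `kx`,
#'   `ky`, spacing `dk`, cutoff `kNA`, and `nodes` (data.frame of in-disk
#'   node pairs with quadrature weight `w`).
#' @export
angular_grid <- function(k, config, n_angle = config$n_angle) {
  if (!(k > 0)) stop("k must be > 0")
  kNA <- k * numerical_aperture(config)
  n <- as.integer(n_angle)
  dk <- 2 * kNA / n
  kx <- -kNA + (seq_len(n) - 0.5) * dk
  kx[abs(kx) < 1e-12 * kNA] <- 0 # exact normal-incidence node for odd n
  KX <- matrix(kx, n, n)
  KY <- t(KX)
  keep <- KX^2 + KY^2 <= kNA^2
  g <- list(kx = kx, ky = kx, dk = dk, kNA = kNA, k = k,
            nodes = data.frame(kx = KX[keep], ky = KY[keep],
                               w = dk * dk))
  class(g) <- "angular_grid"
  g
}

#' Fiber mode projected into the back focal plane
#'
#' Normalized Gaussian mode of field radius `fiber_mode_radius`, centered
#' on the scan position `(xd, yd)` (the collection fiber translates in
#' tandem with the illumination). Normalization is unit L2 norm over the
#' unmasked grid (`sum(|phi|^2) * dx^2 = 1`); values outside the aperture
#' are zeroed after normalization.
#'
#' @param grid an [aperture_grid()].
#' @param xd,yd scan position of the mode center (m).
#' @param config an [oct_system()] configuration.
#' @param masked zero the mode outside the aperture (default TRUE).
#' @return complex-storable numeric matrix (real Gaussian mode).
#' @export
fiber_mode <- function(grid, xd = 0, yd = 0, config, masked = TRUE) {
  w <- config$fiber_mode_radius
  if (!(w > 0)) stop("invalid config: fiber mode radius must be > 0")
  m <- exp(-((grid$X - xd)^2 + (grid$Y - yd)^2) / w^2)
  m <- m / sqrt(sum(m^2) * grid$dx^2)
  if (masked) m[!grid$mask] <- 0
  m
}

#' Source angular spectrum of the focussed illumination beam
#'
#' The illumination and collection share one single-mode fiber, so the
#' angular spectrum of the beam is the fiber mode read at the
#' back-focal-plane point that maps to each plane-wave direction,
#' `(x, y) = (f2*kx/k, f2*ky/k)`, and zero beyond the angular cutoff.
#'
#' @param ang an [angular_grid()].
#' @param k wavenumber (rad/m); defaults to `ang$k`.
#' @param config an [oct_system()] configuration.
#' @return numeric vector of weights, one per in-disk node of `ang`.
#' @export
source_angular_spectrum <- function(ang, k = ang$k, config) {
  w <- config$fiber_mode_radius
  xbfp <- config$f2 * ang$nodes$kx / k
  ybfp <- config$f2 * ang$nodes$ky / k
  # same normalization constant as the gridded fiber mode
  grid <- aperture_grid(config)
  m0 <- exp(-(grid$R2) / w^2)
  nrm <- sqrt(sum(m0^2) * grid$dx^2)
  exp(-(xbfp^2 + ybfp^2) / w^2) / nrm
}
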