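#' Synthesize the tilted-illumination field from the normal-incidence record
#'
#' Core translation step of synthetic scanning: the scattered field that a
#' plane wave with transverse wavenumber `(kx, ky)` and a lens displaced
#' to `(xd, yd)` would produce in the back focal plane is obtained from
#' the normal-incidence record `g1` by a lateral translation plus phase
#' adjustments,
#'
#' `g2(x,y) = g1(xb + kx*f2/k, yb + ky*f2/k)
#'            * exp(i*zs*(kx*xb + ky*yb)/f2)
#'            * exp(-i*k*(xd*xb + yd*yb)/f2) * exp(-i*(kx*xd + ky*yd))`
#'
#' with `xb = x - xd`, `yb = y - yd` and `zs` the *assumed* scatterer
#' depth. The relation is exact for a single point scatterer at depth
#' `zs`; for other depths the (slowly varying) first phase factor is
#' approximate, which is what the zs-banded stitching compensates.
#'
#' Resampling is by Fourier-shift interpolation on a zero-padded grid.
#' The assumed-depth phase is applied through an algebraically equivalent
#' chirp decomposition (`zs*(kx*xb+ky*yb)/f2 = c/2*(|xb+D|^2 - |xb|^2 -
#' |D|^2)`, `c = zs*k/f2^2`, `D = (kx,ky)*f2/k`): the record is
#' pre-multiplied by `exp(i*c/2*r^2)` — which *cancels* the quadratic
#' phase of scatterers near the assumed depth — before interpolation, so
#' the interpolant is applied to the least oscillatory representation.
#'
#' @param g1 a `field_map` holding the normal-incidence record (guard
#'   windowed; see [point_scatterer_g1()] / [compute_g1_cube()]).
#' @param kx,ky transverse wavenumbers of the synthesized illumination
#'   (rad/m).
#' @param xd,yd scan position (m).
#' @param zs_assumed assumed scatterer depth (m).
#' @param config an [oct_system()].
#' @param grid optional [aperture_grid()].
#' @param pad zero-padding factor for the spectral shift (default 2).
#' @return a `field_map` holding g2.
#' @export
synthesize_g2 <- function(g1, kx = 0, ky = 0, xd = 0, yd = 0, zs_assumed = 0,
                          config, grid = aperture_grid(config), pad = 2L) {
  k <- g1$k
  f2 <- config$f2
  Dx <- kx * f2 / k
  Dy <- ky * f2 / k
  # translated support must stay inside the padded periodic cell
  if (max(abs(c(Dx - xd, Dy - yd))) + grid$extent >= pad * grid$extent)
    stop("requested shift pushes the field support outside the padded grid")
  cc <- zs_assumed * k / f2^2
  H <- g1$values * exp(1i * (cc / 2) * grid$R2)
  Hs <- fourier_shift(H, Dx - xd, Dy - yd, grid$dx, pad = pad)
  xb <- grid$X - xd
  yb <- grid$Y - yd
  v <- Hs * exp(-1i * (cc / 2) * (xb^2 + yb^2)) *
    exp(-1i * (cc / 2) * (Dx^2 + Dy^2)) *
    exp(-1i * k / f2 * (xd * xb + yd * yb)) *
    exp(-1i * (kx * xd + ky * yd))
  new_field_map(v, k, kx = kx, ky = ky, xd = xd, yd = yd,
                windowed = g1$windowed)
}

#' Synthesize the focussed-illumination field (angular superposition)
#'
#' Midpoint-rule superposition of synthesized tilted-wave fields over the
#' angular spectrum of the focussed beam:
#' `g3(x,y) = sum_over_angles g2(x,y; kx,ky) * phi_f(kx,ky) * dkx*dky`.
#' This is the literal (per-angle) evaluation; [synthesize_bscan()] uses
#' an algebraically identical factorized path.
#'
#' @inheritParams synthesize_g2
#' @param ang optional [angular_grid()] for this k.
#' @return a `field_map` holding g3.
#' @export
synthesize_g3 <- function(g1, xd = 0, yd = 0, zs_assumed = 0, config,
                          ang = angular_grid(g1$k, config),
                          grid = aperture_grid(config)) {
  phif <- source_angular_spectrum(ang, g1$k, config)
  acc <- matrix(0 + 0i, nrow(g1$values), ncol(g1$values))
  for (a in seq_len(nrow(ang$nodes))) {
    g2 <- synthesize_g2(g1, ang$nodes$kx[a], ang$nodes$ky[a], xd, yd,
                        zs_assumed, config, grid = grid)
    acc <- acc + g2$values * (phif[a] * ang$nodes$w[a])
  }
  new_field_map(acc, g1$k, xd = xd, yd = yd, windowed = g1$windowed)
}

#' Couple a back-focal-plane field into the single-mode fiber
#'
#' Overlap integral of the translated fiber mode with the field over the
#' aperture, `a3 = integral_{x^2+y^2<Ra^2} phi(x-xd, y-yd) g3(x,y) dx dy`,
#' evaluated with the grid's own quadrature. The collection mode
#' translates in tandem with the illumination (same fiber).
#'
#' @param g3 a `field_map`.
#' @param xd,yd scan position of the fiber mode (m).
#' @param config an [oct_system()].
#' @param grid optional [aperture_grid()].
#' @return complex coupling amplitude.
#' @export
couple_to_fiber <- function(g3, xd = 0, yd = 0, config,
                            grid = aperture_grid(config)) {
  m <- fiber_mode(grid, xd, yd, config)  # zero outside aperture
  sum(m * g3$values) * grid$dx^2
}

#' Reference-arm spectrum
#'
#' Source spectral envelope with a constant-path-length phase
#' `exp(i*2*k*z_ref)`; `z_ref = 0` places the reference plane at the
#' focus. The reference return is modelled as a mirror at the reference
#' plane coupled through the same objective/fiber path as the sample arm,
#' so it carries the same quadrature constant (`1/i`) as the paraxial
#' point response: this phase-matches the reference to an in-focus
#' scatterer, whose interference term would otherwise vanish under the
#' real-part operation of the A-scan reconstruction.
#'
#' @param spec a [build_spectral_grid()].
#' @param config an [oct_system()] (unused beyond validation; kept for a
#'   uniform signature).
#' @param z_ref reference-arm offset from the focal plane (m).
#' @return complex vector, one value per wavenumber.
#' @export
reference_arm_spectrum <- function(spec, config = NULL, z_ref = 0) {
  spec$weights * exp(1i * 2 * spec$k * z_ref) / 1i
}

#' Form an A-scan from the coupled spectrum
#'
#' Computes the interference spectrum `2*Re(a3 * Conj(amirr))`, Fourier
#' transforms over the uniform wavenumber grid, and maps the conjugate
#' variable to depth through the round-trip phase `2*k*z` (depth bin
#' `pi/(n_k*dk)`). Returns the one-sided magnitude profile over positive
#' depths (the complex analytic signal is retained in `complex_profile`).
#'
#' @param a3 complex coupling amplitudes, one per wavenumber.
#' @param amirr reference-arm spectrum (same length).
#' @param spec the [build_spectral_grid()] that produced both.
#' @return list with `z` (depth axis, m), `magnitude`, `complex_profile`.
#' @export
form_ascan <- function(a3, amirr, spec) {
  n <- length(spec$k)
  stopifnot(length(a3) == n, length(amirr) == n)
  if (n < 2L) stop("A-scan formation needs more than one wavenumber")
  dks <- diff(spec$k)
  if (max(abs(dks - dks[1])) > 1e-6 * abs(dks[1]))
    stop("non-uniform wavenumber grid: FFT-based A-scan formation requires ",
         "uniform k spacing")
  S <- 2 * Re(a3 * Conj(amirr))
  prof <- stats::fft(S, inverse = TRUE)
  nz <- n %/% 2
  z <- (seq_len(nz) - 1) * pi / (n * dks[1])
  list(z = z, magnitude = Mod(prof[seq_len(nz)]),
       complex_profile = prof[seq_len(nz)])
}

# ---- factorized coupling engine -------------------------------------------
#
# For one wavenumber k, scan position (xd, yd) and assumed depth zs, the
# coupled amplitude is
#   a3 = sum_angles phif * w * exp(-i*c/2*|D|^2) * exp(-i*(kx*xd+ky*yd))
#        * S(D),
#   S(D) = sum_x W(x) * H(x - d + D),
#   W(x) = mode(x-d) * 1(|x|<Ra) * exp(-i*c/2*|x-d|^2)
#          * exp(-i*k*(xd*(x-xd)+yd*(y-yd))/f2) * dx^2,
#   H(v) = g1(v) * exp(i*c/2*|v|^2),    c = zs*k/f2^2,  D = (kx,ky)*f2/k.
# The cross-correlation S is evaluated exactly (same trigonometric
# interpolant as fourier_shift) at every node of the translation lattice
# at once:  S = t(Ex) %*% (What * Hhat / Np^2) %*% Ey, with
# Ex[h, a] = exp(2*pi*i * fr[h] * (Dx_a - xd)/dx).  Because the angular
# nodes scale with k (kx = k*NA*t on a fixed fractional lattice), the
# translation lattice D — and hence Ex/Ey and the source spectrum values —
# are identical for every k.

synth_engine <- function(config, scan_x, scan_y = 0, pad = 2L) {
  grid <- aperture_grid(config)
  n <- config$bfp_samples
  np <- pad * n
  fr <- fft_freq(np)
  # fractional angular lattice (k-independent geometry)
  na <- config$n_angle
  tfrac <- (-1 + (seq_len(na) - 0.5) * 2 / na)  # cell-centered in [-1, 1]
  tfrac[abs(tfrac) < 1e-12] <- 0
  Dx_lat <- config$f2 * numerical_aperture(config) * tfrac
  KXf <- matrix(tfrac, na, na)
  KYf <- t(KXf)
  disk <- KXf^2 + KYf^2 <= 1
  # fiber-mode angular weights at the lattice (k-independent)
  w <- config$fiber_mode_radius
  m0nrm <- sqrt(sum(exp(-grid$R2 / w^2)^2) * grid$dx^2)
  phif <- exp(-(matrix(Dx_lat, na, na)^2 + t(matrix(Dx_lat, na, na))^2) / w^2) / m0nrm
  # per-scan-position mode masks and Ex/Ey phase matrices
  nscan <- length(scan_x)
  modes <- vector("list", nscan)
  Ex <- vector("list", nscan)
  Ey <- vector("list", nscan)
  for (j in seq_len(nscan)) {
    modes[[j]] <- fiber_mode(grid, scan_x[j], scan_y, config) * grid$dx^2
    Ex[[j]] <- exp(2i * pi * outer(fr, (Dx_lat - scan_x[j]) / grid$dx))
    Ey[[j]] <- exp(2i * pi * outer(fr, (Dx_lat - scan_y) / grid$dx))
  }
  list(grid = grid, n = n, np = np, fr = fr, pad = pad,
       tfrac = tfrac, Dx_lat = Dx_lat, disk = disk, phif = phif,
       scan_x = scan_x, scan_y = scan_y, modes = modes, Ex = Ex, Ey = Ey)
}

# Coupled spectra a3[k, scan] for one assumed depth zs, from a g1 cube.
synth_coupling_spectra <- function(cube, eng, zs, config) {
  spec <- cube$spec
  nk <- length(spec$k)
  nscan <- length(eng$scan_x)
  na <- config$n_angle
  grid <- eng$grid
  f2 <- config$f2
  a3 <- matrix(0 + 0i, nk, nscan)
  DX <- matrix(eng$Dx_lat, na, na)
  DY <- t(DX)
  D2 <- DX^2 + DY^2
  for (i in seq_len(nk)) {
    k <- spec$k[i]
    cc <- zs * k / f2^2
    H <- cube$maps[[i]]$values * exp(1i * (cc / 2) * grid$R2)
    Hhat <- fft2(pad_matrix(H, eng$pad))
    kx_lat <- k * numerical_aperture(config) * eng$tfrac
    for (j in seq_len(nscan)) {
      xd <- eng$scan_x[j]
      yd <- eng$scan_y
      vx <- exp(-1i * ((cc / 2) * (grid$x - xd)^2 + k * xd * (grid$x - xd) / f2))
      vy <- exp(-1i * ((cc / 2) * (grid$y - yd)^2 + k * yd * (grid$y - yd) / f2))
      W <- eng$modes[[j]] * outer(vx, vy)
      What <- Conj(fft2(pad_matrix(Conj(W), eng$pad)))
      S <- crossprod(eng$Ex[[j]], (What * Hhat)) %*% eng$Ey[[j]] / eng$np^2
      ph <- exp(-1i * (cc / 2) * D2) *
        exp(-1i * (outer(kx_lat, rep(1, na)) * xd + outer(rep(1, na), kx_lat) * yd))
      contrib <- eng$phif * ph * S
      a3[i, j] <- sum(contrib[eng$disk]) * (2 * k * numerical_aperture(config) / na)^2
    }
  }
  a3
}

#' Synthesize a scanned OCT B-scan from a normal-incidence field cube
#'
#' Runs the full synthesis chain (tilted-field translation, angular
#' superposition, fiber coupling, spectral reconstruction) at every scan
#' position, once per assumed scatterer depth in `zs_list`, and stitches
#' the final image from half-open depth bands centered on each assumed
#' depth (`[zs - dzs/2, zs + dzs/2)` for band spacing `dzs`).
#'
#' @param g1_cube a `field_cube` from [compute_g1_cube()] (or loaded from
#'   a field store).
#' @param scan_xs lateral scan positions (m).
#' @param zs_list assumed depths (m), sorted, uniformly spaced.
#' @param config an [oct_system()].
#' @param z_range depth range `c(z0, z1)` of the output image (m);
#'   default covers `[0, max(zs_list) + dzs/2)`.
#' @param z_ref reference-arm offset (m).
#' @return an `oct_image` (see [oct_image()]): magnitude values
#'   `[n_z, n_scan]`, depth axis `z`, scan axis `x`, provenance
#'   `"synthesized"` and the band boundaries used.
#' @export
synthesize_bscan <- function(g1_cube, scan_xs, zs_list, config,
                             z_range = NULL, z_ref = 0) {
  spec <- g1_cube$spec
  zs_list <- sort(zs_list)
  dzs <- if (length(zs_list) > 1L) {
    d <- diff(zs_list)
    if (max(abs(d - d[1])) > 1e-9 * max(abs(d))) stop("zs_list must be uniformly spaced")
    d[1]
  } else Inf
  amirr <- reference_arm_spectrum(spec, config, z_ref)
  eng <- synth_engine(config, scan_xs)
  nz <- length(spec$k) %/% 2
  zax <- (seq_len(nz) - 1) * pi / (length(spec$k) * spec$dk)
  if (is.null(z_range))
    z_range <- c(0, if (is.finite(dzs)) max(zs_list) + dzs / 2 else max(zax))
  if (z_range[2] > max(zax) + (zax[2] - zax[1]))
    stop("requested depth range exceeds the unambiguous imaging depth ",
         sprintf("%.1f um of this spectral grid; increase n_k", 1e6 * max(zax)))
  keep_z <- zax >= z_range[1] & zax < z_range[2]
  # band membership per depth bin
  band <- rep(NA_integer_, nz)
  for (b in seq_along(zs_list)) {
    lo <- zs_list[b] - dzs / 2
    hi <- zs_list[b] + dzs / 2
    band[zax >= lo & zax < hi] <- b
  }
  if (anyNA(band[keep_z]))
    stop("assumed-depth bands do not cover the requested depth range")
  vals <- matrix(NA_real_, nz, length(scan_xs))
  cvals <- matrix(NA_complex_, nz, length(scan_xs))
  for (b in seq_along(zs_list)) {
    rows <- which(band == b & keep_z)
    if (!length(rows)) next
    a3 <- synth_coupling_spectra(g1_cube, eng, zs_list[b], config)
    for (j in seq_along(scan_xs)) {
      asc <- form_ascan(a3[, j], amirr, spec)
      vals[rows, j] <- asc$magnitude[rows]
      cvals[rows, j] <- asc$complex_profile[rows]
    }
  }
  rows <- which(keep_z)
  oct_image(vals[rows, , drop = FALSE], z = zax[rows], x = scan_xs,
            provenance = "synthesized",
            bands = data.frame(zs = zs_list,
                               lo = zs_list - dzs / 2, hi = zs_list + dzs / 2),
            complex_values = cvals[rows, , drop = FALSE])
}

#' Corrected synthesized A-scan of an isolated scatterer
#'
#' Diagnostic rescaling of a synthesized isolated-scatterer coupled
#' spectrum by the ratio of the directly evaluated incident field at the
#' scatterer to the incident field the synthesis assumed (the
#' normal-incidence field times the free-space tilt phase ramp). The
#' correction is uniform over the scattered field at each wavenumber, so
#' it cannot move the A-scan peak; it quantifies how much of the
#' synthesis error is due to the arriving field alone.
#'
#' @param a3_synth synthesized coupled spectrum (complex, per k).
#' @param incident_true complex incident field at the scatterer per k
#'   (directly evaluated).
#' @param incident_assumed complex incident field the synthesis assumed
#'   at the scatterer per k.
#' @param amirr,spec as in [form_ascan()].
#' @return list as [form_ascan()], plus `correction` (the per-k factors).
#' @export
corrected_ascan <- function(a3_synth, incident_true, incident_assumed,
                            amirr, spec) {
  scale <- max(Mod(incident_true), Mod(incident_assumed))
  if (!(scale > 0) || any(Mod(incident_assumed) < 1e-12 * scale))
    stop("assumed incident field is (near) zero at the scatterer; ",
         "correction factor undefined")
  rho <- incident_true / incident_assumed
  out <- form_ascan(a3_synth * rho, amirr, spec)
  out$correction <- rho
  out
}
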