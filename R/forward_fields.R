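#' Back-focal-plane field of a point scatterer, normal incidence
#'
#' Analytic scattered field collimated onto the back focal plane when a
#' unit plane wave travelling in +z illuminates a point scatterer at
#' `(xs, ys, zs)` (paraxial free-space propagation to the lens, lens
#' collimation):
#'
#' `g1(x,y) = amp/(i*lam*f2) * exp(i*2*k*zs)
#'            * exp(-i*k*zs*(x^2+y^2)/(2*f2^2))
#'            * exp(i*k*(xs*x + ys*y)/f2)`
#'
#' with `lam = 2*pi/k` the wavelength in the medium. Valid for scatterers
#' within the designed depth of focus (warned beyond +-300 um by the
#' phantom constructors). By default the recorded map is windowed by the
#' guard taper (see [guard_taper()]); the hard aperture is applied at the
#' coupling step.
#'
#' @param s one-row data.frame (or list) with `xs`, `ys`, `zs`, `amp`.
#' @param k wavenumber in the medium (rad/m).
#' @param config an [oct_system()].
#' @param grid optional precomputed [aperture_grid()].
#' @param window apply the guard-band taper to the record (default TRUE).
#' @return a `field_map`.
#' @export
point_scatterer_g1 <- function(s, k, config, grid = aperture_grid(config),
                               window = TRUE) {
  if (!(k > 0)) stop("k must be > 0")
  v <- point_scatterer_g1_values(s, k, config, grid)
  if (window) v <- v * grid$taper
  new_field_map(v, k, windowed = window)
}

point_scatterer_g1_values <- function(s, k, config, grid) {
  lam <- 2 * pi / k
  f2 <- config$f2
  s$amp / (1i * lam * f2) * exp(1i * 2 * k * s$zs) *
    exp(-1i * k * s$zs / (2 * f2^2) * grid$R2) *
    exp(1i * k / f2 * (s$xs * grid$X + s$ys * grid$Y))
}

#' Tilted-illumination, displaced-lens point-scatterer field (direct oracle)
#'
#' Exact first-principles back-focal-plane response for a plane wave with
#' transverse wavenumber `(kx, ky)` (referenced to the beam axis at the
#' scan position) illuminating a point scatterer, collected by a lens
#' displaced to `(xd, yd)`:
#' the incident phase at the scatterer is
#' `exp(i*(kx*(xs-xd) + ky*(ys-yd) + kz_par*zs))` with the paraxial axial
#' wavenumber `kz_par = k - (kx^2+ky^2)/(2*k)` (consistent with the
#' Fresnel propagator of the return path), and the return path is the
#' normal-incidence response written in the displaced-lens frame. The
#' identical guard window used when recording g1 is applied analytically
#' at the resampled radius, making this the like-for-like oracle for the
#' translation-based synthesis.
#'
#' @inheritParams point_scatterer_g1
#' @param kx,ky transverse wavenumbers of the illumination (rad/m),
#'   within the angular cutoff `k*NA`.
#' @param xd,yd lens/scan displacement (m).
#' @return a `field_map`.
#' @export
point_scatterer_g2_direct <- function(s, k, kx = 0, ky = 0, xd = 0, yd = 0,
                                      config, grid = aperture_grid(config),
                                      window = TRUE) {
  kt2 <- kx^2 + ky^2
  if (kt2 >= k^2) stop("evanescent illumination: kx^2 + ky^2 >= k^2")
  if (kt2 > (k * numerical_aperture(config))^2 * (1 + 1e-12))
    stop("illumination direction outside the angular cutoff k*NA")
  lam <- 2 * pi / k
  f2 <- config$f2
  Dx <- kx * f2 / k
  Dy <- ky * f2 / k
  xb <- grid$X - xd
  yb <- grid$Y - yd
  v <- s$amp / (1i * lam * f2) * exp(1i * 2 * k * s$zs) *
    exp(-1i * s$zs * kt2 / (2 * k)) *
    exp(1i * (kx * (s$xs - xd) + ky * (s$ys - yd))) *
    exp(-1i * k * s$zs / (2 * f2^2) * (xb^2 + yb^2)) *
    exp(1i * k / f2 * ((s$xs - xd) * xb + (s$ys - yd) * yb))
  if (window)
    v <- v * guard_taper(sqrt((xb + Dx)^2 + (yb + Dy)^2), config)
  new_field_map(v, k, kx = kx, ky = ky, xd = xd, yd = yd, windowed = window)
}

#' Normal-incidence scattered-field cube g1 over the source spectrum
#'
#' One back-focal-plane map per wavenumber, on-axis lens, unit-amplitude
#' plane-wave illumination. For point-scatterer phantoms the maps are
#' coherent sums of analytic single-scatterer responses; if `solver =
#' "multislice"` the forward field inside the phantom is computed with
#' the split-step solver and each scatterer re-radiates the locally
#' incident field (first-Born return path).
#'
#' @param phantom an `oct_phantom`.
#' @param config an [oct_system()].
#' @param spec optional [build_spectral_grid()].
#' @param solver `"points"` (analytic, homogeneous background) or
#'   `"multislice"` (split-step forward field).
#' @param ms options list for the multislice solver (see
#'   [multislice_incident_field()]): `cell`, `lateral_extent`, `z_range`.
#' @return a `field_cube`.
#' @export
compute_g1_cube <- function(phantom, config, spec = build_spectral_grid(config),
                            solver = c("points", "multislice"), ms = list()) {
  solver <- match.arg(solver)
  grid <- aperture_grid(config)
  maps <- vector("list", length(spec$k))
  if (solver == "points") {
    for (i in seq_along(spec$k)) {
      k <- spec$k[i]
      v <- matrix(0 + 0i, config$bfp_samples, config$bfp_samples)
      ss <- phantom$scatterers
      for (j in seq_len(nrow(ss)))
        v <- v + point_scatterer_g1_values(ss[j, ], k, config, grid)
      maps[[i]] <- new_field_map(v * grid$taper, k, windowed = TRUE)
    }
  } else {
    vol <- do.call(phantom_volume_grid, c(list(phantom), ms))
    so <- born_standoff(vol)
    for (i in seq_along(spec$k)) {
      k <- spec$k[i]
      inc <- multislice_incident_field(phantom, k, 0, 0, config, vol = vol)
      m <- born_scattered_g(phantom, inc, k, 0, 0, config, grid = grid,
                            standoff = so)
      maps[[i]] <- new_field_map(m$values * grid$taper, k, windowed = TRUE)
    }
  }
  new_field_cube(maps, spec, config)
}

# Build (or pass through) the index volume used by the split-step solver.
# `slab` (m) sets the propagation step: the accumulated index contrast of
# all raster cells inside a slab is projected onto one phase screen.
phantom_volume_grid <- function(phantom, cell = NULL, lateral_extent = NULL,
                                z_range = NULL, slab = NULL, ...) {
  if (!is.null(phantom$index_grid)) {
    vol <- phantom$index_grid
    if (!is.null(slab)) vol$slab <- slab
    return(vol)
  }
  s <- phantom$scatterers
  if (is.null(cell)) cell <- 0.5e-6
  if (is.null(lateral_extent))
    lateral_extent <- max(abs(c(s$xs, s$ys, 10e-6))) + 15e-6
  if (is.null(z_range)) z_range <- c(0, max(s$zs) + cell)
  vol <- phantom_to_index_grid(phantom, cell, lateral_extent, z_range)
  vol$slab <- slab
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Born sampling standoff: clear the particle's own raster cells plus one
# propagation slab.
born_standoff <- function(vol) vol$cell + (vol$slab %||% vol$cell)

#' Split-step (multi-slice) propagation of a tilted plane wave
#'
#' Propagates the incident field `exp(i*(kx*x + ky*y))` (defined at the
#' top surface, z = z0 of the volume) down through the phantom's
#' refractive-index volume: angular-spectrum free propagation between
#' slices with the non-paraxial `kz = sqrt(k^2 - kx^2 - ky^2)`, then a
#' thin phase screen `exp(i*k*(n - nb)/nb * dz)` per slice (`k` is the
#' background-medium wavenumber, so `k/nb` is the vacuum wavenumber). A
#' raised-cosine absorbing margin over the outer 10% of the transverse
#' grid is applied at each slice.
#'
#' @param phantom an `oct_phantom` (its `index_grid`, or rasterized on
#'   the fly).
#' @param k background-medium wavenumber (rad/m).
#' @param kx,ky transverse wavenumbers of the incident wave (rad/m).
#' @param config an [oct_system()].
#' @param vol optional precomputed [phantom_to_index_grid()] volume.
#' @param keep `"all"` to store every slice, or a numeric vector of z
#'   planes (m) to store (nearest slice).
#' @return object of class `volume_field`: list with `slices` (list of
#'   complex matrices), `z` (stored plane depths), `x`/`y` axes, `dz`,
#'   and `at(xs, ys, zs)` sampling via [volume_field_at()].
#' @export
multislice_incident_field <- function(phantom, k, kx = 0, ky = 0, config,
                                      vol = phantom_volume_grid(phantom),
                                      keep = "all") {
  nx <- length(vol$x)
  lamb <- 2 * pi / k
  # group raster cells into propagation slabs (default one cell per slab)
  slab <- if (is.null(vol$slab)) vol$cell else vol$slab
  per <- max(1L, as.integer(round(slab / vol$cell)))
  nzs <- length(vol$z)
  starts <- seq(1L, nzs, by = per)
  groups <- lapply(starts, function(s) s:min(s + per - 1L, nzs))
  zslab <- vapply(groups, function(g) mean(vol$z[g]), 1.0)
  dzs <- vapply(groups, function(g) length(g) * vol$cell, 1.0)
  contrast <- max(abs(vol$n - vol$nb)) / vol$nb
  if (contrast > 0 && max(dzs) * contrast >= lamb / 2)
    warning("slice spacing too coarse for the index contrast: ",
            "phase per screen may exceed pi")
  X <- matrix(vol$x, nx, nx)
  Y <- t(X)
  E <- exp(1i * (kx * X + ky * Y))
  dx <- vol$x[2] - vol$x[1]
  fr <- 2 * pi * fft_freq(nx) / dx
  KX <- matrix(fr, nx, nx)
  KY <- t(KX)
  kz2 <- k^2 - KX^2 - KY^2
  kz <- sqrt(pmax(kz2, 0))
  evan <- kz2 <= 0 # evanescent components dropped
  # raised-cosine absorbing margin (fraction of the half-extent; set
  # vol$absorb to 0 for an ideal periodic plane-wave run)
  afrac <- vol$absorb %||% 0.1
  edge <- max(abs(vol$x))
  absorb <- if (afrac > 0) {
    marg <- afrac * edge
    rmp <- function(u) {
      a <- pmax(abs(u) - (edge - marg), 0) / marg
      0.5 * (1 + cos(pi * pmin(a, 1)))
    }
    outer(rmp(vol$x), rmp(vol$x))
  } else NULL
  nsl <- length(groups)
  keep_idx <- if (identical(keep, "all")) seq_len(nsl) else
    vapply(keep, function(z) which.min(abs(zslab - z)), 1L)
  slices <- vector("list", length(keep_idx))
  # propagate from the top surface to the first slab center, then slab
  # center to slab center; the stored field is the field ARRIVING at each
  # slab (before that slab's own screen), which is the incident field a
  # scatterer there re-radiates in the Born picture (no self-interaction)
  prev <- 0
  for (j in seq_len(nsl)) {
    step <- zslab[j] - prev
    prop <- exp(1i * kz * step)
    prop[evan] <- 0
    E <- ifft2(fft2(E) * prop)
    hit <- which(keep_idx == j)
    if (length(hit)) for (h in hit) slices[[h]] <- E
    # projected phase screen of all cells in the slab (sparse: the
    # background contributes exactly zero phase)
    phs <- matrix(0, nx, nx)
    for (c_ in groups[[j]]) phs <- phs + (vol$n[, , c_] - vol$nb)
    phs <- phs * (k / vol$nb) * vol$cell
    nz_ <- phs != 0
    if (any(nz_)) E[nz_] <- E[nz_] * exp(1i * phs[nz_])
    if (!is.null(absorb)) E <- E * absorb
    prev <- zslab[j]
  }
  out <- list(slices = slices, z = zslab[keep_idx], x = vol$x, y = vol$y,
              dz = slab, k = k, kx = kx, ky = ky)
  class(out) <- "volume_field"
  out
}

#' Sample a volume field at scatterer positions
#'
#' Transverse bilinear sample of the stored slices at the given
#' positions; z snaps to the nearest stored plane, with the residual
#' axial distance compensated by the on-axis free phase `exp(i*k*(zs -
#' z_plane))` so that depth encoding is preserved between slab planes.
#'
#' When the sampled position is a scatterer that is itself rasterized in
#' the volume, pass a positive `standoff`: the field is then read at the
#' nearest plane above `zs - standoff` — upstream of the particle's own
#' phase screens — and advanced to `zs` with the free phase, which is the
#' incident field of the Born picture (no self-interaction).
#'
#' @param vf a `volume_field`.
#' @param xs,ys,zs position vectors (m).
#' @param standoff sampling offset above each position (m, default 0).
#' @return complex vector of field values.
#' @export
volume_field_at <- function(vf, xs, ys, zs, standoff = 0) {
  dx <- vf$x[2] - vf$x[1]
  n <- length(vf$z)
  # nearest stored plane (vectorized)
  iz <- if (n == 1L) rep(1L, length(zs)) else {
    mids <- (vf$z[-1] + vf$z[-n]) / 2
    findInterval(zs - standoff, mids) + 1L
  }
  fx <- (xs - vf$x[1]) / dx + 1
  fy <- (ys - vf$y[1]) / dx + 1
  x0 <- floor(fx); y0 <- floor(fy)
  tx <- fx - x0; ty <- fy - y0
  nx <- length(vf$x)
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, nx)
  out <- complex(length(xs))
  for (u in unique(iz)) {
    j <- which(iz == u)
    S <- vf$slices[[u]]
    out[j] <- ((1 - tx[j]) * (1 - ty[j]) * S[cbind(x0[j], y0[j])] +
                 tx[j] * (1 - ty[j]) * S[cbind(x1[j], y0[j])] +
                 (1 - tx[j]) * ty[j] * S[cbind(x0[j], y1[j])] +
                 tx[j] * ty[j] * S[cbind(x1[j], y1[j])]) *
      exp(1i * vf$k * (zs[j] - vf$z[u]))
  }
  out
}

#' First-Born return path: scattered back-focal-plane field
#'
#' Each scatterer re-radiates the locally incident field once: the
#' back-focal-plane map is the coherent sum over scatterers of
#' `amp * E_inc(r_s) * h(x, y; r_s)`, where `h` is the paraxial
#' point-source-to-back-focal-plane response of [point_scatterer_g1()]
#' with the one-way incident phase factored out (the incident field
#' supplies it), and the lens displaced to `(xd, yd)`.
#'
#' @param phantom an `oct_phantom`.
#' @param incident a `volume_field` from [multislice_incident_field()],
#'   computed for the same `k`, or `NULL` for free-space incidence
#'   `exp(i*(kx*xs + ky*ys + kz_par*zs))`.
#' @param k wavenumber (rad/m).
#' @param xd,yd lens displacement (m).
#' @param config an [oct_system()].
#' @param grid optional [aperture_grid()].
#' @param standoff Born sampling standoff passed to [volume_field_at()]
#'   when the scatterers are rasterized into the incident-field volume.
#' @return a `field_map` (unwindowed; windowing happens at recording).
#' @export
born_scattered_g <- function(phantom, incident, k, xd = 0, yd = 0, config,
                             grid = aperture_grid(config), standoff = 0) {
  s <- phantom$scatterers
  lam <- 2 * pi / k
  f2 <- config$f2
  Einc <- if (is.null(incident)) {
    exp(1i * k * s$zs)
  } else {
    volume_field_at(incident, s$xs, s$ys, s$zs, standoff = standoff)
  }
  # each scatterer's response is separable, outer(ux_s, uy_s); the
  # coherent sum over scatterers is one rank-S complex matrix product
  xb <- grid$x - xd
  yb <- grid$y - yd
  UX <- exp(outer(xb^2, -1i * k * s$zs / (2 * f2^2)) +
              outer(xb, 1i * k / f2 * (s$xs - xd)))
  UY <- exp(outer(yb^2, -1i * k * s$zs / (2 * f2^2)) +
              outer(yb, 1i * k / f2 * (s$ys - yd)))
  cs <- s$amp * Einc * exp(1i * k * s$zs) / (1i * lam * f2)
  v <- UX %*% t(UY * matrix(cs, length(yb), length(cs), byrow = TRUE))
  new_field_map(v, k, kx = if (is.null(incident)) 0 else incident$kx,
                ky = if (is.null(incident)) 0 else incident$ky,
                xd = xd, yd = yd, windowed = FALSE)
}
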