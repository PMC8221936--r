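#' Direct (non-synthesized) B-scan of a point-scatterer phantom
#'
#' Reference simulation of scanned focussed-beam acquisition: the beam is
#' decomposed into tilted plane waves on the same angular grid used by
#' the synthesis engine, each component's scattered field is evaluated
#' exactly from first principles ([point_scatterer_g2_direct()] — no
#' translation approximation), coupled into the fiber, and the A-scan
#' formed spectrally. Discrepancies between this image and
#' [synthesize_bscan()] therefore isolate the translation (assumed-depth)
#' approximation, not numerics.
#'
#' @param phantom an `oct_phantom` (point-scatterer list).
#' @param scan_xs lateral scan positions (m).
#' @param config an [oct_system()].
#' @param spec optional [build_spectral_grid()].
#' @param z_range depth range of the output (m).
#' @param z_ref reference-arm offset (m).
#' @param method `"fast"` (factorized, algebraically identical) or
#'   `"literal"` (per-angle field maps; for small cross-checks).
#' @param window apply the recorded-field guard window at the translated
#'   radius, as the synthesis chain implicitly does (default TRUE; set
#'   FALSE to compare against references with no recording step, such as
#'   [direct_bscan_multislice()]).
#' @return an `oct_image` with provenance `"direct"`.
#' @export
direct_bscan_points <- function(phantom, scan_xs, config,
                                spec = build_spectral_grid(config),
                                z_range = NULL, z_ref = 0,
                                method = c("fast", "literal"),
                                window = TRUE) {
  method <- match.arg(method)
  amirr <- reference_arm_spectrum(spec, config, z_ref)
  a3 <- if (method == "fast") {
    direct_coupling_spectra_points(phantom, scan_xs, config, spec,
                                   window = window)
  } else {
    direct_coupling_spectra_points_literal(phantom, scan_xs, config, spec,
                                           window = window)
  }
  bscan_from_a3(a3, amirr, spec, scan_xs, z_range, provenance = "direct")
}

# factorized evaluation: for each (k, scan, scatterer) the angular
# dependence of the coupling integral enters only through the guard
# window at the translated radius, so the angle sum reduces to a
# cross-correlation with the window evaluated on the translation lattice
# (same machinery as the synthesis engine), times analytic per-angle
# prefactors.
direct_coupling_spectra_points <- function(phantom, scan_xs, config, spec,
                                           yd = 0, window = TRUE) {
  eng <- synth_engine(config, scan_xs, yd)
  grid <- eng$grid
  f2 <- config$f2
  na <- config$n_angle
  s <- phantom$scatterers
  tauhat <- fft2(pad_matrix(grid$taper + 0i, eng$pad))
  DX <- matrix(eng$Dx_lat, na, na)
  DY <- t(DX)
  nk <- length(spec$k)
  a3 <- matrix(0 + 0i, nk, length(scan_xs))
  for (i in seq_len(nk)) {
    k <- spec$k[i]
    lam <- 2 * pi / k
    kx_lat <- k * numerical_aperture(config) * eng$tfrac
    KXl <- matrix(kx_lat, na, na)
    KYl <- t(KXl)
    kt2 <- KXl^2 + KYl^2
    wq <- (2 * k * numerical_aperture(config) / na)^2
    for (j in seq_along(scan_xs)) {
      xd <- scan_xs[j]
      acc <- matrix(0 + 0i, na, na)
      for (q in seq_len(nrow(s))) {
        ux <- exp(-1i * k * s$zs[q] / (2 * f2^2) * (grid$x - xd)^2 +
                    1i * k / f2 * (s$xs[q] - xd) * (grid$x - xd))
        uy <- exp(-1i * k * s$zs[q] / (2 * f2^2) * (grid$y - yd)^2 +
                    1i * k / f2 * (s$ys[q] - yd) * (grid$y - yd))
        V <- eng$modes[[j]] * outer(ux, uy)
        S <- if (window) {
          Vhat <- Conj(fft2(pad_matrix(Conj(V), eng$pad)))
          t(eng$Ex[[j]]) %*% (Vhat * tauhat) %*% eng$Ey[[j]] / eng$np^2
        } else {
          matrix(sum(V), na, na)
        }
        pref <- s$amp[q] / (1i * lam * f2) * exp(1i * 2 * k * s$zs[q]) *
          exp(-1i * s$zs[q] * kt2 / (2 * k)) *
          exp(1i * (KXl * (s$xs[q] - xd) + KYl * (s$ys[q] - yd)))
        acc <- acc + pref * S
      }
      a3[i, j] <- sum((eng$phif * acc)[eng$disk]) * wq
    }
  }
  a3
}

direct_coupling_spectra_points_literal <- function(phantom, scan_xs, config,
                                                   spec, yd = 0,
                                                   window = TRUE) {
  grid <- aperture_grid(config)
  s <- phantom$scatterers
  nk <- length(spec$k)
  a3 <- matrix(0 + 0i, nk, length(scan_xs))
  for (i in seq_len(nk)) {
    k <- spec$k[i]
    ang <- angular_grid(k, config)
    phif <- source_angular_spectrum(ang, k, config)
    for (j in seq_along(scan_xs)) {
      xd <- scan_xs[j]
      acc <- 0 + 0i
      for (a in seq_len(nrow(ang$nodes))) {
        v <- matrix(0 + 0i, config$bfp_samples, config$bfp_samples)
        for (q in seq_len(nrow(s))) {
          g2 <- point_scatterer_g2_direct(s[q, ], k, ang$nodes$kx[a],
                                          ang$nodes$ky[a], xd, yd,
                                          config, grid = grid,
                                          window = window)
          v <- v + g2$values
        }
        fm <- new_field_map(v, k, ang$nodes$kx[a], ang$nodes$ky[a], xd, yd)
        acc <- acc + couple_to_fiber(fm, xd, yd, config, grid = grid) *
          phif[a] * ang$nodes$w[a]
      }
      a3[i, j] <- acc
    }
  }
  a3
}

#' Direct B-scan through the multi-slice solver
#'
#' The expensive reference the synthesis avoids: for every wavenumber and
#' every plane-wave component of the focussed beam, the incident field is
#' propagated through the phantom with the split-step solver; each
#' scatterer re-radiates the locally incident field (first Born) through
#' the displaced-lens paraxial return path, and the angular superposition,
#' fiber coupling and spectral reconstruction follow. Implemented by
#' linearity: the per-angle incident fields are sampled at the scatterer
#' positions once per (k, angle) and re-weighted per scan position.
#'
#' @inheritParams direct_bscan_points
#' @param ms multislice volume options (see [compute_g1_cube()]).
#' @param n_angle angular samples per axis (default `config$n_angle`).
#' @return an `oct_image` with provenance `"direct"`.
#' @export
direct_bscan_multislice <- function(phantom, scan_xs, config,
                                    spec = build_spectral_grid(config),
                                    z_range = NULL, z_ref = 0,
                                    ms = list(), n_angle = config$n_angle) {
  grid <- aperture_grid(config)
  f2 <- config$f2
  s <- phantom$scatterers
  nsc <- nrow(s)
  vol <- do.call(phantom_volume_grid, c(list(phantom), ms))
  amirr <- reference_arm_spectrum(spec, config, z_ref)
  nk <- length(spec$k)
  a3 <- matrix(0 + 0i, nk, length(scan_xs))
  for (i in seq_len(nk)) {
    k <- spec$k[i]
    ang <- angular_grid(k, config, n_angle = n_angle)
    phif <- source_angular_spectrum(ang, k, config)
    nodes <- ang$nodes
    # incident field at every scatterer for every plane-wave component
    # (sampled upstream of each particle's own screens: Born picture)
    so <- born_standoff(vol)
    Einc <- matrix(0 + 0i, nsc, nrow(nodes))
    for (a in seq_len(nrow(nodes))) {
      vf <- multislice_incident_field(phantom, k, nodes$kx[a], nodes$ky[a],
                                      config, vol = vol)
      Einc[, a] <- volume_field_at(vf, s$xs, s$ys, s$zs, standoff = so)
    }
    for (j in seq_along(scan_xs)) {
      xd <- scan_xs[j]
      # focussed incident field at each scatterer for this scan position
      wts <- phif * nodes$w * exp(-1i * nodes$kx * xd)
      Finc <- Einc %*% wts
      # coupled return response of each scatterer (angle-independent);
      # separable integrand, evaluated as matrix products over scatterers
      lam <- 2 * pi / k
      xb <- grid$x - xd
      UX <- exp(outer(xb^2, -1i * k * s$zs / (2 * f2^2)) +
                  outer(xb, 1i * k / f2 * (s$xs - xd)))
      UY <- exp(outer(grid$y^2, -1i * k * s$zs / (2 * f2^2)) +
                  outer(grid$y, 1i * k / f2 * s$ys))
      modeM <- fiber_mode(grid, xd, 0, config) * grid$dx^2
      resp <- colSums(UY * (t(modeM) %*% UX)) *
        exp(1i * k * s$zs) / (1i * lam * f2)
      a3[i, j] <- sum(s$amp * Finc * resp)
    }
  }
  bscan_from_a3(a3, amirr, spec, scan_xs, z_range, provenance = "direct")
}

#' Directly evaluated vs synthesized internal plane fields
#'
#' Propagates a normally incident and a tilted plane wave through the
#' phantom with the split-step solver, extracts both fields at the plane
#' `plane_z`, and builds the synthesized tilted field by applying to the
#' normal-incidence field the free-space phase ramp a tilt would produce:
#' `exp(i*(kx*x + ky*y + (kz - k)*plane_z))`. Both fields are restricted
#' to a centered square region of interest.
#'
#' @param phantom an `oct_phantom` (with or convertible to an index grid).
#' @param k wavenumber (rad/m).
#' @param theta_i tilt angle (rad) about the y axis: `kx = k*sin(theta_i)`.
#' @param plane_z depth of the inspected plane (m).
#' @param config an [oct_system()].
#' @param roi side length of the square region of interest (m).
#' @param ms multislice volume options.
#' @return list with complex matrices `E_ref` (direct tilted), `E_synth`
#'   (ramped normal-incidence), `E_normal`, axes `x`, `y` (ROI), and the
#'   tilt `kx`.
#' @export
internal_plane_fields <- function(phantom, k, theta_i, plane_z, config,
                                  roi = 50e-6, ms = list()) {
  vol <- do.call(phantom_volume_grid, c(list(phantom), ms))
  if (plane_z < min(vol$z) - vol$cell || plane_z > max(vol$z) + vol$cell)
    stop("plane_z lies outside the phantom volume")
  kx <- k * sin(theta_i)
  kz <- sqrt(k^2 - kx^2)
  En <- multislice_incident_field(phantom, k, 0, 0, config, vol = vol,
                                  keep = plane_z)
  Et <- multislice_incident_field(phantom, k, kx, 0, config, vol = vol,
                                  keep = plane_z)
  zst <- En$z[1]
  sel <- abs(vol$x) <= roi / 2
  X <- matrix(vol$x[sel], sum(sel), sum(sel))
  E_normal <- En$slices[[1]][sel, sel]
  E_ref <- Et$slices[[1]][sel, sel]
  E_synth <- E_normal * exp(1i * (kx * X + (kz - k) * zst))
  list(E_ref = E_ref, E_synth = E_synth, E_normal = E_normal,
       x = vol$x[sel], y = vol$x[sel], kx = kx, plane_z = zst)
}
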