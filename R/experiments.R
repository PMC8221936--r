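#' Synthesized vs direct PSF B-scan comparison
#'
#' Reproduces the axial point-spread-function experiment: a column of
#' on-axis point scatterers (default 9, spaced 152 cells of lambda0/6 =
#' 32.93 um, first at focus) is imaged both by the synthetic-scanning
#' chain (normal-incidence record, translation synthesis, assumed-depth
#' bands 0:50:250 um) and by the direct scanned-focussed-beam reference,
#' with identical angular quadrature, fiber model and spectral grid.
#'
#' @param config an [oct_system()]. The default uses the 36 mm / 3.5 mm
#'   objective at 1.3 um; spectral/angular/scan sampling are set by the
#'   remaining arguments.
#' @param n_points number of scatterers.
#' @param spacing axial spacing (m).
#' @param zs_list assumed depths (m).
#' @param scan_xs scan positions (m); default 21 positions at 1.95 um.
#' @return list with `synth`, `direct` (`oct_image`s on identical axes),
#'   `eps` (the depth-resolved error profile), `max_diff_pct`
#'   (max |difference| as percent of the PSF maximum), `peaks_synth`
#'   (refined peak depths, m), `config`.
#' @export
psf_comparison <- function(config = oct_system(n_k = 256L, n_angle = 31L,
                                               bfp_samples = 96L),
                           n_points = 9L,
                           spacing = 152 * 1.3e-6 / 6,
                           zs_list = seq(0, 250e-6, by = 50e-6),
                           scan_xs = (seq_len(21L) - 11L) * 1.95e-6) {
  phantom <- make_axial_point_grid(n_points, spacing, 0, nb = config$nb)
  spec <- build_spectral_grid(config)
  dzs <- if (length(zs_list) > 1) diff(zs_list)[1] else Inf
  z_range <- c(0, max(zs_list) + dzs / 2)
  cube <- compute_g1_cube(phantom, config, spec)
  synth <- synthesize_bscan(cube, scan_xs, zs_list, config, z_range = z_range)
  direct <- direct_bscan_points(phantom, scan_xs, config, spec,
                                z_range = z_range)
  eps <- error_metric(direct, synth)
  mx <- max(abs(direct$values))
  list(synth = synth, direct = direct, eps = eps,
       max_diff_pct = 100 * max(abs(abs(direct$values) - abs(synth$values))) / mx,
       peaks_synth = find_axial_peaks(synth, n_points,
                                      min_separation = spacing / 2),
       peaks_direct = find_axial_peaks(direct, n_points,
                                       min_separation = spacing / 2),
       phantom = phantom, config = config)
}

#' Error metric evaluated at the scatterer peak depths
#'
#' @param res a [psf_comparison()] result.
#' @return data.frame with the scatterer depths, nearest depth bins and
#'   `eps` values there.
#' @export
psf_peak_errors <- function(res) {
  zs <- res$phantom$scatterers$zs
  idx <- vapply(zs, function(z) which.min(abs(res$synth$z - z)), 1L)
  data.frame(zs = zs, z_bin = res$synth$z[idx], eps = res$eps$eps[idx])
}

#' Synthesized A-scan of an isolated scatterer under tilted illumination
#'
#' A single sub-resolution scatterer is illuminated by one tilted plane
#' wave (`kx = k*sin(theta_i)` at every wavenumber); its isolated
#' scattered field is synthesized from the normal-incidence record via
#' the translation relation with the given assumed depth, coupled into
#' the fiber, and reconstructed. Used to verify that the A-scan peak
#' stays at the scatterer depth even when the assumed depth is the band
#' center, not the true depth.
#'
#' @param depth true scatterer depth (m); default 61.75 um.
#' @param theta_i tilt angle (rad); default 0.0762.
#' @param zs_assumed assumed depth (m); default the 50 um band center
#'   whose band `[25, 75) um` contains the default scatterer.
#' @param config an [oct_system()].
#' @return list with `z`, `magnitude` (synthesized A-scan), `peak_depth`
#'   (refined, m), `a3` (coupled spectrum), `spec`.
#' @export
isolated_scatterer_ascan <- function(depth = 61.75e-6, theta_i = 0.0762,
                                     zs_assumed = 50e-6,
                                     config = oct_system(n_k = 256L,
                                                         bfp_samples = 128L)) {
  phantom <- make_single_scatterer(depth, nb = config$nb)
  spec <- build_spectral_grid(config)
  grid <- aperture_grid(config)
  cube <- compute_g1_cube(phantom, config, spec)
  a3 <- complex(length(spec$k))
  for (i in seq_along(spec$k)) {
    k <- spec$k[i]
    kx <- k * sin(theta_i)
    g2 <- synthesize_g2(cube$maps[[i]], kx = kx, ky = 0, xd = 0, yd = 0,
                        zs_assumed = zs_assumed, config, grid = grid)
    a3[i] <- couple_to_fiber(g2, 0, 0, config, grid = grid)
  }
  amirr <- reference_arm_spectrum(spec, config)
  asc <- form_ascan(a3, amirr, spec)
  pk <- find_axial_peaks(list(z = asc$z, magnitude = asc$magnitude), 1L)
  list(z = asc$z, magnitude = asc$magnitude, peak_depth = pk,
       a3 = a3, spec = spec, config = config)
}

#' Isolated-scatterer study inside a scattering medium
#'
#' The isolated backscattered field of one probe scatterer embedded in a
#' scattering phantom, compared between three routes at a given tilt
#' angle: directly evaluated (tilted split-step incident field), the
#' synthesis from the normal-incidence record, and the "corrected"
#' synthesis where the assumed incident field at the scatterer is
#' replaced by the directly evaluated one (uniform per-k rescale).
#'
#' @param phantom scattering `oct_phantom` (the probe scatterer is added
#'   separately and does not perturb the forward field).
#' @param probe length-3 position of the probe scatterer (m).
#' @param theta_i tilt angle (rad).
#' @param zs_assumed assumed depth for the synthesis (m).
#' @param config an [oct_system()].
#' @param spec a [build_spectral_grid()]; keep `n_k` modest (the solver
#'   runs twice per wavenumber).
#' @param ms multislice options.
#' @return list of A-scans `direct`, `synth`, `corrected` (each with `z`,
#'   `magnitude`), summed-error values `err_synth`, `err_corrected`
#'   (error metric vs the direct A-scan, summed over depth), and the
#'   per-k incident fields.
#' @export
isolated_in_medium_study <- function(phantom, probe = c(0, 0, 61.75e-6),
                                     theta_i = 0.0762, zs_assumed = 50e-6,
                                     config, spec = build_spectral_grid(config),
                                     ms = list()) {
  vol <- do.call(phantom_volume_grid, c(list(phantom), ms))
  grid <- aperture_grid(config)
  sprobe <- make_single_scatterer(probe[3], probe[1], probe[2],
                                  nb = phantom$nb)
  nk <- length(spec$k)
  a3_dir <- a3_syn <- complex(nk)
  Et_s <- En_s <- Ea_s <- complex(nk)
  for (i in seq_len(nk)) {
    k <- spec$k[i]
    kx <- k * sin(theta_i)
    kz <- sqrt(k^2 - kx^2)
    En <- multislice_incident_field(phantom, k, 0, 0, config, vol = vol,
                                    keep = probe[3])
    Et <- multislice_incident_field(phantom, k, kx, 0, config, vol = vol,
                                    keep = probe[3])
    zst <- En$z[1]
    En_s[i] <- volume_field_at(En, probe[1], probe[2], probe[3])
    Et_s[i] <- volume_field_at(Et, probe[1], probe[2], probe[3])
    Ea_s[i] <- En_s[i] * exp(1i * (kx * probe[1] + (kz - k) * zst))
    # direct: probe re-radiates the true tilted field
    gd <- born_scattered_g(sprobe, NULL, k, 0, 0, config, grid = grid)
    gd$values <- gd$values / exp(1i * k * probe[3]) # strip free-space inc.
    vdir <- new_field_map(gd$values * Et_s[i] * grid$taper, k)
    a3_dir[i] <- couple_to_fiber(vdir, 0, 0, config, grid = grid)
    # synthesized: normal-incidence isolated record, translated
    g1iso <- new_field_map(gd$values * En_s[i] * grid$taper, k,
                           windowed = TRUE)
    g2 <- synthesize_g2(g1iso, kx = kx, ky = 0, xd = 0, yd = 0,
                        zs_assumed = zs_assumed, config, grid = grid)
    a3_syn[i] <- couple_to_fiber(g2, 0, 0, config, grid = grid)
  }
  amirr <- reference_arm_spectrum(spec, config)
  dirA <- form_ascan(a3_dir, amirr, spec)
  synA <- form_ascan(a3_syn, amirr, spec)
  corA <- corrected_ascan(a3_syn, incident_true = Et_s,
                          incident_assumed = Ea_s, amirr, spec)
  sum_err <- function(a) {
    img_r <- oct_image(matrix(dirA$magnitude, ncol = 1), dirA$z, 0, "direct")
    img_s <- oct_image(matrix(a$magnitude, ncol = 1), a$z, 0, "synthesized")
    sum(error_metric(img_r, img_s)$eps, na.rm = TRUE)
  }
  list(direct = dirA, synth = synA, corrected = corA,
       err_synth = sum_err(synA), err_corrected = sum_err(corA),
       E_true = Et_s, E_normal = En_s, E_assumed = Ea_s)
}
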