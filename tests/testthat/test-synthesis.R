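test_that("translation synthesis degenerates to the identity and pure shifts", {
  cfg <- mid_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[16]
  s <- list(xs = 0, ys = 0, zs = 120e-6, amp = 1)
  g1 <- point_scatterer_g1(s, k, cfg, grid)

  # no tilt, no scan: identity for any assumed depth
  g2 <- synthesize_g2(g1, 0, 0, 0, 0, zs_assumed = 77e-6, config = cfg,
                      grid = grid)
  expect_lt(rel_l2(g2$values, g1$values), 1e-10)

  # in-focus record, tilt only: pure translation, no phase factors
  s0 <- list(xs = 3e-6, ys = 0, zs = 0, amp = 1)
  g10 <- point_scatterer_g1(s0, k, cfg, grid)
  kx <- 0.05 * k
  g2t <- synthesize_g2(g10, kx, 0, 0, 0, zs_assumed = 0, config = cfg,
                       grid = grid)
  shifted <- fourier_shift(g10$values, kx * cfg$f2 / k, 0, grid$dx)
  expect_lt(rel_l2(g2t$values, shifted), 1e-12)

  # shift beyond the padded grid is refused
  expect_error(synthesize_g2(g10, kx = 0.9 * k, ky = 0, config = cfg,
                             grid = grid), "padded grid")
})

test_that("synthesis matches the tilted direct oracle at the true depth", {
  cfg <- oct_system(n_k = 4L, bfp_samples = 256L, n_angle = 9L)
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[2]
  set.seed(101)
  for (i in 1:5) {
    s <- list(xs = stats::runif(1, -30e-6, 30e-6),
              ys = stats::runif(1, -30e-6, 30e-6),
              zs = stats::runif(1, 0, 260e-6), amp = 1)
    th <- stats::runif(1, 0, 0.07)
    phi <- stats::runif(1, 0, 2 * pi)
    kx <- k * sin(th) * cos(phi)
    ky <- k * sin(th) * sin(phi)
    xd <- stats::runif(1, -40e-6, 40e-6)
    yd <- stats::runif(1, -40e-6, 40e-6)
    g1 <- point_scatterer_g1(s, k, cfg, grid)
    g2 <- synthesize_g2(g1, kx, ky, xd, yd, zs_assumed = s$zs, config = cfg,
                        grid = grid)
    gd <- point_scatterer_g2_direct(s, k, kx, ky, xd, yd, cfg, grid)
    expect_lt(rel_l2(g2$values, gd$values), 1e-6)
  }
})

test_that("factorized coupling equals the literal per-angle chain", {
  cfg <- oct_system(n_k = 3L, bfp_samples = 96L, n_angle = 7L)
  spec <- build_spectral_grid(cfg)
  grid <- aperture_grid(cfg)
  ph <- make_axial_point_grid(2L, 40e-6, 10e-6)
  cube <- compute_g1_cube(ph, cfg, spec)
  scan <- c(-5e-6, 3e-6)
  zs <- 30e-6
  eng <- octsynth:::synth_engine(cfg, scan)
  a3f <- octsynth:::synth_coupling_spectra(cube, eng, zs, cfg)
  a3l <- matrix(0 + 0i, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    g3 <- synthesize_g3(cube$maps[[i]], scan[j], 0, zs, cfg, grid = grid)
    a3l[i, j] <- couple_to_fiber(g3, scan[j], 0, cfg, grid = grid)
  }
  expect_lt(max(Mod(a3f - a3l)) / max(Mod(a3l)), 1e-10)

  # direct arm: factorized vs literal (window interpolated vs analytic)
  a3df <- octsynth:::direct_coupling_spectra_points(ph, scan, cfg, spec)
  a3dl <- octsynth:::direct_coupling_spectra_points_literal(ph, scan, cfg, spec)
  expect_lt(max(Mod(a3df - a3dl)) / max(Mod(a3dl)), 1e-5)
})

test_that("delta-like angular spectrum makes g3 proportional to g1", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[4]
  g1 <- point_scatterer_g1(list(xs = 0, ys = 0, zs = 30e-6, amp = 1), k,
                           cfg, grid)
  ang <- angular_grid(k, cfg)
  keep <- which(ang$nodes$kx == 0 & ang$nodes$ky == 0)
  ang$nodes <- ang$nodes[keep, ]
  g3 <- synthesize_g3(g1, 0, 0, 30e-6, cfg, ang = ang, grid = grid)
  ratio <- g3$values[grid$mask] / g1$values[grid$mask]
  expect_lt(stats::sd(Mod(ratio)) / mean(Mod(ratio)), 1e-10)
})

test_that("fiber coupling obeys parity, the inner-product identity and linearity", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[4]
  # odd field x even mode -> zero
  odd <- new_field_map(grid$X + 0i, k)
  expect_lt(Mod(couple_to_fiber(odd, 0, 0, cfg, grid)),
            1e-12 * max(abs(grid$X)))
  # g3 = conj(mode) -> real positive mode power inside the aperture
  m <- fiber_mode(grid, 0, 0, cfg)
  g <- new_field_map(Conj(m) + 0i, k)
  a <- couple_to_fiber(g, 0, 0, cfg, grid)
  expect_equal(Im(a), 0, tolerance = 1e-14)
  expect_equal(Re(a), sum(Mod(m)^2) * grid$dx^2, tolerance = 1e-12)
  # linearity
  g2 <- new_field_map((2 - 3i) * Conj(m), k)
  expect_equal(couple_to_fiber(g2, 0, 0, cfg, grid), (2 - 3i) * a,
               tolerance = 1e-12)
})

test_that("A-scan formation places peaks at the round-trip depths", {
  cfg <- oct_system(n_k = 128L)
  spec <- build_spectral_grid(cfg)
  amirr <- reference_arm_spectrum(spec, cfg)
  dz <- depth_bin(spec)
  # mirror A-scan: reference offset moves the peak to z_ref
  zr <- 40e-6
  a3 <- reference_arm_spectrum(spec, cfg, z_ref = zr)
  asc <- form_ascan(a3, amirr, spec)
  pk <- find_axial_peaks(list(z = asc$z, magnitude = asc$magnitude), 1L)
  expect_lt(abs(pk - zr), dz)
  # two reflectors spaced d apart -> two peaks spaced d apart
  d <- 60e-6
  a32 <- reference_arm_spectrum(spec, cfg, z_ref = 30e-6) +
    reference_arm_spectrum(spec, cfg, z_ref = 30e-6 + d)
  asc2 <- form_ascan(a32, amirr, spec)
  pks <- find_axial_peaks(list(z = asc2$z, magnitude = asc2$magnitude), 2L,
                          min_separation = d / 2)
  expect_lt(abs(diff(pks) - d), dz)
  # non-uniform grids are refused
  bad <- spec
  bad$k[5] <- bad$k[5] * 1.001
  expect_error(form_ascan(a3, amirr, bad), "uniform")
})

test_that("B-scan stitching respects bands, seams and coverage errors", {
  cfg <- oct_system(n_k = 64L, bfp_samples = 64L, n_angle = 7L)
  spec <- build_spectral_grid(cfg)
  ph <- make_single_scatterer(20e-6)
  cube <- compute_g1_cube(ph, cfg, spec)
  # single-band image equals the zs = 0 reconstruction
  img1 <- synthesize_bscan(cube, 0, 0, cfg, z_range = c(0, 50e-6))
  eng <- octsynth:::synth_engine(cfg, 0)
  a3 <- octsynth:::synth_coupling_spectra(cube, eng, 0, cfg)
  asc <- form_ascan(a3[, 1], reference_arm_spectrum(spec, cfg), spec)
  keep <- asc$z < 50e-6
  expect_equal(img1$values[, 1], asc$magnitude[keep], tolerance = 1e-12)
  # band bookkeeping: half-open bands centered on each assumed depth
  img <- synthesize_bscan(cube, 0, seq(0, 100e-6, 50e-6), cfg)
  expect_equal(img$bands$lo, c(-25e-6, 25e-6, 75e-6))
  expect_equal(img$bands$hi, c(25e-6, 75e-6, 125e-6))
  # depth range beyond the unambiguous depth errors
  expect_error(synthesize_bscan(cube, 0, seq(0, 250e-6, 50e-6), cfg),
               "unambiguous")
  # bands not covering the requested range error
  expect_error(synthesize_bscan(cube, 0, c(0, 50e-6), cfg,
                                z_range = c(0, 120e-6)), "cover")
})

test_that("synthesized images shift with the scatterer (lateral equivariance)", {
  cfg <- oct_system(n_k = 32L, bfp_samples = 192L, n_angle = 9L)
  spec <- build_spectral_grid(cfg)
  pitch <- 1.95e-6
  scan <- (seq_len(7L) - 4L) * pitch
  p0 <- make_single_scatterer(50e-6)
  p1 <- make_single_scatterer(50e-6, xs = pitch)
  i0 <- synthesize_bscan(compute_g1_cube(p0, cfg, spec), scan, c(0, 50e-6), cfg)
  i1 <- synthesize_bscan(compute_g1_cube(p1, cfg, spec), scan, c(0, 50e-6), cfg)
  expect_lt(rel_l2(i1$values[, 2:7], i0$values[, 1:6]), 1e-4)
})

test_that("peak error grows monotonically with assumed-depth mismatch", {
  cfg <- oct_system(n_k = 64L, bfp_samples = 96L, n_angle = 9L)
  spec <- build_spectral_grid(cfg)
  ph <- make_single_scatterer(50e-6)
  cube <- compute_g1_cube(ph, cfg, spec)
  eng <- octsynth:::synth_engine(cfg, 0)
  amirr <- reference_arm_spectrum(spec, cfg)
  dir <- direct_bscan_points(ph, 0, cfg, spec, z_range = c(0, 150e-6))
  pk_dir <- max(dir$values)
  errs <- vapply(c(0, 10e-6, 20e-6), function(dzs) {
    a3 <- octsynth:::synth_coupling_spectra(cube, eng, 50e-6 + dzs, cfg)
    asc <- form_ascan(a3[, 1], amirr, spec)
    abs(max(asc$magnitude[asc$z < 150e-6]) - pk_dir) / pk_dir
  }, 1.0)
  expect_lt(errs[1], 1e-5)
  expect_true(all(diff(errs) > 0))
})

test_that("uniform correction cannot move the A-scan peak and is exact when trivial", {
  cfg <- oct_system(n_k = 64L)
  spec <- build_spectral_grid(cfg)
  amirr <- reference_arm_spectrum(spec, cfg)
  a3 <- reference_arm_spectrum(spec, cfg, z_ref = 30e-6)
  # homogeneous medium: true incident equals assumed -> unchanged
  one <- rep(1 + 0i, length(spec$k))
  cor1 <- corrected_ascan(a3, one, one, amirr, spec)
  base <- form_ascan(a3, amirr, spec)
  expect_equal(cor1$magnitude, base$magnitude, tolerance = 1e-12)
  # constant complex correction preserves the argmax
  rho <- rep(0.7 * exp(0.3i), length(spec$k))
  cor2 <- corrected_ascan(a3, rho, one, amirr, spec)
  expect_equal(which.max(cor2$magnitude), which.max(base$magnitude))
  expect_error(corrected_ascan(a3, one, 0 * one, amirr, spec), "zero")
})
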