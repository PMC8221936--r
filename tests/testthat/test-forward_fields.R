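test_that("g1 of canonical scatterers matches the closed forms", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[4]
  lam <- 2 * pi / k

  # in-focus on-axis scatterer: constant modulus 1/(lam*f2), phase -pi/2
  g <- point_scatterer_g1(list(xs = 0, ys = 0, zs = 0, amp = 1), k, cfg,
                          grid, window = FALSE)
  expect_equal(Mod(g$values), matrix(1 / (lam * cfg$f2), 64, 64),
               tolerance = 1e-12)
  expect_equal(Arg(g$values), matrix(-pi / 2, 64, 64), tolerance = 1e-12)

  # lateral offset: pure linear phase ramp of slope k*xs/f2 along x
  xs <- 10e-6
  g <- point_scatterer_g1(list(xs = xs, ys = 0, zs = 0, amp = 1), k, cfg,
                          grid, window = FALSE)
  ph <- Arg(g$values[, 32] / g$values[1, 32])
  ramp <- wrap_phase(k * xs / cfg$f2 * (grid$x - grid$x[1]))
  expect_equal(wrap_phase(ph), ramp, tolerance = 1e-9)

  # depth: quadratic phase -k*zs/(2*f2^2)*r^2 plus global 2*k*zs
  zs <- 50e-6
  g <- point_scatterer_g1(list(xs = 0, ys = 0, zs = zs, amp = 1), k, cfg,
                          grid, window = FALSE)
  pred <- exp(1i * (2 * k * zs - pi / 2 - k * zs / (2 * cfg$f2^2) * grid$R2))
  expect_lt(rel_l2(g$values * lam * cfg$f2, pred), 1e-12)

  expect_error(point_scatterer_g1(list(xs = 0, ys = 0, zs = 0, amp = 1),
                                  -1, cfg, grid), "k must be")
})

test_that("tilted direct field reduces to g1 and rejects bad directions", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[4]
  s <- list(xs = 5e-6, ys = -2e-6, zs = 80e-6, amp = 1)
  gd <- point_scatterer_g2_direct(s, k, 0, 0, 0, 0, cfg, grid)
  g1 <- point_scatterer_g1(s, k, cfg, grid)
  expect_equal(gd$values, g1$values, tolerance = 1e-12)
  expect_error(point_scatterer_g2_direct(s, k, kx = 1.2 * k, ky = 0,
                                         config = cfg, grid = grid),
               "evanescent|cutoff")
  expect_error(point_scatterer_g2_direct(s, k, kx = 0.5 * k, ky = 0,
                                         config = cfg, grid = grid),
               "cutoff")
})

test_that("field operations are linear over scatterers and amplitudes", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  spec <- build_spectral_grid(cfg)
  k <- spec$k[2]
  s1 <- list(xs = 0, ys = 0, zs = 20e-6, amp = 1)
  s2 <- list(xs = 8e-6, ys = 0, zs = 90e-6, amp = 2i)
  ga <- point_scatterer_g1(s1, k, cfg, grid)
  gb <- point_scatterer_g1(s2, k, cfg, grid)
  ph <- make_axial_point_grid(1L, 1e-6, 20e-6)
  ph$scatterers <- data.frame(xs = c(0, 8e-6), ys = 0, zs = c(20e-6, 90e-6),
                              amp = c(1 + 0i, 2i))
  cube <- compute_g1_cube(ph, cfg, spec)
  expect_equal(cube$maps[[2]]$values, ga$values + gb$values, tolerance = 1e-12)
  # amplitude scaling
  s3 <- modifyList(s1, list(amp = 3 - 1i))
  expect_equal(point_scatterer_g1(s3, k, cfg, grid)$values,
               (3 - 1i) * ga$values, tolerance = 1e-12)
})

test_that("g1 cube round-trips through the field store bit-exactly", {
  cfg <- tiny_cfg(n_k = 3L)
  cube <- compute_g1_cube(make_single_scatterer(30e-6), cfg)
  f <- tempfile(fileext = ".rds")
  save_field_cube(cube, f)
  cube2 <- load_field_cube(f)
  expect_identical(cube2$maps[[2]]$values, cube$maps[[2]]$values)
  expect_identical(cube2$spec$k, cube$spec$k)
})

test_that("split-step propagation reproduces free-space plane waves", {
  cfg <- tiny_cfg(nb = 1.42)
  k <- 2 * pi * 1.42 / 1.3e-6
  # homogeneous volume: no scatterers
  p <- make_single_scatterer(5e-6, nb = 1.42)
  vol <- phantom_to_index_grid(p, cell = 0.5e-6, lateral_extent = 30e-6,
                               z_range = c(0, 6e-6))
  vol$n[] <- 1.42 # remove the particle: homogeneous
  vol$absorb <- 0 # ideal periodic plane wave: no absorbing margin
  # an exact Fourier mode of the transverse grid propagates without leakage
  kx <- 6 * 2 * pi / (length(vol$x) * vol$cell)
  vf <- multislice_incident_field(p, k, kx, 0, cfg, vol = vol)
  kz <- sqrt(k^2 - kx^2)
  i0 <- which.min(abs(vol$x))
  for (j in c(3L, length(vf$z))) {
    zprop <- vf$z[j] # top surface at z = 0
    pred <- exp(1i * (kx * vol$x[i0] + kz * zprop))
    got <- vf$slices[[j]][i0, i0]
    expect_equal(Mod(got), 1, tolerance = 1e-6)
    expect_equal(Arg(got / pred), 0, tolerance = 1e-6)
  }
})

test_that("split-step conserves interior power in a lossless slab", {
  cfg <- tiny_cfg()
  p <- make_single_scatterer(5e-6)
  vol <- phantom_to_index_grid(p, cell = 0.5e-6, lateral_extent = 30e-6,
                               z_range = c(0, 5e-6))
  vol$n[] <- 1
  vol$absorb <- 0
  k <- 2 * pi / 1.3e-6
  vf <- multislice_incident_field(p, k, 0, 0, cfg, vol = vol)
  inner <- abs(vol$x) < 0.8 * max(vol$x)
  p_first <- sum(Mod(vf$slices[[1]][inner, inner])^2)
  p_last <- sum(Mod(vf$slices[[length(vf$z)]][inner, inner])^2)
  expect_equal(p_last / p_first, 1, tolerance = 1e-6)
})

test_that("Born return path reduces to the analytic response and is additive", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[5]
  s <- make_single_scatterer(40e-6)
  g_born <- born_scattered_g(s, NULL, k, 0, 0, cfg, grid)
  g_ref <- point_scatterer_g1(s$scatterers[1, ], k, cfg, grid, window = FALSE)
  expect_lt(rel_l2(g_born$values, g_ref$values), 1e-12)
  # two scatterers: sum of individual responses
  p2 <- s
  p2$scatterers <- rbind(s$scatterers,
                         data.frame(xs = 5e-6, ys = 0, zs = 90e-6,
                                    amp = complex(real = 1)))
  ga <- born_scattered_g(p2, NULL, k, 0, 0, cfg, grid)
  gb1 <- born_scattered_g(make_single_scatterer(90e-6, xs = 5e-6), NULL, k,
                          0, 0, cfg, grid)
  expect_lt(rel_l2(ga$values, g_born$values + gb1$values), 1e-12)
})

test_that("speckle from a dense phantom has near-unit contrast", {
  cfg <- tiny_cfg()
  grid <- aperture_grid(cfg)
  k <- build_spectral_grid(cfg)$k[4]
  ph <- make_letter_phantom(extent = c(60e-6, 20e-6, 80e-6), seed = 5L)
  g <- born_scattered_g(ph, NULL, k, 0, 0, cfg, grid)
  a <- Mod(g$values[grid$mask])
  contrast <- stats::sd(a) / mean(a)
  # fully developed speckle: contrast ~ sqrt(4/pi - 1) = 0.52 in amplitude
  expect_gt(contrast, 0.3)
  expect_lt(contrast, 0.8)
})
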