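mk_img <- function(values, z = NULL, x = NULL, prov = "direct") {
  if (is.null(z)) z <- (seq_len(nrow(values)) - 1) * 1e-6
  if (is.null(x)) x <- (seq_len(ncol(values)) - 1) * 1e-6
  oct_image(values, z, x, prov)
}

test_that("error metric identities: zero, unity and relative scaling", {
  set.seed(1)
  v <- matrix(abs(stats::rnorm(80)) + 0.1, 10, 8)
  ref <- mk_img(v)
  expect_true(all(error_metric(ref, ref)$eps == 0))
  synth0 <- mk_img(v * 0, prov = "synthesized")
  expect_true(all(error_metric(ref, synth0)$eps == 1))
  d <- 0.037
  synth <- mk_img(v * (1 + d), prov = "synthesized")
  expect_equal(error_metric(ref, synth)$eps, rep(d^2, 10), tolerance = 1e-12)
})

test_that("error metric: scale invariant, asymmetric, brute-force exact on 8x8", {
  set.seed(2)
  a <- matrix(abs(stats::rnorm(64)) + 0.05, 8, 8)
  b <- matrix(abs(stats::rnorm(64)) + 0.05, 8, 8)
  ir <- mk_img(a); is <- mk_img(b, prov = "synthesized")
  e1 <- error_metric(ir, is)$eps
  e2 <- error_metric(mk_img(7 * a), mk_img(7 * b, prov = "synthesized"))$eps
  expect_equal(e1, e2, tolerance = 1e-12)
  # not symmetric: denominator uses the reference only
  e_swapped <- error_metric(is, ir)$eps
  expect_false(isTRUE(all.equal(e1, e_swapped)))
  # brute-force recomputation per pixel
  brute <- sapply(1:8, function(i) sum((a[i, ] - b[i, ])^2) / sum(a[i, ]^2))
  expect_equal(e1, brute, tolerance = 1e-14)
  # near-empty reference rows are undefined, not huge
  a2 <- a; a2[3, ] <- 1e-9 * a2[3, ]
  e3 <- error_metric(mk_img(a2), is)
  expect_true(is.na(e3$eps[3]))
  expect_equal(e3$n_undefined, 1L)
  expect_error(error_metric(ir, mk_img(b, z = (1:8) * 2e-6)), "axes")
})

test_that("smoothed error metric: window->0 identity, idempotence, speckle averaging", {
  set.seed(3)
  v <- matrix(abs(stats::rnorm(200)) + 0.1, 20, 10)
  w <- matrix(abs(stats::rnorm(200)) + 0.1, 20, 10)
  ir <- mk_img(v); is <- mk_img(w, prov = "synthesized")
  e0 <- smoothed_error_metric(ir, is, window = 1e-9)
  expect_equal(e0$eps, error_metric(ir, is)$eps, tolerance = 1e-12)
  # constant images: smoothing changes nothing, any window
  cim <- mk_img(matrix(2, 20, 10))
  expect_equal(smoothed_error_metric(cim, cim, 5e-6)$eps, rep(0, 20))
  # equal local mean, decorrelated speckle: smoothing slashes the error
  set.seed(4)
  s1 <- matrix(stats::rexp(3000), 50, 60)
  s2 <- matrix(stats::rexp(3000), 50, 60)
  i1 <- mk_img(s1); i2 <- mk_img(s2, prov = "synthesized")
  raw <- stats::median(error_metric(i1, i2)$eps)
  sm <- stats::median(smoothed_error_metric(i1, i2, 20e-6)$eps)
  expect_lt(sm, raw / 5)
  expect_error(smoothed_error_metric(i1, i2, window = 1), "window")
})

test_that("phase discrepancy statistics match constructed fields", {
  set.seed(5)
  E <- matrix(complex(real = stats::rnorm(256), imaginary = stats::rnorm(256)),
              16, 16)
  # constant offset: mean pi/4, sd 0
  s <- phase_discrepancy_stats(E * exp(1i * pi / 4), E)
  expect_equal(s$mean_phase, pi / 4, tolerance = 1e-10)
  expect_lt(s$std_phase, 1e-10)
  # identical fields: all zeros
  s0 <- phase_discrepancy_stats(E, E)
  expect_equal(s0$mean_phase, 0)
  expect_equal(s0$std_phase, 0)
  expect_equal(sum(s0$hist$counts), 256L)
  # invariance under a global phase on both fields
  sg <- phase_discrepancy_stats(E * exp(2i), E * exp(2i - 1i * pi / 4))
  expect_equal(sg$mean_phase, pi / 4, tolerance = 1e-10)
  # zero-magnitude pixels excluded and counted
  E2 <- E; E2[1, 1] <- 0
  sz <- phase_discrepancy_stats(E2, E)
  expect_equal(sz$n_excluded, 1L)
  expect_equal(sz$n_used, 255L)
})

test_that("phase std recovers a seeded wrapped-Gaussian dispersion", {
  set.seed(6)
  n <- 256L
  E <- matrix(complex(modulus = 1,
                      argument = stats::runif(n^2, -pi, pi)), n, n)
  sg <- 0.3
  Es <- E * exp(-1i * matrix(stats::rnorm(n^2, 0, sg), n, n))
  s <- phase_discrepancy_stats(E, Es)
  expect_equal(s$std_phase, sg, tolerance = 0.02)
  expect_lt(abs(s$mean_phase), 3 * sg / n) # ~ sg/sqrt(n^2)
})

test_that("magnitude discrepancy statistic follows its definition", {
  set.seed(7)
  E <- matrix(complex(real = stats::rnorm(64), imaginary = stats::rnorm(64)),
              8, 8)
  expect_equal(magnitude_discrepancy_stats(E, E)$std_magnitude, 0)
  # constant fields: constant discrepancy has zero spread (STD, not mean)
  Ec <- matrix(1 + 1i, 8, 8)
  expect_lt(magnitude_discrepancy_stats(Ec, 2 * Ec)$std_magnitude, 1e-12)
  # brute-force check on multiplicative noise
  g <- matrix(abs(1 + 0.2 * stats::rnorm(64)), 8, 8)
  Es <- E * g
  brute <- stats::sd(abs(Mod(E) - Mod(Es)) / mean(Mod(E)))
  expect_equal(magnitude_discrepancy_stats(E, Es)$std_magnitude, brute,
               tolerance = 1e-12)
  expect_error(magnitude_discrepancy_stats(0 * E, E), "zero")
})

test_that("phase unwrapping and wrapping are consistent", {
  th <- seq(0, 12 * pi, length.out = 200) + 0.3 * sin(1:200)
  expect_equal(unwrap_phase(wrap_phase(th)), th, tolerance = 1e-10)
  expect_true(all(wrap_phase(c(-pi, pi, 3 * pi, -3 * pi)) == pi))
})

test_that("axial peak finding refines, separates and fails loudly", {
  z <- (0:127) * 2e-6
  prof <- exp(-((z - 50e-6) / 8e-6)^2)
  pk <- find_axial_peaks(list(z = z, magnitude = prof), 1L)
  expect_lt(abs(pk - 50e-6), 2e-6)
  expect_error(find_axial_peaks(list(z = z, magnitude = rep(1, 128)), 1L),
               "flat")
  two <- exp(-((z - 50e-6) / 8e-6)^2) + 0.8 * exp(-((z - 110e-6) / 8e-6)^2)
  pks <- find_axial_peaks(list(z = z, magnitude = two), 2L,
                          min_separation = 20e-6)
  expect_equal(pks, c(50e-6, 110e-6), tolerance = 2e-6)
  expect_error(find_axial_peaks(list(z = z, magnitude = prof), 4L),
               "found only")
})

test_that("spectral phase track recovers the free-propagation slope", {
  # n_k chosen so the per-sample phase increment stays below pi (unwrap)
  cfg <- oct_system(n_k = 12L, bandwidth = 120e-9, nb = 1.42)
  spec <- build_spectral_grid(cfg)
  ph <- make_single_scatterer(20e-6, nb = 1.42)
  ms <- list(cell = 0.65e-6, lateral_extent = 25e-6, z_range = c(0, 30e-6))
  vol <- do.call(octsynth:::phantom_volume_grid, c(list(ph), ms))
  vol$n[] <- 1.42
  ph$index_grid <- vol
  theta <- 0.05
  tr <- spectral_phase_track(ph, c(0, 0, 25e-6), theta, spec, cfg)
  # homogeneous: direct and synthesized coincide up to the spectral
  # leakage of an off-grid tilt on the periodic transverse grid
  expect_lt(max(abs(tr$phase_diff)), 0.02)
  z0 <- vol$z[which.min(abs(vol$z - 25e-6))] # nearest stored slice center
  pred <- cos(theta) * z0   # d(kz)/dk at fixed angle = cos(theta)
  expect_equal(tr$slope_ref, pred, tolerance = 0.02)
  expect_true(tr$slopes_agree)
})
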