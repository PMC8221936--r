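#' Scatterer phantoms
#'
#' A phantom is a list of isotropic point scatterers (positions relative
#' to the beam focus, in metres; complex amplitudes) together with the
#' background refractive index, and optionally a rasterized 3-D
#' refractive-index grid for the beam-propagation solver. Positive `zs`
#' is deeper into the sample (away from the objective).
#'
#' @name phantoms
NULL

new_phantom <- function(scatterers, nb = 1, index_grid = NULL, seed = NULL,
                        extent = NULL) {
  stopifnot(is.data.frame(scatterers),
            all(c("xs", "ys", "zs", "amp") %in% names(scatterers)))
  if (!all(is.finite(Mod(scatterers$amp))))
    stop("scatterer amplitudes must be finite")
  if (nrow(scatterers) > 0 && any(abs(scatterers$zs) > 300e-6))
    warning("scatterer depth beyond +-300 um: outside the intended ",
            "depth-of-focus validity of the paraxial forward model")
  p <- list(scatterers = scatterers, nb = nb, index_grid = index_grid,
            seed = seed, extent = extent)
  class(p) <- "oct_phantom"
  p
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("<oct_phantom> %d scatterers, nb = %.3f", nrow(x$scatterers), x$nb))
  if (nrow(x$scatterers))
    cat(sprintf(", z range [%.1f, %.1f] um",
                1e6 * min(x$scatterers$zs), 1e6 * max(x$scatterers$zs)))
  if (!is.null(x$index_grid)) cat(", with index grid")
  cat("\n")
  invisible(x)
}

#' Axial grid of point scatterers (PSF phantom)
#'
#' `n_points` unit-amplitude scatterers on the optical axis at depths
#' `start_z + (j-1)*spacing`. The default spacing reproduces the PSF test
#' object: 152 grid cells of width `lambda0/6` at `lambda0 = 1.3 um`,
#' i.e. 32.93 um between neighbours, first scatterer at the focus.
#'
#' @param n_points number of scatterers (>= 1).
#' @param spacing axial separation (m).
#' @param start_z depth of the first scatterer (m).
#' @param nb background refractive index.
#' @return an `oct_phantom`.
#' @export
make_axial_point_grid <- function(n_points = 9L,
                                  spacing = 152 * 1.3e-6 / 6,
                                  start_z = 0, nb = 1) {
  stopifnot(n_points >= 1L, spacing > 0)
  z <- start_z + (seq_len(n_points) - 1) * spacing
  new_phantom(data.frame(xs = 0, ys = 0, zs = z, amp = complex(real = 1)),
              nb = nb)
}

#' Single point scatterer
#'
#' @param depth scatterer depth `zs` (m), relative to focus; may be
#'   negative (above focus).
#' @param xs,ys lateral position (m).
#' @param nb background refractive index.
#' @return an `oct_phantom` with one unit-amplitude scatterer.
#' @export
make_single_scatterer <- function(depth, xs = 0, ys = 0, nb = 1) {
  new_phantom(data.frame(xs = xs, ys = ys, zs = depth,
                         amp = complex(real = 1)), nb = nb)
}

# Built-in 12x8 bitmap of the letter "B" (rows = depth, cols = lateral).
letter_B_bitmap <- function() {
  rows <- c("11111100",
            "11111110",
            "11000011",
            "11000011",
            "11111110",
            "11111100",
            "11000110",
            "11000011",
            "11000011",
            "11000011",
            "11111110",
            "11111100")
  do.call(rbind, lapply(strsplit(rows, ""), function(r) as.integer(r) == 1L))
}

#' Random scattering phantom shaped by a binary glyph
#'
#' Places point scatterers uniformly at random (seeded, reproducible)
#' inside the volume obtained by extruding a binary 2-D mask (oriented in
#' the x-z plane) over the y-extent. Emulates a dense cloud of
#' high-index dielectric microspheres (TiO2-like) suspended in a
#' background medium; each particle is an isotropic point scatterer with
#' one complex amplitude proportional to its polarizability,
#' `(n_particle^2 - nb^2) * volume`. No angular (Mie) scattering phase
#' function is modelled.
#'
#' @param mask binary matrix (rows map to depth z, columns to lateral x);
#'   default the built-in letter "B".
#' @param extent numeric length-3: lateral width (x), y width, depth (z),
#'   in metres. Defaults 215 x 40 x 250 um.
#' @param particle_diameter sphere diameter (m), default 1 um.
#' @param n_particle particle refractive index, default 2.488.
#' @param nb background index, default 1.42.
#' @param density number of particles per unit volume (m^-3). The default
#'   7e15 (0.007 per um^3) gives fully developed speckle at these optical
#'   parameters; the physical scattering coefficient is not calibrated.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param z_offset depth of the top surface of the phantom (m).
#' @return an `oct_phantom` (positions centered laterally on the axis,
#'   depths in `[z_offset, z_offset + extent[3]]`).
#' @export
make_letter_phantom <- function(mask = letter_B_bitmap(),
                                extent = c(215e-6, 40e-6, 250e-6),
                                particle_diameter = 1e-6,
                                n_particle = 2.488, nb = 1.42,
                                density = 7e15, seed = 1L,
                                z_offset = 0) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("empty glyph mask")
  if (!(density > 0)) stop("density must be > 0")
  fill <- mean(mask)
  vol <- prod(extent) * fill
  n <- max(1L, as.integer(round(density * vol)))
  set.seed(as.integer(seed))
  nz <- nrow(mask); nx <- ncol(mask)
  pts <- matrix(NA_real_, 0, 3)
  # rejection-sample against the glyph
  while (nrow(pts) < n) {
    m <- 2L * (n - nrow(pts))
    u <- cbind(stats::runif(m), stats::runif(m), stats::runif(m))
    iz <- pmin(nz, 1L + floor(u[, 3] * nz))
    ix <- pmin(nx, 1L + floor(u[, 1] * nx))
    keep <- mask[cbind(iz, ix)]
    pts <- rbind(pts, u[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  xs <- (pts[, 1] - 0.5) * extent[1]
  ys <- (pts[, 2] - 0.5) * extent[2]
  zs <- z_offset + pts[, 3] * extent[3]
  a <- particle_diameter / 2
  amp <- (n_particle^2 - nb^2) * (4 / 3) * pi * a^3
  new_phantom(data.frame(xs = xs, ys = ys, zs = zs,
                         amp = complex(real = amp)),
              nb = nb, seed = as.integer(seed),
              extent = extent)
}

#' Rasterize a point-scatterer phantom onto a refractive-index grid
#'
#' Deposits each scatterer as a sphere of diameter `particle_diameter`
#' and index `n_particle` into a regular 3-D grid over the given lateral
#' extent and the phantom's depth range, for use by the multi-slice
#' beam-propagation solver.
#'
#' @param phantom an `oct_phantom`.
#' @param cell isotropic cell size (m).
#' @param lateral_extent half-extent (m) of the transverse grid in x and y.
#' @param z_range depth range `c(z0, z1)` (m) to rasterize.
#' @param particle_diameter,n_particle particle geometry/index.
#' @return list with `n` (3-D array nx x ny x nz of refractive index),
#'   `x`, `y`, `z` axes (cell centers), `cell`, `nb`.
#' @export
phantom_to_index_grid <- function(phantom, cell, lateral_extent,
                                  z_range,
                                  particle_diameter = 1e-6,
                                  n_particle = 2.488) {
  nx <- 2L * as.integer(ceiling(lateral_extent / cell))
  x <- (seq_len(nx) - 1 - nx / 2) * cell
  z <- seq(z_range[1] + cell / 2, z_range[2], by = cell)
  nz <- length(z)
  n <- array(phantom$nb, dim = c(nx, nx, nz))
  s <- phantom$scatterers
  rad <- particle_diameter / 2
  reach <- max(0L, as.integer(floor(rad / cell)))
  off <- -reach:reach
  for (i in seq_len(nrow(s))) {
    ix <- 1L + round((s$xs[i] - x[1]) / cell)
    iy <- 1L + round((s$ys[i] - x[1]) / cell)
    iz <- 1L + round((s$zs[i] - z[1]) / cell)
    for (dz in off) for (dy in off) for (dx in off) {
      jx <- ix + dx; jy <- iy + dy; jz <- iz + dz
      if (jx >= 1L && jx <= nx && jy >= 1L && jy <= nx &&
          jz >= 1L && jz <= nz) {
        d2 <- (x[jx] - s$xs[i])^2 + (x[jy] - s$ys[i])^2 + (z[jz] - s$zs[i])^2
        if (d2 <= rad^2) n[jx, jy, jz] <- n_particle
      }
    }
  }
  list(n = n, x = x, y = x, z = z, cell = cell, nb = phantom$nb)
}

#' Write / read a phantom as plain-text CSV
#'
#' Columns `xs, ys, zs, amp_re, amp_im` (SI units), with `nb` and `seed`
#' recorded in a `#`-comment header.
#'
#' @param phantom an `oct_phantom`.
#' @param path file path.
#' @return `read_phantom_csv` returns the reconstructed `oct_phantom`.
#' @export
write_phantom_csv <- function(phantom, path) {
  s <- phantom$scatterers
  hdr <- sprintf("# octsynth phantom: nb=%.17g seed=%s", phantom$nb,
                 ifelse(is.null(phantom$seed), "NA", phantom$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(xs = s$xs, ys = s$ys, zs = s$zs,
                              amp_re = Re(s$amp), amp_im = Im(s$amp)),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phantom_csv
#' @export
read_phantom_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  nb <- as.numeric(sub(".*nb=([-0-9.eE+]+).*", "\\1", hdr))
  seed <- sub(".*seed=([^ ]+).*", "\\1", hdr)
  seed <- if (seed == "NA") NULL else as.integer(seed)
  d <- utils::read.csv(path, comment.char = "#")
  new_phantom(data.frame(xs = d$xs, ys = d$ys, zs = d$zs,
                         amp = complex(real = d$amp_re, imaginary = d$amp_im)),
              nb = nb, seed = seed)
}
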