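#' Depth-resolved error metric between two OCT images
#'
#' For each depth bin, the squared magnitude differences are summed over
#' the lateral dimension and normalized by the reference energy:
#' `eps(z) = sum_i (|ref(x_i, z)| - |synth(x_i, z)|)^2 /
#'           sum_i |ref(x_i, z)|^2`.
#' The metric is invariant under simultaneous rescaling of both images
#' but is not symmetric in its arguments (the denominator uses the
#' reference only). Depth bins whose reference energy falls below
#' `1e-6` of the maximum row energy are reported as `NA` (dividing by a
#' vanishing normalizer is meaningless there, and otherwise produces the
#' sharp spurious growth seen below the bottom of an object).
#'
#' @param ref,synth `oct_image`s on identical axes.
#' @return an `error_profile`: list with `z`, `eps`, `n_undefined`,
#'   `window = NA`.
#' @export
error_metric <- function(ref, synth) {
  check_same_axes(ref, synth)
  num <- rowSums((abs(ref$values) - abs(synth$values))^2)
  den <- rowSums(ref$values^2)
  eps <- num / den
  bad <- den < 1e-6 * max(den)
  eps[bad] <- NA_real_
  out <- list(z = ref$z, eps = eps, n_undefined = sum(bad), window = NA_real_)
  class(out) <- "error_profile"
  out
}

check_same_axes <- function(a, b) {
  if (!isTRUE(all.equal(a$z, b$z)) || !isTRUE(all.equal(a$x, b$x)))
    stop("images must share identical depth and scan axes")
  invisible(TRUE)
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> %d depths, median eps = %.3g (%d undefined)",
              length(x$z), stats::median(x$eps, na.rm = TRUE), x$n_undefined))
  if (is.finite(x$window)) cat(sprintf(", smoothed over %.3g um", 1e6 * x$window))
  cat("\n")
  invisible(x)
}

# 2-D boxcar mean with shrinking windows at the edges
boxcar2 <- function(m, hz, hx) {
  n <- nrow(m); p <- ncol(m)
  cs <- matrix(0, n + 1, p + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    i0 <- max(1L, i - hz); i1 <- min(n, i + hz)
    for (j in seq_len(p)) {
      j0 <- max(1L, j - hx); j1 <- min(p, j + hx)
      out[i, j] <- (cs[i1 + 1, j1 + 1] - cs[i0, j1 + 1] -
                      cs[i1 + 1, j0] + cs[i0, j0]) /
        ((i1 - i0 + 1) * (j1 - j0 + 1))
    }
  }
  out
}

#' Error metric after local speckle averaging
#'
#' Both image magnitudes are averaged over a sliding square window
#' (default 20 um a side) before the error metric is evaluated, removing
#' the speckle-realization component of the discrepancy: this measures
#' how well the mean image magnitude — rather than the exact speckle
#' pattern — is reproduced.
#'
#' @inheritParams error_metric
#' @param window side length (m) of the averaging window (default 20 um).
#' @return an `error_profile` with the `window` recorded.
#' @export
smoothed_error_metric <- function(ref, synth, window = 20e-6) {
  check_same_axes(ref, synth)
  dz <- ref$z[2] - ref$z[1]
  dx <- if (length(ref$x) > 1) abs(ref$x[2] - ref$x[1]) else window
  if (window > diff(range(ref$z)) + dz)
    stop("smoothing window exceeds the image depth extent")
  hz <- max(0L, floor(window / (2 * dz)))
  hx <- max(0L, floor(window / (2 * dx)))
  sm <- function(img) {
    out <- img
    out$values <- boxcar2(abs(img$values), hz, hx)
    out
  }
  ep <- error_metric(sm(ref), sm(synth))
  ep$window <- window
  ep
}

#' Phase discrepancy statistics between two complex fields
#'
#' Pointwise phase differences `arg(E_ref) - arg(E_synth)` are wrapped to
#' `(-pi, pi]`; the mean, standard deviation and a histogram over a
#' region of interest are returned. Pixels where either field has (near)
#' zero magnitude are excluded and counted. Statistics are invariant
#' under a global phase applied to both fields.
#'
#' @param E_ref,E_synth complex matrices on the same grid.
#' @param roi optional logical matrix selecting the region of interest.
#' @param breaks number of histogram bins over `(-pi, pi]` (default 61).
#' @return a `discrepancy_stats` list: `mean_phase`, `std_phase` (rad),
#'   `hist` (counts + mids), `n_excluded`, `n_used`.
#' @export
phase_discrepancy_stats <- function(E_ref, E_synth, roi = NULL, breaks = 61L) {
  stopifnot(all(dim(E_ref) == dim(E_synth)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(E_ref), ncol(E_ref))
  tol <- 1e-12 * max(Mod(E_ref), Mod(E_synth))
  ok <- roi & Mod(E_ref) > tol & Mod(E_synth) > tol
  d <- wrap_phase(Arg(E_ref[ok]) - Arg(E_synth[ok]))
  edges <- seq(-pi, pi, length.out = breaks + 1L)
  h <- graphics::hist(d, breaks = edges, plot = FALSE)
  out <- list(mean_phase = mean(d), std_phase = stats::sd(d),
              hist = list(counts = h$counts, mids = h$mids),
              n_excluded = sum(roi) - sum(ok), n_used = sum(ok))
  class(out) <- "discrepancy_stats"
  out
}

#' Wrap phases to (-pi, pi]
#' @param x phases (rad).
#' @return wrapped phases.
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Magnitude discrepancy statistic between two complex fields
#'
#' Standard deviation over the region of interest of
#' `||E_ref| - |E_synth|| / mean(|E_ref|)` — the magnitude discrepancy
#' normalized by the mean reference magnitude.
#'
#' @inheritParams phase_discrepancy_stats
#' @return a `discrepancy_stats` list with `std_magnitude`, `n_used`.
#' @export
magnitude_discrepancy_stats <- function(E_ref, E_synth, roi = NULL) {
  stopifnot(all(dim(E_ref) == dim(E_synth)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(E_ref), ncol(E_ref))
  mref <- mean(Mod(E_ref[roi]))
  if (!(mref > 0)) stop("mean reference magnitude is zero over the ROI")
  d <- abs(Mod(E_ref[roi]) - Mod(E_synth[roi])) / mref
  out <- list(std_magnitude = stats::sd(d), n_used = sum(roi))
  class(out) <- "discrepancy_stats"
  out
}

#' Track field magnitude and phase against wavenumber at one point
#'
#' Returns, for each wavenumber of the spectral grid, the directly
#' evaluated (tilted multi-slice) and synthesized (ramped
#' normal-incidence) field at a single point in the sample, with
#' unwrapped phases and their mean rate of change in k. Depth information
#' in spectral-domain OCT is carried by d(phase)/dk, so agreement of the
#' mean slopes — even when pointwise phase differences are large — is
#' what preserves the reconstruction.
#'
#' @param phantom an `oct_phantom`.
#' @param point length-3 numeric `(x, y, z)` (m).
#' @param theta_i tilt angle (rad).
#' @param spec a [build_spectral_grid()].
#' @param config an [oct_system()].
#' @param ms multislice volume options.
#' @param slope_rtol relative tolerance on mean-slope agreement used for
#'   the `slopes_agree` flag (default 0.15).
#' @return list with per-k vectors `mag_ref`, `mag_synth`, `phase_ref`,
#'   `phase_synth` (unwrapped), `phase_diff`, scalars `slope_ref`,
#'   `slope_synth`, logical `slopes_agree`.
#' @export
spectral_phase_track <- function(phantom, point, theta_i, spec, config,
                                 ms = list(), slope_rtol = 0.15) {
  vol <- do.call(phantom_volume_grid, c(list(phantom), ms))
  nk <- length(spec$k)
  er <- es <- complex(nk)
  for (i in seq_len(nk)) {
    k <- spec$k[i]
    kx <- k * sin(theta_i)
    kz <- sqrt(k^2 - kx^2)
    En <- multislice_incident_field(phantom, k, 0, 0, config, vol = vol,
                                    keep = point[3])
    Et <- multislice_incident_field(phantom, k, kx, 0, config, vol = vol,
                                    keep = point[3])
    er[i] <- volume_field_at(Et, point[1], point[2], point[3])
    en <- volume_field_at(En, point[1], point[2], point[3])
    es[i] <- en * exp(1i * (kx * point[1] + (kz - k) * En$z[1]))
  }
  pr <- unwrap_phase(Arg(er))
  ps <- unwrap_phase(Arg(es))
  sr <- mean(diff(pr)) / spec$dk
  ss <- mean(diff(ps)) / spec$dk
  list(k = spec$k, mag_ref = Mod(er), mag_synth = Mod(es),
       phase_ref = pr, phase_synth = ps,
       phase_diff = wrap_phase(pr - ps),
       slope_ref = sr, slope_synth = ss,
       slopes_agree = abs(sr - ss) <= slope_rtol * max(abs(sr), abs(ss)))
}

#' Unwrap a phase sequence
#' @param p phases (rad).
#' @return unwrapped phases (cumulative sum of wrapped increments).
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  p[1] + c(0, cumsum(wrap_phase(diff(p))))
}

#' Locate axial peaks in an OCT image
#'
#' Local maxima of the laterally averaged magnitude profile (boundary
#' bins count as maxima if they exceed their single neighbour), refined
#' to sub-bin accuracy by a quadratic fit through each interior maximum
#' and its neighbours. The `n_expected` highest peaks are selected
#' greedily, optionally enforcing a minimum axial separation (which
#' rejects the spectral-envelope sidelobes that appear between closely
#' spaced reflectors), and returned sorted by depth.
#'
#' @param img an `oct_image` (or a list with `z` and `magnitude`).
#' @param n_expected number of peaks required (>= 1).
#' @param min_separation minimum distance between accepted peaks (m);
#'   default 0 (accept all local maxima).
#' @return numeric vector of peak depths (m), increasing.
#' @export
find_axial_peaks <- function(img, n_expected, min_separation = 0) {
  stopifnot(n_expected >= 1L)
  if (inherits(img, "oct_image")) {
    prof <- rowMeans(abs(img$values))
    z <- img$z
  } else {
    prof <- img$magnitude
    z <- img$z
  }
  n <- length(prof)
  if (n < 2L || max(prof) == min(prof))
    stop("no peaks: profile is flat or too short")
  i <- which(prof[-c(1, n)] > prof[-c(n - 1, n)] &
               prof[-c(1, n)] >= prof[-(1:2)]) + 1L
  if (prof[1] > prof[2]) i <- c(1L, i)
  if (prof[n] > prof[n - 1]) i <- c(i, n)
  i <- i[order(prof[i], decreasing = TRUE)]
  picked <- integer(0)
  for (j in i) {
    if (length(picked) == n_expected) break
    if (!length(picked) || all(abs(z[j] - z[picked]) >= min_separation))
      picked <- c(picked, j)
  }
  if (length(picked) < n_expected)
    stop("found only ", length(picked), " peaks (expected ", n_expected,
         ") at depths ", paste(signif(z[sort(picked)] * 1e6, 4),
                               collapse = ", "), " um")
  dz <- z[2] - z[1]
  zp <- vapply(picked, function(j) {
    if (j == 1L || j == n) return(z[j])
    a <- prof[j - 1]; b <- prof[j]; cc <- prof[j + 1]
    den <- a - 2 * b + cc
    off <- if (abs(den) > 0) 0.5 * (a - cc) / den else 0
    z[j] + off * dz
  }, 1.0)
  sort(zp)
}
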