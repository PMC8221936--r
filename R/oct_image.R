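#' OCT image container
#'
#' Real-valued A-scan/B-scan container with a calibrated depth axis
#' (metres of physical sample depth, 0 at the focus, positive into the
#' sample) and lateral scan axis.
#'
#' @param values magnitude matrix `[n_z, n_x]`.
#' @param z depth axis (m), uniform.
#' @param x scan positions (m).
#' @param provenance `"synthesized"` or `"direct"`.
#' @param bands optional data.frame of assumed-depth stitching bands.
#' @param complex_values optional complex image (pre-magnitude).
#' @return an object of class `oct_image`.
#' @export
oct_image <- function(values, z, x, provenance = c("synthesized", "direct"),
                      bands = NULL, complex_values = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(values), nrow(values) == length(z),
            ncol(values) == length(x), all(is.finite(values)))
  img <- list(values = values, z = z, x = x, provenance = provenance,
              bands = bands, complex_values = complex_values)
  class(img) <- "oct_image"
  img
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %s, %d depths x %d scan positions, z in [%.1f, %.1f] um\n",
              x$provenance, nrow(x$values), ncol(x$values),
              1e6 * min(x$z), 1e6 * max(x$z)))
  if (!is.null(x$bands))
    cat(sprintf("  stitched from %d assumed-depth bands\n", nrow(x$bands)))
  invisible(x)
}

# assemble an image from coupled spectra a3[k, scan]
bscan_from_a3 <- function(a3, amirr, spec, scan_xs, z_range = NULL,
                          provenance = "direct") {
  n <- length(spec$k)
  nz <- n %/% 2
  zax <- (seq_len(nz) - 1) * pi / (n * spec$dk)
  if (is.null(z_range)) z_range <- c(0, max(zax) + zax[2])
  if (z_range[2] > max(zax) + zax[2])
    stop("requested depth range exceeds the unambiguous imaging depth ",
         sprintf("%.1f um of this spectral grid; increase n_k", 1e6 * max(zax)))
  keep <- zax >= z_range[1] & zax < z_range[2]
  vals <- matrix(NA_real_, sum(keep), ncol(a3))
  cvals <- matrix(NA_complex_, sum(keep), ncol(a3))
  for (j in seq_len(ncol(a3))) {
    asc <- form_ascan(a3[, j], amirr, spec)
    vals[, j] <- asc$magnitude[keep]
    cvals[, j] <- asc$complex_profile[keep]
  }
  oct_image(vals, z = zax[keep], x = scan_xs, provenance = provenance,
            complex_values = cvals)
}
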