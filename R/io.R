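#' Load a system configuration from a YAML/JSON file
#'
#' Keys mirror the arguments of [oct_system()] (SI units); missing keys
#' take the documented defaults. Unknown keys are an error, as are
#' non-numeric values.
#'
#' @param path path to a `.yml`/`.yaml`/`.json` file.
#' @return a validated `oct_system`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- setdiff(names(formals(oct_system)), "")
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  nonnum <- names(vals)[!vapply(vals, is.numeric, TRUE)]
  if (length(nonnum))
    stop("non-numeric config values for: ", paste(nonnum, collapse = ", "))
  do.call(oct_system, vals)
}

#' Save an OCT image: raw arrays plus a display TIFF
#'
#' Writes the raw image (values, axes, provenance, bands) as an RDS
#' container at `path`, and alongside it a 32-bit float TIFF of the
#' display image `10*log10(|OCT|^2)`, normalized to the maximum (0 dB)
#' and clipped at `-db_range` dB.
#'
#' @param img an `oct_image`.
#' @param path output path for the raw container (`.rds`).
#' @param db_range display dynamic range in dB (default 40).
#' @return invisibly, the paths written (`raw`, `tiff`).
#' @export
save_image <- function(img, path, db_range = 40) {
  stopifnot(inherits(img, "oct_image"))
  saveRDS(img, path)
  mx <- max(abs(img$values))
  db <- 10 * log10(pmax((abs(img$values) / mx)^2, 10^(-db_range / 10 - 3)))
  db <- pmax(db, -db_range)
  tpath <- sub("\\.rds$", ".tif", path)
  if (identical(tpath, path)) tpath <- paste0(path, ".tif")
  # tiff wants [0,1] for float display; store dB mapped to [0,1]
  tiff::writeTIFF((db + db_range) / db_range, tpath, bits.per.sample = 32L,
                  reduce = TRUE)
  invisible(list(raw = path, tiff = tpath))
}

#' Load an OCT image saved by [save_image()]
#' @param path the raw container path.
#' @return the `oct_image`.
#' @export
load_image <- function(path) {
  img <- readRDS(path)
  stopifnot(inherits(img, "oct_image"))
  img
}

#' Save / load a normal-incidence field cube
#'
#' Runtime interchange container for g1 cubes (one complex map per
#' wavenumber plus the spectral grid and a full config snapshot), so that
#' externally computed records can be dropped into the synthesis chain.
#'
#' @param cube a `field_cube`.
#' @param path output path (`.rds`).
#' @return `load_field_cube` returns the `field_cube`.
#' @export
save_field_cube <- function(cube, path) {
  stopifnot(inherits(cube, "field_cube"))
  saveRDS(cube, path)
  invisible(path)
}

#' @rdname save_field_cube
#' @export
load_field_cube <- function(path) {
  cube <- readRDS(path)
  stopifnot(inherits(cube, "field_cube"))
  cube
}

#' Run the end-to-end simulation pipeline
#'
#' Orchestrates phantom -> g1 cube -> synthesized and/or direct B-scan ->
#' comparison metrics, writing outputs and a run manifest to `out_dir`.
#'
#' @param config an `oct_system` (or path to a config file).
#' @param phantom an `oct_phantom` (or path to a phantom CSV).
#' @param mode `"synthesize"`, `"direct"` or `"both"`.
#' @param scan_xs scan positions (m).
#' @param zs_list assumed depths for the synthesis (m).
#' @param out_dir output directory (created if needed).
#' @param solver forward solver for the g1 record and the direct arm:
#'   `"points"` or `"multislice"`.
#' @param seed integer seed recorded in the manifest (phantom generation
#'   is already seeded at source).
#' @param ms multislice options.
#' @return the run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, phantom, mode = c("both", "synthesize", "direct"),
                         scan_xs, zs_list, out_dir, solver = "points",
                         seed = NULL, ms = list()) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- load_config(config)
  if (is.character(phantom)) {
    if (!file.exists(phantom)) stop("phantom file not found: ", phantom)
    phantom <- read_phantom_csv(phantom)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  times <- list()
  outputs <- list()
  spec <- build_spectral_grid(config)
  z_range <- c(0, max(zs_list) +
                 (if (length(zs_list) > 1) diff(zs_list)[1] / 2 else Inf))
  if (!is.finite(z_range[2]))
    z_range[2] <- (length(spec$k) %/% 2) * pi / (length(spec$k) * spec$dk)
  synth <- direct <- NULL
  if (mode %in% c("both", "synthesize")) {
    t1 <- Sys.time()
    cube <- compute_g1_cube(phantom, config, spec, solver = solver, ms = ms)
    times$g1_cube <- as.numeric(Sys.time() - t1, units = "secs")
    outputs$g1_cube <- file.path(out_dir, "g1_cube.rds")
    save_field_cube(cube, outputs$g1_cube)
    t1 <- Sys.time()
    synth <- synthesize_bscan(cube, scan_xs, zs_list, config, z_range = z_range)
    times$synthesize <- as.numeric(Sys.time() - t1, units = "secs")
    outputs$synthesized <- file.path(out_dir, "synthesized.rds")
    save_image(synth, outputs$synthesized)
  }
  if (mode %in% c("both", "direct")) {
    t1 <- Sys.time()
    direct <- if (solver == "points") {
      direct_bscan_points(phantom, scan_xs, config, spec, z_range = z_range)
    } else {
      direct_bscan_multislice(phantom, scan_xs, config, spec,
                              z_range = z_range, ms = ms)
    }
    times$direct <- as.numeric(Sys.time() - t1, units = "secs")
    outputs$direct <- file.path(out_dir, "direct.rds")
    save_image(direct, outputs$direct)
  }
  report <- NULL
  if (mode == "both") {
    ep <- error_metric(direct, synth)
    report <- list(eps = ep$eps, z_um = ep$z * 1e6,
                   n_undefined = ep$n_undefined,
                   max_abs_diff_pct = 100 *
                     max(abs(abs(direct$values) - abs(synth$values))) /
                     max(abs(direct$values)))
    outputs$report <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(report, outputs$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("octsynth")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    phantom = list(n_scatterers = nrow(phantom$scatterers),
                   nb = phantom$nb, seed = phantom$seed),
    mode = mode, solver = solver,
    scan_xs = scan_xs, zs_list = zs_list,
    outputs = outputs, wall_times_s = times)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, synthesized = synth, direct = direct,
                 report = report))
}
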