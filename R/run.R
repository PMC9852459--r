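# Preset experiments and the run manifest.

default_cell_from <- function(geo) {
  make_cell(core_diameter = geo$core_diameter %||% 18,
            cytoplasm_thickness = geo$cytoplasm_thickness %||% 1,
            membrane_thickness = geo$membrane_thickness %||% 0.01,
            n_core = geo$n_core %||% 1.46,
            n_cytoplasm = geo$n_cytoplasm %||% 1.35,
            n_membrane = geo$n_membrane %||% 1.42,
            boundary_softness = geo$boundary_softness %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a preset experiment
#'
#' Executes one of the named pipelines and writes its outputs plus a
#' manifest (config hash, seeds, per-output checksums) to the output
#' directory:
#'
#' * `"transmittance"` -- collimated transmittance of the 6-layer stack for
#'   `n_ISF` = 1.36/1.38/1.40, both the full lattice solve and the
#'   Bouguer-Beer-Lambert estimate, as CSV.
#' * `"jets"` -- intensity maps for the three incidence scenarios
#'   (cell centre, gap, quarter offset) on a two-layer stack, as float TIFF.
#' * `"ascans"` -- A-scans with the beam on a cell centre and between
#'   cells for an 8-layer fragment.
#' * `"cscan"` -- en-face C-scan raster on a 3-D sphere lattice.
#' * `"inversion"` -- relative-index inversion of measured transmittances.
#'
#' @param config A `run_config` (see [read_run_config()]), or a preset name.
#' @param output_dir Overrides `config$run$output_dir`.
#' @return A `run_manifest` (invisibly the written outputs).
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config))
    config <- validate_run_config(list(
      experiment = list(preset = config), run = list(seed = 1)))
  stopifnot(inherits(config, "run_config"))
  preset <- config$experiment$preset %||% config$experiment$name
  out <- output_dir %||% config$run$output_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$run$seed
  geo <- config$geometry %||% list()
  sol <- config$solver %||% list()
  cell <- default_cell_from(geo)
  files <- character(0)
  t_start <- Sys.time()
  preset_fun <- switch(preset,
    transmittance = run_preset_transmittance, jets = run_preset_jets,
    ascans = run_preset_ascans, cscan = run_preset_cscan,
    inversion = run_preset_inversion,
    stop("unknown preset: ", preset, call. = FALSE))
  files <- preset_fun(cell, geo, sol, config, seed, out)
  manifest <- list(
    preset = preset,
    config_hash = config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("adiposim")),
    outputs = stats::setNames(as.list(tools::md5sum(files)), basename(files)),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  manifest_path <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  structure(c(manifest, list(path = manifest_path)), class = "run_manifest")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run '%s' (seed %s): %d output(s), %.1f s\n", x$preset,
              x$seed, length(x$outputs), x$elapsed_s))
  invisible(x)
}

run_preset_transmittance <- function(cell, geo, sol, config, seed, out) {
  n_isf <- c(1.36, 1.38, 1.40)
  layers <- geo$n_layers %||% 6
  gs <- sol$grid_spacing %||% 0.08
  rows <- lapply(n_isf, function(nn) {
    lat <- build_lattice(cell, n_layers = layers,
                         cells_per_layer = geo$cells_per_layer %||% 10,
                         n_ISF = nn, packing = geo$packing %||% "hexagonal")
    fld <- rasterize(lat, grid_spacing = gs,
                     domain_padding = sol$domain_padding %||% 40)
    sfw <- solve_forward(fld, beam_spec(), method = sol$method %||%
                           "split_step", dz = sol$dz, absorb = sol$absorb
                         %||% 0.08)
    tr <- transmitted_fraction(sfw)
    data.frame(n_ISF = nn, m = cell$n_core / nn,
               T_solver = tr$T,
               T_beer_lambert = transmittance(n_LD = cell$n_core, n_ISF = nn,
                                              l = lat$thickness))
  })
  df <- do.call(rbind, rows)
  p <- file.path(out, "transmittance_sweep.csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

run_preset_jets <- function(cell, geo, sol, config, seed, out) {
  D <- cell$outer_diameter
  offsets <- c(center = 0, gap = D / 2, mixed = D / 4)
  gs <- sol$grid_spacing %||% 0.08
  files <- character(0)
  for (o in names(offsets)) {
    lat <- build_lattice(cell, n_layers = geo$n_layers %||% 2,
                         n_ISF = geo$n_ISF %||% 1.36,
                         packing = geo$packing %||% "hexagonal")
    fld <- rasterize(lat, grid_spacing = gs)
    sfw <- solve_forward(fld, beam_spec(lateral_offset = offsets[[o]]))
    p <- file.path(out, sprintf("jet_intensity_%s.tif", o))
    write_field_tiff(sfw, p)
    files <- c(files, p)
  }
  files
}

run_preset_ascans <- function(cell, geo, sol, config, seed, out) {
  # stacked columns: the beam either runs down a cell column (paired
  # top/bottom echoes) or down the interstitial channel between columns
  lat <- build_lattice(cell, n_layers = geo$n_layers %||% 8,
                       cells_per_layer = geo$cells_per_layer %||% 10,
                       n_ISF = geo$n_ISF %||% 1.36,
                       packing = geo$packing %||% "square",
                       jitter_fraction = geo$jitter_fraction %||% 0)
  src <- oct_source(n_spectral_samples =
                      config$source$n_spectral_samples %||% 192)
  D <- cell$outer_diameter
  top_x <- lat$centers$x[lat$centers$layer == 1]
  x_ref <- top_x[ceiling(length(top_x) / 2)]
  files <- character(0)
  for (pos in c(center = 0, gap = D / 2)) {
    sc <- synthesize_ascan(lat, src, beam_position = x_ref + pos,
      n_trials = sol$n_trials %||% 1, seed = stage_seed(seed, 1),
      grid_spacing = sol$grid_spacing %||% 0.15, soft = sol$soft %||% 0.1)
    p <- file.path(out, sprintf("ascan_%s.csv",
                                if (pos == 0) "center" else "gap"))
    write_oct_scan(sc, p)
    files <- c(files, p)
  }
  files
}

run_preset_cscan <- function(cell, geo, sol, config, seed, out) {
  lat3 <- build_lattice_3d(cell, n_layers = geo$n_layers %||% 3,
                           cells_x = 3, cells_y = 3,
                           n_ISF = geo$n_ISF %||% 1.36,
                           jitter_fraction = geo$jitter_fraction %||% 0,
                           seed = stage_seed(seed, 2))
  src <- oct_source(n_spectral_samples =
                      config$source$n_spectral_samples %||% 32)
  pos <- as.matrix(expand.grid(
    x = seq(-20, 20, length.out = 21), y = seq(-20, 20, length.out = 21)))
  sc <- scan_raster(lat3, src, pos, c_depth = (geo$n_layers %||% 3) * 10,
                    seed = stage_seed(seed, 3),
                    grid_spacing = sol$grid_spacing %||% 0.4)
  p <- file.path(out, "cscan.tif")
  write_oct_scan(sc, p)
  p
}

run_preset_inversion <- function(cell, geo, sol, config, seed, out) {
  measured <- data.frame(temperature_C = c(25, 30, 38),
                         T = c(0.394, 0.401, 0.414))
  measured$m_reconstructed <- relative_index_from_T(measured$T, l = 120)
  p <- file.path(out, "index_inversion.csv")
  utils::write.csv(measured, p, row.names = FALSE)
  p
}
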