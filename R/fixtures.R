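# Seeded generators of benchmark inputs with closed-form expectations.
# Every oracle here is computed by code independent of the solver under test
# (the analytic cylinder series, closed-form Gaussian-beam optics, or direct
# construction), so the test suite needs no external data.

#' Single layered-cylinder benchmark case
#'
#' A lipid-core cylinder with a cytoplasm coat in interstitial fluid,
#' together with its analytic plane-wave scattering solution sampled on the
#' simulation grid -- the oracle used to gate the full-wave solver.
#'
#' @param radius Core radius (um).
#' @param coat Coat thickness (um); 0 gives a bare cylinder.
#' @param n_in,n_coat,n_out Core, coat and embedding refractive indices.
#' @param wavelength Vacuum wavelength (um).
#' @param grid_spacing Pixel size (um).
#' @param half_width,z_before,z_after Domain extents around the cylinder
#'   centre (um).
#' @return A `fixture_case`: the `index_field` (cylinder centred at
#'   `z = z_before`), the incident plane-wave description and a function
#'   `oracle(x, z)` evaluating the analytic scattered field.
#' @export
single_cylinder_case <- function(radius = 5, coat = 1, n_in = 1.46,
                                 n_coat = 1.35, n_out = 1.36,
                                 wavelength = 0.93, grid_spacing = 0.05,
                                 half_width = 16, z_before = 12,
                                 z_after = 18) {
  if (radius < wavelength)
    stop("'radius' must be at least one wavelength", call. = FALSE)
  nx <- round(2 * half_width / grid_spacing)
  nz <- round((z_before + z_after) / grid_spacing)
  x <- (seq_len(nx) - 0.5) * grid_spacing - half_width
  z <- (seq_len(nz) - 0.5) * grid_spacing - z_before
  n <- matrix(n_out, nx, nz)
  r2 <- outer(x^2, z^2, `+`)
  if (coat > 0) n[r2 < (radius + coat)^2] <- n_coat
  n[r2 < radius^2] <- n_in
  fld <- structure(list(n = n, x = x, z = z, grid_spacing = grid_spacing,
                        origin = c(x = x[1], z = z[1]), lattice = NULL),
                   class = "index_field")
  radii <- if (coat > 0) c(radius, radius + coat) else radius
  n_layer <- if (coat > 0) c(n_in, n_coat) else n_in
  oracle <- function(xe, ze, field = "scattered")
    cylinder_series_field(xe, ze, radii, n_layer, n_out,
                          wavelength = wavelength, field = field)
  structure(list(name = sprintf("coated_cylinder_r%g", radius),
                 index_field = fld, wavelength = wavelength, n_out = n_out,
                 radii = radii, n_layer = n_layer, oracle = oracle),
            class = "fixture_case")
}

#' Benchmark lattice suite
#'
#' The grid of forward-solve scenarios spanned by the three beam positions
#' (cell centre, cell gap, quarter offset), two stack depths and the three
#' interstitial-fluid indices used in the optical-clearing comparison.
#'
#' @param cell A [make_cell()] model.
#' @param packing Lattice packing (offset rows by default; a centred jet is
#'   scattered by the two cells below it).
#' @return List of cases, each with the `cell_lattice`, a [beam_spec()] and
#'   an `expect_symmetric` flag.
#' @export
lattice_suite <- function(cell = make_cell(), packing = "hexagonal") {
  D <- cell$outer_diameter
  offsets <- c(center = 0, gap = D / 2, mixed = D / 4)
  out <- list()
  for (n_layers in c(2, 6)) {
    for (n_isf in c(1.36, 1.38, 1.40)) {
      for (o in names(offsets)) {
        lat <- build_lattice(cell, n_layers = n_layers, n_ISF = n_isf,
                             packing = packing)
        out[[sprintf("L%d_n%0.2f_%s", n_layers, n_isf, o)]] <- list(
          lattice = lat,
          beam = beam_spec(lateral_offset = offsets[[o]]),
          offset = offsets[[o]],
          expect_symmetric = (o == "center"))
      }
    }
  }
  out
}

#' Synthetic B-scan with planted hot spots
#'
#' Constant background plus Gaussian hot spots on a given interface row and
#' seeded Gaussian noise -- ground truth for the image-statistics module
#' (its relative dispersion follows from the construction parameters).
#'
#' @param shape `c(rows, cols)` of the image.
#' @param spot_cols Lateral pixel positions of the planted spots.
#' @param spot_row Interface row carrying the spots.
#' @param spot_amplitude Peak amplitude above background.
#' @param spot_sigma Spot width (px).
#' @param background Background level.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A `bscan_image` (negative noise excursions are clipped at 0).
#' @export
synth_bscan <- function(shape = c(200, 400), spot_cols = numeric(0),
                        spot_row = round(shape[1] * 0.8),
                        spot_amplitude = 100, spot_sigma = 3,
                        background = 100, noise_sigma = 0, seed = 1L) {
  if (length(spot_cols) && (any(spot_cols < 1) || any(spot_cols > shape[2])))
    stop("spot positions outside the image", call. = FALSE)
  w <- matrix(background, shape[1], shape[2])
  if (length(spot_cols)) {
    cols <- seq_len(shape[2])
    prof <- rep(0, shape[2])
    for (sc in spot_cols)
      prof <- prof + spot_amplitude * exp(-(cols - sc)^2 / (2 * spot_sigma^2))
    rows <- seq_len(shape[1])
    rowfac <- exp(-(rows - spot_row)^2 / (2 * spot_sigma^2))
    w <- w + outer(rowfac, prof)
  }
  if (noise_sigma > 0) {
    noise <- withr_local_seed(seed,
      matrix(stats::rnorm(prod(shape), 0, noise_sigma), shape[1], shape[2]))
    w <- w + noise
  }
  bscan_image(pmax(w, 0))
}

#' Materialize all fixture cases to files
#'
#' Writes the benchmark geometries and synthetic scans to TIFF/CSV files for
#' manual inspection.
#'
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  cyl <- single_cylinder_case()
  p <- file.path(out_dir, "coated_cylinder_index.tif")
  write_field_tiff(cyl$index_field, p)
  paths <- c(paths, p)
  suite <- lattice_suite()
  for (nm in names(suite)[1:3]) {
    p <- file.path(out_dir, paste0(nm, "_centers.csv"))
    write_centers_csv(suite[[nm]]$lattice, p)
    paths <- c(paths, p)
  }
  b <- synth_bscan(spot_cols = c(100, 200, 300), noise_sigma = 5)
  p <- file.path(out_dir, "synthetic_bscan.csv")
  utils::write.csv(b$values, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
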