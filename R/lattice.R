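#' Build a lattice of cells
#'
#' Arranges identical cells in `n_layers` rows of `cells_per_layer` cells,
#' close-packed laterally (centre spacing = outer diameter) with rows stacked
#' along the propagation axis z at one diameter spacing, so the layer stack
#' is `n_layers * outer_diameter` thick. `packing = "hexagonal"` offsets every
#' second row laterally by half a diameter, the arrangement that sends the
#' photonic jet of one cell into the gap between the two cells beneath it.
#'
#' A quasi-regular variant is obtained with `jitter_fraction = f`: every
#' centre is displaced per axis by an independent uniform draw in
#' `[-f D/2, +f D/2]` and (optionally) every cell diameter is scaled by a
#' uniform factor in `[1 - f, 1 + f]`, both deterministic given `seed`.
#'
#' @param cell A [make_cell()] model.
#' @param n_layers Number of cell rows along z.
#' @param cells_per_layer Cells per row.
#' @param n_ISF Refractive index of the interstitial fluid.
#' @param packing `"square"` (rows aligned) or `"hexagonal"` (offset rows).
#' @param jitter_fraction Relative disorder scale in `[0, 0.5)`.
#' @param seed Integer seed controlling the jitter draws.
#' @param jitter_diameter Also scale per-cell diameters by `[1 - f, 1 + f]`.
#' @return A `cell_lattice` object: the cell, packing parameters and a
#'   data.frame `centers` with columns `id, x, z, diameter`.
#' @examples
#' lat <- build_lattice(make_cell(), n_layers = 6)
#' nrow(lat$centers)  # 60
#' @export
build_lattice <- function(cell,
                          n_layers = 6,
                          cells_per_layer = 10,
                          n_ISF = 1.36,
                          packing = c("square", "hexagonal"),
                          jitter_fraction = 0,
                          seed = 1L,
                          jitter_diameter = TRUE) {
  stopifnot(inherits(cell, "cell_model"))
  packing <- match.arg(packing)
  if (n_layers < 1) stop("'n_layers' must be >= 1", call. = FALSE)
  if (jitter_fraction < 0 || jitter_fraction >= 0.5)
    stop("'jitter_fraction' must be in [0, 0.5)", call. = FALSE)
  if (n_ISF < 1) stop("'n_ISF' must be >= 1", call. = FALSE)
  D <- cell$outer_diameter
  cx0 <- (seq_len(cells_per_layer) - (cells_per_layer + 1) / 2) * D
  rows <- lapply(seq_len(n_layers), function(j) {
    off <- if (packing == "hexagonal" && j %% 2 == 0) D / 2 else 0
    data.frame(x = cx0 + off, z = rep((j - 0.5) * D, length(cx0)),
               layer = rep(j, length(cx0)))
  })
  centers <- do.call(rbind, rows)
  centers$diameter <- rep(D, nrow(centers))
  if (jitter_fraction > 0 && nrow(centers) > 0) {
    n <- nrow(centers)
    # local RNG: deterministic given seed, leaves the global stream untouched
    draws <- withr_local_seed(seed, {
      list(dx = stats::runif(n, -1, 1), dz = stats::runif(n, -1, 1),
           ds = stats::runif(n, -1, 1))
    })
    centers$x <- centers$x + draws$dx * jitter_fraction * D / 2
    centers$z <- centers$z + draws$dz * jitter_fraction * D / 2
    if (jitter_diameter)
      centers$diameter <- D * (1 + draws$ds * jitter_fraction)
  }
  centers <- data.frame(id = seq_len(nrow(centers)), centers)
  structure(list(
    cell = cell, n_layers = n_layers, cells_per_layer = cells_per_layer,
    n_ISF = n_ISF, packing = packing, jitter_fraction = jitter_fraction,
    seed = seed, centers = centers,
    thickness = n_layers * D
  ), class = "cell_lattice")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat(sprintf("Cell lattice: %d layers x %d cells (%s packing), n_ISF = %.3f\n",
              x$n_layers, x$cells_per_layer, x$packing, x$n_ISF))
  cat(sprintf("  jitter %.0f%%, thickness %.2f um\n",
              100 * x$jitter_fraction, x$thickness))
  invisible(x)
}

#' Rasterize a lattice into a refractive-index field
#'
#' Samples the refractive index of a [build_lattice()] arrangement on a
#' regular (x, z) grid with pixel centres at `(i - 0.5) * grid_spacing`.
#' The 10 nm membrane cannot be resolved by any affordable grid; with
#' `include_membrane = TRUE` it is represented by assigning the membrane
#' index to the single boundary pixel ring, otherwise it is omitted.
#' With `soft > 0` shell boundaries are blended sigmoidally over that width
#' (the rendering used by the OCT module).
#'
#' @param lattice A `cell_lattice`.
#' @param grid_spacing Pixel size (um).
#' @param domain_padding Lateral padding beyond the lattice on each side (um).
#' @param z_padding Padding above and below the layer stack (um).
#' @param include_membrane Render the membrane as a one-pixel ring.
#' @param soft Boundary blend width (um); 0 = hard boundaries.
#' @return An `index_field`: matrix `n` (x by z), coordinate vectors `x`, `z`,
#'   `grid_spacing`, `origin` and the generating lattice.
#' @export
rasterize <- function(lattice, grid_spacing = 0.1, domain_padding = 30,
                      z_padding = 0, include_membrane = FALSE, soft = 0) {
  stopifnot(inherits(lattice, "cell_lattice"))
  cell <- lattice$cell
  D <- cell$outer_diameter
  if (grid_spacing > D / 40)
    message(sprintf(
      "grid_spacing %.3g um is coarse for a %.3g um cell (recommended <= %.3g)",
      grid_spacing, D, D / 40))
  half_w <- lattice$cells_per_layer * D / 2 + domain_padding
  nx <- ceiling(2 * half_w / grid_spacing)
  nz <- ceiling((lattice$thickness + 2 * z_padding) / grid_spacing)
  x <- (seq_len(nx) - 0.5) * grid_spacing - nx * grid_spacing / 2
  z <- (seq_len(nz) - 0.5) * grid_spacing - z_padding
  n <- matrix(lattice$n_ISF, nx, nz)
  r_core <- cell$core_diameter / 2
  r_cyt <- r_core + cell$cytoplasm_thickness
  r_mem <- r_cyt + cell$membrane_thickness
  for (ic in seq_len(nrow(lattice$centers))) {
    cc <- lattice$centers[ic, ]
    scale <- cc$diameter / D
    # only touch pixels near this cell
    xi <- which(abs(x - cc$x) <= r_mem * scale + 4 * max(soft, grid_spacing))
    zi <- which(abs(z - cc$z) <= r_mem * scale + 4 * max(soft, grid_spacing))
    if (!length(xi) || !length(zi)) next
    r <- sqrt(outer((x[xi] - cc$x)^2, (z[zi] - cc$z)^2, `+`)) / scale
    if (soft > 0) {
      blend <- function(r, rb) 1 / (1 + exp((r - rb) / (soft / 4)))
      dn <- blend(r, r_cyt) * (cell$n_cytoplasm - lattice$n_ISF) +
        blend(r, r_core) * (cell$n_core - cell$n_cytoplasm)
      if (include_membrane)
        dn <- dn + (blend(r, r_mem) - blend(r, r_cyt)) *
          (cell$n_membrane - lattice$n_ISF)
      n[xi, zi] <- n[xi, zi] + dn
    } else {
      blk <- n[xi, zi]
      if (include_membrane) {
        ring <- r < r_cyt + max(cell$membrane_thickness, grid_spacing)
        blk[ring] <- cell$n_membrane
      }
      blk[r < r_cyt] <- cell$n_cytoplasm
      blk[r < r_core] <- cell$n_core
      n[xi, zi] <- blk
    }
  }
  structure(list(
    n = n, x = x, z = z, grid_spacing = grid_spacing,
    origin = c(x = x[1], z = z[1]), lattice = lattice
  ), class = "index_field")
}

#' @export
print.index_field <- function(x, ...) {
  cat(sprintf("Refractive-index field: %d x %d pixels, %.3g um/px\n",
              nrow(x$n), ncol(x$n), x$grid_spacing))
  cat(sprintf("  n in [%.4f, %.4f]\n", min(x$n), max(x$n)))
  invisible(x)
}

#' Uniform refractive-index field
#'
#' @param n_medium Constant refractive index.
#' @param width,depth Physical extent (um).
#' @param grid_spacing Pixel size (um).
#' @return An `index_field` with constant `n`.
#' @export
uniform_field <- function(n_medium = 1.36, width = 80, depth = 120,
                          grid_spacing = 0.1) {
  nx <- ceiling(width / grid_spacing)
  nz <- ceiling(depth / grid_spacing)
  x <- (seq_len(nx) - 0.5) * grid_spacing - nx * grid_spacing / 2
  z <- (seq_len(nz) - 0.5) * grid_spacing
  structure(list(
    n = matrix(n_medium, nx, nz), x = x, z = z, grid_spacing = grid_spacing,
    origin = c(x = x[1], z = z[1]), lattice = NULL
  ), class = "index_field")
}

#' Export lattice cell centres as CSV
#'
#' @param lattice A `cell_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(lattice, path) {
  stopifnot(inherits(lattice, "cell_lattice"))
  utils::write.csv(lattice$centers[c("id", "x", "z", "diameter")], path,
                   row.names = FALSE)
  invisible(path)
}
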