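# Thin-3-D mode: sphere lattices and en-face C-scan rasters.
#
# C-scans need a genuinely 3-D sample (a 2-D cylinder lattice is invariant
# along y). Spheres are laid out in stacked (x, y) grids; the split-step
# propagator acts on 2-D transverse fields via the 2-D FFT. Grids are kept
# coarse: the C-scan reproduces the lateral quasi-periodicity of the cell
# arrangement, not fine interference detail.

#' Build a 3-D lattice of spherical cells
#'
#' `n_layers` stacked square grids of `cells_x` by `cells_y` spheres at one
#' outer diameter spacing; `packing = "hexagonal"` offsets every second
#' layer by half a diameter along x. Jitter displaces each centre per axis
#' by uniform draws in `[-f D/2, f D/2]` and scales diameters by
#' `[1 - f, 1 + f]`, deterministically in `seed`.
#'
#' @inheritParams build_lattice
#' @param cells_x,cells_y Cells per layer along x and y.
#' @return A `cell_lattice_3d` with a `centers` data.frame
#'   (`id, x, y, z, diameter`).
#' @export
build_lattice_3d <- function(cell, n_layers = 3, cells_x = 3, cells_y = 3,
                             n_ISF = 1.36, packing = c("square", "hexagonal"),
                             jitter_fraction = 0, seed = 1L,
                             jitter_diameter = TRUE) {
  stopifnot(inherits(cell, "cell_model"))
  packing <- match.arg(packing)
  if (jitter_fraction < 0 || jitter_fraction >= 0.5)
    stop("'jitter_fraction' must be in [0, 0.5)", call. = FALSE)
  D <- cell$outer_diameter
  cx <- (seq_len(cells_x) - (cells_x + 1) / 2) * D
  cy <- (seq_len(cells_y) - (cells_y + 1) / 2) * D
  rows <- lapply(seq_len(n_layers), function(j) {
    off <- if (packing == "hexagonal" && j %% 2 == 0) D / 2 else 0
    g <- expand.grid(x = cx + off, y = cy)
    g$z <- (j - 0.5) * D
    g$layer <- j
    g
  })
  centers <- do.call(rbind, rows)
  centers$diameter <- D
  if (jitter_fraction > 0) {
    n <- nrow(centers)
    draws <- withr_local_seed(seed, {
      list(dx = stats::runif(n, -1, 1), dy = stats::runif(n, -1, 1),
           dz = stats::runif(n, -1, 1), ds = stats::runif(n, -1, 1))
    })
    f <- jitter_fraction
    centers$x <- centers$x + draws$dx * f * D / 2
    centers$y <- centers$y + draws$dy * f * D / 2
    centers$z <- centers$z + draws$dz * f * D / 2
    if (jitter_diameter) centers$diameter <- D * (1 + draws$ds * f)
  }
  centers <- data.frame(id = seq_len(nrow(centers)), centers)
  structure(list(cell = cell, n_layers = n_layers, cells_x = cells_x,
                 cells_y = cells_y, n_ISF = n_ISF, packing = packing,
                 jitter_fraction = jitter_fraction, seed = seed,
                 centers = centers, thickness = n_layers * D),
            class = "cell_lattice_3d")
}

#' @export
print.cell_lattice_3d <- function(x, ...) {
  cat(sprintf(
    "3-D cell lattice: %d layers x %d x %d spheres (%s), n_ISF = %.3f\n",
    x$n_layers, x$cells_x, x$cells_y, x$packing, x$n_ISF))
  invisible(x)
}

# Refractive-index slice of a 3-D lattice at depth z (soft boundaries).
lattice3d_slice <- function(lat, xg, yg, z, soft) {
  cell <- lat$cell
  r_core <- cell$core_diameter / 2
  r_cyt <- r_core + cell$cytoplasm_thickness
  n <- matrix(lat$n_ISF, length(xg), length(yg))
  blend <- function(r, rb) 1 / (1 + exp((r - rb) / (max(soft, 1e-6) / 4)))
  cc <- lat$centers
  near <- which(abs(cc$z - z) <= cc$diameter / 2 + 3 * soft)
  for (i in near) {
    scale <- cc$diameter[i] / cell$outer_diameter
    dz2 <- (z - cc$z[i])^2
    r <- sqrt(outer((xg - cc$x[i])^2, (yg - cc$y[i])^2, `+`) + dz2) / scale
    n <- n + blend(r, r_cyt) * (cell$n_cytoplasm - lat$n_ISF) +
      blend(r, r_core) * (cell$n_core - cell$n_cytoplasm)
  }
  n
}

# En-face C-scan over a 2-D raster of beam positions on a 3-D sphere lattice.
scan_cscan_3d <- function(lattice3, source, positions, c_depth = 100,
                          n_trials = 1, seed = 1, grid_spacing = 0.4,
                          soft = 0.1, dz = NULL, ambient_index = 1,
                          domain_padding = 12, k_stride = 2, ...) {
  stopifnot(inherits(lattice3, "cell_lattice_3d"))
  if (is.null(dz)) dz <- 3 * grid_spacing
  D <- lattice3$cell$outer_diameter
  half_x <- lattice3$cells_x * D / 2 + domain_padding
  half_y <- lattice3$cells_y * D / 2 + domain_padding
  nx <- 2L * ceiling(half_x / grid_spacing)
  ny <- 2L * ceiling(half_y / grid_spacing)
  xg <- (seq_len(nx) - 0.5) * grid_spacing - nx * grid_spacing / 2
  yg <- (seq_len(ny) - 0.5) * grid_spacing - ny * grid_spacing / 2
  zmax <- lattice3$thickness
  zg <- seq(dz / 2, zmax, by = dz)
  nz <- length(zg)
  if (any(positions[, 1] < min(xg)) || any(positions[, 1] > max(xg)) ||
      any(positions[, 2] < min(yg)) || any(positions[, 2] > max(yg)))
    stop("positions outside fragment", call. = FALSE)
  ki <- seq(1, length(source$k), by = k_stride)
  ks <- source$k[ki]
  wk <- source$weights[ki]
  n_ref <- lattice3$n_ISF
  kx2 <- outer(lateral_wavenumbers(nx, grid_spacing)^2,
               lateral_wavenumbers(ny, grid_spacing)^2, `+`)
  mask <- outer(edge_mask(nx, 0.08), edge_mask(ny, 0.08))
  w0 <- source$focus_beam_diameter / 2
  npos <- nrow(positions)
  Wmat <- matrix(0, npos, 2)
  mean_n <- NA_real_
  for (trial in seq_len(n_trials)) {
    lat <- lattice3
    if (lattice3$jitter_fraction > 0) {
      trial_seed <- (seed %% 1000003L) * 1009L + trial
      lat <- build_lattice_3d(lattice3$cell, lattice3$n_layers,
                              lattice3$cells_x, lattice3$cells_y,
                              lattice3$n_ISF, lattice3$packing,
                              lattice3$jitter_fraction, seed = trial_seed)
    }
    slices <- lapply(zg, function(z) lattice3d_slice(lat, xg, yg, z, soft))
    if (is.na(mean_n)) mean_n <- mean(vapply(slices, mean, numeric(1)))
    zeta0 <- c_depth * mean_n  # target slab, geometric -> optical depth
    rmaps <- vector("list", nz)
    for (j in seq_len(nz))
      rmaps[[j]] <- if (j < nz)
        (slices[[j]] - slices[[j + 1]]) / (slices[[j]] + slices[[j + 1]])
      else matrix(0, nx, ny)
    r_surf <- (ambient_index - slices[[1]]) / (ambient_index + slices[[1]])
    Fst <- array(0i, c(nx, ny, nz))
    for (p in seq_len(npos)) {
      beam0 <- exp(-(outer((xg - positions[p, 1])^2,
                           (yg - positions[p, 2])^2, `+`)) / w0^2)
      S <- complex(length(ks))
      for (q in seq_along(ks)) {
        k0q <- ks[q]
        kz <- sqrt(as.complex((k0q * n_ref)^2 - kx2))
        kz[Re(kz) == 0] <- 0
        A0 <- stats::fft(beam0 + 0i)
        E0 <- stats::fft(A0 * exp(-1i * kz * source$focus_depth),
                         inverse = TRUE) / (nx * ny)
        prop <- exp(1i * kz * dz)
        E <- E0
        for (j in seq_len(nz)) {
          scr <- exp(1i * k0q * (slices[[j]] - n_ref) * dz / 2)
          E <- E * scr
          E <- stats::fft(stats::fft(E) * prop, inverse = TRUE) / (nx * ny)
          E <- E * scr * mask
          Fst[, , j] <- E
        }
        B <- matrix(0i, nx, ny)
        for (j in rev(seq_len(nz))) {
          B <- B + rmaps[[j]] * Fst[, , j]
          scr <- exp(1i * k0q * (slices[[j]] - n_ref) * dz / 2)
          B <- B * scr
          B <- stats::fft(stats::fft(B) * prop, inverse = TRUE) / (nx * ny)
          B <- B * scr * mask
        }
        B <- B + r_surf * E0
        S[q] <- sum(B * Conj(E0)) * grid_spacing^2
      }
      env <- Mod(c(sum(wk * S), sum(wk * S * exp(-2i * ks * zeta0))))^2
      Wmat[p, ] <- Wmat[p, ] + env
    }
  }
  Wmat <- Wmat / n_trials
  Wv <- log10(1 + Wmat[, 2] / Wmat[, 1])
  ux <- sort(unique(positions[, 1]))
  uy <- sort(unique(positions[, 2]))
  W <- if (npos == length(ux) * length(uy)) {
    matrix(Wv[order(positions[, 2], positions[, 1])], length(ux), length(uy))
  } else matrix(Wv, ncol = 1)
  structure(list(kind = "C", W = W, positions = positions, c_depth = c_depth,
                 x = ux, y = uy, n_trials = n_trials, seed = seed,
                 source = source, mean_index = mean_n),
            class = "oct_scan")
}
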