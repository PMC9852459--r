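# Wave Monte-Carlo synthesis of OCT scans.
#
# A time-domain OCT measurement is emulated spectrally: the source spectrum
# is sampled at N_k wavenumbers, the sample beam is propagated down through
# the refractive-index map with the unidirectional split-step propagator,
# local backscatter is seeded at every depth step from the refractive-index
# gradient, the backscattered field is propagated back to the surface
# through the same medium, and its overlap with the reference (incident)
# beam gives the interference signal per wavenumber. The inverse transform
# over the spectrum yields the depth-resolved envelope; averaging the
# envelope energy over Monte-Carlo trials (each redrawing the lattice
# disorder) and applying the log transform
# W = log10(1 + W_oct(z)/W_oct(0)) gives the displayed scan.

#' OCT source and beam geometry
#'
#' Describes the low-coherence source and the focused sample beam. The
#' Gaussian power spectrum is fitted so that the axial point-spread function
#' in air has FWHM equal to `axial_resolution_air` (the width of the
#' envelope of the spectral synthesis), and it is sampled at
#' `n_spectral_samples` wavenumbers across +/- 3 standard deviations.
#'
#' @param center_wavelength Centre vacuum wavelength (um).
#' @param bandwidth Nominal source bandwidth (um), informational.
#' @param axial_resolution_air Axial resolution (PSF FWHM) in air (um).
#' @param surface_beam_diameter Beam diameter at the tissue surface (um).
#' @param focus_beam_diameter Beam diameter (2x waist) in the focus (um).
#' @param focus_depth Depth of the focus below the surface (um).
#' @param n_spectral_samples Number of spectral samples N_k.
#' @param n_medium Tissue index used for the focus-geometry consistency
#'   check.
#' @return An `oct_source` with the sampled wavenumbers `k` and their
#'   power-spectrum weights `weights`.
#' @export
oct_source <- function(center_wavelength = 0.93, bandwidth = 0.1,
                       axial_resolution_air = 6.2,
                       surface_beam_diameter = 12, focus_beam_diameter = 10,
                       focus_depth = 100, n_spectral_samples = 64,
                       n_medium = 1.36) {
  k0 <- 2 * pi / center_wavelength
  sigma_k <- sqrt(2 * log(2)) / axial_resolution_air
  k <- k0 + seq(-3, 3, length.out = n_spectral_samples) * sigma_k
  w <- exp(-(k - k0)^2 / (2 * sigma_k^2))
  # check the focus geometry against Gaussian-beam spreading in the medium
  w0 <- focus_beam_diameter / 2
  zr <- pi * w0^2 * n_medium / center_wavelength
  d_surf <- focus_beam_diameter * sqrt(1 + (focus_depth / zr)^2)
  if (abs(d_surf - surface_beam_diameter) / surface_beam_diameter > 0.2)
    warning(sprintf(
      "surface beam diameter %.3g um inconsistent with focus geometry (%.3g um)",
      surface_beam_diameter, d_surf))
  structure(list(center_wavelength = center_wavelength, bandwidth = bandwidth,
                 axial_resolution_air = axial_resolution_air,
                 surface_beam_diameter = surface_beam_diameter,
                 focus_beam_diameter = focus_beam_diameter,
                 focus_depth = focus_depth,
                 n_spectral_samples = n_spectral_samples,
                 k = k, weights = w, sigma_k = sigma_k),
            class = "oct_source")
}

#' @export
print.oct_source <- function(x, ...) {
  cat(sprintf(
    "OCT source: %.0f nm centre, axial resolution %.2f um (air), %d k-samples\n",
    1000 * x$center_wavelength, x$axial_resolution_air, x$n_spectral_samples))
  cat(sprintf("  beam: %.3g um at surface, %.3g um at %.3g um focus\n",
              x$surface_beam_diameter, x$focus_beam_diameter, x$focus_depth))
  invisible(x)
}

#' Axial point-spread function of the synthesized scan
#'
#' Envelope of the spectral synthesis for a single perfect reflector at zero
#' depth in a medium of index `n_medium` -- the coherence-gating PSF of the
#' simulated system.
#'
#' @param source An [oct_source()].
#' @param n_medium Medium refractive index.
#' @param span,dz Evaluation range and step around the reflector (um).
#' @return data.frame with `z` (um) and normalized envelope `a`, FWHM in
#'   attribute `"fwhm"`.
#' @export
axial_psf <- function(source, n_medium = 1, span = 20, dz = 0.02) {
  z <- seq(-span / 2, span / 2, by = dz)
  ph <- outer(z * n_medium, source$k, function(zz, kk) exp(-2i * kk * zz))
  a <- Mod(ph %*% source$weights)
  a <- a / max(a)
  half <- which(a >= 0.5)
  fwhm <- z[max(half)] - z[min(half)]
  out <- data.frame(z = z, a = as.numeric(a))
  attr(out, "fwhm") <- fwhm
  out
}

#' In-tissue axial resolution
#'
#' The axial resolution inside tissue is the in-air figure divided by the
#' mean refractive index. Also verifies, by synthesizing a point reflector,
#' that the source spectrum actually delivers the stated in-air resolution
#' (to 5%).
#'
#' @param source An [oct_source()].
#' @param mean_index Mean tissue refractive index.
#' @return Resolution in tissue (um), with the measured in-air PSF FWHM in
#'   attribute `"psf_fwhm_air"`.
#' @examples
#' calibrate_axial_resolution(oct_source(), 1.47)  # 4.2 um
#' @export
calibrate_axial_resolution <- function(source, mean_index) {
  stopifnot(inherits(source, "oct_source"), mean_index >= 1)
  fwhm <- attr(axial_psf(source, n_medium = 1), "fwhm")
  if (abs(fwhm - source$axial_resolution_air) / source$axial_resolution_air >
      0.05)
    warning(sprintf(
      "synthesized PSF FWHM %.3g um deviates from nominal %.3g um",
      fwhm, source$axial_resolution_air))
  structure(source$axial_resolution_air / mean_index, psf_fwhm_air = fwhm)
}

#' Local amplitude reflectance from the refractive-index gradient
#'
#' Per-step Fresnel amplitude reflectance between successive depth pixels,
#' `(n(z) - n(z + dz)) / (n(z) + n(z + dz))`, evaluated at every
#' transverse position. Summed over a soft boundary the per-step values
#' converge to the sharp-interface Fresnel coefficient. Optionally includes
#' the ambient/tissue surface step ahead of the first pixel.
#'
#' @param index_field An `index_field`.
#' @param ambient_index Index of the medium above the sample (`NA` to omit
#'   the surface reflection).
#' @return A `reflectance_map`: matrix `r` (x by z; column j is the
#'   reflectance at the lower boundary of pixel j), `r_surface`, coordinates.
#' @export
local_reflectance <- function(index_field, ambient_index = NA) {
  n <- index_field$n
  nz <- ncol(n)
  r <- (n[, -nz, drop = FALSE] - n[, -1, drop = FALSE]) /
    (n[, -nz, drop = FALSE] + n[, -1, drop = FALSE])
  r <- cbind(r, 0)
  r_surface <- if (is.na(ambient_index)) rep(0, nrow(n)) else
    (ambient_index - n[, 1]) / (ambient_index + n[, 1])
  structure(list(r = r, r_surface = r_surface, x = index_field$x,
                 z = index_field$z, grid_spacing = index_field$grid_spacing),
            class = "reflectance_map")
}

#' Aggregate power reflectance of a depth slab
#'
#' Sums `|r|^2` of a [local_reflectance()] map over a depth slab, giving the
#' lateral reflection-coefficient profile `R(z0, x)` of that layer (maximal
#' at cell edges).
#'
#' @param rmap A `reflectance_map`.
#' @param depth Slab centre (um).
#' @param slab_width Slab thickness (um).
#' @return Numeric vector `R(x)`.
#' @export
aggregate_reflectance <- function(rmap, depth, slab_width = 20) {
  sel <- abs(rmap$z - depth) <= slab_width / 2
  if (!any(sel)) stop("slab outside the field", call. = FALSE)
  rowSums(rmap$r[, sel, drop = FALSE]^2)
}

# Resolve the geometry argument: a ready index_field, or a cell_lattice that
# is (re-)jittered per Monte-Carlo trial and rasterized with soft boundaries.
oct_geometry <- function(geometry, trial, seed, grid_spacing, soft,
                         domain_padding) {
  if (inherits(geometry, "index_field")) return(geometry)
  stopifnot(inherits(geometry, "cell_lattice"))
  lat <- geometry
  if (lat$jitter_fraction > 0) {
    trial_seed <- (seed %% 1000003L) * 1009L + trial
    lat <- build_lattice(lat$cell, lat$n_layers, lat$cells_per_layer,
                         lat$n_ISF, lat$packing, lat$jitter_fraction,
                         seed = trial_seed)
  }
  rasterize(lat, grid_spacing = grid_spacing, domain_padding = domain_padding,
            soft = soft)
}

# Core spectral-domain engine: returns the complex interference signal per
# wavenumber for one geometry realisation and one beam position.
oct_signal_2d <- function(index_field, source, beam_position, dz = NULL,
                          ambient_index = 1, absorb = 0.08, k_batch = 16) {
  n <- index_field$n
  dx <- index_field$grid_spacing
  if (is.null(dz)) dz <- dx
  nx <- nrow(n); nz <- ncol(n)
  x <- index_field$x
  n_ref <- stats::median(n[, 1])
  ks <- source$k
  w0 <- source$focus_beam_diameter / 2
  kx <- lateral_wavenumbers(nx, dx)
  mask <- edge_mask(nx, absorb)
  rmap <- local_reflectance(index_field, ambient_index)
  S <- complex(length(ks))
  A0 <- stats::fft(exp(-((x - beam_position)^2) / w0^2) + 0i)
  for (b0 in seq(1, length(ks), by = k_batch)) {
    bi <- b0:min(b0 + k_batch - 1, length(ks))
    kb <- ks[bi]
    nb <- length(bi)
    kz <- sqrt(outer(-kx^2, (kb * n_ref)^2, `+`) + 0i)
    kz[Re(kz) == 0] <- 0    # drop evanescent content of the focused beam
    # incident beam at the surface, waist at focus_depth, per wavenumber
    E0 <- stats::mvfft(A0 * exp(-1i * kz * source$focus_depth),
                       inverse = TRUE) / nx
    prop <- exp(1i * sqrt(outer(-kx^2, (kb * n_ref)^2, `+`) + 0i) * dz)
    # forward sweep, storing the field at every depth pixel
    Fst <- array(0i, c(nx, nb, nz))
    E <- E0
    for (j in seq_len(nz)) {
      E <- split_step_slab(E, n[, j], kb, n_ref, dz, prop, mask)
      Fst[, , j] <- E
    }
    # backward sweep: seed backscatter at each depth, propagate to surface
    B <- matrix(0i, nx, nb)
    for (j in rev(seq_len(nz))) {
      B <- B + rmap$r[, j] * Fst[, , j]
      B <- split_step_slab(B, n[, j], kb, n_ref, dz, prop, mask)
    }
    B <- B + rmap$r_surface * E0
    # overlap with the reference (incident) beam
    S[bi] <- colSums(B * Conj(E0)) * dx
  }
  S
}

# Spectral synthesis: envelope energy on an optical-depth grid.
oct_synthesize <- function(S, source, zeta) {
  ph <- outer(zeta, source$k, function(zz, kk) exp(-2i * kk * zz))
  Mod(ph %*% (source$weights * S))^2
}

#' Synthesize an OCT A-scan
#'
#' Runs the wave Monte-Carlo scheme for a single lateral beam position:
#' spectral forward propagation, gradient-derived backscatter, backward
#' propagation, interference with the reference beam, ensemble averaging
#' over trials (each trial redraws the lattice disorder when `geometry` is a
#' jittered lattice) and the log transform
#' `W = log10(1 + W_oct(z)/W_oct(0))`, normalized to the top-surface
#' specular response.
#'
#' @param geometry An `index_field`, or a `cell_lattice` (rasterized with
#'   soft boundaries; re-jittered each trial when its `jitter_fraction > 0`).
#' @param source An [oct_source()].
#' @param beam_position Lateral beam position (um).
#' @param n_trials Monte-Carlo ensemble size.
#' @param seed Integer seed; scans are reproducible given the seed.
#' @param grid_spacing Raster pixel size when `geometry` is a lattice (um).
#' @param soft Soft-boundary width for lattice rasterization (um).
#'   Kept well below the wavelength: a blur of ~lambda/2 or more suppresses
#'   the coherent backscatter of the shell boundaries almost completely.
#' @param dz Propagation step (um); defaults to the grid spacing.
#' @param ambient_index Index above the sample surface (gives the z = 0
#'   reference peak); `NA` disables the surface echo.
#' @param dzeta Output sampling in optical depth (um).
#' @param zeta_max Maximum optical depth (um); default covers the domain.
#' @param domain_padding Lateral raster padding for lattices (um).
#' @param k_batch Wavenumbers propagated per batch (memory/time trade-off).
#' @return An `oct_scan` of kind "A": `W` (vector), `zeta` (optical depth,
#'   um), `depth` (geometric depth, um), plus the raw averaged envelope.
#' @export
synthesize_ascan <- function(geometry, source = oct_source(),
                             beam_position = 0, n_trials = 1, seed = 1,
                             grid_spacing = 0.1, soft = 0.1, dz = NULL,
                             ambient_index = 1, dzeta = 0.5, zeta_max = NULL,
                             domain_padding = 20, k_batch = 16) {
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  acc <- NULL
  for (trial in seq_len(n_trials)) {
    fld <- oct_geometry(geometry, trial, seed, grid_spacing, soft,
                        domain_padding)
    if (trial == 1) {
      if (beam_position < min(fld$x) || beam_position > max(fld$x))
        stop("beam position outside the lateral extent", call. = FALSE)
      zspan <- max(fld$z) + fld$grid_spacing / 2
      if (source$focus_depth > zspan)
        warning("focus depth lies below the simulated fragment")
      if (is.null(zeta_max)) zeta_max <- ceiling(zspan * max(fld$n) + 10)
      zeta <- seq(0, zeta_max, by = dzeta)
      dk <- source$k[2] - source$k[1]
      if (zeta_max > 0.9 * pi / dk)
        warning(sprintf(
          "optical depth %.0f um close to the spectral alias range %.0f um; increase n_spectral_samples",
          zeta_max, pi / dk))
      mean_n <- mean(fld$n)
    }
    S <- oct_signal_2d(fld, source, beam_position, dz = dz,
                       ambient_index = ambient_index, k_batch = k_batch)
    env <- oct_synthesize(S, source, zeta)
    acc <- if (is.null(acc)) env else acc + env
  }
  Wo <- as.numeric(acc) / n_trials
  W <- log10(1 + Wo / Wo[1])
  structure(list(kind = "A", W = W, envelope = Wo, zeta = zeta,
                 depth = zeta / mean_n, mean_index = mean_n,
                 positions = beam_position, n_trials = n_trials, seed = seed,
                 source = source),
            class = "oct_scan")
}

#' Assemble B- or C-scans from a raster of beam positions
#'
#' Stacks A-scans over a line of lateral positions (B-scan) or, for a 3-D
#' sphere lattice, over a 2-D grid of positions, extracting the en-face W
#' slab at `c_depth` (C-scan).
#'
#' @param geometry As in [synthesize_ascan()]; for C-scans a
#'   `cell_lattice_3d` from [build_lattice_3d()].
#' @param source An [oct_source()].
#' @param positions Numeric vector of lateral positions (B), or a 2-column
#'   matrix / data.frame of (x, y) positions (C).
#' @param c_depth Geometric depth of the extracted C-scan slab (um).
#' @param ... Passed on to the A-scan engine.
#' @return An `oct_scan` of kind "B" (`W` is depth x position) or "C"
#'   (`W` is a position-grid matrix at `c_depth`).
#' @export
scan_raster <- function(geometry, source = oct_source(), positions,
                        c_depth = 100, ...) {
  if (is.matrix(positions) || is.data.frame(positions)) {
    return(scan_cscan_3d(geometry, source, as.matrix(positions), c_depth,
                         ...))
  }
  scans <- vector("list", length(positions))
  bad <- character(0)
  for (i in seq_along(positions)) {
    res <- tryCatch(
      synthesize_ascan(geometry, source, beam_position = positions[i], ...),
      error = function(e) {
        if (grepl("outside the lateral extent", conditionMessage(e)))
          NULL else stop(e)
      })
    if (is.null(res)) bad <- c(bad, format(positions[i]))
    else scans[[i]] <- res
  }
  if (length(bad))
    stop("positions outside fragment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  W <- do.call(cbind, lapply(scans, `[[`, "W"))
  s1 <- scans[[1]]
  structure(list(kind = "B", W = W, zeta = s1$zeta, depth = s1$depth,
                 mean_index = s1$mean_index, positions = positions,
                 n_trials = s1$n_trials, seed = s1$seed, source = source),
            class = "oct_scan")
}

#' @export
print.oct_scan <- function(x, ...) {
  cat(sprintf("OCT %s-scan: ", x$kind))
  if (x$kind == "A")
    cat(sprintf("%d depth samples to %.0f um optical depth", length(x$W),
                max(x$zeta)))
  else if (x$kind == "B")
    cat(sprintf("%d x %d (depth x position)", nrow(x$W), ncol(x$W)))
  else
    cat(sprintf("%d x %d positions at %.0f um depth", nrow(x$W), ncol(x$W),
                x$c_depth))
  cat(sprintf(", %d trial(s)\n", x$n_trials))
  invisible(x)
}
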