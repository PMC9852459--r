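#' Solve monochromatic propagation of a focused beam through a cell lattice
#'
#' Computes the steady-state complex field of a Gaussian beam travelling
#' through the refractive-index map of a cell lattice. Two engines are
#' available:
#'
#' * `"born"` -- convergent Born series, a full-wave frequency-domain solve
#'   in the scattered-field formalism with an absorbing boundary ramp.
#'   Accurate to the Mie-oracle gate (including backscatter) but costly on
#'   large domains.
#' * `"split_step"` -- unidirectional Helmholtz split-step (angular-spectrum
#'   diffraction + refractive phase screens). Seconds per lattice solve;
#'   forward-only physics.
#'
#' @param index_field An `index_field` from [rasterize()] or
#'   [uniform_field()].
#' @param beam A [beam_spec()].
#' @param method `"split_step"` or `"born"`.
#' @param dz Propagation step for the split-step engine (um); defaults to the
#'   grid spacing.
#' @param tol Convergence tolerance of the Born iteration (relative update
#'   norm).
#' @param absorb Lateral edge-absorber fraction for the split-step engine.
#' @return A `complex_field`: `amplitude` (x by z complex matrix of the total
#'   field), `intensity`, coordinates, `wavelength`, the beam, the method and
#'   its convergence diagnostics.
#' @export
solve_forward <- function(index_field, beam = beam_spec(),
                          method = c("split_step", "born"),
                          dz = NULL, tol = 1e-5, absorb = 0.08) {
  stopifnot(inherits(index_field, "index_field"),
            inherits(beam, "beam_spec"))
  method <- match.arg(method)
  if (any(index_field$n < 1))
    stop("index field must be >= 1 everywhere", call. = FALSE)
  x <- index_field$x
  z <- index_field$z
  n_bg <- index_field$n[1, 1]  # corner pixel: embedding medium
  x0 <- beam_axis(index_field, beam)
  if (method == "split_step") {
    E0 <- gaussian_beam_field(x, z[1] - index_field$grid_spacing / 2,
                              beam$waist, beam$wavelength, n_bg, x0,
                              focus_z = beam$focus_depth)
    run <- split_step_run(index_field, E0, beam$wavelength, n_ref = n_bg,
                          dz = dz, absorb = absorb, keep_map = TRUE)
    amp <- NULL
    conv <- list(deterministic = TRUE)
    intensity <- run$I
    exit_field <- run$E
  } else {
    E_inc <- gaussian_beam_field(x, z, beam$waist, beam$wavelength, n_bg,
                                 x0, focus_z = beam$focus_depth)
    sol <- solve_born(index_field, E_inc, beam$wavelength, n_bg, tol = tol)
    amp <- sol$E_scat + E_inc
    conv <- list(iterations = sol$iterations, residuals = sol$residuals)
    intensity <- Mod(amp)^2
    exit_field <- amp[, ncol(amp)]
  }
  structure(list(
    amplitude = amp, intensity = intensity, exit_field = exit_field,
    x = x, z = z, grid_spacing = index_field$grid_spacing,
    wavelength = beam$wavelength, beam = beam, beam_axis = x0,
    n_background = n_bg, method = method, convergence = conv
  ), class = "complex_field")
}

# Lateral position of the beam axis: the reference cell centre (the cell just
# left of the lattice midline in the top layer) plus the requested offset;
# plain x = offset for uniform fields.
beam_axis <- function(index_field, beam) {
  lat <- index_field$lattice
  if (is.null(lat)) return(beam$lateral_offset)
  top <- lat$centers[lat$centers$layer == 1, ]
  ref <- top$x[ceiling(nrow(top) / 2)]
  ref + beam$lateral_offset
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("Complex field (%s): %d x %d px, lambda = %.3f um\n",
              x$method, length(x$x), length(x$z), x$wavelength))
  if (!is.null(x$convergence$iterations))
    cat(sprintf("  Born iterations: %d (final residual %.2e)\n",
                x$convergence$iterations, utils::tail(x$convergence$residuals, 1)))
  invisible(x)
}

#' Windowed collimated transmittance
#'
#' Fraction of the incident beam power that crosses a lateral window at a
#' given depth, the quantity reported for cleared and uncleared lattices.
#' Power is measured as the integral of `|E|^2` across the window (the
#' paraxial surrogate for the longitudinal Poynting flux, validated against
#' the free-space closed form) and normalized by the total incident beam
#' power.
#'
#' @param field A `complex_field` from [solve_forward()].
#' @param z_plane Depth of the evaluation plane (um); defaults to the exit
#'   plane of the solved domain.
#' @param window_width Width of the collection window (um).
#' @param window_center Lateral centre of the window (um); defaults to the
#'   beam axis.
#' @return A `transmission_result`: `T`, the window, the plane and the raw
#'   powers.
#' @export
transmitted_fraction <- function(field, z_plane = NULL, window_width = 20,
                                 window_center = NULL) {
  stopifnot(inherits(field, "complex_field"))
  x <- field$x
  if (is.null(window_center)) window_center <- field$beam_axis
  win <- abs(x - window_center) <= window_width / 2
  if (x[1] > window_center - window_width / 2 ||
      x[length(x)] < window_center + window_width / 2)
    stop("window extends outside the solved domain", call. = FALSE)
  if (is.null(z_plane)) {
    profile <- Mod(field$exit_field)^2
    z_plane <- field$z[length(field$z)] + field$grid_spacing / 2
  } else {
    j <- which.min(abs(field$z - z_plane))
    profile <- field$intensity[, j]
  }
  # incident power of the unit-amplitude Gaussian beam on the same grid
  P0 <- sum(exp(-2 * (x - field$beam_axis)^2 / field$beam$waist^2))
  Pt <- sum(profile[win])
  structure(list(T = Pt / P0, window_width = window_width,
                 window_center = window_center, z_plane = z_plane,
                 incident_power = P0, transmitted_power = Pt),
            class = "transmission_result")
}

#' @export
print.transmission_result <- function(x, ...) {
  cat(sprintf("T = %.4f (%.1f%%), window %.3g um at z = %.5g um\n",
              x$T, 100 * x$T, x$window_width, x$z_plane))
  invisible(x)
}

#' Locate intensity hot spots along a lateral line
#'
#' Finds local maxima of the intensity profile at a given depth whose
#' prominence (peak height above the higher of the two flanking minima)
#' exceeds a threshold. This is how the bright transmitted sub-beams at the
#' bottom surface of a cell stack are counted.
#'
#' @param field A `complex_field`.
#' @param z_line Depth of the extraction line (um); defaults to the exit
#'   plane.
#' @param min_prominence Minimum prominence as a fraction of the profile
#'   maximum.
#' @return A `hotspot_set`: sorted positions (um), intensities, the profile
#'   and the threshold used. May be empty.
#' @export
find_hotspots <- function(field, z_line = NULL, min_prominence = 0.05) {
  stopifnot(inherits(field, "complex_field"))
  if (is.null(z_line)) {
    profile <- Mod(field$exit_field)^2
  } else {
    j <- which.min(abs(field$z - z_line))
    profile <- field$intensity[, j]
  }
  pk <- peak_prominences(profile)
  keep <- pk$prominence >= min_prominence * max(profile)
  structure(list(positions = field$x[pk$index[keep]],
                 intensities = profile[pk$index[keep]],
                 profile = profile, x = field$x,
                 min_prominence = min_prominence),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("%d hot spot(s)\n", length(x$positions)))
  if (length(x$positions))
    print(data.frame(position_um = round(x$positions, 3),
                     intensity = signif(x$intensities, 4)))
  invisible(x)
}

# Local maxima of a vector with their prominences (height above the higher of
# the two flanking valley minima, walking outward until a higher peak or the
# signal edge).
peak_prominences <- function(y) {
  n <- length(y)
  if (n < 3) return(list(index = integer(0), prominence = numeric(0)))
  is_pk <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(is_pk, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) + 1 else 1,
                             to = i - 1)])
    right <- y[seq.int(i + 1, n)]
    higher_r <- which(right > h)
    rmin <- min(right[seq.int(1, if (length(higher_r)) min(higher_r) - 1
                              else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  list(index = is_pk, prominence = prom)
}
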