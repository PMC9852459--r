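# Numerical engines for monochromatic scalar Helmholtz propagation.
#
# Two solvers share the module contract:
#  * solve_born():  convergent Born series -- a full-wave frequency-domain
#    method. The Helmholtz operator is split around a complex reference
#    wavenumber; the resulting preconditioned fixed-point iteration converges
#    unconditionally and each step costs two FFTs. Scattered-field formalism:
#    the incident beam is prescribed analytically everywhere and only the
#    scattered field is solved for; an absorbing ramp surrounds the domain.
#  * split_step_run(): unidirectional (one-way) Helmholtz split-step --
#    exact angular-spectrum diffraction in the homogeneous reference medium
#    alternated with local refractive phase screens (Strang splitting).
#    Fast enough for lattice-scale sweeps and the OCT Monte-Carlo ensemble,
#    but blind to backscatter and to components beyond ~30 deg off axis.

lateral_wavenumbers <- function(n, dx) {
  2 * pi / (n * dx) * c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1)))
}

# Supergaussian absorbing mask over `frac` of each lateral edge.
edge_mask <- function(n, frac = 0.08, strength = 6) {
  na <- max(round(frac * n), 2L)
  m <- rep(1, n)
  i <- seq_len(na)
  m[i] <- exp(-strength * ((na - i + 1) / na)^4)
  m[n + 1 - i] <- m[i]
  m
}

#' Free-space Gaussian beam field
#'
#' Exact (non-paraxial) free-space propagation of a Gaussian beam specified
#' by its waist, evaluated by the angular-spectrum method on the grid of an
#' index field. The waist plane sits at `focus_z` (0 = the illuminated
#' surface).
#'
#' @param x Lateral coordinate vector (um).
#' @param z Depth coordinate vector (um), or a single plane.
#' @param waist 1/e^2 intensity radius at the waist (um).
#' @param wavelength Vacuum wavelength (um).
#' @param n_medium Homogeneous background index.
#' @param x0 Lateral beam-centre position (um).
#' @param focus_z Depth of the waist plane (um).
#' @return Complex matrix `length(x)` by `length(z)`.
#' @export
gaussian_beam_field <- function(x, z, waist = 10, wavelength = 0.93,
                                n_medium = 1.36, x0 = 0, focus_z = 0) {
  nx <- length(x)
  dx <- x[2] - x[1]
  k0 <- 2 * pi / wavelength
  kx <- lateral_wavenumbers(nx, dx)
  kz <- sqrt(as.complex((k0 * n_medium)^2 - kx^2))
  propagating <- Re(kz) > 0   # a free beam carries no evanescent content
  A0 <- stats::fft(exp(-((x - x0)^2) / waist^2) + 0i)
  E <- matrix(0i, nx, length(z))
  for (j in seq_along(z)) {
    ph <- exp(1i * kz * (z[j] - focus_z))
    ph[!propagating] <- 0i
    E[, j] <- stats::fft(A0 * ph, inverse = TRUE) / nx
  }
  E
}

#' Specification of the illuminating beam
#'
#' @param wavelength Vacuum wavelength (um).
#' @param waist 1/e^2 intensity radius at the waist (um); the undisturbed
#'   beam width is twice this.
#' @param focus_depth Depth of the waist plane below the surface (um).
#' @param lateral_offset Beam centre relative to the lattice reference cell
#'   (um); 0 aims at a cell centre, half a diameter at the gap between cells.
#' @param polarization `"TE"` (field along the cylinder axis; the scalar
#'   problem solved here) or `"TM"`, accepted for interface compatibility.
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(wavelength = 0.93, waist = 10, focus_depth = 0,
                      lateral_offset = 0, polarization = c("TE", "TM")) {
  polarization <- match.arg(polarization)
  if (wavelength <= 0) stop("'wavelength' must be > 0", call. = FALSE)
  if (waist <= wavelength / 2)
    stop("'waist' must exceed wavelength/2", call. = FALSE)
  structure(list(wavelength = wavelength, waist = waist,
                 focus_depth = focus_depth, lateral_offset = lateral_offset,
                 polarization = polarization), class = "beam_spec")
}

# One split-step z-slab applied to field columns (one column per wavenumber).
# E: nx x m complex matrix; n_col: refractive index over x at the slab
# midplane; k0: vacuum wavenumbers (length m); prop: precomputed angular
# spectrum factors (nx x m).
split_step_slab <- function(E, n_col, k0, n_ref, dz, prop, mask = NULL) {
  scr <- exp(outer(n_col - n_ref, 1i * k0 * dz / 2))
  E <- E * scr
  E <- stats::mvfft(stats::mvfft(E) * prop, inverse = TRUE) / nrow(E)
  E <- E * scr
  if (!is.null(mask)) E <- E * mask
  E
}

#' Advance a field by one unidirectional split-step
#'
#' Applies one z-step of the one-way Helmholtz propagator: half a refractive
#' phase screen, the exact angular-spectrum diffraction step in the reference
#' medium, and the second half screen (Strang splitting). The propagator is
#' unitary in lossless media; evanescent lateral components decay.
#'
#' @param field Complex vector over x (or matrix with one column per
#'   wavenumber).
#' @param n_col Refractive index across the slab midplane.
#' @param k0 Vacuum wavenumber(s) `2*pi/lambda`, one per field column.
#' @param dx Lateral pixel size (um).
#' @param dz Step length (um).
#' @param n_ref Reference (background) index.
#' @param direction `+1` downward (into the tissue) or `-1` upward; the
#'   scalar one-way propagator is symmetric, so both use the same factors.
#' @param absorb Lateral edge-absorber fraction (0 disables).
#' @return The advanced field, same shape as `field`.
#' @export
propagate_split_step <- function(field, n_col, k0, dx, dz, n_ref,
                                 direction = 1, absorb = 0) {
  field <- as.matrix(field)
  nx <- nrow(field)
  kx <- lateral_wavenumbers(nx, dx)
  kz <- sqrt(outer(kx^2, -(k0 * n_ref)^2, `+`) * -1 + 0i)
  prop <- exp(1i * kz * abs(dz))
  mask <- if (absorb > 0) edge_mask(nx, absorb) else NULL
  spec <- Mod(stats::mvfft(field))^2
  near_nyquist <- abs(kx) > 0.95 * max(abs(kx))
  if (sum(spec[near_nyquist, ]) > 0.01 * sum(spec))
    warning("field carries > 1% of its energy at the grid Nyquist limit; ",
            "refine the lateral grid")
  out <- split_step_slab(field, n_col, k0, n_ref, abs(dz), prop, mask)
  if (ncol(out) == 1) drop(out) else out
}

# Full split-step sweep through an index field. Returns the final field and
# (optionally) the intensity map.
split_step_run <- function(index_field, E0, wavelength, n_ref = NULL,
                           dz = NULL, absorb = 0.08, keep_map = TRUE) {
  n <- index_field$n
  nx <- nrow(n)
  dx <- index_field$grid_spacing
  if (is.null(dz)) dz <- dx
  k0 <- 2 * pi / wavelength
  if (is.null(n_ref)) n_ref <- stats::median(n[, 1])
  # resample columns of n onto the dz ladder if dz != grid spacing
  nz_out <- ncol(n)
  z <- index_field$z
  z_steps <- seq(z[1] - dx / 2 + dz / 2, z[nz_out] + dx / 2 - dz / 2 + 1e-9,
                 by = dz)
  col_idx <- pmin(pmax(ceiling((z_steps - (z[1] - dx / 2)) / dx), 1L), nz_out)
  kx <- lateral_wavenumbers(nx, dx)
  prop <- matrix(exp(1i * sqrt(as.complex((k0 * n_ref)^2 - kx^2)) * dz),
                 nx, 1)
  mask <- if (absorb > 0) edge_mask(nx, absorb) else NULL
  E <- matrix(E0 + 0i, nx, 1)
  I <- if (keep_map) matrix(0, nx, nz_out) else NULL
  for (s in seq_along(z_steps)) {
    E <- split_step_slab(E, n[, col_idx[s]], k0, n_ref, dz, prop, mask)
    if (keep_map) I[, col_idx[s]] <- Mod(E)^2
  }
  list(E = drop(E), I = I, z_exit = z[nz_out] + dx / 2, n_ref = n_ref)
}

# Convergent Born series solve of (lap + k0^2 n(r)^2) E = 0 with incident
# field E_inc defined in the homogeneous background n_b. Returns the
# scattered field on the index_field grid plus the residual history.
solve_born <- function(index_field, E_inc, wavelength, n_background,
                       pad = 10, absorb_n = 0.15, tol = 1e-5,
                       max_iter = 4000, check_every = 25) {
  n0 <- index_field$n
  dx <- index_field$grid_spacing
  k0 <- 2 * pi / wavelength
  nx0 <- nrow(n0); nz0 <- ncol(n0)
  npad <- max(round(pad / dx), 4L)
  nx <- nx0 + 2L * npad; nz <- nz0 + 2L * npad
  nf <- matrix(n_background + 0i, nx, nz)
  nf[npad + seq_len(nx0), npad + seq_len(nz0)] <- n0
  ramp <- function(n, np) {
    w <- rep(0, n); i <- seq_len(np)
    w[i] <- ((np - i + 1) / np)^3
    w[n + 1 - i] <- w[i]
    w
  }
  wa <- outer(ramp(nx, npad), rep(1, nz)) + outer(rep(1, nx), ramp(nz, npad))
  nf <- nf + 1i * absorb_n * pmin(wa, 1)
  k2 <- (k0 * nf)^2
  kbar2 <- (min(Re(k2)) + max(Re(k2))) / 2
  eps <- max(Mod(k2 - kbar2)) * 1.05
  kb2c <- kbar2 + 1i * eps
  V <- k2 - kb2c
  gam <- (1i / eps) * V
  kx2 <- lateral_wavenumbers(nx, dx)^2
  kz2 <- lateral_wavenumbers(nz, dx)^2
  Gk <- 1 / (outer(kx2, kz2, `+`) - kb2c)
  Ei <- matrix(0i, nx, nz)
  Ei[npad + seq_len(nx0), npad + seq_len(nz0)] <- E_inc
  S <- (k2 - (k0 * n_background)^2) * Ei
  E <- matrix(0i, nx, nz)
  res_hist <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    upd <- gam * (stats::fft(stats::fft(V * E + S) * Gk,
                             inverse = TRUE) / length(E) - E)
    E <- E + upd
    if (it %% check_every == 0L || it >= max_iter) {
      r <- sqrt(sum(Mod(upd)^2) / max(sum(Mod(E)^2), .Machine$double.xmin))
      res_hist <- c(res_hist, r)
      if (r < tol) break
      if (it >= max_iter)
        stop(sprintf(
          "Born series did not reach tol %.1e in %d iterations (residual %.2e)",
          tol, max_iter, r), call. = FALSE)
    }
  }
  list(E_scat = E[npad + seq_len(nx0), npad + seq_len(nz0)],
       iterations = it, residuals = res_hist)
}
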