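#' Mie-estimate scattering coefficient of a packed particle layer
#'
#' Rough Mie estimate for large soft particles: `mu_s = a^2 * rho_s * (m-1)^2`
#' with particle size `a`, number density `rho_s` and relative refractive
#' index `m = n_LD / n_ISF` of the lipid droplets against the interstitial
#' fluid. Under the close-packing convention used throughout this package,
#' `a` is the cell outer diameter and `rho_s` one cell per `a^2 x 1 um` of
#' depth, so `a^2 * rho_s = 1 um^-1` exactly; the product is exposed as the
#' single parameter `a2rho` in [transmittance()] and
#' [relative_index_from_T()].
#'
#' @param a Particle size entering the estimate (um).
#' @param rho_s Particle number density (um^-3).
#' @param m Relative refractive index (dimensionless), or supply `n_LD` and
#'   `n_ISF`.
#' @param n_LD,n_ISF Component indices; used when `m` is missing.
#' @return Scattering coefficient (um^-1).
#' @examples
#' scattering_coefficient(20.02, 1 / 20.02^2, n_LD = 1.46, n_ISF = 1.36)
#' @export
scattering_coefficient <- function(a, rho_s, m = NULL, n_LD = NULL,
                                   n_ISF = NULL) {
  if (is.null(m)) {
    if (is.null(n_LD) || is.null(n_ISF))
      stop("supply 'm' or both 'n_LD' and 'n_ISF'", call. = FALSE)
    m <- n_LD / n_ISF
  }
  if (any(a <= 0) || any(rho_s <= 0)) stop("'a' and 'rho_s' must be > 0",
                                           call. = FALSE)
  if (any(m <= 0)) stop("'m' must be > 0", call. = FALSE)
  a^2 * rho_s * (m - 1)^2
}

#' Collimated transmittance of a scattering layer
#'
#' Bouguer-Beer-Lambert attenuation `T = exp(-mu_s * l)` of the collimated
#' beam through a layer of thickness `l`, with the scattering coefficient
#' either given directly or estimated from the relative index via
#' [scattering_coefficient()].
#'
#' @param mu_s Scattering coefficient (um^-1); alternatively give `m` (or
#'   `n_LD`/`n_ISF`) and `a2rho`.
#' @param l Layer thickness (um).
#' @param m,n_LD,n_ISF Relative index specification (see
#'   [scattering_coefficient()]).
#' @param a2rho The product `a^2 * rho_s` (um^-1); 1 under the close-packing
#'   convention.
#' @return Transmittance fraction in (0, 1].
#' @examples
#' transmittance(n_LD = 1.46, n_ISF = 1.36, l = 120)  # 0.523
#' @export
transmittance <- function(mu_s = NULL, l, m = NULL, n_LD = NULL, n_ISF = NULL,
                          a2rho = 1) {
  if (is.null(mu_s)) {
    if (is.null(m)) {
      if (is.null(n_LD) || is.null(n_ISF))
        stop("supply 'mu_s', 'm', or 'n_LD' and 'n_ISF'", call. = FALSE)
      m <- n_LD / n_ISF
    }
    mu_s <- a2rho * (m - 1)^2
  }
  if (any(mu_s < 0)) stop("'mu_s' must be >= 0", call. = FALSE)
  if (any(l < 0)) stop("'l' must be >= 0", call. = FALSE)
  exp(-mu_s * l)
}

#' Relative refractive index reconstructed from measured transmittance
#'
#' Inverts the Bouguer-Beer-Lambert law with the Mie-estimate scattering
#' coefficient: `m = 1 + sqrt(-log(T) / (a2rho * l))`. The round trip
#' through [transmittance()] is an exact identity.
#'
#' @param T Measured collimated transmittance, in (0, 1].
#' @param l Layer thickness (um).
#' @param a2rho The product `a^2 * rho_s` (um^-1).
#' @return Relative refractive index `m >= 1`.
#' @examples
#' relative_index_from_T(0.394, l = 120)  # 1.088
#' @export
relative_index_from_T <- function(T, l, a2rho = 1) {
  if (any(T <= 0) || any(T > 1))
    stop("'T' must be in (0, 1]", call. = FALSE)
  if (any(l <= 0) || any(a2rho <= 0))
    stop("'l' and 'a2rho' must be > 0", call. = FALSE)
  1 + sqrt(-log(T) / (a2rho * l))
}
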