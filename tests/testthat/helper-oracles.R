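# Shared closed-form oracles for the test suite.

# Gauss error function via pnorm
erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Paraxial Gaussian beam amplitude (waist w0 at z = 0)
paraxial_gaussian <- function(x, z, w0, wavelength, n, x0 = 0) {
  zr <- pi * w0^2 * n / wavelength
  k <- 2 * pi * n / wavelength
  wz <- w0 * sqrt(1 + (z / zr)^2)
  Rinv <- z / (z^2 + zr^2)
  gouy <- atan(z / zr)
  sqrt(w0 / wz) * exp(-(x - x0)^2 / wz^2) *
    exp(1i * (k * z + k * (x - x0)^2 * Rinv / 2 - gouy / 2))
}

# Fresnel normal-incidence power reflectance
fresnel_R <- function(n1, n2) ((n1 - n2) / (n1 + n2))^2
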