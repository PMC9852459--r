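test_that("scattering coefficient follows the Mie estimate", {
  expect_equal(scattering_coefficient(20.02, 1 / 20.02^2, m = 1), 0)
  # close-packing convention: a^2 rho_s = 1, paper-strength contrast
  mu <- scattering_coefficient(20.02, 1 / 20.02^2, n_LD = 1.46, n_ISF = 1.36)
  expect_equal(mu, (1.46 / 1.36 - 1)^2, tolerance = 1e-12)
  # consistent with the printed 52.3% transmittance over 120 um
  expect_equal(mu, -log(0.523) / 120, tolerance = 2e-3)
  # a^2 scaling
  expect_equal(scattering_coefficient(2, 1, m = 1.1),
               4 * scattering_coefficient(1, 1, m = 1.1))
  expect_error(scattering_coefficient(-1, 1, m = 1.1), "> 0")
})

test_that("Bouguer-Beer-Lambert transmittance matches the analytic row", {
  expect_equal(transmittance(mu_s = 0, l = 120), 1)
  Tvals <- transmittance(n_LD = 1.46, n_ISF = c(1.36, 1.38, 1.40), l = 120)
  expect_equal(round(100 * Tvals, 1), c(52.3, 66.8, 80.2))
  expect_error(transmittance(mu_s = -1, l = 10), "mu_s")
  expect_error(transmittance(mu_s = 1, l = -10), "l")
})

test_that("relative-index inversion reproduces the measured reconstruction", {
  expect_equal(relative_index_from_T(1, l = 120), 1)
  m <- relative_index_from_T(c(0.394, 0.401, 0.414), l = 120)
  expect_equal(round(m, 3), c(1.088, 1.087, 1.086))
  expect_error(relative_index_from_T(1.2, 120), "T")
  expect_error(relative_index_from_T(0, 120), "T")
})

test_that("forward and inverse transforms are an exact round trip", {
  ms <- seq(1.001, 1.2, length.out = 50)
  for (l in c(60, 120, 240)) {
    Tv <- transmittance(m = ms, l = l, a2rho = 1)
    expect_equal(relative_index_from_T(Tv, l = l, a2rho = 1), ms,
                 tolerance = 1e-12)
  }
})

test_that("attenuation scales as the squared index mismatch", {
  # ratios of -log(T) across the three ISF indices against the printed row
  m <- 1.46 / c(1.36, 1.38, 1.40)
  printed <- -log(c(0.523, 0.668, 0.802))
  computed <- (m - 1)^2 * 120
  expect_equal(computed / computed[1], printed / printed[1],
               tolerance = 0.005)
  # monotonicity: T increases with n_ISF, reconstructed m decreases in T
  Tv <- transmittance(n_LD = 1.46, n_ISF = seq(1.36, 1.44, by = 0.01),
                      l = 120)
  expect_true(all(diff(Tv) > 0))
  expect_true(all(diff(relative_index_from_T(Tv, 120)) < 0))
})
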