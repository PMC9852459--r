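test_that("cylinder series vanishes without index contrast", {
  x <- seq(-8, 8, by = 0.5); z <- seq(-8, 8, by = 0.5)
  E <- cylinder_series_field(x, z, radii = 5, n_layer = 1.36, n_out = 1.36)
  expect_lt(max(Mod(E)), 1e-6)   # truncation-limited reconstruction residual
})

test_that("cylinder series field is mirror-symmetric about the beam axis", {
  case <- single_cylinder_case()
  x <- seq(-10, 10, by = 0.25); z <- c(8, 12)
  E <- case$oracle(x, z)
  expect_equal(E, E[rev(seq_along(x)), ], tolerance = 1e-10)
  # scattered energy is substantial in the forward region
  expect_gt(max(Mod(E)), 0.5)
})

test_that("single cylinder case builds a consistent index field", {
  case <- single_cylinder_case(radius = 5, coat = 1)
  fld <- case$index_field
  i0 <- which.min(abs(fld$x)); j0 <- which.min(abs(fld$z))
  expect_equal(fld$n[i0, j0], 1.46)
  expect_equal(fld$n[1, 1], 1.36)
  expect_error(single_cylinder_case(radius = 0.5), "wavelength")
})

test_that("the lattice suite enumerates the study scenarios", {
  suite <- lattice_suite()
  expect_length(suite, 3 * 2 * 3)
  sym <- vapply(suite, `[[`, logical(1), "expect_symmetric")
  expect_equal(sum(sym), 6)   # one centred case per depth x index
  offs <- vapply(suite, `[[`, numeric(1), "offset")
  expect_setequal(round(unique(offs), 3), round(c(0, 20.02 / 2, 20.02 / 4), 3))
  # regeneration is bit-identical
  suite2 <- lattice_suite()
  expect_identical(suite[["L2_n1.36_center"]]$lattice$centers,
                   suite2[["L2_n1.36_center"]]$lattice$centers)
})

test_that("synthetic B-scans have the constructed statistics", {
  expect_equal(relative_dispersion(synth_bscan(noise_sigma = 0)), 0)
  b <- synth_bscan(shape = c(320, 320), background = 100, noise_sigma = 10,
                   seed = 3)
  expect_equal(relative_dispersion(b), 0.1, tolerance = 0.05)
  # seeded reproducibility
  expect_identical(synth_bscan(noise_sigma = 5, seed = 9)$values,
                   synth_bscan(noise_sigma = 5, seed = 9)$values)
  expect_error(synth_bscan(shape = c(50, 50), spot_cols = 60), "outside")
})

test_that("fixture materialization writes inspectable files", {
  out <- file.path(tempdir(), "fixtures")
  paths <- make_fixtures(out)
  expect_true(all(file.exists(paths)))
  unlink(out, recursive = TRUE)
})
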