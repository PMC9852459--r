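test_that("the split-step propagator is unitary in lossless media", {
  uf <- uniform_field(1.36, width = 80, depth = 120, grid_spacing = 0.1)
  E0 <- gaussian_beam_field(uf$x, 0, waist = 10, n_medium = 1.36)
  run <- adiposim:::split_step_run(uf, drop(E0), 0.93, n_ref = 1.36,
                                   absorb = 0, keep_map = FALSE)
  drift <- abs(sum(Mod(run$E)^2) - sum(Mod(E0)^2)) / sum(Mod(E0)^2)
  expect_lt(drift, 0.005)
})

test_that("beam spreading follows the closed form and tilts walk off", {
  uf <- uniform_field(1.36, width = 120, depth = 100, grid_spacing = 0.1)
  E0 <- gaussian_beam_field(uf$x, 0, waist = 8, n_medium = 1.36)
  run <- adiposim:::split_step_run(uf, drop(E0), 0.93, n_ref = 1.36,
                                   absorb = 0)
  I <- Mod(run$E)^2
  # second-moment width of a Gaussian: <x^2> = w^2 / 4
  w_num <- 2 * sqrt(sum(uf$x^2 * I) / sum(I))
  zr <- pi * 64 * 1.36 / 0.93
  w_ref <- 8 * sqrt(1 + (100 / zr)^2)
  expect_lt(abs(w_num - w_ref) / w_ref, 0.005)

  # tilted input walks off by z * tan(theta)
  theta <- 5 * pi / 180
  kxt <- 2 * pi / 0.93 * 1.36 * sin(theta)
  Et <- drop(E0) * exp(1i * kxt * uf$x)
  runt <- adiposim:::split_step_run(uf, Et, 0.93, n_ref = 1.36, absorb = 0)
  It <- Mod(runt$E)^2
  centroid <- sum(uf$x * It) / sum(It)
  expect_lt(abs(centroid - 100 * tan(theta)), uf$grid_spacing + 0.05)
})

test_that("gradient reflectance reproduces the Fresnel coefficient", {
  uf <- uniform_field(1.36, width = 10, depth = 20, grid_spacing = 0.1)
  expect_true(all(local_reflectance(uf)$r == 0))

  # sharp interface: the single-step value is exactly Fresnel
  fld <- uniform_field(1.36, width = 10, depth = 20, grid_spacing = 0.1)
  fld$n[, fld$z > 10] <- 1.46
  r <- local_reflectance(fld)$r
  expect_equal(sum(r[1, ]), (1.36 - 1.46) / (1.36 + 1.46), tolerance = 1e-12)

  # soft interface: the per-step sum converges to the same total
  soft <- uniform_field(1.36, width = 10, depth = 20, grid_spacing = 0.05)
  prof <- 1.36 + (1.46 - 1.36) / (1 + exp(-(soft$z - 10) / 0.125))
  soft$n <- matrix(prof, nrow(soft$n), ncol(soft$n), byrow = TRUE)
  rs <- sum(local_reflectance(soft)$r[1, ])
  expect_equal(rs, (1.36 - 1.46) / (1.36 + 1.46), tolerance = 0.05 * 0.0355)
})

test_that("surface echo calibrates the scan and uniform media stay dark", {
  uf <- uniform_field(1.36, width = 80, depth = 80, grid_spacing = 0.1)
  src <- oct_source(focus_depth = 0, n_spectral_samples = 48)
  sc <- synthesize_ascan(uf, src, beam_position = 0, zeta_max = 105,
                         k_batch = 12)
  # surface peak at zero optical depth
  expect_equal(sc$zeta[which.max(sc$envelope)], 0, tolerance = 1)
  # no interior structure above 1% of the surface response
  interior <- sc$envelope[sc$zeta > 8 & sc$zeta < 100]
  expect_lt(max(interior) / max(sc$envelope), 0.01)
})

test_that("a buried interface echoes at its optical depth with Fresnel scaling", {
  mk <- function(n2) {
    fld <- uniform_field(1.36, width = 90, depth = 40, grid_spacing = 0.1)
    fld$n[, fld$z > 25] <- n2
    fld
  }
  src <- oct_source(surface_beam_diameter = 40, focus_beam_diameter = 40,
                    focus_depth = 0, n_spectral_samples = 48)
  peak_energy <- function(sc, zeta0, halfw = 4) {
    max(sc$envelope[abs(sc$zeta - zeta0) <= halfw])
  }
  sc1 <- synthesize_ascan(mk(1.46), src, k_batch = 12)
  zeta_if <- 1.36 * 25
  ipk <- which.max(sc1$envelope * (sc1$zeta > 10))
  expect_lt(abs(sc1$zeta[ipk] - zeta_if), 6.2)  # within one resolution element

  # amplitude scaling between a 0.10 and a 0.05 index step
  sc2 <- synthesize_ascan(mk(1.41), src, k_batch = 12)
  r1 <- (1.46 - 1.36) / (1.46 + 1.36)
  r2 <- (1.41 - 1.36) / (1.41 + 1.36)
  ratio <- peak_energy(sc1, zeta_if) / peak_energy(sc2, zeta_if)
  expect_equal(ratio, (r1 / r2)^2, tolerance = 0.1)

  # absolute Fresnel gate: interface/surface energy ratio
  rs <- (1 - 1.36) / (1 + 1.36)
  meas <- peak_energy(sc1, zeta_if) / peak_energy(sc1, 0)
  expect_equal(meas, r1^2 / rs^2, tolerance = 0.05)
})

test_that("the axial PSF matches the nominal resolution", {
  src <- oct_source()
  psf <- axial_psf(src)
  expect_equal(attr(psf, "fwhm"), 6.2, tolerance = 0.3 / 6.2)
  expect_equal(as.numeric(calibrate_axial_resolution(src, 1.47)), 6.2 / 1.47,
               tolerance = 1e-12)
  expect_equal(round(as.numeric(calibrate_axial_resolution(src, 1.47)), 1),
               4.2)
  expect_equal(as.numeric(calibrate_axial_resolution(src, 1)), 6.2)
  expect_equal(round(as.numeric(calibrate_axial_resolution(src, 1.44)), 2),
               4.31)
})

test_that("scans are reproducible given the seed", {
  lat <- build_lattice(make_cell(), n_layers = 2, cells_per_layer = 3,
                       n_ISF = 1.36, packing = "hexagonal",
                       jitter_fraction = 0.2)
  src <- oct_source(focus_depth = 20, n_spectral_samples = 32)
  a1 <- synthesize_ascan(lat, src, n_trials = 2, seed = 5, zeta_max = 50,
                         grid_spacing = 0.2, k_batch = 16)
  a2 <- synthesize_ascan(lat, src, n_trials = 2, seed = 5, zeta_max = 50,
                         grid_spacing = 0.2, k_batch = 16)
  a3 <- synthesize_ascan(lat, src, n_trials = 2, seed = 6, zeta_max = 50,
                         grid_spacing = 0.2, k_batch = 16)
  expect_identical(a1$W, a2$W)
  expect_false(identical(a1$W, a3$W))
})

test_that("B-scans over a regular lattice repeat at the cell period", {
  lat <- build_lattice(make_cell(), n_layers = 2, cells_per_layer = 6,
                       n_ISF = 1.36, packing = "hexagonal")
  src <- oct_source(focus_depth = 20, n_spectral_samples = 32)
  x1 <- lat$centers$x[lat$centers$layer == 1][3]
  bs <- scan_raster(lat, src, positions = c(x1, x1 + 20.02), zeta_max = 55,
                    grid_spacing = 0.2, k_batch = 16)
  expect_equal(dim(bs$W)[2], 2)
  expect_gt(cor(bs$W[, 1], bs$W[, 2]), 0.99)
})

test_that("C-scans of a homogeneous medium are flat", {
  # spheres with no index contrast: optically uniform medium
  cell0 <- make_cell(n_core = 1.36, n_cytoplasm = 1.36, n_membrane = 1.36)
  lat3 <- build_lattice_3d(cell0, n_layers = 2, cells_x = 2, cells_y = 2,
                           n_ISF = 1.36)
  src <- oct_source(focus_depth = 20, n_spectral_samples = 16)
  pos <- as.matrix(expand.grid(x = seq(-8, 8, length.out = 3),
                               y = seq(-8, 8, length.out = 3)))
  cs <- scan_raster(lat3, src, pos, c_depth = 20, grid_spacing = 0.5)
  expect_equal(dim(cs$W), c(3, 3))
  expect_lt(sd(cs$W) / mean(cs$W), 0.02)
})

test_that("ensemble averaging shrinks the variance between runs", {
  lat <- build_lattice(make_cell(), n_layers = 2, cells_per_layer = 3,
                       n_ISF = 1.36, packing = "hexagonal",
                       jitter_fraction = 0.2)
  src <- oct_source(focus_depth = 20, n_spectral_samples = 24)
  stat <- function(n_trials, seed)
    mean(synthesize_ascan(lat, src, n_trials = n_trials, seed = seed,
                          zeta_max = 50, grid_spacing = 0.25,
                          k_batch = 12)$W)
  s1 <- vapply(1:5, function(s) stat(1, 100 + s), numeric(1))
  s4 <- vapply(1:5, function(s) stat(4, 200 + s), numeric(1))
  expect_lt(var(s4), var(s1))
})

test_that("raster scans name offending positions and steps flag aliasing", {
  uf <- uniform_field(1.36, width = 40, depth = 10, grid_spacing = 0.2)
  src <- oct_source(focus_depth = 0, n_spectral_samples = 8)
  expect_error(scan_raster(uf, src, positions = c(0, 500), zeta_max = 15,
                           k_batch = 8), "500")
  # a field oscillating at the pixel scale is under-resolved
  x <- uf$x
  bad_field <- exp(-x^2 / 25) * rep_len(c(1, -1), length(x))
  expect_warning(propagate_split_step(bad_field, rep(1.36, length(x)),
                                      k0 = 2 * pi / 0.93, dx = 0.2,
                                      dz = 0.1, n_ref = 1.36), "Nyquist")
})
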