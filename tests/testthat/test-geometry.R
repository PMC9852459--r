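test_that("cell model dimensions and validation", {
  cell <- make_cell()
  expect_equal(cell$outer_diameter, 20.02, tolerance = 1e-12)
  expect_equal(make_cell(18, 0, 0)$outer_diameter, 18)
  expect_equal(make_cell(9, 1, 0.01)$outer_diameter, 11.02)
  expect_error(make_cell(core_diameter = -1), "core_diameter")
  expect_error(make_cell(n_core = 0.9), "n_core")
})

test_that("radial profile is piecewise constant with hard boundaries", {
  cell <- make_cell()
  expect_equal(radial_profile(cell, 0), 1.46)
  expect_equal(radial_profile(cell, 9.5), 1.35)
  expect_equal(radial_profile(cell, 10.005), 1.42)  # inside the membrane
  expect_equal(radial_profile(cell, 50), 1.36)      # far field: ISF
  expect_equal(radial_profile(cell, 50, n_embed = 1.40), 1.40)
  expect_error(radial_profile(cell, -1), "r")
})

test_that("soft boundaries blend to the midpoint at each interface", {
  cell <- make_cell(boundary_softness = 0.2)
  # exactly at the core boundary the blend is symmetric
  expect_equal(radial_profile(cell, 9), (1.46 + 1.35) / 2, tolerance = 1e-6)
  # profile is monotone decreasing through the core boundary
  rs <- seq(8.5, 9.5, by = 0.01)
  expect_true(all(diff(radial_profile(cell, rs)) <= 0))
})

test_that("regular lattices close-pack at the outer diameter", {
  lat <- build_lattice(make_cell(), n_layers = 6, cells_per_layer = 10,
                       n_ISF = 1.36)
  expect_equal(nrow(lat$centers), 60)
  expect_equal(lat$thickness, 6 * 20.02)
  # nearest-neighbour distances all equal one outer diameter
  cc <- lat$centers
  d <- as.matrix(dist(cc[, c("x", "z")]))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(20.02, 60), tolerance = 1e-12)
})

test_that("jitter is seeded, bounded, and centred", {
  lat1 <- build_lattice(make_cell(), 3, 10, jitter_fraction = 0.2, seed = 1)
  lat2 <- build_lattice(make_cell(), 3, 10, jitter_fraction = 0.2, seed = 1)
  lat3 <- build_lattice(make_cell(), 3, 10, jitter_fraction = 0.2, seed = 2)
  expect_identical(lat1$centers, lat2$centers)
  expect_false(identical(lat1$centers, lat3$centers))
  expect_error(build_lattice(make_cell(), 3, jitter_fraction = 0.6),
               "jitter_fraction")

  reg <- build_lattice(make_cell(), 3, 10)$centers
  bound <- 0.2 * 20.02 / 2   # per-axis displacement bound: f * D / 2
  sum_dx <- 0; sum_dz <- 0; n_lat <- 400
  for (s in seq_len(n_lat)) {
    cc <- build_lattice(make_cell(), 3, 10, jitter_fraction = 0.2,
                        seed = s)$centers
    dx <- cc$x - reg$x; dz <- cc$z - reg$z
    expect_true(max(abs(c(dx, dz))) <= bound + 1e-12)
    sum_dx <- sum_dx + mean(dx); sum_dz <- sum_dz + mean(dz)
  }
  expect_lt(abs(sum_dx / n_lat), 0.1)
  expect_lt(abs(sum_dz / n_lat), 0.1)
})

test_that("rasterization reproduces the shell indices", {
  lat <- build_lattice(make_cell(), n_layers = 1, cells_per_layer = 1,
                       n_ISF = 1.36)
  fld <- rasterize(lat, grid_spacing = 0.1, domain_padding = 15)
  ctr <- lat$centers[1, ]
  i <- which.min(abs(fld$x - ctr$x)); j <- which.min(abs(fld$z - ctr$z))
  expect_equal(fld$n[i, j], 1.46)
  # far corner is pure ISF
  expect_equal(fld$n[1, 1], 1.36)
  # hard mode with the membrane ring: only the four model indices appear
  fldm <- rasterize(lat, grid_spacing = 0.1, domain_padding = 15,
                    include_membrane = TRUE)
  expect_true(all(unique(c(fldm$n)) %in% c(1.35, 1.36, 1.42, 1.46)))
  expect_true(1.42 %in% fldm$n)
})

test_that("an empty lattice rasterizes to uniform interstitial fluid", {
  lat <- build_lattice(make_cell(), n_layers = 1, cells_per_layer = 0,
                       n_ISF = 1.38)
  fld <- rasterize(lat, grid_spacing = 0.2, domain_padding = 10)
  expect_true(all(fld$n == 1.38))
})

test_that("phase area fractions are stable under grid refinement", {
  lat <- build_lattice(make_cell(), n_layers = 1, cells_per_layer = 2)
  frac <- function(gs) {
    fld <- rasterize(lat, grid_spacing = gs, domain_padding = 5)
    c(mean(fld$n == 1.46), mean(fld$n == 1.35))
  }
  f1 <- frac(0.2); f2 <- frac(0.1)
  expect_true(all(abs(f1 - f2) < 0.01))
})

test_that("coarse grids trigger a resolution message", {
  lat <- build_lattice(make_cell(), n_layers = 1, cells_per_layer = 1)
  expect_message(rasterize(lat, grid_spacing = 1, domain_padding = 5),
                 "coarse")
})
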