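test_that("split-step propagation matches the free-space closed form", {
  uf <- uniform_field(1.36, width = 160, depth = 120, grid_spacing = 0.1)
  sfw <- solve_forward(uf, beam_spec(waist = 10), absorb = 0)
  zj <- c(30, 120)
  for (z in zj) {
    j <- which.min(abs(uf$z - (z - uf$grid_spacing / 2)))
    num <- sfw$intensity[, j]
    ref <- Mod(paraxial_gaussian(uf$x, uf$z[j] + uf$grid_spacing / 2, 10,
                                 0.93, 1.36))^2
    expect_lt(sqrt(sum((num - ref)^2) / sum(ref^2)), 0.01)
  }
})

test_that("free-space windowed transmittance matches the erf closed form", {
  uf <- uniform_field(1.36, width = 160, depth = 120, grid_spacing = 0.1)
  sfw <- solve_forward(uf, beam_spec(waist = 10))
  Tv <- transmitted_fraction(sfw)$T
  # fraction of a diffracting Gaussian inside |x| <= 10 um after 120 um
  zr <- pi * 100 * 1.36 / 0.93
  wz <- 10 * sqrt(1 + (120 / zr)^2)
  expect_equal(Tv, unname(erf_(sqrt(2) * 10 / wz)), tolerance = 5e-3)
  expect_error(transmitted_fraction(sfw, window_center = 75), "outside")
})

test_that("a single cell focuses the beam into a photonic jet", {
  lat <- build_lattice(make_cell(), n_layers = 1, cells_per_layer = 1,
                       n_ISF = 1.36)
  fld <- rasterize(lat, grid_spacing = 0.08, domain_padding = 20,
                   z_padding = 15)
  sfw <- solve_forward(fld, beam_spec())
  i0 <- which.min(abs(fld$x))
  on_axis <- sfw$intensity[i0, ]
  peak_z <- fld$z[which.max(on_axis)]
  # incident peak intensity is 1 (unit amplitude); the jet exceeds it just
  # beyond the shadow surface of the cell (z > 20 um)
  expect_gt(max(on_axis), 1)
  expect_gt(peak_z, 15)
  expect_lt(peak_z, 35)
})

test_that("uniform media show a single hot spot, lattices many", {
  uf <- uniform_field(1.36, width = 120, depth = 60, grid_spacing = 0.1)
  hs <- find_hotspots(solve_forward(uf, beam_spec()))
  expect_length(hs$positions, 1)
  expect_lt(abs(hs$positions), 0.2)
})

test_that("centred incidence is symmetric, offset incidence is not", {
  lat <- build_lattice(make_cell(), n_layers = 2, n_ISF = 1.36,
                       packing = "hexagonal")
  fld <- rasterize(lat, grid_spacing = 0.1, domain_padding = 30)
  ctr <- solve_forward(fld, beam_spec())
  prof <- Mod(ctr$exit_field)^2
  i0 <- which.min(abs(ctr$x - ctr$beam_axis))
  k <- min(i0 - 1, length(prof) - i0, 250)
  left <- prof[i0 - seq_len(k)]; right <- prof[i0 + seq_len(k)]
  expect_lt(abs(sum(left) - sum(right)) / (sum(left) + sum(right)), 0.01)

  mix <- solve_forward(fld, beam_spec(lateral_offset = 20.02 / 4))
  prof2 <- Mod(mix$exit_field)^2
  i1 <- which.min(abs(mix$x - mix$beam_axis))
  k2 <- min(i1 - 1, length(prof2) - i1, 250)
  l2 <- sum(prof2[i1 - seq_len(k2)]); r2 <- sum(prof2[i1 + seq_len(k2)])
  expect_gt(abs(l2 - r2) / (l2 + r2), 0.05)
})

test_that("full-wave and split-step engines agree on a small lattice", {
  lat <- build_lattice(make_cell(), n_layers = 2, cells_per_layer = 4,
                       n_ISF = 1.36, packing = "hexagonal")
  fld <- rasterize(lat, grid_spacing = 0.15, domain_padding = 20)
  ss <- transmitted_fraction(solve_forward(fld, beam_spec()))$T
  fw <- transmitted_fraction(solve_forward(fld, beam_spec(), method = "born",
                                           tol = 3e-5))$T
  expect_equal(ss, fw, tolerance = 0.05)
})

test_that("transmittance is stable under grid refinement", {
  Tat <- function(gs, dz) {
    lat <- build_lattice(make_cell(), n_layers = 2, n_ISF = 1.36,
                         packing = "hexagonal")
    fld <- rasterize(lat, grid_spacing = gs, domain_padding = 30)
    transmitted_fraction(solve_forward(fld, beam_spec(), dz = dz))$T
  }
  expect_lt(abs(Tat(0.16, 0.2) - Tat(0.08, 0.1)), 0.01)
})
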