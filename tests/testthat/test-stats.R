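test_that("relative dispersion is exact on constructed images", {
  expect_equal(relative_dispersion(matrix(5, 10, 10)), 0)
  expect_equal(relative_dispersion(c(1, 3)), 0.5)
  w <- matrix(runif(400, 1, 2), 20, 20)
  expect_equal(relative_dispersion(w * 7.3), relative_dispersion(w),
               tolerance = 1e-12)
  expect_error(relative_dispersion(matrix(0, 5, 5)), "mean")
})

test_that("contrast stretch maps noise floor to 0 and maximum to 1", {
  w <- matrix(10, 80, 80)
  w[60, 10] <- 110   # global max outside the noise box
  w[70, 20] <- 60
  w[75, 30] <- 5     # below the noise floor
  out <- contrast_stretch(w)$values
  expect_equal(out[60, 10], 1)
  expect_equal(out[70, 20], 0.5)
  expect_equal(out[75, 30], 0)
  # monotone and idempotent up to clipping
  s2 <- contrast_stretch(bscan_image(out))$values
  expect_equal(s2[60, 10], 1)
  expect_error(contrast_stretch(matrix(1, 60, 60)), "stretch")
  expect_error(contrast_stretch(matrix(1, 20, 20)), "noise box")
})

test_that("group averaging reduces noise by the square root of the count", {
  base <- matrix(100, 100, 100)
  expect_equal(average_group(list(base, base, base, base))$values, base)
  expect_equal(average_group(list(base))$values, base)
  set.seed(42)
  noisy <- lapply(1:4, function(i) base + matrix(rnorm(1e4, 0, 8), 100, 100))
  avg <- average_group(noisy)$values
  expect_equal(sd(avg - base), 8 / 2, tolerance = 0.1 * 4)
  expect_error(average_group(list(base, matrix(1, 2, 2))), "dimensions")
})

test_that("bottom profile recovers planted interface rows and spots", {
  w <- matrix(0, 100, 200)
  w[80, ] <- seq_len(200)   # planted interface row
  prof <- bottom_profile(w, interface_row = 80, band_halfwidth = 0)
  expect_equal(as.numeric(prof), as.numeric(seq_len(200)))
  # autodetection finds the brightest deep row
  prof2 <- bottom_profile(w, band_halfwidth = 0)
  expect_equal(attr(prof2, "row"), 80)
  # planted Gaussian spots peak at the right columns
  b <- synth_bscan(shape = c(100, 300), spot_cols = c(60, 150, 240),
                   spot_row = 75, background = 10)
  prof3 <- bottom_profile(b, interface_row = 75)
  pk <- which(diff(sign(diff(prof3))) == -2) + 1
  expect_true(all(vapply(c(60, 150, 240),
                         function(p) min(abs(pk - p)) <= 1, logical(1))))
  # an all-zero image gives a zero profile
  expect_equal(max(suppressWarnings(
    bottom_profile(matrix(0, 50, 50)))), 0)
})

test_that("windowed ratios cover the scan line in fixed windows", {
  n <- 2000   # 1 um pitch over 0..2000 um
  ref <- runif(n, 50, 100)
  rep1 <- windowed_ratio(1.18 * ref, ref, pitch = 1, window = 20,
                         range = c(0, 2000))
  expect_equal(rep1$n_windows, 100)
  expect_equal(rep1$window_means$ratio, rep(1.18, 100), tolerance = 1e-12)
  expect_equal(rep1$sd_ratio, 0, tolerance = 1e-12)
  # independent unit-mean noise: mean ratio statistically consistent with 1
  set.seed(7)
  a <- 1 + abs(rnorm(n, 0, 0.1)); b <- 1 + abs(rnorm(n, 0, 0.1))
  rep2 <- windowed_ratio(a, b, pitch = 1)
  expect_lt(abs(rep2$mean_ratio - 1),
            3 * rep2$sd_ratio / sqrt(rep2$n_windows) + 0.02)
  expect_error(windowed_ratio(1:5, 1:6), "equal length")
})
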