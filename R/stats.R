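#' B-scan image container
#'
#' Wraps a matrix of non-negative brightness values with its pixel pitch and
#' the mean tissue refractive index used to convert optical to geometric
#' depth.
#'
#' @param values Numeric matrix (rows = depth, columns = lateral position).
#' @param pitch_lateral,pitch_axial Pixel pitch (um).
#' @param mean_index Mean tissue refractive index for depth conversion.
#' @return A `bscan_image`.
#' @export
bscan_image <- function(values, pitch_lateral = 1, pitch_axial = 1,
                        mean_index = 1.44) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("brightness values must be >= 0", call. = FALSE)
  structure(list(values = values, pitch_lateral = pitch_lateral,
                 pitch_axial = pitch_axial, mean_index = mean_index),
            class = "bscan_image")
}

as_bscan <- function(x) {
  if (inherits(x, "bscan_image")) x else bscan_image(as.matrix(x))
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("B-scan image: %d x %d px (%.3g x %.3g um/px)\n",
              nrow(x$values), ncol(x$values), x$pitch_axial,
              x$pitch_lateral))
  invisible(x)
}

#' Relative brightness dispersion of an image
#'
#' The coefficient of variation of the local brightness, `D_b = sd / mean`
#' with the population standard deviation, used as a scalar measure of how
#' inhomogeneous a B-scan is. Scale-invariant and zero for a constant image.
#'
#' @param image A `bscan_image`, matrix or numeric vector.
#' @return `D_b` (dimensionless, >= 0).
#' @examples
#' relative_dispersion(c(1, 3))  # 0.5
#' @export
relative_dispersion <- function(image) {
  w <- if (inherits(image, "bscan_image")) image$values else image
  w <- as.numeric(w)
  mu <- mean(w)
  if (mu <= 0) stop("mean brightness must be > 0", call. = FALSE)
  sqrt(mean((w - mu)^2)) / mu
}

#' Noise-referenced linear contrast stretch
#'
#' Linearly rescales a B-scan between a noise floor and the image maximum:
#' the lower bound is the mean inside a sample-free reference box in the top
#' left corner, the upper bound the maximum over the remaining pixels.
#' Output values are clipped below at 0 and reach 1 at the global maximum.
#'
#' @param bscan A `bscan_image` or matrix (rows = depth).
#' @param noise_box Height and width (px) of the top-left noise reference.
#' @return A `bscan_image` with values in `[0, 1]`.
#' @export
contrast_stretch <- function(bscan, noise_box = c(50, 50)) {
  b <- as_bscan(bscan)
  w <- b$values
  if (nrow(w) < noise_box[1] || ncol(w) < noise_box[2])
    stop(sprintf("image smaller than the %d x %d noise box",
                 noise_box[1], noise_box[2]), call. = FALSE)
  box <- w[seq_len(noise_box[1]), seq_len(noise_box[2])]
  lower <- mean(box)
  rest <- w
  rest[seq_len(noise_box[1]), seq_len(noise_box[2])] <- NA
  upper <- max(rest, na.rm = TRUE)
  if (upper <= lower)
    stop("image maximum does not exceed the noise floor; nothing to stretch",
         call. = FALSE)
  out <- pmin(pmax((w - lower) / (upper - lower), 0), 1)
  bscan_image(out, b$pitch_lateral, b$pitch_axial, b$mean_index)
}

#' Average a group of co-located B-scans
#'
#' Pixel-wise arithmetic mean of repeated scans acquired at the same
#' location, the standard noise-reduction step before further analysis.
#'
#' @param scans List of `bscan_image`s or matrices of equal dimensions.
#' @return A `bscan_image` of the mean.
#' @export
average_group <- function(scans) {
  if (!is.list(scans)) scans <- list(scans)
  bs <- lapply(scans, as_bscan)
  dims <- vapply(bs, function(b) dim(b$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all scans must have identical dimensions", call. = FALSE)
  acc <- Reduce(`+`, lapply(bs, `[[`, "values")) / length(bs)
  b1 <- bs[[1]]
  bscan_image(acc, b1$pitch_lateral, b1$pitch_axial, b1$mean_index)
}

#' Brightness profile along the bottom interface
#'
#' Extracts the lateral brightness profile of the bright band where the
#' transmitted sub-beams hit the bottom surface of the sample. The interface
#' row is given explicitly or auto-detected as the row with maximal mean
#' brightness in the lower half of the image; a band of `band_halfwidth`
#' rows on each side is averaged to stabilise against interface roughness.
#'
#' @param image A `bscan_image` or matrix (rows = depth).
#' @param interface_row Row index of the interface, or `NULL` to auto-detect.
#' @param band_halfwidth Rows averaged on each side of the interface.
#' @return Numeric vector of brightness vs lateral pixel, with the detected
#'   row in attribute `"row"`.
#' @export
bottom_profile <- function(image, interface_row = NULL, band_halfwidth = 2) {
  b <- as_bscan(image)
  w <- b$values
  nr <- nrow(w)
  if (is.null(interface_row)) {
    lower <- seq.int(max(1L, floor(nr / 2)), nr)
    means <- rowMeans(w[lower, , drop = FALSE])
    best <- which.max(means)
    near <- which(means >= 0.99 * means[best])
    if (length(near) > 1 && any(near != best)) {
      warning("interface auto-detection ambiguous; picking the deeper row")
      best <- max(near)
    }
    interface_row <- lower[best]
  }
  if (interface_row < 1 || interface_row > nr)
    stop("interface row outside the image", call. = FALSE)
  rows <- seq.int(max(1L, interface_row - band_halfwidth),
                  min(nr, interface_row + band_halfwidth))
  out <- colMeans(w[rows, , drop = FALSE])
  attr(out, "row") <- interface_row
  out
}

#' Windowed mean intensities and hot/reference ratio distribution
#'
#' Splits two lateral intensity profiles (e.g. the bottom-interface profiles
#' of a heated and a reference scan) into fixed-width windows, computes the
#' per-window means and their ratio, and summarises the ratio distribution.
#'
#' @param profile_hot,profile_ref Numeric profiles on the same lateral
#'   sampling.
#' @param pitch Lateral pixel pitch (um).
#' @param window Window width (um).
#' @param range Lateral range analysed (um), `c(from, to)`.
#' @return A `stats_report` list: `window_means` (data.frame with per-window
#'   means and ratios), `mean_ratio`, `sd_ratio`, `n_windows`.
#' @export
windowed_ratio <- function(profile_hot, profile_ref, pitch = 1, window = 20,
                           range = c(0, 2000)) {
  if (length(profile_hot) != length(profile_ref))
    stop("profiles must have equal length", call. = FALSE)
  n_win <- floor((range[2] - range[1]) / window)
  pos <- (seq_along(profile_hot) - 0.5) * pitch
  idx <- floor((pos - range[1]) / window) + 1
  ok <- idx >= 1 & idx <= n_win
  mh <- tapply(profile_hot[ok], factor(idx[ok], levels = seq_len(n_win)),
               mean)
  mr <- tapply(profile_ref[ok], factor(idx[ok], levels = seq_len(n_win)),
               mean)
  ratio <- as.numeric(mh) / as.numeric(mr)
  bad <- !is.finite(ratio)
  if (any(bad, na.rm = TRUE))
    warning(sprintf("%d window(s) with empty or zero reference excluded",
                    sum(bad, na.rm = TRUE)))
  df <- data.frame(window = seq_len(n_win),
                   from_um = range[1] + (seq_len(n_win) - 1) * window,
                   mean_hot = as.numeric(mh), mean_ref = as.numeric(mr),
                   ratio = ratio)
  structure(list(window_means = df,
                 mean_ratio = mean(ratio[!bad], na.rm = TRUE),
                 sd_ratio = stats::sd(ratio[!bad]),
                 n_windows = n_win),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("Windowed intensity ratio: %d windows, mean %.3f +/- %.3f\n",
              x$n_windows, x$mean_ratio, x$sd_ratio))
  invisible(x)
}
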