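# File I/O: 32-bit float TIFF with plain-text sidecar headers, CSV matrices,
# scaled PNG export, and image loading for the statistics module.

sidecar_path <- function(path) paste0(path, ".txt")

write_sidecar <- function(path, meta) {
  writeLines(paste(names(meta), vapply(meta, format, character(1)),
                   sep = " = "), sidecar_path(path))
}

read_sidecar <- function(path) {
  if (!file.exists(sidecar_path(path))) return(list())
  lines <- readLines(sidecar_path(path))
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) p[2] else v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Write a refractive-index or intensity field as float TIFF
#'
#' Stores the matrix as a 32-bit IEEE-float grayscale TIFF (image rows run
#' along z) with a plain-text sidecar recording the grid spacing and origin.
#' Values are stored as raw float samples, so round trips are exact at
#' float32 precision.
#'
#' @param field An `index_field`, `complex_field` (its intensity) or matrix.
#' @param path Output path.
#' @param what For complex fields: `"intensity"` or `"amplitude"` (modulus).
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, what = "intensity") {
  if (inherits(field, "index_field")) {
    m <- field$n
    meta <- list(grid_spacing = field$grid_spacing,
                 origin_x = field$origin[["x"]],
                 origin_z = field$origin[["z"]], content = "refractive_index")
  } else if (inherits(field, "complex_field")) {
    m <- if (what == "amplitude") sqrt(field$intensity) else field$intensity
    meta <- list(grid_spacing = field$grid_spacing, origin_x = field$x[1],
                 origin_z = field$z[1], content = what)
  } else {
    m <- as.matrix(field)
    meta <- list(content = "matrix")
  }
  write_float_tiff(m, path)
  write_sidecar(path, meta)
  invisible(path)
}

#' Read a float TIFF written by [write_field_tiff()]
#'
#' @param path TIFF path (sidecar `path.txt` read if present).
#' @return List with the matrix `values` (x by z) and any sidecar metadata.
#' @export
read_field_tiff <- function(path) {
  m <- read_float_tiff(path)
  if (is.null(m)) m <- t(tiff::readTIFF(path, as.is = FALSE))
  c(list(values = m), read_sidecar(path))
}

#' Export a matrix as 8- or 16-bit grayscale PNG
#'
#' @param m Matrix (or `complex_field` intensity).
#' @param path Output path.
#' @param bits 8 or 16.
#' @param scale `"linear"` or `"log"` (log10(1 + x) before scaling).
#' @return `path`, invisibly. The applied range is recorded in the sidecar.
#' @export
write_png_scaled <- function(m, path, bits = 16L, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (inherits(m, "complex_field")) m <- m$intensity
  m <- as.matrix(m)
  if (scale == "log") m <- log10(1 + m)
  lo <- min(m); hi <- max(m)
  s <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  png::writePNG(t(s), path, dpi = NULL)
  write_sidecar(path, list(scale = scale, min = lo, max = hi, bits = bits))
  invisible(path)
}

#' Load a B-scan image from TIFF, PNG or CSV
#'
#' @param path Image path; format inferred from the extension. CSV files
#'   must contain a plain numeric matrix (rows = depth).
#' @param pitch_lateral,pitch_axial Pixel pitch (um).
#' @param mean_index Mean tissue index for depth conversion.
#' @return A [bscan_image()].
#' @export
read_bscan <- function(path, pitch_lateral = 1, pitch_axial = 1,
                       mean_index = 1.44) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    tif = , tiff = {
      m <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    },
    png = {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    },
    csv = as.matrix(utils::read.csv(path, header = TRUE)),
    stop("unsupported image format: ", ext, call. = FALSE))
  storage.mode(vals) <- "double"
  bscan_image(vals, pitch_lateral, pitch_axial, mean_index)
}

#' Write an OCT scan to file
#'
#' A-scans as CSV (`zeta`, `depth`, `W`); B/C-scans as float TIFF with axis
#' metadata in the sidecar.
#'
#' @param scan An `oct_scan`.
#' @param path Output path (`.csv` for A, `.tif` for B/C).
#' @return `path`, invisibly.
#' @export
write_oct_scan <- function(scan, path) {
  stopifnot(inherits(scan, "oct_scan"))
  if (scan$kind == "A") {
    utils::write.csv(data.frame(zeta_um = scan$zeta, depth_um = scan$depth,
                                W = scan$W), path, row.names = FALSE)
  } else {
    lo <- min(scan$W); hi <- max(scan$W)
    s <- if (hi > lo) (scan$W - lo) / (hi - lo) else scan$W * 0
    tiff::writeTIFF(t(s), path, bits.per.sample = 32L)
    meta <- list(kind = scan$kind, n_trials = scan$n_trials,
                 seed = scan$seed, value_min = lo, value_max = hi)
    if (scan$kind == "B") {
      meta$zeta_min <- min(scan$zeta); meta$zeta_max <- max(scan$zeta)
      meta$positions <- paste(signif(scan$positions, 6), collapse = ";")
    } else {
      meta$c_depth <- scan$c_depth
    }
    write_sidecar(path, meta)
  }
  invisible(path)
}

#' Convert between the supported matrix formats
#'
#' Lossless TIFF/CSV round trips; conversion to PNG quantizes and requires
#' `allow_lossy = TRUE`. Applied scalings are recorded in the sidecar.
#'
#' @param input Input file (float TIFF or CSV matrix).
#' @param output Output file; format from the extension.
#' @param allow_lossy Permit quantizing conversions (PNG).
#' @return `output`, invisibly.
#' @export
convert_image <- function(input, output, allow_lossy = FALSE) {
  ext_in <- tolower(tools::file_ext(input))
  ext_out <- tolower(tools::file_ext(output))
  m <- switch(ext_in,
    tif = , tiff = read_field_tiff(input)$values,
    csv = as.matrix(utils::read.csv(input, header = TRUE)),
    stop("unsupported input format: ", ext_in, call. = FALSE))
  storage.mode(m) <- "double"
  switch(ext_out,
    tif = , tiff = write_field_tiff(m, output),
    csv = {
      # 17 significant digits: doubles survive the text leg exactly
      txt <- matrix(formatC(m, digits = 17, format = "g"), nrow(m))
      utils::write.table(txt, output, sep = ",", row.names = FALSE,
                         col.names = paste0("V", seq_len(ncol(m))),
                         quote = FALSE)
    },
    png = {
      if (!allow_lossy)
        stop("conversion to PNG quantizes; pass allow_lossy = TRUE",
             call. = FALSE)
      write_png_scaled(m, output)
    },
    stop("unsupported output format: ", ext_out, call. = FALSE))
  invisible(output)
}
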