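# Minimal 32-bit IEEE-float grayscale TIFF codec (single strip, little
# endian). The general-purpose TIFF package stores integer samples
# normalized to [0, 1]; field maps (refractive index, intensity, W) need
# true float samples, so those are written with this codec. Reading falls
# back to the general package for foreign files.

write_float_tiff <- function(m, path) {
  m <- as.matrix(m)
  w <- nrow(m)   # image width  = x (lateral)
  h <- ncol(m)   # image length = z (rows run along depth)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42L); u32(8L)  # header: IFD at byte 8
  tags <- list(  # tag, type (3 = short, 4 = long), value
    c(256L, 4L, w), c(257L, 4L, h), c(258L, 3L, 32L), c(259L, 3L, 1L),
    c(262L, 3L, 1L), c(273L, 4L, 0L),  # strip offset patched below
    c(277L, 3L, 1L), c(278L, 4L, h), c(279L, 4L, 4L * w * h),
    c(339L, 3L, 3L))                   # sample format: IEEE float
  n <- length(tags)
  data_offset <- 8L + 2L + n * 12L + 4L
  u16(n)
  for (tg in tags) {
    u16(tg[1]); u16(tg[2]); u32(1L)
    v <- if (tg[1] == 273L) data_offset else tg[3]
    if (tg[2] == 3L) { u16(v); u16(0L) } else u32(v)
  }
  u32(0L)  # no further IFD
  # TIFF row j holds the lateral (x) samples at depth index j = column j of m
  writeBin(as.numeric(m), con, size = 4, endian = "little")
  invisible(path)
}

# Returns the matrix (x by z) or NULL if the file is not one of ours.
read_float_tiff <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", sz)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II") return(NULL)
  u16at <- function(o) sum(as.integer(raw[o + 1:2]) * c(1, 256))
  u32at <- function(o) sum(as.integer(raw[o + 1:4]) * 256^(0:3))
  if (u16at(2) != 42) return(NULL)
  ifd <- u32at(4)
  n <- u16at(ifd)
  fields <- list()
  for (i in seq_len(n)) {
    o <- ifd + 2 + (i - 1) * 12
    tag <- u16at(o); typ <- u16at(o + 2)
    val <- if (typ == 3) u16at(o + 8) else u32at(o + 8)
    fields[[as.character(tag)]] <- val
  }
  need <- c("256", "257", "258", "273", "339")
  if (!all(need %in% names(fields))) return(NULL)
  if (fields[["258"]] != 32 || fields[["339"]] != 3) return(NULL)
  w <- fields[["256"]]; h <- fields[["257"]]
  off <- fields[["273"]]
  vals <- readBin(raw[(off + 1):(off + 4 * w * h)], "numeric", n = w * h,
                  size = 4, endian = "little")
  matrix(vals, w, h)
}
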