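#' Write a 16-bit grayscale PGM image
#'
#' Frames are exchanged as binary 16-bit portable graymaps (PGM `P5`,
#' maxval 65535), a dependency-free raster format readable by scikit-image,
#' ImageMagick and most viewers. Intensities are scaled from `[0, scale]`
#' to the full 16-bit range.
#'
#' @param img A [projection_image()] or a numeric matrix (rows = v).
#' @param path Output file path.
#' @param scale Intensity mapped to the maximum gray value (default the
#'   image maximum, or 1 for an all-zero image).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, scale = NULL) {
  px <- if (inherits(img, "projection_image")) img$pixels else img
  scale <- scale %||% max(max(px), 1)
  q <- round(pmin(pmax(px / scale, 0), 1) * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(px), nrow(px)), "65535"), con)
  # row-major (v fastest over u), big-endian per the PGM spec
  writeBin(as.integer(t(q)), con, size = 2, endian = "big")
  invisible(path)
}

#' Read a 16-bit PGM image written by [write_pgm()]
#'
#' @param path File path.
#' @return Numeric matrix (rows = v) with values in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "P5")) stop("read_pgm: not a binary PGM file")
  dims <- scan(con, what = integer(), n = 2, quiet = TRUE)
  maxval <- scan(con, what = integer(), n = 1, quiet = TRUE)
  # the single whitespace byte after maxval was consumed by scan
  raw <- readBin(con, "integer", n = dims[1] * dims[2], size = 2,
                 signed = FALSE, endian = "big")
  matrix(raw / maxval, nrow = dims[2], byrow = TRUE)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
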