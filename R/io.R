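# Image I/O.  Portable graymap (PGM) is used as the on-disk raster format:
# it round-trips 8- and 16-bit grayscale losslessly, needs no external
# library, and every scientific image tool (ImageJ, scikit-image, ImageMagick)
# reads it.  P5 (binary, big-endian for 16-bit) is written; P2 and P5 are
# both read.

#' Write a matrix as a PGM grayscale image
#'
#' @param mat integer-valued numeric matrix (row = image row).
#' @param path output file path.
#' @param maxval maximum gray value declared in the header; 255 gives an
#'   8-bit file, anything larger (up to 65535) a 16-bit file.
#' @param ascii write plain-text P2 instead of binary P5.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path, maxval = 65535L, ascii = FALSE) {
  stopifnot(is.matrix(mat), all(mat >= 0), all(mat <= maxval))
  v <- as.integer(round(t(mat)))  # PGM is row-major
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
    writeLines(paste(v, collapse = " "), con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(mat), nrow(mat), maxval), con,
            eos = NULL)
  if (maxval > 255L) writeBin(v, con, size = 2L, endian = "big")
  else writeBin(as.raw(v), con)
  invisible(path)
}

#' Read a PGM grayscale image
#'
#' @param path file path of a P2 (ASCII) or P5 (binary) PGM file.
#' @return An integer matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header")
      if (ch == "#") repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  n <- w * h
  v <- if (magic == "P5") {
    if (maxval > 255L) readBin(con, "integer", n, size = 2L, signed = FALSE,
                               endian = "big")
    else as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) != n) stop("truncated PGM pixel data: ", path)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

write_mask_pgm <- function(mask, path) {
  write_pgm(matrix(as.integer(mask), nrow(mask)), path, maxval = 255L)
}

read_mask_pgm <- function(path) read_pgm(path) != 0L

#' Read a qBEI image from a PGM file
#'
#' @param path PGM file path.
#' @param pixel_size_um pixel edge length in micrometers (1.8 is the
#'   conventional qBEI overview resolution).
#' @param accelerating_voltage_kv beam energy metadata, in kV.
#' @return A [qbei_image()] object.
#' @export
read_qbei <- function(path, pixel_size_um = 1.8, accelerating_voltage_kv = 20) {
  qbei_image(read_pgm(path), pixel_size_um, accelerating_voltage_kv)
}

#' Construct a qBEI image object
#'
#' A thin container for a nonnegative integer gray-level grid plus the two
#' pieces of acquisition metadata the analysis needs.
#'
#' @param gray nonnegative integer matrix of gray levels.
#' @param pixel_size_um pixel edge length, micrometers.
#' @param accelerating_voltage_kv beam energy metadata, kV.
#' @return An object of class `qbei_image`.
#' @export
qbei_image <- function(gray, pixel_size_um = 1.8, accelerating_voltage_kv = 20) {
  stopifnot(is.matrix(gray), all(gray >= 0))
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  structure(list(gray = gray, pixel_size_um = pixel_size_um,
                 accelerating_voltage_kv = accelerating_voltage_kv),
            class = "qbei_image")
}

#' @export
print.qbei_image <- function(x, ...) {
  cat(sprintf("qBEI image: %d x %d px, %.3g um/px, %g kV, gray range [%d, %d]\n",
              nrow(x$gray), ncol(x$gray), x$pixel_size_um,
              x$accelerating_voltage_kv, min(x$gray), max(x$gray)))
  invisible(x)
}
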