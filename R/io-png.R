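## Lossless 16-bit grayscale PNG I/O for depth images (value = mm,
## 0 = invalid). Reading goes through png::readPNG, which handles 16-bit
## rasters natively. No installed package writes 16-bit PNGs, so the
## writer below emits the minimal conforming stream itself: IHDR + IDAT
## (filter-None scanlines, zlib-compressed) + IEND.

.crcTable <- local({
  tab <- integer(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L)) bitwXor(bitwShiftR(cc, 1L), -306674912L)
            else bitwShiftR(cc, 1L)
    tab[n + 1L] <- cc
  }
  tab
})

.crc32 <- function(bytes) {
  b <- as.integer(bytes)
  cc <- -1L
  for (x in b)
    cc <- bitwXor(bitwShiftR(cc, 8L), .crcTable[bitwAnd(bitwXor(cc, x), 255L) + 1L])
  bitwXor(cc, -1L)
}

## big-endian uint32 as 4 raw bytes; accepts a (possibly negative) 32-bit int
.u32 <- function(x) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256,
           x %% 256))
}

.pngChunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(.u32(length(data)), td, .u32(.crc32(td)))
}

#' Read and write 16-bit depth PNGs
#'
#' Depth images are stored as single-channel 16-bit PNGs whose pixel value
#' is the depth in millimetres (0 = invalid). The round trip is lossless.
#'
#' @param path file path.
#' @return \code{readDepthPNG} returns a \code{\link{DepthImage}};
#'   \code{writeDepthPNG} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' d <- DepthImage(matrix(c(0, 700, 900, 0), 2, 2))
#' writeDepthPNG(d, f)
#' identical(depthData(readDepthPNG(f)), depthData(d))
#' @export
readDepthPNG <- function(path) {
  if (!file.exists(path)) formatError(paste("no such file:", path))
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 16L)
    formatError(sprintf("expected a 16-bit depth PNG, got %d-bit: %s",
                        info$bit.depth, path))
  if (length(dim(img)) != 2L)
    formatError(paste("expected a single-channel depth PNG:", path))
  d <- round(img * 65535)
  attributes(d) <- list(dim = dim(d))
  DepthImage(d)
}

#' @rdname readDepthPNG
#' @param depth a \code{\link{DepthImage}} with values in [0, 65535] mm.
#' @export
writeDepthPNG <- function(depth, path) {
  stopifnot(is(depth, "DepthImage"))
  d <- round(depth@data)
  if (any(d < 0) || any(d > 65535))
    formatError("depth values must lie in [0, 65535] mm for 16-bit storage")
  h <- nrow(d); w <- ncol(d)
  v <- as.integer(t(d))                        # row-major scanlines
  bytes <- as.raw(rbind(v %/% 256L, v %% 256L))  # big-endian 16-bit
  scan <- matrix(bytes, nrow = 2L * w)
  filtered <- as.raw(rbind(as.raw(0L), scan))  # filter type 0 per scanline
  dim(filtered) <- NULL
  ## memCompress emits an RFC-1950 zlib stream, which is what IDAT holds
  idat <- memCompress(filtered, type = "gzip")
  ihdr <- c(.u32(w), .u32(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))   # 16-bit grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .pngChunk("IHDR", ihdr), .pngChunk("IDAT", idat),
           .pngChunk("IEND", raw()))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Read and write 8-bit color PNGs
#'
#' Thin wrappers around the \pkg{png} package returning/accepting H x W x 3
#' integer arrays of 8-bit RGB values.
#'
#' @param path file path.
#' @return \code{readColorPNG} returns an H x W x 3 integer array in
#'   [0, 255]; \code{writeColorPNG} returns \code{path} invisibly.
#' @export
readColorPNG <- function(path) {
  if (!file.exists(path)) formatError(paste("no such file:", path))
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    formatError(paste("expected an RGB PNG:", path))
  out <- round(img[, , 1:3] * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname readColorPNG
#' @param image H x W x 3 array of RGB values in [0, 255].
#' @export
writeColorPNG <- function(image, path) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    formatError("image must be an H x W x 3 array")
  png::writePNG(image / 255, path)
  invisible(path)
}
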