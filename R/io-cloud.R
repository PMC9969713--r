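## PLY and PCD point-cloud files. Coordinates are stored as 32-bit floats
## in mm and colors as unsigned bytes; both ascii and binary
## (little-endian) encodings are supported in both directions. The color-
## validity flag is not part of either format: writing drops it, reading a
## colored file marks every point color-valid.

## write text lines to a binary-mode connection (keeps text and binary
## payload in one stream with deterministic \n separators)
.writeTextLines <- function(lines, con) {
  writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
}

#' Write a point cloud to PLY or PCD
#'
#' @param cloud a \code{\link{PointCloud}}.
#' @param path output path; the format is taken from the extension when
#'   \code{format = "auto"}.
#' @param format \code{"auto"}, \code{"ply"} or \code{"pcd"}.
#' @param encoding \code{"ascii"} or \code{"binary"} (little-endian).
#' @return \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".ply")
#' writePointCloud(PointCloud(matrix(rnorm(9), 3, 3)), f)
#' readPointCloud(f)
#' @export
writePointCloud <- function(cloud, path, format = c("auto", "ply", "pcd"),
                            encoding = c("ascii", "binary")) {
  stopifnot(is(cloud, "PointCloud"))
  format <- match.arg(format)
  encoding <- match.arg(encoding)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "pcd"))
      formatError(paste("cannot infer point-cloud format from extension:",
                        path))
  }
  n <- nPoints(cloud)
  hasCol <- nrow(cloud@colors) > 0L
  xyz <- cloud@coords
  if (format == "ply") .writePLY(xyz, if (hasCol) cloud@colors, path, encoding)
  else .writePCD(xyz, if (hasCol) cloud@colors, path, encoding)
  invisible(path)
}

.writePLY <- function(xyz, colors, path, encoding) {
  n <- nrow(xyz)
  fmt <- if (encoding == "ascii") "ascii"
         else "binary_little_endian"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", n),
              "property float x", "property float y", "property float z")
  if (!is.null(colors))
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue")
  header <- c(header, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  .writeTextLines(header, con)
  if (encoding == "ascii") {
    if (n > 0L) {
      rows <- apply(cbind(signif(xyz, 9),
                          if (!is.null(colors)) colors), 1L, paste,
                    collapse = " ")
      .writeTextLines(rows, con)
    }
  } else if (n > 0L) {
    stride <- 12L + if (!is.null(colors)) 3L else 0L
    buf <- raw(n * stride)
    co <- writeBin(as.vector(t(xyz)), raw(), size = 4L,
                   endian = "little")
    cm <- matrix(co, nrow = 12L)
    for (b in 1:12) buf[seq(b, by = stride, length.out = n)] <- cm[b, ]
    if (!is.null(colors)) {
      rcol <- as.raw(t(colors))
      dim(rcol) <- c(3L, n)
      for (b in 1:3)
        buf[seq(12L + b, by = stride, length.out = n)] <- rcol[b, ]
    }
    writeBin(buf, con)
  }
}

.writePCD <- function(xyz, colors, path, encoding) {
  n <- nrow(xyz)
  if (!is.null(colors)) {
    fields <- "x y z r g b"; size <- "4 4 4 1 1 1"
    type <- "F F F U U U"; count <- "1 1 1 1 1 1"
  } else {
    fields <- "x y z"; size <- "4 4 4"; type <- "F F F"; count <- "1 1 1"
  }
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7", paste("FIELDS", fields), paste("SIZE", size),
              paste("TYPE", type), paste("COUNT", count),
              paste("WIDTH", n), "HEIGHT 1", "VIEWPOINT 0 0 0 1 0 0 0",
              paste("POINTS", n),
              paste("DATA", if (encoding == "ascii") "ascii" else "binary"))
  con <- file(path, "wb")
  on.exit(close(con))
  .writeTextLines(header, con)
  if (n == 0L) return(invisible())
  if (encoding == "ascii") {
    rows <- apply(cbind(signif(xyz, 9), colors), 1L, paste, collapse = " ")
    .writeTextLines(rows, con)
  } else {
    stride <- 12L + if (!is.null(colors)) 3L else 0L
    buf <- raw(n * stride)
    co <- writeBin(as.vector(t(xyz)), raw(), size = 4L, endian = "little")
    cm <- matrix(co, nrow = 12L)
    for (b in 1:12) buf[seq(b, by = stride, length.out = n)] <- cm[b, ]
    if (!is.null(colors)) {
      rcol <- as.raw(t(colors))
      dim(rcol) <- c(3L, n)
      for (b in 1:3)
        buf[seq(12L + b, by = stride, length.out = n)] <- rcol[b, ]
    }
    writeBin(buf, con)
  }
}

#' Read a point cloud from PLY or PCD
#'
#' @param path input path (format inferred from the header).
#' @return a \code{\link{PointCloud}}; colored when the file stores
#'   colors.
#' @export
readPointCloud <- function(path) {
  if (!file.exists(path)) formatError(paste("no such file:", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (identical(first, "ply")) .readPLY(path)
  else if (grepl("^(# \\.PCD|VERSION)", first)) .readPCD(path)
  else formatError(paste0("unrecognised point-cloud header (line 1: '",
                          first, "'): ", path))
}

## read header lines of a binary-capable file: scan raw until the marker
.readHeaderLines <- function(path, stopPattern) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    line <- character()
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L)
        formatError(sprintf("header of %s ended before '%s' (line %d)",
                            path, stopPattern, length(lines) + 1L))
      if (b == as.raw(10L)) break
      bytes <- c(bytes, b)
    }
    line <- rawToChar(bytes[bytes != as.raw(13L)])
    lines <- c(lines, line)
    if (grepl(stopPattern, line)) break
    if (length(lines) > 100L)
      formatError(paste("header too long (malformed?) in", path))
  }
  list(lines = lines, offset = seek(con))
}

.readBinaryVertices <- function(path, offset, n, stride, floatOffsets,
                                ucharOffsets) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, offset)
  payload <- readBin(con, "raw", n * stride)
  if (length(payload) < n * stride)
    formatError(sprintf("binary payload of %s truncated (%d of %d bytes)",
                        path, length(payload), n * stride))
  base <- (seq_len(n) - 1L) * stride
  getFloat <- function(off) {
    idx <- rep(base, each = 4L) + off + seq_len(4L)
    readBin(payload[idx], "numeric", n = n, size = 4L, endian = "little")
  }
  xyz <- vapply(floatOffsets, getFloat, numeric(n))
  if (n == 1L) xyz <- matrix(xyz, 1L)
  cols <- NULL
  if (length(ucharOffsets))
    cols <- vapply(ucharOffsets,
                   function(off) as.integer(payload[base + off + 1L]),
                   integer(n))
  if (!is.null(cols) && n == 1L) cols <- matrix(cols, 1L)
  list(xyz = xyz, colors = cols)
}

.readPLY <- function(path) {
  hdr <- .readHeaderLines(path, "^end_header")
  lines <- hdr$lines
  fmtLine <- grep("^format ", lines, value = TRUE)
  if (length(fmtLine) != 1L)
    formatError(paste("PLY header missing format line in", path))
  binary <- grepl("binary_little_endian", fmtLine)
  if (!binary && !grepl("ascii", fmtLine))
    formatError(paste("unsupported PLY format:", fmtLine))
  vLine <- grep("^element vertex ", lines)
  if (length(vLine) != 1L)
    formatError(paste("PLY header missing 'element vertex' in", path))
  n <- as.integer(sub("^element vertex ", "", lines[vLine]))
  props <- sub("^property ", "", grep("^property ", lines, value = TRUE))
  ptype <- vapply(strsplit(props, " "), `[`, "", 1L)
  pname <- vapply(strsplit(props, " "), `[`, "", 2L)
  need <- match(c("x", "y", "z"), pname)
  if (any(is.na(need)))
    formatError(paste("PLY vertex lacks x/y/z properties in", path))
  colIdx <- match(c("red", "green", "blue"), pname)
  hasCol <- !any(is.na(colIdx))
  if (n == 0L)
    return(PointCloud(matrix(numeric(), 0L, 3L)))
  if (!binary) {
    dat <- utils::read.table(path, skip = length(lines), nrows = n)
    if (ncol(dat) < length(pname))
      formatError(paste("PLY vertex rows are narrower than the header in",
                        path))
    PointCloud(as.matrix(dat[, need]),
               colors = if (hasCol) as.matrix(dat[, colIdx]))
  } else {
    sizes <- c(float = 4L, double = 8L, uchar = 1L, uint8 = 1L, int = 4L,
               uint = 4L, short = 2L, ushort = 2L, char = 1L, int8 = 1L)
    psz <- sizes[ptype]
    if (any(is.na(psz)))
      formatError(paste("unsupported PLY property type in", path))
    offs <- cumsum(c(0L, psz[-length(psz)]))
    r <- .readBinaryVertices(path, hdr$offset, n, sum(psz), offs[need],
                             if (hasCol) offs[colIdx] else integer())
    PointCloud(r$xyz, colors = r$colors)
  }
}

.readPCD <- function(path) {
  hdr <- .readHeaderLines(path, "^DATA ")
  lines <- hdr$lines
  getField <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(ln) != 1L)
      formatError(sprintf("PCD header missing '%s' in %s", key, path))
    strsplit(sub(paste0("^", key, " "), "", ln), " ")[[1L]]
  }
  fields <- getField("FIELDS")
  sizes <- as.integer(getField("SIZE"))
  types <- getField("TYPE")
  n <- as.integer(getField("POINTS"))
  mode <- sub("^DATA ", "", grep("^DATA ", lines, value = TRUE))
  need <- match(c("x", "y", "z"), fields)
  if (any(is.na(need))) formatError(paste("PCD lacks x/y/z fields in", path))
  colIdx <- match(c("r", "g", "b"), fields)
  hasCol <- !any(is.na(colIdx))
  if (n == 0L) return(PointCloud(matrix(numeric(), 0L, 3L)))
  if (mode == "ascii") {
    dat <- utils::read.table(path, skip = length(lines), nrows = n)
    PointCloud(as.matrix(dat[, need]),
               colors = if (hasCol) as.matrix(dat[, colIdx]))
  } else if (mode == "binary") {
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    r <- .readBinaryVertices(path, hdr$offset, n, sum(sizes), offs[need],
                             if (hasCol) offs[colIdx] else integer())
    PointCloud(r$xyz, colors = r$colors)
  } else formatError(paste("unsupported PCD DATA mode:", mode))
}
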