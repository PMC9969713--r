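## Depth back-projection, rigid motion and colorization.
##
## Camera frame convention: +Z points forward along the optical axis (depth),
## +Y points up, +X to the right as seen in the image. Because image rows
## grow downwards while world Y grows upwards, the row term is negated in
## both directions of the projection.

#' Back-project a depth image into a metric point cloud
#'
#' Converts every valid depth pixel into a 3-D point in the depth camera's
#' frame using the inverse pinhole model:
#' \deqn{x = (u - c_x) d / f_x,\quad y = -(v - c_y) d / f_y,\quad z = d}
#' where \eqn{(v, u)} is the (row, column) pixel position and \eqn{d} the
#' depth in mm. Pixels with \eqn{d = 0} or with \eqn{d} outside
#' \code{depthRange} are excluded. The output carries each point's pixel of
#' origin so that projection round-trips can be verified.
#'
#' @param depth a \code{\link{DepthImage}}.
#' @param intr the depth camera's \code{\link{CameraIntrinsics}}.
#' @param depthRange valid depth interval in mm (default 500--4000, the
#'   working range of the Kinect v2 class of sensors).
#' @return a \code{\link{PointCloud}} with pixel origins attached. An empty
#'   cloud (zero points) is returned when no pixel is valid.
#' @examples
#' intr <- CameraIntrinsics(365, 365, 4, 4, 8, 8)
#' d <- matrix(0, 8, 8); d[4, 4] <- 1000
#' backprojectDepth(DepthImage(d), intr)
#' @export
backprojectDepth <- function(depth, intr, depthRange = c(500, 4000)) {
  stopifnot(is(depth, "DepthImage"), is(intr, "CameraIntrinsics"))
  d <- depth@data
  if (nrow(d) != intr@height || ncol(d) != intr@width)
    configurationError(sprintf(
      "depth image is %dx%d px but intrinsics expect %dx%d",
      ncol(d), nrow(d), intr@width, intr@height))
  if (length(depthRange) != 2L || depthRange[1] >= depthRange[2])
    configurationError("depthRange must be (min, max) with min < max")
  keep <- which(d > 0 & d >= depthRange[1] & d <= depthRange[2])
  if (length(keep) == 0L)
    return(PointCloud(matrix(numeric(), 0L, 3L),
                      pixels = matrix(integer(), 0L, 2L)))
  v <- ((keep - 1L) %% nrow(d)) + 1L       # row
  u <- ((keep - 1L) %/% nrow(d)) + 1L      # column
  dv <- d[keep]
  PointCloud(cbind(x = (u - intr@cx) * dv / intr@fx,
                   y = -(v - intr@cy) * dv / intr@fy,
                   z = dv),
             pixels = cbind(v, u))
}

#' Apply a rigid transform to a point cloud
#'
#' Maps every point \code{p} to \code{rotation \%*\% p + translation}.
#' Colors, color flags and pixel origins are carried through unchanged; the
#' input cloud is not modified.
#'
#' @param cloud a \code{\link{PointCloud}} (may be empty).
#' @param xf a \code{\link{RigidTransform}}.
#' @return the transformed \code{PointCloud}.
#' @export
applyRigidTransform <- function(cloud, xf) {
  stopifnot(is(cloud, "PointCloud"))
  if (!is(xf, "RigidTransform"))
    validationError("'xf' must be a RigidTransform (orthonormal, det +1)")
  validObject(xf)
  out <- cloud
  if (nrow(cloud@coords) > 0L)
    out@coords <- sweep(cloud@coords %*% t(xf@rotation), 2L,
                        xf@translation, "+")
  colnames(out@coords) <- c("x", "y", "z")
  out
}

#' Invert a rigid transform
#'
#' @param xf a \code{\link{RigidTransform}}.
#' @return the inverse \code{RigidTransform}.
#' @export
invertRigidTransform <- function(xf) {
  stopifnot(is(xf, "RigidTransform"))
  RigidTransform(t(xf@rotation), -as.vector(t(xf@rotation) %*% xf@translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first}, then
#' \code{second}.
#'
#' @param second,first \code{\link{RigidTransform}}s.
#' @return their composition as a \code{RigidTransform}.
#' @export
composeRigidTransforms <- function(second, first) {
  RigidTransform(second@rotation %*% first@rotation,
                 as.vector(second@rotation %*% first@translation) +
                   second@translation)
}

#' Project points to pixel positions
#'
#' Perspective projection with nearest-pixel rounding:
#' \deqn{u = c_x + f_x x / z,\quad v = c_y - f_y y / z}
#' rounded half-away-from-zero to the nearest integer pixel. Points with
#' \eqn{z \le 0} (behind the camera) or whose rounded pixel falls outside
#' the raster receive the out-of-frame marker \code{NA}.
#'
#' @param cloud a \code{\link{PointCloud}}.
#' @param intr \code{\link{CameraIntrinsics}} of the target camera.
#' @return an N x 2 integer matrix of (row, col) pixel positions, with both
#'   entries \code{NA} for out-of-frame points.
#' @export
projectPointsToPixels <- function(cloud, intr) {
  stopifnot(is(cloud, "PointCloud"), is(intr, "CameraIntrinsics"))
  p <- cloud@coords
  n <- nrow(p)
  out <- matrix(NA_integer_, n, 2L, dimnames = list(NULL, c("row", "col")))
  if (n == 0L) return(out)
  ok <- p[, 3L] > 0
  if (any(ok)) {
    u <- .roundHalfAway(intr@cx + intr@fx * p[ok, 1L] / p[ok, 3L])
    v <- .roundHalfAway(intr@cy - intr@fy * p[ok, 2L] / p[ok, 3L])
    inframe <- u >= 1 & u <= intr@width & v >= 1 & v <= intr@height
    idx <- which(ok)[inframe]
    out[idx, 1L] <- as.integer(v[inframe])
    out[idx, 2L] <- as.integer(u[inframe])
  }
  out
}

## round-to-nearest, ties half away from zero (base round() ties to even)
.roundHalfAway <- function(x) trunc(x + 0.5 * sign(x))

#' Attach image colors to a point cloud
#'
#' Projects each point into the color camera's raster and assigns the
#' nearest pixel's RGB value. Points projecting outside the raster (or
#' behind the camera) are retained with their color-valid flag set to
#' \code{FALSE}, unless \code{dropColorless = TRUE}.
#'
#' @param cloud a \code{\link{PointCloud}} already expressed in the color
#'   camera's frame.
#' @param rgbImage an H x W x 3 array of 8-bit RGB values (0--255), or
#'   values in [0, 1] which are rescaled.
#' @param intr the color camera's \code{\link{CameraIntrinsics}}.
#' @param dropColorless drop out-of-frame points instead of flagging them.
#' @return the colorized \code{PointCloud}.
#' @export
colorizeCloud <- function(cloud, rgbImage, intr, dropColorless = FALSE) {
  stopifnot(is(cloud, "PointCloud"), is(intr, "CameraIntrinsics"))
  dm <- dim(rgbImage)
  if (length(dm) != 3L || dm[3L] < 3L)
    configurationError("rgbImage must be an H x W x 3 array")
  if (dm[1L] != intr@height || dm[2L] != intr@width)
    configurationError(sprintf(
      "rgbImage is %dx%d px but intrinsics expect %dx%d",
      dm[2L], dm[1L], intr@width, intr@height))
  if (is.double(rgbImage) && length(rgbImage) && max(rgbImage) <= 1)
    rgbImage <- rgbImage * 255    # [0,1] raster (e.g. png::readPNG output)
  n <- nrow(cloud@coords)
  px <- projectPointsToPixels(cloud, intr)
  valid <- !is.na(px[, 1L])
  cols <- matrix(0L, n, 3L)
  if (any(valid)) {
    h <- dm[1L]; w <- dm[2L]
    lin <- px[valid, 1L] + (px[valid, 2L] - 1L) * h
    for (ch in 1:3)
      cols[valid, ch] <- as.integer(round(rgbImage[lin + (ch - 1L) * h * w]))
  }
  out <- PointCloud(cloud@coords, colors = cols, colorValid = valid,
                    pixels = if (nrow(cloud@pixels)) cloud@pixels)
  if (dropColorless) out[valid] else out
}
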