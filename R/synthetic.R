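## Virtual dual-camera rig: procedural plant scenes, z-buffer depth
## rendering with per-surface color coding, and a Kinect-like depth noise
## model. Provides exact ground truth for every downstream stage.

#' Default virtual depth-camera intrinsics
#'
#' Kinect-v2-like defaults: a 512 x 424 depth raster with a centred
#' principal point and a focal length of about 365 px (the raster size is
#' the sensor's; the focal length is a rig default, as it is not part of
#' the published calibration).
#'
#' @return a \code{\link{CameraIntrinsics}}.
#' @export
defaultDepthIntrinsics <- function() {
  CameraIntrinsics(fx = 365, fy = 365, cx = (512 + 1) / 2,
                   cy = (424 + 1) / 2, width = 512, height = 424)
}

#' @rdname defaultDepthIntrinsics
#' @export
defaultColorIntrinsics <- function() {
  CameraIntrinsics(fx = 1100, fy = 1100, cx = (1920 + 1) / 2,
                   cy = (1080 + 1) / 2, width = 1920, height = 1080)
}

#' Camera pose on a virtual turntable
#'
#' World -> camera transform of a camera viewing the pot centre from
#' azimuth \code{azimuthDeg}, at \code{standoff} mm. Azimuth 0 is the
#' reference camera (identity); azimuth 180 is the opposed mirror camera.
#'
#' @param azimuthDeg azimuth in degrees.
#' @param standoff camera-to-target distance in mm (default 700).
#' @return a \code{\link{RigidTransform}}.
#' @export
turntablePose <- function(azimuthDeg, standoff = 700) {
  th <- azimuthDeg * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th),
                0, 1, 0,
                sin(th), 0, cos(th)), 3L, 3L)
  C <- c(0, 0, standoff)
  RigidTransform(R, C - as.vector(R %*% C))
}

.surfaceColors <- rbind(stem = c(105L, 75L, 55L),
                        leaf = c(40L, 140L, 50L),
                        pot = c(170L, 70L, 50L))

#' Generate a procedural potted-plant scene
#'
#' Samples points on a vertical stem cylinder and on elliptical leaf disks
#' attached at random heights and azimuths, in the world frame (the
#' reference camera's frame: the stem axis passes through x = 0,
#' z = 700 mm, growing upward from the lens line y = 0). A pot cylinder
#' below the lens line is generated as clutter: it is rendered, but it is
#' not part of the plant and not part of the ground-truth traits. The
#' scene is deterministic in the spec's seed.
#'
#' @param spec a \code{\link{PlantSpec}}.
#' @return a \code{\link{SceneTruth}} whose \code{traits} slot is exactly
#'   \code{computeTraits} of the plant points.
#' @examples
#' scene <- generatePlant(PlantSpec(seed = 7, nPoints = 500))
#' scene
#' @export
generatePlant <- function(spec = PlantSpec()) {
  stopifnot(is(spec, "PlantSpec"))
  validObject(spec)
  withr::with_seed(spec@seed, {
    nL <- spec@leafCount
    stemArea <- 2 * pi * spec@stemRadius * spec@stemHeight
    leafArea <- pi * spec@leafMajor * spec@leafMinor
    areas <- c(stemArea, rep(leafArea, nL))
    counts <- floor(spec@nPoints * areas / sum(areas))
    counts[1L] <- counts[1L] + (spec@nPoints - sum(counts))

    ## stem cylinder
    th <- stats::runif(counts[1L], 0, 2 * pi)
    y <- stats::runif(counts[1L], 0, spec@stemHeight)
    pts <- cbind(spec@stemRadius * cos(th), y,
                 700 + spec@stemRadius * sin(th))
    nrm <- cbind(cos(th), 0, sin(th))
    surf <- rep("stem", counts[1L])
    two <- rep(FALSE, counts[1L])

    if (nL > 0L) {
      ## leaflets tilt upward (peanut foliage is diaheliotropic), which
      ## also keeps the canopy's bounding extremes on its visible exterior
      tilt <- 30 * pi / 180
      azr <- spec@azimuthRange * pi / 180
      for (i in seq_len(nL)) {
        y0 <- stats::runif(1, spec@attachLow * spec@stemHeight,
                           spec@attachHigh * spec@stemHeight)
        phi <- stats::runif(1, azr[1L], azr[2L])
        u <- c(cos(phi), 0, sin(phi))              # radial direction
        e1 <- u * cos(tilt) + c(0, 1, 0) * sin(tilt)
        e2 <- c(-sin(phi), 0, cos(phi))
        nvec <- c(e1[2] * e2[3] - e1[3] * e2[2],
                  e1[3] * e2[1] - e1[1] * e2[3],
                  e1[1] * e2[2] - e1[2] * e2[1])
        centre <- c(0, y0, 700) + spec@stemRadius * u + spec@leafMajor * e1
        tt <- stats::runif(counts[i + 1L], 0, 2 * pi)
        rr <- sqrt(stats::runif(counts[i + 1L]))
        off <- outer(spec@leafMajor * rr * cos(tt), e1) +
               outer(spec@leafMinor * rr * sin(tt), e2)
        pts <- rbind(pts, sweep(off, 2L, centre, "+"))
        nrm <- rbind(nrm, matrix(nvec, counts[i + 1L], 3L, byrow = TRUE))
        surf <- c(surf, rep("leaf", counts[i + 1L]))
        two <- c(two, rep(TRUE, counts[i + 1L]))
      }
    }

    ## pot clutter below the lens line
    thp <- stats::runif(spec@potPoints, 0, 2 * pi)
    yp <- stats::runif(spec@potPoints, -spec@potHeight, 0)
    clutter <- cbind(spec@potRadius * cos(thp), yp,
                     700 + spec@potRadius * sin(thp))
    clutterNrm <- cbind(cos(thp), 0, sin(thp))
  })
  colnames(pts) <- c("x", "y", "z")
  new("SceneTruth", points = pts, surface = surf, normals = nrm,
      twoSided = two, clutter = clutter, clutterNormals = clutterNrm,
      poses = list(), traits = computeTraits(pts))
}

#' Render a depth view of a scene
#'
#' Transforms the scene's points (plant plus clutter) into the camera
#' frame, projects them through the pinhole model and keeps the nearest
#' depth per pixel (z-buffer); untouched pixels stay 0. Depths are
#' quantised to integer millimetres, as a real depth sensor reports them.
#' A color raster with a flat per-surface color code and the index of the
#' winning scene point per pixel are returned alongside.
#'
#' Surface visibility is physical: closed surfaces (stem, pot) are
#' back-face culled; thin leaf disks are visible from both sides. With
#' \code{maxIncidenceDeg < 90}, surfaces viewed at grazing incidence
#' return no signal, emulating the loss of time-of-flight returns at
#' steep angles.
#'
#' @param scene a \code{\link{SceneTruth}}.
#' @param pose world -> camera \code{\link{RigidTransform}}.
#' @param intr \code{\link{CameraIntrinsics}}.
#' @param maxIncidenceDeg maximum surface incidence angle that still
#'   returns a depth sample (90 = back-face culling only).
#' @param includeClutter render the pot clutter (default TRUE).
#' @return a list with \code{depth} (a \code{\link{DepthImage}}),
#'   \code{color} (H x W x 3 integer array) and \code{index} (H x W
#'   matrix of scene point indices; clutter points follow plant points).
#' @export
renderDepthView <- function(scene, pose, intr = defaultDepthIntrinsics(),
                            maxIncidenceDeg = 90, includeClutter = TRUE) {
  stopifnot(is(scene, "SceneTruth"), is(pose, "RigidTransform"),
            is(intr, "CameraIntrinsics"))
  validObject(intr)
  P <- scene@points
  N <- nrm <- two <- surf <- NULL
  if (includeClutter && nrow(scene@clutter)) {
    P <- rbind(P, scene@clutter)
    nrm <- rbind(scene@normals, scene@clutterNormals)
    two <- c(scene@twoSided, rep(FALSE, nrow(scene@clutter)))
    surf <- c(scene@surface, rep("pot", nrow(scene@clutter)))
  } else {
    nrm <- scene@normals
    two <- scene@twoSided
    surf <- scene@surface
  }
  pc <- sweep(P %*% t(pose@rotation), 2L, pose@translation, "+")
  nc <- nrm %*% t(pose@rotation)

  z <- pc[, 3L]
  ok <- z > 0
  ray <- pc / sqrt(rowSums(pc^2))
  cosInc <- -rowSums(nc * ray)
  cosInc[two] <- abs(cosInc[two])
  ok <- ok & cosInc > cos(maxIncidenceDeg * pi / 180) & cosInc > 0

  u <- .roundHalfAway(intr@cx + intr@fx * pc[, 1L] / z)
  v <- .roundHalfAway(intr@cy - intr@fy * pc[, 2L] / z)
  ok <- ok & u >= 1 & u <= intr@width & v >= 1 & v <= intr@height

  depth <- matrix(0, intr@height, intr@width)
  colorR <- array(0L, c(intr@height, intr@width, 3L))
  index <- matrix(NA_integer_, intr@height, intr@width)
  idx <- which(ok)
  if (length(idx)) {
    ord <- idx[order(z[idx])]
    pix <- v[ord] + (u[ord] - 1) * intr@height
    first <- !duplicated(pix)
    win <- ord[first]
    pixw <- pix[first]
    depth[pixw] <- round(z[win])
    index[pixw] <- win
    cols <- .surfaceColors[surf[win], , drop = FALSE]
    hw <- intr@height * intr@width
    for (ch in 1:3) colorR[pixw + (ch - 1L) * hw] <- cols[, ch]
  }
  list(depth = DepthImage(depth), color = colorR, index = index)
}

#' Corrupt a rendered depth image with sensor-like noise
#'
#' Applies the three corruption modes of the noise model, in order:
#' zero-mean Gaussian depth noise whose standard deviation grows with the
#' normalised radial distance from the image centre (the depth-edge
#' effect), replacement of a sparse sampled fraction of pixels with
#' uniform outlier depths in the 500--4000 mm working range, and painting
#' of the background-plane depth into a sampled band of empty pixels.
#' Output depths are re-quantised to integer millimetres; the result is
#' reproducible from the spec's seed.
#'
#' @param depth a \code{\link{DepthImage}}.
#' @param noise a \code{\link{NoiseSpec}}.
#' @return the corrupted \code{\link{DepthImage}}.
#' @export
corruptDepth <- function(depth, noise = NoiseSpec()) {
  stopifnot(is(depth, "DepthImage"), is(noise, "NoiseSpec"))
  validObject(noise)
  d <- depth@data
  h <- nrow(d); w <- ncol(d)
  withr::with_seed(noise@seed, {
    valid <- which(d > 0)
    if (noise@baseSd > 0 && length(valid)) {
      vr <- ((valid - 1L) %% h) + 1L
      vc <- ((valid - 1L) %/% h) + 1L
      rho <- sqrt(((vr - (h + 1) / 2) / (h / 2))^2 +
                  ((vc - (w + 1) / 2) / (w / 2))^2) / sqrt(2)
      sd <- noise@baseSd * (1 + noise@edgeMultiplier * rho)
      d[valid] <- d[valid] + stats::rnorm(length(valid), 0, sd)
    }
    nOut <- round(noise@outlierFraction * length(d))
    if (nOut > 0) {
      out <- sample.int(length(d), nOut)
      d[out] <- stats::runif(nOut, 500, 4000)
    }
    if (noise@backgroundFill > 0) {
      empty <- which(d == 0)
      nBg <- round(noise@backgroundFill * length(empty))
      if (nBg > 0) d[sample(empty, nBg)] <- noise@backgroundDepth
    }
  })
  d <- round(d)
  d[d < 0] <- 0
  DepthImage(d)
}

#' Simulate a dual-camera capture of a scene
#'
#' Builds the two opposed mirror-symmetric camera poses implied by the rig
#' geometry (reference camera at the world origin, secondary camera across
#' the pot at one baseline along Z, each half a baseline from the pot
#' centre), renders a depth and color view from each, and optionally
#' corrupts both depth images with the noise model (the secondary view
#' gets an independent noise stream derived from the same seed). The
#' poses are exactly consistent with \code{\link{transformSecondaryCloud}},
#' so fused world points coincide up to rendering quantisation.
#'
#' @param scene a \code{\link{SceneTruth}}.
#' @param rig a \code{\link{RigGeometry}}.
#' @param intr \code{\link{CameraIntrinsics}} shared by both depth cameras.
#' @param noise optional \code{\link{NoiseSpec}}; \code{NULL} renders
#'   noise-free.
#' @param maxIncidenceDeg passed to \code{\link{renderDepthView}}.
#' @return a list with \code{view1} and \code{view2} (each as returned by
#'   \code{\link{renderDepthView}}) and \code{scene}, whose \code{poses}
#'   slot now holds the two camera poses.
#' @export
simulateDualCapture <- function(scene, rig = RigGeometry(),
                                intr = defaultDepthIntrinsics(),
                                noise = NULL, maxIncidenceDeg = 90) {
  stopifnot(is(scene, "SceneTruth"), is(rig, "RigGeometry"))
  validObject(rig)
  poses <- list(camera1 = RigidTransform(),
                camera2 = RigidTransform(diag(c(-1, 1, -1)),
                                         c(0, 0, rig@baseline)))
  v1 <- renderDepthView(scene, poses$camera1, intr, maxIncidenceDeg)
  v2 <- renderDepthView(scene, poses$camera2, intr, maxIncidenceDeg)
  if (all(v1$depth@data == 0) && all(v2$depth@data == 0))
    emptyRenderError("scene is outside both camera frusta")
  if (!is.null(noise)) {
    stopifnot(is(noise, "NoiseSpec"))
    n2 <- noise
    n2@seed <- noise@seed + 1L
    v1$depth <- corruptDepth(v1$depth, noise)
    v2$depth <- corruptDepth(v2$depth, n2)
  }
  scene@poses <- poses
  list(view1 = v1, view2 = v2, scene = scene)
}
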