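#' @import methods
NULL

## ---------------------------------------------------------------------------
## Camera model
## ---------------------------------------------------------------------------

#' Pinhole camera intrinsics
#'
#' Focal lengths and principal point of a pinhole camera, in pixels, plus the
#' raster size. Pixel coordinates follow the R matrix convention: 1-based,
#' rows increase downwards, columns increase to the right; the principal
#' point \code{(cx, cy)} is expressed in the same (column, row) units.
#'
#' @slot fx,fy focal lengths in pixels (> 0).
#' @slot cx,cy principal point, column and row, in pixels.
#' @slot width,height raster size in pixels.
#'
#' @examples
#' intr <- CameraIntrinsics(fx = 365, fy = 365, cx = 256.5, cy = 212.5,
#'                          width = 512, height = 424)
#' intr
#' @export
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", width = "integer", height = "integer"))

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  for (s in c("fx", "fy", "cx", "cy", "width", "height"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(msg)) return(msg)
  if (object@fx <= 0 || object@fy <= 0) msg <- c(msg, "focal lengths must be positive")
  if (object@width < 1L || object@height < 1L) msg <- c(msg, "image size must be positive")
  if (object@cx < 0 || object@cx >= object@width + 1)
    msg <- c(msg, "cx must lie within the raster")
  if (object@cy < 0 || object@cy >= object@height + 1)
    msg <- c(msg, "cy must lie within the raster")
  if (length(msg)) msg else TRUE
})

#' @rdname CameraIntrinsics-class
#' @param fx,fy,cx,cy,width,height see slots.
#' @export
CameraIntrinsics <- function(fx, fy, cx, cy, width, height) {
  new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      width = as.integer(width), height = as.integer(height))
}

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %dx%d  f=(%.2f, %.2f) px  c=(%.2f, %.2f) px\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy))
})

## ---------------------------------------------------------------------------
## Rigid transform
## ---------------------------------------------------------------------------

#' Rigid-body transform (rotation + translation)
#'
#' A proper rigid motion: 3x3 rotation with determinant +1 and a translation
#' in millimetres. Applied to a point \code{p} as \code{rotation \%*\% p +
#' translation}.
#'
#' @slot rotation 3x3 orthonormal matrix, det = +1.
#' @slot translation numeric length-3, mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
    return("rotation must be a numeric 3x3 matrix")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be a finite length-3 vector")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation determinant is not +1 within 1e-9 (improper rotation)")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat(sprintf("  translation: (%.3f, %.3f, %.3f) mm\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

## ---------------------------------------------------------------------------
## Depth image
## ---------------------------------------------------------------------------

#' Depth image
#'
#' A single-channel raster of depth values in millimetres, one per pixel,
#' stored as a numeric matrix (rows = image rows). A value of 0 encodes an
#' invalid (missing) measurement.
#'
#' @slot data numeric matrix of depths in mm; 0 = invalid.
#' @export
setClass("DepthImage", representation(data = "matrix"))

setValidity("DepthImage", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("depth data must be numeric")
  if (any(!is.finite(d))) return("depth data must be finite")
  if (any(d < 0)) return("depth values must be non-negative")
  TRUE
})

#' @rdname DepthImage-class
#' @param data numeric matrix of depths in mm (0 = invalid).
#' @export
DepthImage <- function(data) new("DepthImage", data = data)

#' @describeIn DepthImage-class the depth matrix.
#' @param x a \code{DepthImage}.
#' @export
depthData <- function(x) x@data

setMethod("show", "DepthImage", function(object) {
  v <- object@data[object@data > 0]
  cat(sprintf("DepthImage %dx%d px, %d valid px%s\n",
              ncol(object@data), nrow(object@data), length(v),
              if (length(v)) sprintf(", range [%.0f, %.0f] mm",
                                     min(v), max(v)) else ""))
})

## ---------------------------------------------------------------------------
## Point cloud
## ---------------------------------------------------------------------------

#' 3-D point cloud
#'
#' The universal currency of the pipeline: an N x 3 matrix of coordinates in
#' millimetres, with optional per-point 8-bit RGB colors, a color-validity
#' flag, and (for clouds back-projected from a depth image) the pixel of
#' origin of each point.
#'
#' @slot coords N x 3 numeric matrix, columns x, y, z, mm.
#' @slot colors N x 3 integer matrix in [0, 255], or 0 x 3 when absent.
#' @slot colorValid logical of length N (or 0 when colors are absent).
#' @slot pixels N x 2 integer matrix (row, col) of the source pixel, or 0 x 2.
#'
#' @examples
#' pc <- PointCloud(matrix(rnorm(30), ncol = 3))
#' nPoints(pc)
#' @export
setClass("PointCloud",
  representation(coords = "matrix", colors = "matrix",
                 colorValid = "logical", pixels = "matrix"))

setValidity("PointCloud", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  nc <- nrow(object@colors)
  if (ncol(object@colors) != 3L) return("colors must have 3 columns")
  if (nc != 0L && nc != n) return("colors must have one row per point")
  if (nc > 0L) {
    if (any(object@colors < 0L | object@colors > 255L))
      return("color channels must lie in [0, 255]")
    if (length(object@colorValid) != n)
      return("colorValid must have one flag per point when colors are present")
  }
  np <- nrow(object@pixels)
  if (np != 0L && np != n) return("pixels must have one row per point")
  TRUE
})

#' @rdname PointCloud-class
#' @param coords N x 3 numeric matrix (mm).
#' @param colors optional N x 3 matrix of 8-bit RGB values.
#' @param colorValid optional logical vector of length N; defaults to all
#'   \code{TRUE} when \code{colors} is given.
#' @param pixels optional N x 2 integer matrix of source pixels (row, col).
#' @export
PointCloud <- function(coords, colors = NULL, colorValid = NULL,
                       pixels = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(), 0L, 3L)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  n <- nrow(coords)
  if (is.null(colors)) {
    colors <- matrix(integer(), 0L, 3L)
    colorValid <- logical(0)
  } else {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    dimnames(colors) <- NULL
    if (is.null(colorValid)) colorValid <- rep(TRUE, n)
  }
  if (is.null(pixels)) pixels <- matrix(integer(), 0L, 2L)
  else { pixels <- as.matrix(pixels); storage.mode(pixels) <- "integer" }
  new("PointCloud", coords = coords, colors = colors,
      colorValid = as.logical(colorValid), pixels = pixels)
}

setMethod("show", "PointCloud", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("PointCloud with %d point%s%s%s\n", n,
              if (n == 1L) "" else "s",
              if (nrow(object@colors)) ", colored" else "",
              if (nrow(object@pixels)) ", pixel-indexed" else ""))
  if (n > 0L) {
    r <- apply(object@coords, 2L, range)
    cat(sprintf("  x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
})

## ---------------------------------------------------------------------------
## Filtering parameter objects
## ---------------------------------------------------------------------------

#' Axis-aligned region-of-interest bounds
#'
#' Open-interval bounds, in mm, of the PassThrough region-of-interest crop.
#' Defaults follow the dual-camera rig: the plant pot is centred on the
#' optical axis 700 mm from each lens, the lens line sits level with the pot
#' rim, and plant extent does not exceed 400 mm, giving x in (-200, 200),
#' y in (0, 400) and z in (500, 900).
#'
#' @slot xMin,xMax,yMin,yMax,zMin,zMax bounds in mm; min < max on every axis.
#' @export
setClass("ROIBounds",
  representation(xMin = "numeric", xMax = "numeric", yMin = "numeric",
                 yMax = "numeric", zMin = "numeric", zMax = "numeric"))

setValidity("ROIBounds", function(object) {
  b <- c(object@xMin, object@xMax, object@yMin, object@yMax,
         object@zMin, object@zMax)
  if (any(!is.finite(b))) return("bounds must be finite")
  if (object@xMin >= object@xMax || object@yMin >= object@yMax ||
      object@zMin >= object@zMax)
    return("min must be < max on every axis")
  TRUE
})

#' @rdname ROIBounds-class
#' @param xMin,xMax,yMin,yMax,zMin,zMax bounds in mm.
#' @export
ROIBounds <- function(xMin = -200, xMax = 200, yMin = 0, yMax = 400,
                      zMin = 500, zMax = 900) {
  new("ROIBounds", xMin = as.numeric(xMin), xMax = as.numeric(xMax),
      yMin = as.numeric(yMin), yMax = as.numeric(yMax),
      zMin = as.numeric(zMin), zMax = as.numeric(zMax))
}

setMethod("show", "ROIBounds", function(object) {
  cat(sprintf("ROIBounds x (%g, %g)  y (%g, %g)  z (%g, %g) mm\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              object@zMin, object@zMax))
})

#' Statistical outlier-removal parameters
#'
#' Neighbour count \code{m} and spread coefficient \code{k} of the
#' statistical filter. Defaults (m = 35, k = 1.0) are the values selected by
#' the coordinate-descent procedure on the greenhouse data.
#'
#' @slot m positive integer neighbour count.
#' @slot k non-negative spread coefficient.
#' @export
setClass("StatFilterParams", representation(m = "integer", k = "numeric"))

setValidity("StatFilterParams", function(object) {
  if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
    return("m must be a positive integer")
  if (length(object@k) != 1L || !is.finite(object@k) || object@k < 0)
    return("k must be a non-negative number")
  TRUE
})

#' @rdname StatFilterParams-class
#' @param m neighbour count.
#' @param k spread coefficient.
#' @export
StatFilterParams <- function(m = 35, k = 1.0) {
  new("StatFilterParams", m = as.integer(m), k = as.numeric(k))
}

setMethod("show", "StatFilterParams", function(object) {
  cat(sprintf("StatFilterParams m = %d, k = %g\n", object@m, object@k))
})

#' Filtering report
#'
#' Point counts before/after a filtering stage and, for the statistical
#' filter, the mean and population standard deviation of the per-point mean
#' neighbour distance.
#'
#' @slot nBefore,nRemoved,nAfter point counts; nBefore = nRemoved + nAfter.
#' @slot mu,sigma mm; NA for filters that do not estimate them.
#' @export
setClass("FilterReport",
  representation(nBefore = "integer", nRemoved = "integer",
                 nAfter = "integer", mu = "numeric", sigma = "numeric"))

setValidity("FilterReport", function(object) {
  if (object@nBefore != object@nRemoved + object@nAfter)
    return("nBefore must equal nRemoved + nAfter")
  if (!is.na(object@sigma) && object@sigma < 0)
    return("sigma must be non-negative")
  TRUE
})

#' @rdname FilterReport-class
#' @param nBefore,nRemoved,nAfter counts.
#' @param mu,sigma mean-neighbour-distance statistics in mm (optional).
#' @export
FilterReport <- function(nBefore, nRemoved, nAfter, mu = NA_real_,
                         sigma = NA_real_) {
  new("FilterReport", nBefore = as.integer(nBefore),
      nRemoved = as.integer(nRemoved), nAfter = as.integer(nAfter),
      mu = as.numeric(mu), sigma = as.numeric(sigma))
}

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport %d -> %d points (%d removed)%s\n",
              object@nBefore, object@nAfter, object@nRemoved,
              if (!is.na(object@mu))
                sprintf("  mu = %.3f mm, sigma = %.3f mm",
                        object@mu, object@sigma) else ""))
})

## ---------------------------------------------------------------------------
## Rig geometry and fusion
## ---------------------------------------------------------------------------

#' Dual-camera rig geometry
#'
#' Camera-to-camera separation of the mirror-symmetric rig and the sign of
#' the Z translation used by the PSC fusion transform. The default baseline
#' of 1400 mm corresponds to two cameras each 700 mm from the pot centre.
#' The geometrically consistent sign under the positive-forward Z convention
#' is +1; -1 reproduces the literal printed form of the rig equations.
#'
#' @slot baseline camera separation along Z, mm (> 0).
#' @slot translationSign +1 or -1.
#' @export
setClass("RigGeometry",
  representation(baseline = "numeric", translationSign = "numeric"))

setValidity("RigGeometry", function(object) {
  if (!is.finite(object@baseline) || object@baseline <= 0)
    return("baseline must be positive")
  if (!object@translationSign %in% c(-1, 1))
    return("translationSign must be +1 or -1")
  TRUE
})

#' @rdname RigGeometry-class
#' @param baseline camera separation in mm.
#' @param translationSign +1 (geometrically consistent) or -1.
#' @export
RigGeometry <- function(baseline = 1400, translationSign = 1) {
  new("RigGeometry", baseline = as.numeric(baseline),
      translationSign = as.numeric(translationSign))
}

setMethod("show", "RigGeometry", function(object) {
  cat(sprintf("RigGeometry baseline = %g mm, translation sign = %+d\n",
              object@baseline, as.integer(object@translationSign)))
})

#' Fused dual-view model
#'
#' The union of the reference-view cloud and the transformed secondary-view
#' cloud, with a per-point provenance label.
#'
#' @slot cloud the fused \code{PointCloud}.
#' @slot provenance character vector, one source-camera label per point.
#' @export
setClass("FusedModel",
  representation(cloud = "PointCloud", provenance = "character"))

setValidity("FusedModel", function(object) {
  if (length(object@provenance) != nrow(object@cloud@coords))
    return("provenance must label every point")
  TRUE
})

setMethod("show", "FusedModel", function(object) {
  tab <- table(object@provenance)
  cat(sprintf("FusedModel with %d points (%s)\n", nrow(object@cloud@coords),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Traits
## ---------------------------------------------------------------------------

#' Plant trait set
#'
#' Axis-aligned bounding-box extents of a plant model: height (Y), width (X)
#' and length (Z) in mm, and their product as a volume in cubic centimetres.
#'
#' @slot height,width,length mm.
#' @slot volume cm^3; equals height * width * length / 1000 within 0.005.
#' @export
setClass("TraitSet",
  representation(height = "numeric", width = "numeric", length = "numeric",
                 volume = "numeric"))

setValidity("TraitSet", function(object) {
  v <- c(object@height, object@width, object@length, object@volume)
  if (any(!is.finite(v)) || any(v < 0))
    return("traits must be finite and non-negative")
  expected <- object@height * object@width * object@length / 1000
  if (abs(object@volume - expected) > 0.005 + 1e-9)
    return("volume must equal height*width*length/1000 cm^3 within 0.005")
  TRUE
})

#' @rdname TraitSet-class
#' @param height,width,length extents in mm.
#' @param volume cm^3; computed from the extents when omitted.
#' @export
TraitSet <- function(height, width, length, volume = NULL) {
  if (is.null(volume)) volume <- height * width * length / 1000
  new("TraitSet", height = as.numeric(height), width = as.numeric(width),
      length = as.numeric(length), volume = as.numeric(volume))
}

#' @describeIn TraitSet-class named numeric of the four traits.
#' @param x a \code{TraitSet}.
#' @export
traitValues <- function(x) {
  c(height = x@height, width = x@width, length = x@length, volume = x@volume)
}

setMethod("show", "TraitSet", function(object) {
  cat(sprintf(
    "TraitSet  H %.1f mm  W %.1f mm  L %.1f mm  V %.2f cm^3\n",
    object@height, object@width, object@length, object@volume))
})

## ---------------------------------------------------------------------------
## Synthetic rig specs
## ---------------------------------------------------------------------------

#' Procedural plant specification
#'
#' Parameters of the procedural potted-plant generator: a vertical stem
#' cylinder carrying upward-tilted elliptical leaf disks at sampled heights
#' and azimuths, plus a pot cylinder below the lens line rendered as
#' background clutter. Default dimensions emulate a flowering-stage potted
#' peanut (extents around 300 mm, under the rig's 400 mm region of
#' interest), and the default surface sampling is dense enough that a
#' rendered view is limited by the depth raster, yielding on the order of
#' 10^4 in-ROI points per view -- the point-count regime of the real rig.
#' The same seed always reproduces the same scene.
#'
#' @slot stemHeight,stemRadius stem cylinder size, mm.
#' @slot leafCount number of leaves.
#' @slot leafMajor,leafMinor leaf ellipse semi-axes, mm.
#' @slot attachLow,attachHigh leaf attachment range as fractions of stem
#'   height.
#' @slot azimuthRange leaf azimuth range in degrees (uniformly sampled).
#' @slot nPoints total number of plant surface points.
#' @slot potRadius,potHeight,potPoints pot clutter cylinder (below y = 0).
#' @slot seed RNG seed.
#' @export
setClass("PlantSpec",
  representation(stemHeight = "numeric", stemRadius = "numeric",
                 leafCount = "integer", leafMajor = "numeric",
                 leafMinor = "numeric", attachLow = "numeric",
                 attachHigh = "numeric", azimuthRange = "numeric",
                 nPoints = "integer", potRadius = "numeric",
                 potHeight = "numeric", potPoints = "integer",
                 seed = "integer"))

setValidity("PlantSpec", function(object) {
  pos <- c(object@stemHeight, object@stemRadius, object@leafMajor,
           object@leafMinor, object@potRadius, object@potHeight)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all dimensions must be positive")
  if (object@leafCount < 0L) return("leafCount must be >= 0")
  if (object@nPoints < 1L) return("nPoints must be >= 1")
  if (object@attachLow < 0 || object@attachHigh > 1 ||
      object@attachLow > object@attachHigh)
    return("attachment range must satisfy 0 <= low <= high <= 1")
  TRUE
})

#' @rdname PlantSpec-class
#' @param stemHeight,stemRadius,leafCount,leafMajor,leafMinor,attachLow,attachHigh,azimuthRange,nPoints,potRadius,potHeight,potPoints,seed
#'   see slots.
#' @export
PlantSpec <- function(stemHeight = 280, stemRadius = 5, leafCount = 22,
                      leafMajor = 80, leafMinor = 45, attachLow = 0.25,
                      attachHigh = 1, azimuthRange = c(0, 360),
                      nPoints = 70000, potRadius = 115, potHeight = 200,
                      potPoints = 8000, seed = 1) {
  new("PlantSpec", stemHeight = as.numeric(stemHeight),
      stemRadius = as.numeric(stemRadius), leafCount = as.integer(leafCount),
      leafMajor = as.numeric(leafMajor), leafMinor = as.numeric(leafMinor),
      attachLow = as.numeric(attachLow), attachHigh = as.numeric(attachHigh),
      azimuthRange = as.numeric(azimuthRange), nPoints = as.integer(nPoints),
      potRadius = as.numeric(potRadius), potHeight = as.numeric(potHeight),
      potPoints = as.integer(potPoints), seed = as.integer(seed))
}

#' Depth-noise specification
#'
#' A minimal Kinect-like corruption model for rendered depth images: zero-
#' mean Gaussian noise whose standard deviation grows with distance from the
#' image centre (the depth-edge effect), a sparse fraction of uniform outlier
#' depths, and a background plane painted into a sampled band of empty
#' pixels.
#'
#' @slot baseSd depth noise standard deviation at the image centre, mm.
#' @slot edgeMultiplier growth of the noise sd towards the image corner:
#'   sd = baseSd * (1 + edgeMultiplier * normalised radial distance).
#' @slot outlierFraction fraction of pixels replaced by uniform outliers.
#' @slot backgroundDepth background plane depth in mm.
#' @slot backgroundFill fraction of empty pixels painted with the background.
#' @slot seed RNG seed.
#' @export
setClass("NoiseSpec",
  representation(baseSd = "numeric", edgeMultiplier = "numeric",
                 outlierFraction = "numeric", backgroundDepth = "numeric",
                 backgroundFill = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (object@baseSd < 0) return("baseSd must be >= 0")
  if (object@edgeMultiplier < 0) return("edgeMultiplier must be >= 0")
  if (object@outlierFraction < 0 || object@outlierFraction > 1)
    return("outlierFraction must lie in [0, 1]")
  if (object@backgroundFill < 0 || object@backgroundFill > 1)
    return("backgroundFill must lie in [0, 1]")
  if (object@backgroundDepth < 0) return("backgroundDepth must be >= 0")
  TRUE
})

#' @rdname NoiseSpec-class
#' @param baseSd,edgeMultiplier,outlierFraction,backgroundDepth,backgroundFill,seed
#'   see slots.
#' @export
NoiseSpec <- function(baseSd = 2, edgeMultiplier = 2, outlierFraction = 0.002,
                      backgroundDepth = 1600, backgroundFill = 0.15,
                      seed = 1) {
  new("NoiseSpec", baseSd = as.numeric(baseSd),
      edgeMultiplier = as.numeric(edgeMultiplier),
      outlierFraction = as.numeric(outlierFraction),
      backgroundDepth = as.numeric(backgroundDepth),
      backgroundFill = as.numeric(backgroundFill), seed = as.integer(seed))
}

#' Synthetic scene with ground truth
#'
#' A procedural plant scene in the world frame (taken to coincide with the
#' reference camera's frame): plant surface points with per-point surface
#' labels and outward normals, clutter points (the pot), camera poses once a
#' capture has been simulated, and the exact bounding-box trait set of the
#' plant points.
#'
#' @slot points N x 3 plant surface points, world frame, mm.
#' @slot surface character length N: "stem" or "leaf".
#' @slot normals N x 3 unit outward normals ("leaf" surfaces are two-sided).
#' @slot twoSided logical length N; TRUE for thin two-sided surfaces.
#' @slot clutter M x 3 clutter points (pot), with \code{clutterNormals}.
#' @slot clutterNormals M x 3 unit normals of the clutter points.
#' @slot poses list of per-camera \code{RigidTransform}s (world -> camera).
#' @slot traits ground-truth \code{TraitSet} of the plant points.
#' @export
setClass("SceneTruth",
  representation(points = "matrix", surface = "character",
                 normals = "matrix", twoSided = "logical",
                 clutter = "matrix", clutterNormals = "matrix",
                 poses = "list", traits = "TraitSet"))

setValidity("SceneTruth", function(object) {
  n <- nrow(object@points)
  if (length(object@surface) != n || nrow(object@normals) != n ||
      length(object@twoSided) != n)
    return("surface, normals and twoSided must match the point count")
  if (nrow(object@clutter) != nrow(object@clutterNormals))
    return("clutterNormals must match clutter")
  TRUE
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth  %d plant points (%d leaf, %d stem), %d clutter\n",
              nrow(object@points), sum(object@surface == "leaf"),
              sum(object@surface == "stem"), nrow(object@clutter)))
  show(object@traits)
})

## ---------------------------------------------------------------------------
## ICP
## ---------------------------------------------------------------------------

#' ICP configuration
#'
#' @slot maxIterations iteration cap (>= 1).
#' @slot tolerance convergence threshold on the change of mean squared
#'   correspondence error, mm^2.
#' @slot maxCorrespondenceDistance correspondence gating distance, mm.
#' @slot init initial \code{RigidTransform} (identity by default).
#' @export
setClass("ICPConfig",
  representation(maxIterations = "integer", tolerance = "numeric",
                 maxCorrespondenceDistance = "numeric",
                 init = "RigidTransform"))

setValidity("ICPConfig", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@tolerance <= 0) return("tolerance must be positive")
  if (object@maxCorrespondenceDistance <= 0)
    return("maxCorrespondenceDistance must be positive")
  TRUE
})

#' @rdname ICPConfig-class
#' @param maxIterations,tolerance,maxCorrespondenceDistance,init see slots.
#' @export
ICPConfig <- function(maxIterations = 50, tolerance = 1e-6,
                      maxCorrespondenceDistance = 50,
                      init = RigidTransform()) {
  new("ICPConfig", maxIterations = as.integer(maxIterations),
      tolerance = as.numeric(tolerance),
      maxCorrespondenceDistance = as.numeric(maxCorrespondenceDistance),
      init = init)
}

#' ICP result
#'
#' @slot transform the final source-to-target \code{RigidTransform}.
#' @slot mseTrace per-iteration mean squared correspondence error, mm^2.
#' @slot converged logical.
#' @slot iterations iterations used.
#' @export
setClass("ICPResult",
  representation(transform = "RigidTransform", mseTrace = "numeric",
                 converged = "logical", iterations = "integer"))

setMethod("show", "ICPResult", function(object) {
  cat(sprintf(
    "ICPResult  %d iteration%s, %sconverged, final MSE %.4g mm^2\n",
    object@iterations, if (object@iterations == 1L) "" else "s",
    if (object@converged) "" else "not ",
    utils::tail(object@mseTrace, 1L)))
})
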