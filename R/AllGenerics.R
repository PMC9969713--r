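#' Accessors for pipeline objects
#'
#' Slot access for the core classes goes through these accessors.
#'
#' @param x a \code{PointCloud}, \code{FusedModel} or other pipeline object.
#' @return \code{nPoints} the point count; \code{pointCoords} the N x 3
#'   coordinate matrix (mm); \code{pointColors} the N x 3 RGB matrix (0 x 3
#'   when uncolored); \code{colorFlags} the per-point color-validity flags;
#'   \code{pixelOrigins} the N x 2 source-pixel matrix; \code{fusedCloud}
#'   and \code{provenance} the components of a \code{FusedModel}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))

#' @rdname accessors
#' @export
setGeneric("pointColors", function(x) standardGeneric("pointColors"))

#' @rdname accessors
#' @export
setGeneric("colorFlags", function(x) standardGeneric("colorFlags"))

#' @rdname accessors
#' @export
setGeneric("pixelOrigins", function(x) standardGeneric("pixelOrigins"))

#' @rdname accessors
#' @export
setGeneric("fusedCloud", function(x) standardGeneric("fusedCloud"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname accessors
setMethod("nPoints", "FusedModel", function(x) nrow(x@cloud@coords))

#' @rdname accessors
setMethod("pointCoords", "PointCloud", function(x) x@coords)

#' @rdname accessors
setMethod("pointColors", "PointCloud", function(x) x@colors)

#' @rdname accessors
setMethod("colorFlags", "PointCloud", function(x) x@colorValid)

#' @rdname accessors
setMethod("pixelOrigins", "PointCloud", function(x) x@pixels)

#' @rdname accessors
setMethod("fusedCloud", "FusedModel", function(x) x@cloud)

#' @rdname accessors
setMethod("provenance", "FusedModel", function(x) x@provenance)

#' Subset a point cloud by point index
#'
#' @param x a \code{PointCloud}.
#' @param i integer or logical index over points.
#' @param j,...,drop ignored.
#' @return a \code{PointCloud} with the selected points; colors, flags and
#'   pixel origins are carried through.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  PointCloud(
    x@coords[i, , drop = FALSE],
    colors = if (nrow(x@colors)) x@colors[i, , drop = FALSE],
    colorValid = if (length(x@colorValid)) x@colorValid[i],
    pixels = if (nrow(x@pixels)) x@pixels[i, , drop = FALSE]
  )
})
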