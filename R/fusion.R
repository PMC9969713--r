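## Correspondence-free fusion of the two opposed views (the PSC method):
## a fixed 180-degree rotation about Y followed by a baseline translation
## along Z maps the secondary camera's cloud into the reference frame.

#' Mirror rotation about the Y axis
#'
#' The 180-degree rotation that keeps Y unchanged:
#' \eqn{(x, y, z) \to (-x, y, -z)}. Applying it twice is the identity.
#'
#' @param p a length-3 vector or an N x 3 matrix, mm.
#' @return the rotated vector or matrix.
#' @examples
#' mirrorRotateY(c(1, 2, 3))
#' @export
mirrorRotateY <- function(p) {
  if (is.matrix(p)) {
    out <- p
    out[, 1L] <- -p[, 1L]
    out[, 3L] <- -p[, 3L]
    out
  } else c(-p[1L], p[2L], -p[3L])
}

#' Baseline translation along Z
#'
#' Moves a point along Z by \code{translationSign * baseline}; with the
#' default rig (baseline 1400 mm, sign +1) this shifts the mirrored
#' secondary cloud forward onto the reference camera's working volume.
#' Sign -1 reproduces the literal "minus 1400 mm" form.
#'
#' @param p a length-3 vector or an N x 3 matrix, mm.
#' @param rig a \code{\link{RigGeometry}}.
#' @return the translated vector or matrix.
#' @export
translateAlongZ <- function(p, rig = RigGeometry()) {
  stopifnot(is(rig, "RigGeometry"))
  dz <- rig@translationSign * rig@baseline
  if (is.matrix(p)) { p[, 3L] <- p[, 3L] + dz; p }
  else c(p[1L], p[2L], p[3L] + dz)
}

#' The PSC fusion transform as a rigid motion
#'
#' @param rig a \code{\link{RigGeometry}}.
#' @return the \code{\link{RigidTransform}} equivalent to
#'   \code{\link{mirrorRotateY}} followed by \code{\link{translateAlongZ}}.
#' @export
pscTransform <- function(rig = RigGeometry()) {
  RigidTransform(diag(c(-1, 1, -1)),
                 c(0, 0, rig@translationSign * rig@baseline))
}

#' Transform the secondary camera's cloud into the reference frame
#'
#' Applies the mirror rotation then the baseline translation to every point
#' (the single matrix-plus-offset form of the same map). Colors are
#' preserved; the motion is rigid, so all pairwise distances are too.
#'
#' @param cloud2 the secondary view's \code{\link{PointCloud}}.
#' @param rig a \code{\link{RigGeometry}}.
#' @return the transformed \code{PointCloud}, in the reference frame.
#' @export
transformSecondaryCloud <- function(cloud2, rig = RigGeometry()) {
  stopifnot(is(cloud2, "PointCloud"))
  validObject(rig)
  applyRigidTransform(cloud2, pscTransform(rig))
}

#' Fuse the two registered views into one model
#'
#' Direct splicing: the two clouds (already in the same frame) are
#' concatenated with per-point provenance labels. No deduplication and no
#' resampling are performed; overlapping regions stay duplicated.
#'
#' @param view1 the reference view's \code{\link{PointCloud}}.
#' @param view2Transformed the secondary view, already mapped into the
#'   reference frame (see \code{\link{transformSecondaryCloud}}).
#' @param labels provenance labels for the two views.
#' @return a \code{\link{FusedModel}}.
#' @export
fuseClouds <- function(view1, view2Transformed,
                       labels = c("camera1", "camera2")) {
  stopifnot(is(view1, "PointCloud"), is(view2Transformed, "PointCloud"))
  n1 <- nPoints(view1); n2 <- nPoints(view2Transformed)
  if (n1 + n2 == 0L)
    degenerateInputError("cannot fuse two empty clouds")
  hasCol <- nrow(view1@colors) > 0L || nrow(view2Transformed@colors) > 0L
  colorsOf <- function(cl, n) {
    if (nrow(cl@colors)) cl@colors else matrix(0L, n, 3L)
  }
  flagsOf <- function(cl, n) {
    if (length(cl@colorValid)) cl@colorValid else rep(FALSE, n)
  }
  cloud <- PointCloud(
    rbind(view1@coords, view2Transformed@coords),
    colors = if (hasCol) rbind(colorsOf(view1, n1),
                               colorsOf(view2Transformed, n2)),
    colorValid = if (hasCol) c(flagsOf(view1, n1),
                               flagsOf(view2Transformed, n2))
  )
  new("FusedModel", cloud = cloud,
      provenance = rep(labels, c(n1, n2)))
}
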