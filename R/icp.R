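## Point-to-point ICP: nearest-neighbour correspondences (kd-tree),
## closed-form SVD (Kabsch) rigid-transform estimation, and the
## alternating refinement loop. Serves as the registration baseline that
## the correspondence-free PSC fusion is compared against.

#' Nearest-neighbour correspondences between two clouds
#'
#' For each source point, its nearest target point within
#' \code{maxDist}; pairs beyond the gate are dropped. Registration is
#' impossible without corresponding points, so zero surviving pairs raise
#' a no-overlap error.
#'
#' @param source,target nonempty \code{\link{PointCloud}}s.
#' @param maxDist correspondence gating distance, mm.
#' @return a data frame with columns \code{source}, \code{target},
#'   \code{distance}.
#' @export
nearestCorrespondences <- function(source, target, maxDist = 50) {
  stopifnot(is(source, "PointCloud"), is(target, "PointCloud"))
  if (nPoints(source) == 0L || nPoints(target) == 0L)
    degenerateInputError("both clouds must be nonempty")
  nn <- RANN::nn2(target@coords, source@coords, k = 1L)
  keep <- which(nn$nn.dists[, 1L] <= maxDist)
  if (length(keep) == 0L)
    noOverlapError(sprintf(
      "no corresponding points within %g mm: the clouds do not overlap",
      maxDist))
  data.frame(source = keep, target = nn$nn.idx[keep, 1L],
             distance = nn$nn.dists[keep, 1L])
}

#' Least-squares rigid transform from matched point pairs
#'
#' The Kabsch/SVD closed form: centroids are subtracted, the rotation is
#' recovered from the SVD of the cross-covariance, and the determinant is
#' forced to +1 so a reflection can never be returned.
#'
#' @param sourcePoints,targetPoints matched N x 3 matrices (N >= 3,
#'   non-collinear).
#' @return the \code{\link{RigidTransform}} mapping source onto target in
#'   the least-squares sense.
#' @export
estimateRigidTransformSVD <- function(sourcePoints, targetPoints) {
  sourcePoints <- as.matrix(sourcePoints)
  targetPoints <- as.matrix(targetPoints)
  n <- nrow(sourcePoints)
  if (n < 3L || nrow(targetPoints) != n)
    degenerateInputError("need at least 3 matched pairs")
  cs <- colMeans(sourcePoints)
  ct <- colMeans(targetPoints)
  S <- sweep(sourcePoints, 2L, cs)
  T_ <- sweep(targetPoints, 2L, ct)
  H <- crossprod(S, T_)
  sv <- svd(H)
  spread <- svd(S, nu = 0, nv = 0)$d
  if (spread[2L] < 1e-9 * max(spread[1L], 1))
    degenerateInputError("matched points are collinear; rotation is not identifiable")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  RigidTransform(R, ct - as.vector(R %*% cs))
}

#' Register a source cloud onto a target cloud with ICP
#'
#' Alternates nearest-neighbour correspondence search and closed-form
#' rigid-transform estimation, starting from \code{cfg@init}, until the
#' change in mean squared correspondence error drops below the tolerance
#' or the iteration cap is reached. The MSE trace is recorded at every
#' correspondence step.
#'
#' @param source,target nonempty \code{\link{PointCloud}}s with overlap
#'   under the initial transform.
#' @param cfg an \code{\link{ICPConfig}}.
#' @return an \code{\link{ICPResult}} whose transform maps \code{source}
#'   into the target frame.
#' @export
icpRegister <- function(source, target, cfg = ICPConfig()) {
  stopifnot(is(source, "PointCloud"), is(target, "PointCloud"),
            is(cfg, "ICPConfig"))
  validObject(cfg)
  xf <- cfg@init
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg@maxIterations)) {
    iters <- it
    moved <- applyRigidTransform(source, xf)
    corr <- nearestCorrespondences(moved, target,
                                   cfg@maxCorrespondenceDistance)
    mse <- mean(corr$distance^2)
    if (length(trace) && abs(trace[length(trace)] - mse) < cfg@tolerance) {
      trace <- c(trace, mse)
      converged <- TRUE
      break
    }
    trace <- c(trace, mse)
    upd <- estimateRigidTransformSVD(moved@coords[corr$source, , drop = FALSE],
                                     target@coords[corr$target, , drop = FALSE])
    xf <- composeRigidTransforms(upd, xf)
  }
  new("ICPResult", transform = xf, mseTrace = trace,
      converged = converged, iterations = iters)
}
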