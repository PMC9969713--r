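## PassThrough ROI crop and statistical outlier removal, plus the
## coordinate-descent selection of the statistical filter's (m, k).

#' PassThrough region-of-interest filter
#'
#' Retains exactly the points with \code{x} in \code{(xMin, xMax)},
#' \code{y} in \code{(yMin, yMax)} and \code{z} in \code{(zMin, zMax)}
#' (open intervals: boundary points are removed). Everything outside the
#' region of interest is treated as background noise. Colors and pixel
#' origins are carried through; points are never moved or recolored.
#'
#' @param cloud a \code{\link{PointCloud}}.
#' @param roi \code{\link{ROIBounds}} in mm.
#' @return a list with elements \code{cloud} (the cropped
#'   \code{PointCloud}) and \code{report} (a \code{\link{FilterReport}}).
#' @examples
#' pc <- PointCloud(rbind(c(0, 200, 700), c(0, 200, 950)))
#' passthroughFilter(pc, ROIBounds())$report
#' @export
passthroughFilter <- function(cloud, roi = ROIBounds()) {
  stopifnot(is(cloud, "PointCloud"))
  if (!is(roi, "ROIBounds")) configurationError("'roi' must be an ROIBounds")
  validObject(roi)
  p <- cloud@coords
  keep <- p[, 1L] > roi@xMin & p[, 1L] < roi@xMax &
          p[, 2L] > roi@yMin & p[, 2L] < roi@yMax &
          p[, 3L] > roi@zMin & p[, 3L] < roi@zMax
  list(cloud = cloud[keep],
       report = FilterReport(nrow(p), sum(!keep), sum(keep)))
}

#' Mean distance to the m nearest neighbours
#'
#' For each point, the mean Euclidean distance to its \code{m} nearest
#' other points (the query point itself is excluded). \code{m} is capped at
#' N - 1 for small clouds.
#'
#' @param cloud a \code{\link{PointCloud}} with at least 2 points.
#' @param m neighbour count (>= 1).
#' @return numeric vector of per-point mean neighbour distances, mm.
#' @export
knnMeanDistances <- function(cloud, m) {
  stopifnot(is(cloud, "PointCloud"))
  n <- nrow(cloud@coords)
  if (n < 2L)
    degenerateInputError("need at least 2 points for neighbour distances")
  m <- min(as.integer(m), n - 1L)
  if (m < 1L) degenerateInputError("m must be >= 1")
  nn <- RANN::nn2(cloud@coords, cloud@coords, k = m + 1L)
  ## column 1 is the self-match (distance 0, or a coincident duplicate,
  ## which has the same distance multiset either way)
  rowMeans(nn$nn.dists[, -1L, drop = FALSE])
}

#' Statistical outlier filter
#'
#' Computes every point's mean distance \eqn{\bar d} to its \code{m} nearest
#' neighbours, the mean \eqn{\mu} and population standard deviation
#' \eqn{\sigma} of those distances over the input cloud, and keeps the
#' points with \eqn{\mu - k\sigma \le \bar d \le \mu + k\sigma} (closed
#' interval, so a perfectly regular cloud with \eqn{\sigma = 0} is kept in
#' full). \eqn{\mu} and \eqn{\sigma} are estimated once from the input and
#' never re-estimated from the survivors.
#'
#' Removal is two-sided by default ("not within the range" removes both
#' unusually sparse and unusually dense points); \code{tails = "upper"}
#' gives the conventional one-sided outlier removal.
#'
#' @param cloud a \code{\link{PointCloud}} with at least 2 points.
#' @param params \code{\link{StatFilterParams}} (defaults m = 35, k = 1.0).
#' @param tails \code{"two-sided"} (default) or \code{"upper"}.
#' @return a list with elements \code{cloud} and \code{report}; the report
#'   carries \eqn{\mu} and \eqn{\sigma} in mm.
#' @export
statisticalFilter <- function(cloud, params = StatFilterParams(),
                              tails = c("two-sided", "upper")) {
  stopifnot(is(cloud, "PointCloud"), is(params, "StatFilterParams"))
  validObject(params)
  tails <- match.arg(tails)
  dbar <- knnMeanDistances(cloud, params@m)
  mu <- mean(dbar)
  sigma <- sqrt(mean((dbar - mu)^2))    # population sd
  lo <- mu - params@k * sigma
  hi <- mu + params@k * sigma
  keep <- if (tails == "two-sided") dbar >= lo & dbar <= hi else dbar <= hi
  list(cloud = cloud[keep],
       report = FilterReport(length(dbar), sum(!keep), sum(keep),
                             mu = mu, sigma = sigma))
}

#' Select statistical-filter parameters by coordinate descent
#'
#' Two-pass selection of (m, k): the first pass holds \code{k} at
#' \code{kInit} and scans \code{mGrid}; the second holds the chosen \code{m}
#' and scans \code{kGrid}. The qualitative stopping rule -- stop before the
#' filtered structure visibly deteriorates -- is operationalised as
#' maximising the mean
#' synthetic accuracy of the traits extracted from the filtered clouds
#' against the supplied reference traits. Ties are broken toward the
#' candidate that removes more points (fewer points mean faster downstream
#' modeling).
#'
#' @param clouds list of \code{\link{PointCloud}}s.
#' @param referenceTraits list of ground-truth \code{\link{TraitSet}}s,
#'   aligned with \code{clouds}.
#' @param mGrid integer candidates for m.
#' @param kGrid numeric candidates for k.
#' @param kInit k held fixed during the m scan (default 1.0).
#' @param tails passed to \code{\link{statisticalFilter}}.
#' @return a list with \code{params} (the chosen
#'   \code{\link{StatFilterParams}}) and \code{table}, a data frame with one
#'   row per scanned candidate: pass, parameter, value, mean points removed,
#'   mean points remaining and mean synthetic accuracy.
#' @export
optimizeFilterParams <- function(clouds, referenceTraits, mGrid, kGrid,
                                 kInit = 1.0,
                                 tails = c("two-sided", "upper")) {
  tails <- match.arg(tails)
  if (length(clouds) == 0L || length(clouds) != length(referenceTraits))
    configurationError("clouds and referenceTraits must be nonempty and aligned")
  if (length(mGrid) == 0L || length(kGrid) == 0L)
    configurationError("parameter grids must be nonempty")

  score <- function(m, k) {
    accs <- rem <- kept <- numeric(length(clouds))
    for (i in seq_along(clouds)) {
      f <- statisticalFilter(clouds[[i]], StatFilterParams(m, k), tails)
      rem[i] <- f$report@nRemoved
      kept[i] <- f$report@nAfter
      accs[i] <- if (nPoints(f$cloud) > 0L)
        syntheticAccuracy(referenceTraits[[i]], computeTraits(f$cloud))
      else -Inf
    }
    c(removed = mean(rem), remaining = mean(kept), meanAcc = mean(accs))
  }
  best <- function(values, scores) {
    acc <- vapply(scores, `[[`, numeric(1), "meanAcc")
    rem <- vapply(scores, `[[`, numeric(1), "removed")
    top <- which(acc == max(acc))
    values[top[which.max(rem[top])]]    # tie: prefer more removal
  }

  mScores <- lapply(mGrid, function(m) score(m, kInit))
  mBest <- best(mGrid, mScores)
  kScores <- lapply(kGrid, function(k) score(mBest, k))
  kBest <- best(kGrid, kScores)

  tab <- rbind(
    data.frame(pass = 1L, parameter = "m", value = as.numeric(mGrid),
               t(vapply(mScores, identity, numeric(3)))),
    data.frame(pass = 2L, parameter = "k", value = as.numeric(kGrid),
               t(vapply(kScores, identity, numeric(3))))
  )
  rownames(tab) <- NULL
  list(params = StatFilterParams(mBest, kBest), table = tab)
}
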