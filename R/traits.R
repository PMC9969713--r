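## Bounding-box trait extraction and the per-trait / synthetic accuracy
## scores used to compare model-calculated traits with manual measurements.

#' Extract bounding-box traits from a point cloud
#'
#' Height is the Y extent, width the X extent and length the Z extent of
#' the cloud's axis-aligned bounding box (mm); volume is their product in
#' cubic centimetres.
#'
#' @param cloud a nonempty \code{\link{PointCloud}} or \code{FusedModel}.
#' @return a \code{\link{TraitSet}}.
#' @examples
#' computeTraits(PointCloud(rbind(c(0, 0, 0), c(175, 93, 124))))
#' @export
computeTraits <- function(cloud) {
  if (is(cloud, "FusedModel")) cloud <- cloud@cloud
  if (is.matrix(cloud)) cloud <- PointCloud(cloud)
  stopifnot(is(cloud, "PointCloud"))
  p <- cloud@coords
  if (nrow(p) == 0L)
    degenerateInputError("cannot compute traits of an empty cloud")
  TraitSet(height = max(p[, 2L]) - min(p[, 2L]),
           width = max(p[, 1L]) - min(p[, 1L]),
           length = max(p[, 3L]) - min(p[, 3L]))
}

#' Accuracy percentage of a calculated trait
#'
#' \deqn{AP = (1 - |M - C| / M) \times 100}
#' for measured value \eqn{M} and model-calculated value \eqn{C}. The value
#' is returned unrounded; it can exceed neither 100 nor be clamped below --
#' relative errors above 100\% give negative AP.
#'
#' @param measured nonzero measured value(s).
#' @param calculated calculated value(s).
#' @return accuracy percentage(s).
#' @examples
#' accuracyPercentage(101, 124)   # 77.23 when rounded to 2 dp
#' @export
accuracyPercentage <- function(measured, calculated) {
  if (any(measured == 0))
    undefinedRatioError("accuracy percentage is undefined for measured = 0")
  (1 - abs(measured - calculated) / measured) * 100
}

#' Synthetic accuracy of a reconstructed model
#'
#' The equal-weight mean of the four per-trait accuracy percentages
#' (height, width, length, volume).
#'
#' @param measured ground-truth \code{\link{TraitSet}}.
#' @param calculated model-derived \code{\link{TraitSet}}.
#' @return synthetic accuracy in percent (unrounded).
#' @export
syntheticAccuracy <- function(measured, calculated) {
  stopifnot(is(measured, "TraitSet"), is(calculated, "TraitSet"))
  m <- traitValues(measured)
  c_ <- traitValues(calculated)
  if (any(m == 0))
    undefinedRatioError("synthetic accuracy is undefined for a zero measured trait")
  mean(accuracyPercentage(m, c_))
}

#' Goodness of fit between measured and calculated trait values
#'
#' The coefficient of determination of the ordinary least-squares
#' regression of calculated on measured values (equivalently the squared
#' Pearson correlation). A through-origin variant is available for fits
#' constrained to pass through zero.
#'
#' @param measured,calculated numeric vectors of paired values (>= 3 pairs).
#' @param throughOrigin fit \code{calculated ~ 0 + measured} instead.
#' @return R squared.
#' @export
goodnessOfFit <- function(measured, calculated, throughOrigin = FALSE) {
  if (length(measured) < 3L || length(measured) != length(calculated))
    degenerateInputError("need at least 3 aligned pairs")
  if (stats::var(measured) == 0)
    degenerateInputError("measured values have zero variance")
  fit <- if (throughOrigin) stats::lm(calculated ~ 0 + measured)
         else stats::lm(calculated ~ measured)
  r2 <- summary(fit)$r.squared
  if (is.nan(r2)) 0 else r2    # constant response: no explained variance
}

## round half away from zero to `digits` decimals (the tables' convention;
## base round() ties to even)
.round2 <- function(x, digits = 2L) {
  s <- 10^digits
  trunc(x * s + 0.5 * sign(x)) / s
}
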