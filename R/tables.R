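## Bundled reference data: manually measured vs model-calculated traits of
## 20 potted peanut plants at three growth stages, and the accuracy/timing
## summary of the 12-group turntable comparison between ICP and PSC
## modeling. Values are transcribed as printed from the published study
## tables (dimensions mm, volumes cm^3, accuracies percent).

#' Bundled plant trait records
#'
#' Measured (\code{*_m}) and 3-D-model-calculated (\code{*_c}) height,
#' width, length (mm) and volume (cm^3) for 20 potted peanut plants at
#' each of three growth stages (60 records). These are the reference
#' records used by the evaluation examples and by the acceptance checks.
#'
#' @param stage \code{"all"} (default) or one of \code{"sprout"},
#'   \code{"seedling"}, \code{"flowering"}.
#' @return a data frame in the \code{\link{evaluateBatch}} input schema.
#' @examples
#' head(plantTraitRecords("sprout"))
#' @export
plantTraitRecords <- function(stage = c("all", "sprout", "seedling",
                                        "flowering")) {
  stage <- match.arg(stage)
  d <- utils::read.csv(system.file("extdata", "plant_traits.csv",
                                   package = "pscplant"))
  d$stage <- factor(d$stage, levels = c("sprout", "seedling", "flowering"))
  if (stage == "all") d else d[d$stage == stage, , drop = FALSE]
}

#' Bundled turntable comparison records
#'
#' Per-group model accuracies (percent) and modeling times (seconds) of
#' the 12-group turntable experiment comparing three-view ICP modeling
#' with two-view PSC modeling of one plant captured every 10 degrees.
#' Times are hardware-bound and informational only.
#'
#' @return a data frame with columns \code{group}, \code{time_icp_s},
#'   \code{time_psc_s}, \code{acc_icp}, \code{acc_psc}.
#' @examples
#' colMeans(turntableComparison()[, c("acc_icp", "acc_psc")])
#' @export
turntableComparison <- function() {
  utils::read.csv(system.file("extdata", "turntable_comparison.csv",
                              package = "pscplant"))
}
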