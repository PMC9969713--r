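## Batch evaluation of measured vs model-calculated traits: per-record
## accuracy percentages, per-stage and overall column means, and per-trait
## goodness of fit.

#' Batch evaluation report
#'
#' @slot records data frame with one row per (plant, stage) record: the
#'   measured and calculated traits, the four unrounded accuracy
#'   percentages (\code{ap_height} .. \code{ap_volume}) and their mean
#'   \code{acc}.
#' @slot stageMeans data frame of per-stage column means of the APs and
#'   Acc, rounded half-away-from-zero to 2 decimals.
#' @slot overallMeans named numeric of the grand column means, rounded to
#'   2 decimals.
#' @slot r2 named numeric: per-trait OLS R squared between measured and
#'   calculated values (unrounded).
#' @export
setClass("EvaluationReport",
  representation(records = "data.frame", stageMeans = "data.frame",
                 overallMeans = "numeric", r2 = "numeric"))

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport  %d records, %d stage%s\n",
              nrow(object@records), nrow(object@stageMeans),
              if (nrow(object@stageMeans) == 1L) "" else "s"))
  print(object@stageMeans, row.names = FALSE)
  cat("overall: ",
      paste(sprintf("%s %.2f", names(object@overallMeans),
                    object@overallMeans), collapse = "  "), "\n")
})

#' Evaluate a batch of measured/calculated trait records
#'
#' Takes one record per reconstructed plant: a plant id, a growth-stage
#' label, the manually measured traits and the model-calculated traits.
#' Computes every record's four accuracy percentages and synthetic
#' accuracy, then per-stage and overall column means (reported rounded
#' half-away-from-zero to 2 decimals, as in the published tables; record-
#' level values stay unrounded) and the per-trait goodness of fit.
#'
#' @param records a data frame with columns \code{plant}, \code{stage},
#'   \code{h_m}, \code{w_m}, \code{l_m}, \code{v_m}, \code{h_c},
#'   \code{w_c}, \code{l_c}, \code{v_c} (dimensions mm, volumes cm^3), or
#'   a path to a CSV file with those columns.
#' @return an \code{\link{EvaluationReport}}.
#' @examples
#' rep <- evaluateBatch(plantTraitRecords("sprout"))
#' rep@overallMeans[["acc"]]
#' @export
evaluateBatch <- function(records) {
  if (is.character(records)) records <- utils::read.csv(records)
  need <- c("plant", "stage", "h_m", "w_m", "l_m", "v_m",
            "h_c", "w_c", "l_c", "v_c")
  miss <- setdiff(need, names(records))
  if (length(miss))
    configurationError(paste("records is missing columns:",
                             paste(miss, collapse = ", ")))
  if (nrow(records) == 0L) configurationError("records is empty")
  key <- paste(records$plant, records$stage)
  if (anyDuplicated(key))
    validationError("duplicate (plant, stage) records")
  mcols <- c("h_m", "w_m", "l_m", "v_m")
  if (any(records[mcols] == 0))
    undefinedRatioError("measured trait values must be nonzero")

  out <- records[need]
  out$ap_height <- accuracyPercentage(records$h_m, records$h_c)
  out$ap_width  <- accuracyPercentage(records$w_m, records$w_c)
  out$ap_length <- accuracyPercentage(records$l_m, records$l_c)
  out$ap_volume <- accuracyPercentage(records$v_m, records$v_c)
  apcols <- c("ap_height", "ap_width", "ap_length", "ap_volume")
  out$acc <- rowMeans(out[apcols])

  stages <- unique(out$stage)
  stageMeans <- do.call(rbind, lapply(stages, function(s) {
    sub <- out[out$stage == s, c(apcols, "acc")]
    data.frame(stage = s, t(.round2(colMeans(sub))))
  }))
  overall <- .round2(colMeans(out[c(apcols, "acc")]))

  gof <- function(m, c_) {                # NA when the fit is degenerate
    tryCatch(goodnessOfFit(m, c_), degenerateInputError = function(e) NA_real_)
  }
  r2 <- c(height = gof(out$h_m, out$h_c), width = gof(out$w_m, out$w_c),
          length = gof(out$l_m, out$l_c), volume = gof(out$v_m, out$v_c))
  new("EvaluationReport", records = out, stageMeans = stageMeans,
      overallMeans = overall, r2 = r2)
}
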