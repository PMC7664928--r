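#' Fit the mean-GDD threshold baseline model
#'
#' The benchmark phenology model: the threshold for each phase rank is
#' the mean cumulative GDD of the training points observed in that
#' phase. Prediction is a simple interval lookup over those thresholds,
#' so the model is a monotone step function of GDD.
#'
#' Noisy data can yield thresholds that are not increasing in rank; the
#' interval semantics then break down, so the fitted sequence is
#' replaced by its running maximum over rank order (with a warning)
#' before prediction. The raw per-rank means are kept in the returned
#' object for inspection.
#'
#' @param gdd Numeric vector of cumulative GDD at the observation dates.
#' @param rank Integer phase ranks, same length.
#' @return An object of class `threshold_model`: per-rank raw thresholds,
#'   the monotonised thresholds used for prediction, and the ordered set
#'   of fitted ranks. Ranks absent from training are never predicted.
#' @examples
#' m <- fit_baseline(c(90, 110, 200, 290, 310), c(1, 1, 2, 3, 3))
#' m$thresholds$threshold  # 100 200 300
#' predict_baseline(m, c(50, 250, 1e6))  # 1 2 3
#' @export
fit_baseline <- function(gdd, rank) {
  if (length(gdd) == 0L) thermophen_stop("cannot fit baseline on an empty training set")
  if (length(gdd) != length(rank)) thermophen_stop("gdd and rank lengths differ")
  if (any(!is.finite(gdd))) thermophen_stop("non-finite GDD in training data")
  rank <- as.integer(rank)
  means <- tapply(gdd, rank, mean)
  ranks <- as.integer(names(means))
  ord <- order(ranks)
  ranks <- ranks[ord]
  theta <- as.numeric(means)[ord]
  effective <- cummax(theta)
  if (any(diff(theta) < 0)) {
    warning(sprintf(
      "non-monotone baseline thresholds at rank(s) %s; using running maximum",
      paste(ranks[which(diff(theta) < 0) + 1L], collapse = ", ")),
      call. = FALSE)
  }
  structure(list(
    thresholds = data.frame(rank = ranks, threshold = theta),
    effective = effective,
    ranks = ranks), class = "threshold_model")
}

#' Predict phase ranks from cumulative GDD
#'
#' Returns, for each GDD value, the largest fitted rank whose threshold
#' is `<=` the value and below the next rank's threshold. Values below
#' the smallest threshold map to the smallest fitted rank; values at or
#' above the largest threshold map to the largest. A value exactly equal
#' to the next phase's threshold belongs to that next phase.
#'
#' @param model A `threshold_model` from [fit_baseline()].
#' @param gdd Numeric vector of cumulative GDD.
#' @return Integer vector of predicted ranks, non-decreasing in `gdd`.
#' @export
predict_baseline <- function(model, gdd) {
  if (!inherits(model, "threshold_model")) thermophen_stop("not a threshold_model")
  if (any(!is.finite(gdd))) thermophen_stop("non-finite GDD in prediction input")
  model$ranks[pmax(1L, findInterval(gdd, model$effective))]
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Mean-GDD threshold baseline: %d fitted rank(s)\n",
              length(x$ranks)))
  print(x$thresholds, row.names = FALSE)
  invisible(x)
}

# fit/predict closure matching the resample_evaluate() contract; the
# baseline consumes exactly one GDD feature column.
baseline_fit_fun <- function(gdd_col) {
  force(gdd_col)
  function(train, test) {
    if (!gdd_col %in% names(train)) {
      thermophen_stop("baseline feature column '%s' not in table", gdd_col)
    }
    m <- fit_baseline(train[[gdd_col]], train$rank)
    predict_baseline(m, test[[gdd_col]])
  }
}
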