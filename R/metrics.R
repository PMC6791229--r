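#' Forecast accuracy statistics
#'
#' Computes the five standard accuracy statistics for a pairing of actual and
#' predicted values, with the signed error defined as `e = actual - predicted`
#' (so a model that over-predicts has negative mean error and mean percentage
#' error):
#'
#' * `ME`  — mean error, `mean(e)` (count units);
#' * `RMSE` — root-mean-squared error, `sqrt(mean(e^2))`;
#' * `MAE` — mean absolute error, `mean(|e|)`;
#' * `MPE` — mean percentage error, `100 * mean(e / actual)` (percent);
#' * `MAPE` — mean absolute percentage error, `100 * mean(|e| / actual)`.
#'
#' All points supplied are included in the means — in particular, training
#' reports for grey fits include the zero-error anchored first observation.
#'
#' @param actual numeric vector of positive observed values.
#' @param predicted numeric vector of predictions, same length.
#' @return A one-row data frame of class `accuracy_report` with columns
#'   `ME`, `RMSE`, `MAE`, `MPE`, `MAPE` and `n`.
#' @examples
#' accuracy(c(100, 200), c(110, 180))
#' @export
accuracy <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("'actual' and 'predicted' must have the same length", call. = FALSE)
  if (length(actual) < 1L) stop("empty input", call. = FALSE)
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop("'actual' values must be positive and finite", call. = FALSE)
  e <- actual - predicted
  structure(data.frame(ME = mean(e),
                       RMSE = sqrt(mean(e^2)),
                       MAE = mean(abs(e)),
                       MPE = 100 * mean(e / actual),
                       MAPE = 100 * mean(abs(e) / actual),
                       n = length(e)),
            class = c("accuracy_report", "data.frame"))
}

#' Round half away from zero
#'
#' Reporting-layer rounding used for the printed tables (fitted values to
#' integers, accuracy statistics to two decimals). R's `round()` rounds half
#' to even; the published tables round half up, so ties like `.5` go away
#' from zero here. Internal computations never round.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Accuracy table for grey fits
#'
#' One training and one testing row per fitted grey model: the training row
#' compares the restored fitted values with the training actuals (all
#' training points included), the testing row compares the out-of-sample
#' forecasts with the testing actuals.
#'
#' @param fits a `grey_fit_list` from [fit_all_grey()], trained on
#'   `split$train`.
#' @param split a `dataset_split` from [split_series()].
#' @param digits reporting rounding for the statistic columns (default 2
#'   decimals, half up); `NULL` leaves them unrounded.
#' @return A data frame with columns `label` (`<model>_<training|testing>`),
#'   `model`, `group` and the five statistics plus `n`.
#' @examples
#' sp <- split_series(china_occupational())
#' accuracy_table(fit_all_grey(sp$train), sp)
#' @export
accuracy_table <- function(fits, split, digits = 2) {
  stopifnot(inherits(fits, "grey_fit_list"), inherits(split, "dataset_split"))
  rows <- lapply(names(fits), function(m) {
    f <- fits[[m]]
    if (!identical(f$years, split$train$years))
      stop(sprintf("%s fit does not match the training years of 'split'", m),
           call. = FALSE)
    h <- length(split$test)
    rbind(cbind(model = m, group = "training",
                accuracy(split$train$values, f$fitted)),
          cbind(model = m, group = "testing",
                accuracy(split$test$values, unname(forecast(f, h)))))
  })
  out <- do.call(rbind, rows)
  out <- cbind(label = paste(out$model, out$group, sep = "_"), out)
  stat_cols <- c("ME", "RMSE", "MAE", "MPE", "MAPE")
  if (!is.null(digits))
    out[stat_cols] <- lapply(out[stat_cols], round_half_up, digits = digits)
  rownames(out) <- NULL
  out
}
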