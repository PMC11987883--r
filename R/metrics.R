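#' Regression metrics for remaining-time predictions
#'
#' Mean absolute error, root-mean-squared error (both in the units of the
#' labels, typically minutes) and the coefficient of determination
#' \eqn{R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2}. \eqn{R^2} can
#' be negative when predictions fit worse than the label mean; it is
#' undefined (returned as `NA` with a warning) when all labels are equal.
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @return A one-row tibble with columns `n`, `mae`, `rmse`, `r2`.
#' @export
#' @examples
#' regression_metrics(c(1, 1), c(0, 2))  # mae 1, rmse 1, r2 0
regression_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    fc_abort("`predictions` and `labels` must have equal non-zero length.")
  }
  if (!all(is.finite(predictions)) || !all(is.finite(labels))) {
    fc_abort("metrics require finite predictions and labels.")
  }
  err <- predictions - labels
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  ss_tot <- sum((labels - mean(labels))^2)
  r2 <- if (ss_tot == 0) {
    warn("all labels are equal: R^2 is undefined and returned as NA.",
         class = "farrowcast_r2_undefined")
    NA_real_
  } else {
    1 - sum(err^2) / ss_tot
  }
  tibble::tibble(n = length(labels), mae = mae, rmse = rmse, r2 = r2)
}
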