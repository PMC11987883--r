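#' Pearson correlation between two activity series
#'
#' @param x,y Equal-length numeric vectors of length at least 2; neither may
#'   be constant (the correlation is undefined there).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    fc_abort("`x` and `y` must have equal length >= 2.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    fc_abort("correlation is undefined for a constant series.",
             class = "farrowcast_constant_series")
  }
  cor(x, y)
}

#' Pairwise activity-correlation matrix for a cohort
#'
#' Computes the Pearson correlation between every pair of sows' activity
#' series (aligned on `minutes_to_onset`).
#'
#' @param cohort Long tibble with columns `sow_id`, `minutes_to_onset`,
#'   `activity`; all sows must share the same time grid.
#' @return A symmetric correlation matrix with unit diagonal, sows in
#'   column/row-name order.
#' @export
activity_pcc <- function(cohort) {
  need <- c("sow_id", "minutes_to_onset", "activity")
  if (!all(need %in% names(cohort))) {
    fc_abort(sprintf("`cohort` must have columns %s.", paste(need, collapse = ", ")))
  }
  wide <- cohort |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "sow_id", values_from = "activity") |>
    dplyr::arrange(dplyr::desc(.data$minutes_to_onset))
  m <- as.matrix(wide[, setdiff(names(wide), "minutes_to_onset")])
  if (anyNA(m)) fc_abort("sows are not on a common time grid (missing values).")
  constant <- apply(m, 2, sd) == 0
  if (any(constant)) {
    fc_abort(sprintf("constant activity series: %s.",
                     paste(colnames(m)[constant], collapse = ", ")),
             class = "farrowcast_constant_series")
  }
  cor(m)
}

#' Average activity correlation coefficient per subject
#'
#' For each subject, the mean Pearson correlation with the other subjects.
#' By default the mean runs over the `N - 1` off-diagonal entries of the
#' subject's row ("the other sows"); `denominator = "all"` divides by `N`
#' instead, i.e. includes the unit self-correlation in the count.
#'
#' @param pcc_matrix Square symmetric correlation matrix with unit diagonal.
#' @param denominator `"others"` (divide by N-1, default) or `"all"`
#'   (divide by N).
#' @return A tibble with columns `sow_id` and `aacc`.
#' @export
#' @examples
#' m <- diag(3); m[upper.tri(m)] <- m[lower.tri(m)] <- c(0.5, 0.5, 1)
#' aacc(m)
aacc <- function(pcc_matrix, denominator = c("others", "all")) {
  denominator <- match.arg(denominator)
  m <- as.matrix(pcc_matrix)
  n <- nrow(m)
  if (n != ncol(m)) fc_abort("`pcc_matrix` must be square.")
  if (n < 2L) fc_abort("need at least two subjects.")
  if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-8) {
    fc_abort("`pcc_matrix` must be symmetric with unit diagonal.")
  }
  off_sum <- rowSums(m) - diag(m)
  val <- switch(denominator, others = off_sum / (n - 1), all = off_sum / n)
  ids <- rownames(m) %||% sprintf("sow_%02d", seq_len(n))
  tibble::tibble(sow_id = ids, aacc = unname(val))
}

#' Seasonal-trend decomposition of an activity series
#'
#' Additive STL (seasonal-trend decomposition using loess) of a
#' 5-min-resolution activity series with a diurnal period; the retained
#' trend component isolates the pre-farrowing activity rise from the 24-h
#' rhythm. Components satisfy `trend + seasonal + remainder == value`
#' exactly.
#'
#' @param values Numeric series; length must be at least two periods.
#' @param period Seasonal period in points (288 = 24 h at 5-min steps).
#' @param s_window Seasonal loess window, per [stats::stl()]; the default
#'   `"periodic"` fits one fixed diurnal profile.
#' @param t_window Optional trend loess window (points); `NULL` uses the
#'   `stl` default for the period.
#' @return A tibble with columns `point_index`, `value`, `trend`,
#'   `seasonal`, `remainder`.
#' @export
stl_trend <- function(values, period = 288L, s_window = "periodic",
                      t_window = NULL) {
  period <- check_count(period, "period", min = 2L)
  if (!is.numeric(values) || length(values) < 2L * period) {
    fc_abort(sprintf("series must contain at least 2 periods (%d points).",
                     2L * period))
  }
  x <- stats::ts(values, frequency = period)
  fit <- if (is.null(t_window)) {
    stats::stl(x, s.window = s_window)
  } else {
    stats::stl(x, s.window = s_window, t.window = t_window)
  }
  comp <- fit$time.series
  tibble::tibble(
    point_index = seq_along(values),
    value = as.numeric(values),
    trend = as.numeric(comp[, "trend"]),
    seasonal = as.numeric(comp[, "seasonal"]),
    remainder = as.numeric(comp[, "remainder"])
  )
}

#' Daily activity-distribution statistics counted back from onset
#'
#' Splits a pre-onset activity series into consecutive 24-h blocks counted
#' backward from farrowing onset (day 0 = the final block) and reports the
#' distribution summary used for box plots: mean, min, max, quartiles
#' (linear interpolation between order statistics, `stats::quantile`
#' type 7) and SD.
#'
#' @param values Numeric series whose last point falls at onset.
#' @param block_points Points per day block (288 = 24 h); the series length
#'   must be a positive multiple of it.
#' @return A tibble with one row per day, most recent (`day == 0`) first.
#' @export
daily_stats <- function(values, block_points = 288L) {
  block_points <- check_count(block_points, "block_points", min = 1L)
  n <- length(values)
  if (n == 0L || n %% block_points != 0L) {
    fc_abort(sprintf("series length %d is not a positive multiple of %d.",
                     n, block_points))
  }
  n_days <- n %/% block_points
  purrr::map_dfr(seq_len(n_days) - 1L, function(day) {
    block <- values[(n - (day + 1L) * block_points + 1L):(n - day * block_points)]
    q <- quantile(block, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(day = day, mean = mean(block), min = min(block),
                   max = max(block), q1 = q[1], q2 = q[2], q3 = q[3],
                   sd = sd(block), n = length(block))
  })
}

#' Interval-wise prediction report
#'
#' Bins prediction records by their remaining-time label into consecutive
#' pre-onset intervals (default 30-24, 24-18, 18-12, 12-6, 6-0 hours) and
#' computes [regression_metrics()] within each bin. Empty bins are kept and
#' flagged rather than dropped.
#'
#' @param predictions Tibble with columns `label` (minutes to onset) and
#'   `prediction` (predicted minutes); extra columns are ignored.
#' @param breaks_hours Decreasing vector of interval edges in hours before
#'   onset; bin `k` covers labels in `[lo, hi)` minutes except the interval
#'   nearest 30 h, which includes its upper edge.
#' @return A tibble of class `interval_report` with columns `interval`,
#'   `from_min`, `to_min`, `n`, `mae`, `rmse`, `r2`, `empty`.
#' @export
interval_report <- function(predictions, breaks_hours = c(30, 24, 18, 12, 6, 0)) {
  need <- c("label", "prediction")
  if (!all(need %in% names(predictions))) {
    fc_abort("`predictions` must have columns `label` and `prediction`.")
  }
  if (length(breaks_hours) < 2L || any(diff(breaks_hours) >= 0)) {
    fc_abort("`breaks_hours` must be strictly decreasing.")
  }
  edges_min <- breaks_hours * 60
  k <- length(edges_min) - 1L
  rows <- purrr::map_dfr(seq_len(k), function(i) {
    hi <- edges_min[i]; lo <- edges_min[i + 1L]
    sel <- predictions$label >= lo & (predictions$label < hi |
                                        (i == 1L & predictions$label == hi))
    sub <- predictions[sel, , drop = FALSE]
    base <- tibble::tibble(
      interval = sprintf("%g-%g h", breaks_hours[i], breaks_hours[i + 1L]),
      from_min = hi, to_min = lo
    )
    if (nrow(sub) == 0L) {
      dplyr::bind_cols(base, tibble::tibble(n = 0L, mae = NA_real_,
                                            rmse = NA_real_, r2 = NA_real_,
                                            empty = TRUE))
    } else {
      met <- regression_metrics(sub$prediction, sub$label)
      dplyr::bind_cols(base, met, tibble::tibble(empty = FALSE))
    }
  })
  class(rows) <- c("interval_report", class(rows))
  rows
}

#' Return-on-investment calculator for a farrowing-prediction system
#'
#' Net benefit comprises reduced stillbirth losses (`delta_piglets x
#' piglet_value`) and labor savings (`delta_labor_hours x hourly_wage`);
#' implementation cost combines equipment and operational cost either as
#' their sum (default, the standard accounting reading) or their product.
#' `roi_pct = (benefit - cost) / cost * 100`.
#'
#' @param delta_piglets Piglets saved per sow.
#' @param piglet_value Market value per piglet (currency units).
#' @param delta_labor_hours Labor hours saved per sow.
#' @param hourly_wage Hourly wage of farm personnel.
#' @param equipment_cost,operational_cost Implementation cost components.
#' @param cost_combine `"sum"` or `"product"`.
#' @return A one-row tibble with `b_piglets`, `b_labor`, `total_cost`,
#'   `roi_pct`.
#' @export
#' @examples
#' roi_calc(1, 100, 0, 20, 25, 25)  # ROI 100%
roi_calc <- function(delta_piglets, piglet_value, delta_labor_hours,
                     hourly_wage, equipment_cost, operational_cost,
                     cost_combine = c("sum", "product")) {
  cost_combine <- match.arg(cost_combine)
  for (nm in c("delta_piglets", "piglet_value", "delta_labor_hours",
               "hourly_wage", "equipment_cost", "operational_cost")) {
    check_scalar_number(get(nm), nm, min = 0)
  }
  b_p <- delta_piglets * piglet_value
  b_l <- delta_labor_hours * hourly_wage
  c_total <- switch(cost_combine,
                    sum = equipment_cost + operational_cost,
                    product = equipment_cost * operational_cost)
  if (c_total <= 0) {
    fc_abort("total implementation cost must be positive.")
  }
  tibble::tibble(b_piglets = b_p, b_labor = b_l, total_cost = c_total,
                 roi_pct = (b_p + b_l - c_total) / c_total * 100)
}
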