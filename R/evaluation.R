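# Fit-quality metrics: median squared deviation (the study's headline metric,
# m^2 s^-2), mean squared error (the GA objective), and the r squared of the
# observed-versus-predicted ordinary least-squares line.

#' Median squared deviation
#'
#' Median of the squared differences between observed and predicted settling
#' velocities (m^2 s^-2). For an even number of residuals the median is the
#' mean of the two central order statistics.
#'
#' @param observed,predicted Numeric vectors of equal length (m s^-1).
#' @return MSD, m^2 s^-2.
#' @examples
#' median_squared_deviation(c(1, 2, 3), c(0, 0, 0))
#' @export
median_squared_deviation <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_validity("`observed` and `predicted` must have equal length")
  }
  if (length(observed) == 0) abort_validity("empty input")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(c(observed, predicted)))) {
    abort_validity("inputs must be finite")
  }
  median((observed - predicted)^2)
}

#' r squared of the observed-versus-predicted line
#'
#' Coefficient of determination of the ordinary least-squares regression of
#' observed on predicted velocity.
#'
#' @param observed,predicted Numeric vectors, length >= 3; `predicted` must
#'   not be constant.
#' @return r squared in \[0, 1\].
#' @export
observed_predicted_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_validity("`observed` and `predicted` must have equal length")
  }
  if (length(observed) < 3) abort_validity("need at least 3 pairs")
  if (var(predicted) == 0) abort_validity("`predicted` is constant")
  # a perfect fit trips summary.lm's reliability warning; r.squared is exact
  suppressWarnings(summary(lm(observed ~ predicted))$r.squared)
}

#' Aggregate replicate velocities per specimen
#'
#' Collapses replicate settling measurements to one central value per
#' specimen: the mean with the range as dispersion (the convention used when
#' fitting), or the median with type-7 quartiles.
#'
#' @param data Data frame with columns `specimen_id` and `omega` (one row per
#'   replicate). Rows with `NA` omega (floating specimens) are dropped.
#' @param statistic `"mean"` or `"median"`.
#' @return A tibble with one row per specimen: `specimen_id`, `omega`, `n_rep`
#'   and dispersion columns (`omega_lo`, `omega_hi`). Carries `rho_sw`, `nu`,
#'   `g` columns through (per-specimen means) when present.
#' @export
aggregate_replicates <- function(data, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  data <- as_tibble(data)
  if (!all(c("specimen_id", "omega") %in% names(data))) {
    abort_validity("`data` must have specimen_id and omega columns")
  }
  data <- data |> filter(!is.na(.data$omega))
  if (nrow(data) == 0) abort_validity("no replicate velocities to aggregate")
  extra <- intersect(c("rho_sw", "nu", "g"), names(data))
  central <- if (statistic == "mean") mean else median
  lo_fun <- if (statistic == "mean") min else
    function(x) quantile(x, 0.25, type = 7, names = FALSE)
  hi_fun <- if (statistic == "mean") max else
    function(x) quantile(x, 0.75, type = 7, names = FALSE)
  data |>
    group_by(.data$specimen_id) |>
    summarise(
      across(all_of(extra), mean),
      n_rep = dplyr::n(),
      omega_lo = lo_fun(.data$omega),
      omega_hi = hi_fun(.data$omega),
      omega = central(.data$omega),
      .groups = "drop"
    )
}

#' Evaluation report for one prediction set
#'
#' Pairs observed and predicted velocities and computes the study's metrics:
#' MSD, MSE (the optimiser's objective, reported alongside for comparison)
#' and the observed~predicted r squared.
#'
#' @param data Data frame with columns `specimen_id`, `omega` (observed) and
#'   `omega_pred`; rows with `NA` predictions (out-of-domain) are dropped with
#'   a warning.
#' @param group Label for the report (e.g. "modeling", "testing", "plastics").
#' @return A one-row tibble: `group`, `n`, `msd`, `mse`, `r_squared`, plus a
#'   `residuals` list-column of per-specimen observed minus predicted values.
#' @export
evaluate_predictions <- function(data, group = "all") {
  data <- as_tibble(data)
  need <- c("specimen_id", "omega", "omega_pred")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_validity(paste0("missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
  }
  dropped <- sum(is.na(data$omega_pred))
  if (dropped > 0) {
    warning(sprintf("%d specimen(s) without a valid prediction dropped",
                    dropped), call. = FALSE)
    data <- data |> filter(!is.na(.data$omega_pred))
  }
  if (nrow(data) == 0) abort_validity("no evaluable predictions")
  res <- data$omega - data$omega_pred
  tibble::tibble(
    group = group,
    n = nrow(data),
    msd = median(res^2),
    mse = mean(res^2),
    r_squared = if (nrow(data) >= 3 && var(data$omega_pred) > 0)
      observed_predicted_r2(data$omega, data$omega_pred) else NA_real_,
    residuals = list(setNames(res, data$specimen_id))
  )
}

#' Observed-versus-predicted scatter plot
#'
#' @param data Data frame with `omega`, `omega_pred` and optionally a `group`
#'   column.
#' @return A ggplot object with the 1:1 line and the least-squares fit.
#' @export
plot_observed_predicted <- function(data) {
  data <- as_tibble(data)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(.data$omega_pred, .data$omega)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = expression("predicted" ~ omega ~ (m ~ s^-1)),
                  y = expression("observed" ~ omega ~ (m ~ s^-1)))
  if ("group" %in% names(data)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}
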