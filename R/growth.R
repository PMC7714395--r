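# Endpoint growth summaries and the bootstrap CI for the growth effect of
# expressing a full CCM. The resampling unit is the biological replicate
# curve: replicate trajectories are exchangeable, individual time points
# within a curve are not.

#' Apply dilution correction to OD readings
#'
#' Turbid cultures are read in five- or tenfold dilution to stay in the
#' spectrophotometer's linear regime; when a `dilution` column is present the
#' reading is multiplied by it, otherwise the table is returned unchanged.
#'
#' @param curves growth table with at least an `od600` column.
#' @return The table with corrected `od600` and no `dilution` column.
#' @export
correct_od_dilution <- function(curves) {
  if (!"od600" %in% names(curves)) stop("growth table needs an 'od600' column")
  if ("dilution" %in% names(curves)) {
    curves$od600 <- curves$od600 * curves$dilution
    curves$dilution <- NULL
  }
  tibble::as_tibble(curves)
}

#' Endpoint mean with a t confidence interval
#'
#' `mean +/- t_{n-1, 1-(1-level)/2} * SE`, the standard error-bar summary for
#' replicate endpoint densities.
#'
#' @param values numeric vector of endpoint ODs, `n >= 2`.
#' @param level confidence level.
#' @return A one-row tibble: `n`, `mean`, `lo`, `hi`, `level`.
#' @export
endpoint_summary <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 replicates for a confidence interval")
  stopifnot(level > 0, level < 1)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  tibble::tibble(n = n, mean = m, lo = m - tcrit * se, hi = m + tcrit * se,
                 level = level)
}

.check_curves <- function(curves) {
  req <- c("arm", "replicate", "time_hr", "od600")
  if (!all(req %in% names(curves))) {
    stop("growth table needs columns: ", paste(req, collapse = ", "))
  }
  invisible(curves)
}

# OD at t_eval for each replicate of one arm, linear interpolation
.od_at_time <- function(curves, t_eval) {
  curves |>
    dplyr::group_by(.data$arm, .data$replicate) |>
    dplyr::arrange(.data$time_hr, .by_group = TRUE) |>
    dplyr::summarise(od = {
      if (dplyr::n() < 2) stop("each replicate curve needs >= 2 time points")
      if (is.unsorted(.data$time_hr, strictly = TRUE)) {
        stop("times must be strictly increasing within a replicate")
      }
      if (t_eval < min(.data$time_hr) || t_eval > max(.data$time_hr)) {
        stop("t_eval = ", t_eval, " outside the span of replicate '",
             .data$replicate[1], "'")
      }
      stats::approx(.data$time_hr, .data$od600, xout = t_eval)$y
    }, .groups = "drop")
}

#' Growth effect at an evaluation time
#'
#' Mean experiment OD minus mean control OD at `t_eval`, with linear
#' interpolation between sampled time points within each replicate curve.
#'
#' @param curves growth table: `arm` (`"experiment"`/`"control"`),
#'   `replicate`, `time_hr`, `od600`.
#' @param t_eval evaluation time (h); must lie within every curve's span.
#' @return The OD difference (a single number).
#' @export
effect_at_time <- function(curves, t_eval) {
  .check_curves(curves)
  od <- .od_at_time(curves, t_eval)
  arms <- split(od$od, od$arm)
  if (is.null(arms$experiment) || is.null(arms$control)) {
    stop("growth table must contain both 'experiment' and 'control' arms")
  }
  mean(arms$experiment) - mean(arms$control)
}

#' Bootstrap confidence interval for the growth effect
#'
#' Resamples replicate curves with replacement within each arm, recomputes
#' the effect at `t_eval` for each resample, and reports the percentile
#' interval. Output is identical for identical inputs and seed.
#'
#' @inheritParams effect_at_time
#' @param level confidence level (0.999 reproduces a 99.9% interval).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @return An object of class `bootstrap_ci`: `effect` (observed), `lo`,
#'   `hi`, `level`, `n_boot`, `seed`, `n_experiment`, `n_control`.
#' @export
bootstrap_effect_ci <- function(curves, t_eval, level = 0.999,
                                n_boot = 10000, seed = 1) {
  .check_curves(curves)
  stopifnot(level > 0, level < 1, n_boot >= 1)
  od <- .od_at_time(curves, t_eval)
  arms <- split(od$od, od$arm)
  e <- arms$experiment
  ctl <- arms$control
  if (is.null(e) || is.null(ctl) || length(e) < 1 || length(ctl) < 1) {
    stop("both arms must contain at least one replicate")
  }
  effect <- mean(e) - mean(ctl)
  draws <- withr::with_seed(as.integer(seed), {
    boot_e <- matrix(sample(e, length(e) * n_boot, replace = TRUE),
                     nrow = n_boot)
    boot_c <- matrix(sample(ctl, length(ctl) * n_boot, replace = TRUE),
                     nrow = n_boot)
    rowMeans(boot_e) - rowMeans(boot_c)
  })
  alpha <- 1 - level
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(effect = effect, lo = q[1], hi = q[2], level = level,
         n_boot = n_boot, seed = as.integer(seed),
         n_experiment = length(e), n_control = length(ctl),
         draws = draws),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat("<bootstrap_ci> effect = ", format(x$effect, digits = 4), " OD, ",
      100 * x$level, "% CI [", format(x$lo, digits = 4), ", ",
      format(x$hi, digits = 4), "]  (", x$n_boot, " resamples, seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' @rdname bootstrap_effect_ci
#' @param x a `bootstrap_ci`.
#' @param ... unused.
#' @export
tidy.bootstrap_ci <- function(x, ...) {
  tibble::tibble(effect = x$effect, lo = x$lo, hi = x$hi, level = x$level)
}

#' @rdname bootstrap_effect_ci
#' @export
glance.bootstrap_ci <- function(x, ...) {
  tibble::tibble(effect = x$effect, lo = x$lo, hi = x$hi, level = x$level,
                 n_boot = x$n_boot, seed = x$seed,
                 n_experiment = x$n_experiment, n_control = x$n_control)
}

#' Plot replicate growth curves by arm
#'
#' @param curves growth table (`arm`, `replicate`, `time_hr`, `od600`).
#' @param t_eval optional evaluation time drawn as a vertical line.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(curves, t_eval = NULL) {
  .check_curves(curves)
  p <- ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$time_hr, y = .data$od600, colour = .data$arm,
                 group = interaction(.data$arm, .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (h)", y = "OD600", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(t_eval)) {
    p <- p + ggplot2::geom_vline(xintercept = t_eval, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}
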