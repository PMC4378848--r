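#' Extract polymerization kinetics metrics from a turbidity trace
#'
#' Computes the four standard turbidity metrics of collagen fibrillogenesis
#' from an absorbance-vs-time trace:
#' * `delta_abs` -- total change in absorbance, plateau minus initial level
#'   (window means of the last and first 5% of samples);
#' * `t_half_s` -- half-time, the first time the (lightly smoothed) trace
#'   crosses initial + delta/2, located by linear interpolation between
#'   samples;
#' * `rate_au_per_s` -- polymerization rate, the slope of the smoothed trace
#'   at the half-time (local linear fit over the smoothing window);
#' * `lag_time_s` -- lag time, the intercept of the tangent line through
#'   (t_half, initial + delta/2) with slope `rate` and the initial absorbance
#'   level: `t_half - (delta/2)/rate`.
#'
#' A trace that has not plateaued (final-window slope still a substantial
#' fraction of the total rise) is flagged `plateaued = FALSE` with a warning
#' unless `require_plateau = FALSE`. A flat trace (no signal) or a
#' non-positive rate yields `valid = FALSE` with the reason recorded.
#'
#' @param trace data frame with columns `time_s` (monotone increasing,
#'   near-uniform sampling, >= 10 samples) and `absorbance` (AU).
#' @param smoothing_window centered moving-average window (samples, odd;
#'   default 11) used to stabilize the derivative.
#' @param require_plateau if `TRUE` (default) a non-plateaued trace triggers
#'   a warning; metrics are still returned.
#' @param signal_threshold minimum `delta_abs` (AU) regarded as a
#'   polymerization signal; below it the result is invalid with reason
#'   `"no polymerization signal"`.
#'
#' @return One-row tibble: `delta_abs`, `t_half_s`, `rate_au_per_s`,
#'   `lag_time_s`, `valid`, `reason`, `plateaued`.
#' @examples
#' tr <- sim_turbidity_trace(noise_sd = 0)
#' extract_kinetics(tr)
#' @export
extract_kinetics <- function(trace, smoothing_window = 11,
                             require_plateau = TRUE,
                             signal_threshold = 1e-6) {
  trace <- as_tibble(trace)
  if (!all(c("time_s", "absorbance") %in% names(trace)))
    stopf("`trace` must have columns `time_s` and `absorbance`")
  t <- trace$time_s
  a <- trace$absorbance
  n <- length(t)
  if (n < 10) stopf("trace must have >= 10 samples (got %d)", n)
  if (any(diff(t) <= 0)) stopf("`time_s` must be strictly increasing")
  dts <- diff(t)
  if (max(dts) > 1.5 * median(dts))
    warnf("sampling interval is not uniform (max/median dt = %.2f)",
          max(dts) / median(dts))

  nw <- max(3L, ceiling(0.05 * n))  # 5% end windows for baseline/plateau
  baseline <- mean(head(a, nw))
  plateau <- mean(tail(a, nw))
  delta <- plateau - baseline

  invalid <- function(reason) tibble(
    delta_abs = max(delta, 0), t_half_s = NA_real_, rate_au_per_s = NA_real_,
    lag_time_s = NA_real_, valid = FALSE, reason = reason, plateaued = NA
  )
  if (delta <= signal_threshold) return(invalid("no polymerization signal"))

  sm <- moving_average(a, smoothing_window)

  # plateau check: the residual rise expected over another end-window span
  # must be small relative to the total signal
  end_t <- tail(t, nw)
  end_fit <- ols_line(end_t, tail(sm, nw))
  plateaued <- abs(end_fit$slope) * (max(end_t) - min(end_t)) < 0.05 * delta
  if (!plateaued && require_plateau)
    warnf("trace does not appear to have plateaued; metrics may be biased")

  level <- baseline + delta / 2
  above <- sm >= level
  ix <- which(above & !c(FALSE, head(above, -1)))  # upward crossings
  ix <- ix[ix > 1]
  t_half <- if (length(ix)) {
    i <- ix[1]  # earliest crossing
    t[i - 1] + (level - sm[i - 1]) / (sm[i] - sm[i - 1]) * (t[i] - t[i - 1])
  } else if (above[1]) t[1] else NA_real_
  if (!is.finite(t_half)) return(invalid("no half-max crossing"))

  # rate: local linear fit to the smoothed trace centered on t_half
  h <- max(1L, (as.integer(smoothing_window) - 1L) %/% 2L)
  ic <- which.min(abs(t - t_half))
  win <- max(1L, ic - h):min(n, ic + h)
  rate <- ols_line(t[win], sm[win])$slope
  if (!is.finite(rate) || rate <= 0)
    return(invalid("non-positive rate at half-time"))

  tibble(
    delta_abs = delta,
    t_half_s = t_half,
    rate_au_per_s = rate,
    lag_time_s = t_half - (delta / 2) / rate,
    valid = TRUE,
    reason = "none",
    plateaued = plateaued
  )
}

#' Plot a turbidity trace with its kinetic metrics
#'
#' Overlays the half-time crossing and the tangent-line lag-time construction
#' on the raw trace.
#'
#' @param trace data frame with `time_s`, `absorbance`.
#' @param metrics optional result of [extract_kinetics()]; computed if absent.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(trace, metrics = NULL) {
  metrics <- metrics %||% extract_kinetics(trace)
  p <- ggplot(trace, aes(x = .data$time_s, y = .data$absorbance)) +
    geom_line(color = "grey30") +
    labs(x = "time (s)", y = "absorbance (AU)")
  if (isTRUE(metrics$valid)) {
    nw <- max(3L, ceiling(0.05 * nrow(trace)))
    baseline <- mean(head(trace$absorbance, nw))
    half_level <- baseline + metrics$delta_abs / 2
    tangent <- function(t) half_level + metrics$rate_au_per_s * (t - metrics$t_half_s)
    p <- p +
      geom_hline(yintercept = baseline, linetype = 3) +
      geom_hline(yintercept = baseline + metrics$delta_abs, linetype = 3) +
      geom_abline(slope = metrics$rate_au_per_s,
                  intercept = tangent(0), color = "steelblue") +
      geom_vline(xintercept = metrics$t_half_s, linetype = 2, color = "steelblue") +
      geom_point(data = tibble(time_s = metrics$lag_time_s, absorbance = baseline),
                 color = "firebrick", size = 2)
  }
  p
}
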