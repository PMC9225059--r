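#' Forecast summaries from a conditional fit
#'
#' @param object a fitted object.
#' @param ... passed to methods.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

#' Forecast the end-of-cycle trough and threshold attainment
#'
#' For each retained posterior draw the concentration profile of the current
#' cycle is evaluated; the day-`trough_day` trough (immediately before the
#' next scheduled infusion) is summarized by its median and 80% prediction
#' interval (10th/90th percentile across draws), the probability of
#' attaining each threshold is the fraction of draws whose trough exceeds
#' it, and profile quantile bands (10/25/50/75/90%) are returned on a daily
#' grid. Intervals describe parameter uncertainty in the model-predicted
#' concentration; residual assay error is not resampled.
#'
#' @param object a [mipd_fit].
#' @param trough_day trough time in days after the most recent infusion
#'   (default 56, a q8w cycle).
#' @param thresholds concentration thresholds (µg/mL) for attainment
#'   probabilities; default `c(5, 10)`.
#' @param grid times (days post infusion) for the profile quantile bands;
#'   default daily from 0 to `trough_day`.
#' @param at optional extra evaluation time (days post infusion), e.g. the
#'   actual end-of-cycle specimen time; summarized like the trough.
#' @param ... unused.
#' @return An object of class `"mipd_forecast"`.
#' @export
forecast.mipd_fit <- function(object, trough_day = 56, thresholds = c(5, 10),
                              grid = seq(0, trough_day, by = 1), at = NULL,
                              ...) {
  if (trough_day <= 0)
    stop("trough_day must fall after the most recent infusion (> 0 days)")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  record <- object$record
  t0 <- last_dose_time(record)
  draws <- object$draws
  n <- nrow(draws)
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)

  trough <- vapply(seq_len(n), function(i)
    pk_concentration(draws[i, ], record$dosing, t0 + trough_day), 0)
  qs <- stats::quantile(trough, c(0.1, 0.5, 0.9), names = FALSE)
  prob_above <- vapply(thresholds, function(th) mean(trough > th), 0)
  names(prob_above) <- paste0("above_", thresholds)

  prof <- vapply(seq_len(n), function(i)
    pk_profile(draws[i, ], record$dosing, t0 + grid), numeric(length(grid)))
  prof <- matrix(prof, nrow = length(grid))
  pq <- t(apply(prof, 1, stats::quantile, probs = probs, names = FALSE))
  colnames(pq) <- paste0("p", probs * 100)
  profile_quantiles <- data.frame(time = grid, pq)

  at_summary <- NULL
  if (!is.null(at)) {
    ca <- vapply(seq_len(n), function(i)
      pk_concentration(draws[i, ], record$dosing, t0 + at), 0)
    qa <- stats::quantile(ca, c(0.1, 0.5, 0.9), names = FALSE)
    at_summary <- list(time = at, median = qa[2], pi80 = c(p10 = qa[1], p90 = qa[3]))
  }

  flag_high <- any(record$observations$value[!record$observations$blq] > 34)
  structure(list(id = record$id, trough_day = trough_day,
                 trough_median = qs[2],
                 trough_pi80 = c(p10 = qs[1], p90 = qs[3]),
                 prob_above = prob_above, thresholds = thresholds,
                 profile_quantiles = profile_quantiles,
                 at = at_summary, trough_draws = trough,
                 above_assay_range = flag_high),
            class = "mipd_forecast")
}

#' @export
print.mipd_forecast <- function(x, digits = 2, ...) {
  cat(sprintf("Forecast for patient %s (day %g trough):\n", x$id, x$trough_day))
  cat(sprintf("  median trough %.2f ug/mL, 80%% PI [%.2f, %.2f]\n",
              x$trough_median, x$trough_pi80[1], x$trough_pi80[2]))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  P(trough > %g ug/mL) = %.2f\n",
                x$thresholds[i], x$prob_above[i]))
  if (!is.null(x$at))
    cat(sprintf("  at day %g: median %.2f ug/mL, 80%% PI [%.2f, %.2f]\n",
                x$at$time, x$at$median, x$at$pi80[1], x$at$pi80[2]))
  if (isTRUE(x$above_assay_range))
    cat("  note: an observation exceeded the assay upper range (34 ug/mL)\n")
  invisible(x)
}

#' @describeIn mipd_fit forecast summaries (median day-56 trough, 80%
#'   prediction interval, threshold attainment); see [forecast.mipd_fit()].
#' @export
summary.mipd_fit <- function(object, ...) forecast(object, ...)

#' @describeIn mipd_fit posterior quantiles (or draws) of the predicted
#'   concentration at `times` days post most-recent infusion.
#' @param times evaluation times, days post most-recent infusion.
#' @param type `"quantiles"` for a data frame of 10/25/50/75/90% bands,
#'   `"draws"` for the raw draws-by-time matrix.
#' @export
predict.mipd_fit <- function(object, times, type = c("quantiles", "draws"),
                             ...) {
  type <- match.arg(type)
  times <- as.numeric(times)
  abs_t <- last_dose_time(object$record) + times
  n <- nrow(object$draws)
  cm <- vapply(seq_len(n), function(i)
    pk_concentration(object$draws[i, ], object$record$dosing, abs_t),
    numeric(length(abs_t)))
  cm <- matrix(cm, nrow = length(abs_t))
  if (type == "draws") {
    rownames(cm) <- paste0("t", times)
    return(t(cm))
  }
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  pq <- t(apply(cm, 1, stats::quantile, probs = probs, names = FALSE))
  colnames(pq) <- paste0("p", probs * 100)
  data.frame(time = times, pq)
}

#' @describeIn mipd_fit plot the forecast concentration profile: grey band
#'   is the 10th-90th percentile, shaded inner band the interquartile range,
#'   solid line the median; observations are overplotted, thresholds dashed.
#' @param trough_day,thresholds see [forecast.mipd_fit()].
#' @export
plot.mipd_fit <- function(x, trough_day = 56, thresholds = c(5, 10), ...) {
  fc <- forecast(x, trough_day = trough_day, thresholds = thresholds)
  pq <- fc$profile_quantiles
  graphics::plot(pq$time, pq$p90, type = "n", xlab = "Days post infusion",
                 ylab = "IFX concentration (ug/mL)",
                 ylim = c(0, max(pq$p90, x$record$observations$value) * 1.05),
                 main = sprintf("Patient %s", x$record$id), ...)
  graphics::polygon(c(pq$time, rev(pq$time)), c(pq$p10, rev(pq$p90)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::polygon(c(pq$time, rev(pq$time)), c(pq$p25, rev(pq$p75)),
                    col = grDevices::rgb(0.6, 0.75, 0.95), border = NA)
  graphics::lines(pq$time, pq$p50, lwd = 2)
  graphics::abline(h = thresholds, lty = 2, col = "grey40")
  obs <- x$record$observations
  if (nrow(obs))
    graphics::points(obs$time, ifelse(obs$blq, x$prior$loq, obs$value),
                     pch = ifelse(obs$blq, 1, 19))
  invisible(fc)
}

#' Time for the forecast profile to fall to a threshold
#'
#' For each posterior draw, finds the time on the elimination limb of the
#' current cycle at which the concentration falls to `threshold` (bisection
#' to 0.01 day). Draws whose profile never crosses the threshold within
#' `[0, cycle_end]` days post infusion contribute `cycle_end` as a
#' right-censored value and are flagged; `extrapolate` widens the search to
#' `2 * cycle_end` for draws remaining above the threshold at cycle end.
#'
#' @param object a [mipd_fit].
#' @param threshold concentration threshold (µg/mL, > 0); default 5.
#' @param cycle_end cycle length in days post infusion (default 56).
#' @param extrapolate logical; search past the cycle end for draws still
#'   above the threshold.
#' @param tol bisection tolerance in days.
#' @return A list with `median`, `iqr` (25th/75th percentile), the per-draw
#'   `times`, a per-draw `censored` flag and `any_censored`.
#' @export
time_to_threshold <- function(object, threshold = 5, cycle_end = 56,
                              extrapolate = FALSE, tol = 0.01) {
  stopifnot(inherits(object, "mipd_fit"))
  if (threshold <= 0) stop("threshold must be positive")
  record <- object$record
  t0 <- last_dose_time(record)
  t_start <- record$dosing$duration[nrow(record$dosing)]  # end of infusion
  horizon <- if (extrapolate) 2 * cycle_end else cycle_end
  n <- nrow(object$draws)
  times <- numeric(n)
  censored <- logical(n)
  for (i in seq_len(n)) {
    p <- object$draws[i, ]
    fa <- pk_concentration(p, record$dosing, t0 + t_start) - threshold
    fb <- pk_concentration(p, record$dosing, t0 + horizon) - threshold
    if (fa <= 0 || fb > 0) {  # never crosses from above within the horizon
      times[i] <- if (fb > 0) horizon else cycle_end
      censored[i] <- TRUE
      next
    }
    lo <- t_start; hi <- horizon
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pk_concentration(p, record$dosing, t0 + mid) > threshold) lo <- mid
      else hi <- mid
    }
    times[i] <- (lo + hi) / 2
  }
  qs <- stats::quantile(times, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = qs[2], iqr = c(p25 = qs[1], p75 = qs[3]), times = times,
       censored = censored, any_censored = any(censored))
}
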