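#' Stepwise trend-curve parameters
#'
#' `alpha_max` bounds how strongly the previous step's trend curve may
#' be pulled toward the current step data (a balance between adapting
#' to the subject's walking habit and overfitting each step);
#' `epsilon_threshold` is the mean-absolute-deviation level below which
#' the trend is considered converged to the step.
#'
#' @param alpha_max Maximum blending coefficient, in (0, 1].
#' @param epsilon_threshold Convergence threshold, normalized units.
#' @return An object of class `trend_params`.
#' @export
trend_params <- function(alpha_max = 0.23, epsilon_threshold = 1e-6) {
  if (!is.finite(alpha_max) || alpha_max <= 0 || alpha_max > 1) {
    stop("alpha_max must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(epsilon_threshold) || epsilon_threshold <= 0) {
    stop("epsilon_threshold must be > 0", call. = FALSE)
  }
  structure(list(alpha_max = alpha_max, epsilon_threshold = epsilon_threshold),
            class = "trend_params")
}

#' Scale a trend curve to a new length by nearest-neighbor interpolation
#'
#' Output element j (0-based) takes `prev_trend[round(j * (Lp - 1) /
#' (Lc - 1))]` with half-up rounding, where Lp and Lc are the previous
#' and new lengths. For `new_length == 1` the first element is taken.
#'
#' @param prev_trend Numeric vector, length >= 1.
#' @param new_length Target length >= 1.
#' @return Numeric vector of length `new_length`.
#' @export
scale_trend <- function(prev_trend, new_length) {
  lp <- length(prev_trend)
  if (lp < 1L) stop("empty trend curve", call. = FALSE)
  new_length <- as.integer(new_length)
  if (new_length < 1L) stop("new_length must be >= 1", call. = FALSE)
  if (new_length == 1L) return(prev_trend[1L])
  j <- 0:(new_length - 1L)
  idx <- floor(j * (lp - 1) / (new_length - 1) + 0.5) # round half-up
  prev_trend[idx + 1L]
}

#' Fit the per-step trend by bounded blending
#'
#' The current step's trend is `T = alpha * F + (1 - alpha) * T_prev`,
#' with `T_prev` the previous trend already scaled to the step length.
#' The adopted alpha is the smallest value in `[0, alpha_max]` for
#' which the error `epsilon = mean(|T - F|)` drops below
#' `epsilon_threshold`; if no alpha in range achieves that, alpha is
#' capped at `alpha_max`. Because `mean(|T - F|) = (1 - alpha) * e0`
#' with `e0 = mean(|T_prev - F|)`, the minimizer has the closed form
#' `alpha = 0` if `e0 <= threshold`, else
#' `alpha = min(alpha_max, 1 - threshold / e0)`.
#'
#' @param f Current step data.
#' @param t_scaled Previous trend scaled to `length(f)`.
#' @param params A [trend_params()].
#' @return List with `trend`, `alpha`, `epsilon` (achieved mean
#'   absolute deviation).
#' @export
fit_step_trend <- function(f, t_scaled, params = trend_params()) {
  if (length(f) != length(t_scaled)) {
    stop("step data and scaled trend differ in length", call. = FALSE)
  }
  if (length(f) < 1L) stop("empty step", call. = FALSE)
  e0 <- mean(abs(t_scaled - f))
  if (e0 <= params$epsilon_threshold) {
    alpha <- 0
  } else {
    alpha <- min(params$alpha_max, 1 - params$epsilon_threshold / e0)
  }
  trend <- alpha * f + (1 - alpha) * t_scaled
  list(trend = trend, alpha = alpha, epsilon = (1 - alpha) * e0)
}

#' Detrend a walk with the adaptive stepwise trend algorithm
#'
#' The first step is its own trend (zero residual, by construction).
#' For every later step the previous step's adopted trend is
#' nearest-neighbor scaled to the current step length and blended with
#' the step data by [fit_step_trend()]. The residuals (data minus
#' trend) isolate the fluctuation around the subject's walking habit.
#'
#' @param steps A `step_series` from [preprocess_walk()].
#' @param params A [trend_params()].
#' @return A `step_trend` object: per sensor, a list of steps each
#'   holding `data`, `trend`, `residual`, `alpha`, `epsilon`; plus the
#'   `method` used.
#' @export
detrend_walk <- function(steps, params = trend_params()) {
  res <- lapply(steps$steps, function(sensor_steps) {
    if (length(sensor_steps) < 1L) stop("sensor has no steps", call. = FALSE)
    out <- vector("list", length(sensor_steps))
    prev_trend <- NULL
    for (i in seq_along(sensor_steps)) {
      f <- sensor_steps[[i]]
      if (i == 1L) {
        fit <- list(trend = f, alpha = 0, epsilon = 0)
      } else {
        t_scaled <- scale_trend(prev_trend, length(f))
        fit <- fit_step_trend(f, t_scaled, params)
      }
      prev_trend <- fit$trend
      out[[i]] <- list(data = f, trend = fit$trend,
                       residual = f - fit$trend,
                       alpha = fit$alpha, epsilon = fit$epsilon)
    }
    out
  })
  structure(list(sensors = res, method = "stepwise", rate = steps$rate),
            class = "step_trend")
}

#' Polynomial-fit detrending baseline
#'
#' Per step, an ordinary least-squares polynomial of the given degree
#' in normalized time (0 to 1 across the step) is fitted and
#' subtracted. Used as the comparison baseline for the adaptive
#' stepwise algorithm.
#'
#' @param steps A `step_series`.
#' @param degree Polynomial degree (2, 3 or 4).
#' @return A `step_trend` object (`alpha` is `NA` for this method).
#' @export
detrend_polynomial <- function(steps, degree = 2L) {
  degree <- as.integer(degree)
  if (!degree %in% 2:4) stop("degree must be 2, 3 or 4", call. = FALSE)
  res <- lapply(steps$steps, function(sensor_steps) {
    lapply(sensor_steps, function(f) {
      L <- length(f)
      if (L <= degree) {
        stop(sprintf("step of length %d too short for degree-%d fit", L, degree),
             call. = FALSE)
      }
      u <- seq(0, 1, length.out = L)
      fit <- stats::lm(f ~ stats::poly(u, degree, raw = TRUE))
      trend <- as.numeric(stats::fitted(fit))
      list(data = f, trend = trend, residual = f - trend,
           alpha = NA_real_, epsilon = mean(abs(f - trend)))
    })
  })
  structure(list(sensors = res, method = paste0("poly", degree),
                 rate = steps$rate),
            class = "step_trend")
}

#' @export
print.step_trend <- function(x, ...) {
  ns <- vapply(x$sensors, length, 0L)
  cat(sprintf("Detrended walk (%s): %s steps per sensor\n",
              x$method, paste(range(ns), collapse = "-")))
  invisible(x)
}
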