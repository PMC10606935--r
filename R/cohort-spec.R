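#' Sensor names and foot assignment
#'
#' Eight force-sensitive resistors, four under each foot: S0-S3 right,
#' S4-S7 left. Within a foot the order runs heel (S0/S4), lateral and
#' medial metatarsal heads (S1,S2 / S5,S6), hallux (S3/S7).
#'
#' @return Character vector of the eight channel names.
#' @export
sensor_names <- function() paste0("S", 0:7)

#' @rdname sensor_names
#' @return `sensor_foot()`: named character vector mapping each sensor to
#'   `"right"` or `"left"`.
#' @export
sensor_foot <- function() {
  stats::setNames(rep(c("right", "left"), each = 4L), sensor_names())
}

#' Heel channels (weak class effect)
#' @return Character vector `c("S0", "S4")`.
#' @export
heel_sensors <- function() c("S0", "S4")

#' Default per-sensor stance pressure profile parameters
#'
#' Each stance phase is modelled as a smooth unimodal pressure bump
#' with a rounded plateau: a generalized Gaussian
#' `amp * exp(-0.5 * ((u - peak_frac) / width)^(2 * flat))` over stance
#' fraction `u`, where `flat = 1` is an ordinary Gaussian and larger
#' values flatten the top and steepen the loading/unloading flanks, as
#' real force-time curves under individual sensors do. Heel sensors
#' peak early in stance, metatarsal sensors mid-stance, and the hallux
#' sensors late, mirroring the heel-to-toe roll of normal gait.
#'
#' @return A data.frame with columns `sensor`, `amp`, `peak_frac`,
#'   `width`, `flat`.
#' @export
default_trend_shapes <- function() {
  one_foot <- data.frame(
    amp       = c(0.95, 0.85, 0.80, 0.75),
    peak_frac = c(0.30, 0.45, 0.55, 0.70),
    width     = c(0.24, 0.27, 0.27, 0.24),
    flat      = c(4, 4, 4, 4)
  )
  out <- rbind(one_foot, one_foot)
  out$sensor <- sensor_names()
  out[, c("sensor", "amp", "peak_frac", "width", "flat")]
}

#' Specify a synthetic insole-gait cohort
#'
#' Describes the statistical structure of a cohort of short walks
#' recorded by an eight-sensor insole at a fixed sampling rate: how many
#' healthy and diseased subjects, the walk length, the stance/swing
#' timing ranges, and the fluctuation model around each subject's
#' habitual (trend) pressure waveform. Diseased subjects carry both a
#' larger fluctuation amplitude and a larger step-to-step jitter of that
#' amplitude; the class effect is attenuated on the under-heel channels
#' (S0, S4), where even impaired subjects press down consistently.
#'
#' @param n_healthy,n_diseased Subjects per class.
#' @param sample_rate Sampling rate in Hz.
#' @param walk_duration Walk length in seconds.
#' @param stance_duration_range,swing_duration_range Two-element ranges
#'   (seconds) from which per-step stance/swing durations are drawn
#'   uniformly.
#' @param trend_shape_params Data frame as [default_trend_shapes()].
#' @param fluct_sigma_healthy,fluct_sigma_diseased Stationary standard
#'   deviation (normalized force units) of the within-stance fluctuation
#'   around the trend for each class. Must satisfy
#'   `fluct_sigma_diseased >= fluct_sigma_healthy`.
#' @param fluct_ar_coeff First-order autoregression coefficient of the
#'   fluctuation, in (-1, 1); positive values give the slowly-wandering
#'   deviations seen in force traces rather than white noise.
#' @param step_scale_sdlog Log-scale standard deviation of the
#'   per-step lognormal multiplier applied to the fluctuation sigma
#'   (baseline step-to-step variability, both classes).
#' @param step_jitter_diseased Multiplier (>= 1) on `step_scale_sdlog`
#'   for diseased subjects: their fluctuation level itself varies more
#'   from step to step.
#' @param heel_attenuation In \[0, 1\]; scales the healthy-vs-diseased
#'   difference (in both sigma and jitter) on the heel channels S0/S4.
#'   0 removes the class effect there entirely, 1 leaves it untouched.
#' @param swing_noise_level Mean of the small positive sensor noise
#'   emitted while the foot is in the air (so contact detection is
#'   non-trivial).
#' @param subject_profile_cv Relative subject-to-subject variation of
#'   the trend-shape parameters (each subject walks with their own fixed
#'   habit).
#' @param rng_seed Integer seed; the generator is fully deterministic
#'   given the spec.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_healthy = 30L,
                        n_diseased = 30L,
                        sample_rate = 20,
                        walk_duration = 12,
                        stance_duration_range = c(0.55, 0.75),
                        swing_duration_range = c(0.35, 0.50),
                        trend_shape_params = default_trend_shapes(),
                        fluct_sigma_healthy = 0.02,
                        fluct_sigma_diseased = 0.06,
                        fluct_ar_coeff = 0.8,
                        step_scale_sdlog = 0.35,
                        step_jitter_diseased = 2.0,
                        heel_attenuation = 0.3,
                        swing_noise_level = 0.01,
                        subject_profile_cv = 0.06,
                        rng_seed = 1L) {
  spec <- list(
    n_healthy = as.integer(n_healthy),
    n_diseased = as.integer(n_diseased),
    sample_rate = sample_rate,
    walk_duration = walk_duration,
    stance_duration_range = stance_duration_range,
    swing_duration_range = swing_duration_range,
    trend_shape_params = trend_shape_params,
    fluct_sigma_healthy = fluct_sigma_healthy,
    fluct_sigma_diseased = fluct_sigma_diseased,
    fluct_ar_coeff = fluct_ar_coeff,
    step_scale_sdlog = step_scale_sdlog,
    step_jitter_diseased = step_jitter_diseased,
    heel_attenuation = heel_attenuation,
    swing_noise_level = swing_noise_level,
    subject_profile_cv = subject_profile_cv,
    rng_seed = as.integer(rng_seed)
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_spec field '%s': %s", field, msg), call. = FALSE)
  }
  if (spec$n_healthy < 0L || spec$n_diseased < 0L) {
    stop_field("n_healthy/n_diseased", "subject counts must be non-negative")
  }
  if (!is.finite(spec$sample_rate) || spec$sample_rate <= 0) {
    stop_field("sample_rate", "must be > 0")
  }
  if (!is.finite(spec$walk_duration) || spec$walk_duration <= 0) {
    stop_field("walk_duration", "must be > 0")
  }
  for (f in c("stance_duration_range", "swing_duration_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      stop_field(f, "must be an increasing pair of positive durations")
    }
  }
  shp <- spec$trend_shape_params
  if (!is.data.frame(shp) || nrow(shp) != 8L ||
      !all(c("sensor", "amp", "peak_frac", "width") %in% names(shp)) ||
      !identical(sort(shp$sensor), sort(sensor_names()))) {
    stop_field("trend_shape_params", "must give amp/peak_frac/width for all of S0..S7")
  }
  if (is.null(shp$flat)) spec$trend_shape_params$flat <- shp$flat <- rep(1, 8L)
  if (any(shp$amp <= 0) || any(shp$width <= 0) || any(shp$flat < 1) ||
      any(shp$peak_frac <= 0) || any(shp$peak_frac >= 1)) {
    stop_field("trend_shape_params",
               "amp/width must be > 0, flat >= 1, peak_frac in (0,1)")
  }
  if (spec$fluct_sigma_healthy <= 0) stop_field("fluct_sigma_healthy", "must be > 0")
  if (spec$fluct_sigma_diseased < spec$fluct_sigma_healthy) {
    stop_field("fluct_sigma_diseased", "must be >= fluct_sigma_healthy")
  }
  if (abs(spec$fluct_ar_coeff) >= 1) stop_field("fluct_ar_coeff", "must lie in (-1, 1)")
  if (spec$step_scale_sdlog < 0) stop_field("step_scale_sdlog", "must be >= 0")
  if (spec$step_jitter_diseased < 1) stop_field("step_jitter_diseased", "must be >= 1")
  if (spec$heel_attenuation < 0 || spec$heel_attenuation > 1) {
    stop_field("heel_attenuation", "must lie in [0, 1]")
  }
  if (spec$swing_noise_level < 0) stop_field("swing_noise_level", "must be >= 0")
  if (spec$subject_profile_cv < 0) stop_field("subject_profile_cv", "must be >= 0")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic insole-gait cohort spec\n")
  cat(sprintf("  subjects: %d healthy / %d diseased\n", x$n_healthy, x$n_diseased))
  cat(sprintf("  sampling: %g Hz, %g s walks\n", x$sample_rate, x$walk_duration))
  cat(sprintf("  stance %g-%g s, swing %g-%g s\n",
              x$stance_duration_range[1], x$stance_duration_range[2],
              x$swing_duration_range[1], x$swing_duration_range[2]))
  cat(sprintf("  fluctuation sigma: %g (healthy) / %g (diseased), AR %g\n",
              x$fluct_sigma_healthy, x$fluct_sigma_diseased, x$fluct_ar_coeff))
  cat(sprintf("  step jitter sdlog %g (x%g diseased), heel attenuation %g\n",
              x$step_scale_sdlog, x$step_jitter_diseased, x$heel_attenuation))
  cat(sprintf("  seed %d\n", x$rng_seed))
  invisible(x)
}
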