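#' Generate a seeded synthetic cohort of insole walk recordings
#'
#' Draws `n_healthy + n_diseased` subjects. Each subject has a fixed
#' habitual stance pressure profile per sensor (a smooth unimodal bump;
#' heel channels peak early in stance, toe channels late). A walk
#' alternates stance and swing phases per foot, the left foot offset by
#' roughly half a gait cycle. Within each stance the emitted signal is
#' the subject's profile plus correlated AR(1) fluctuation whose
#' standard deviation is redrawn every step from a lognormal
#' distribution; diseased subjects have both a larger mean fluctuation
#' and a wider step-to-step spread of it, except on the heel channels
#' where the class effect is attenuated. Swing intervals emit small
#' positive noise.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `walk_recording` objects (healthy subjects first).
#'   Each has fields `subject_id`, `label` (factor healthy/diseased),
#'   `sample_rate`, `units`, and `channels`, a numeric matrix with one
#'   column per sensor S0..S7.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(unclass(spec))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$rng_seed)
  labels <- c(rep("healthy", spec$n_healthy), rep("diseased", spec$n_diseased))
  ids <- c(sprintf("H%02d", seq_len(spec$n_healthy)),
           sprintf("D%02d", seq_len(spec$n_diseased)))
  mapply(function(id, lab) generate_walk(spec, id, lab),
         ids, labels, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

# One subject's walk. Uses the current RNG stream (caller seeds it).
generate_walk <- function(spec, subject_id, label) {
  n <- round(spec$walk_duration * spec$sample_rate)
  if (n < 2L) stop("walk too short: fewer than 2 samples", call. = FALSE)
  t <- (seq_len(n) - 1L) / spec$sample_rate

  shapes <- spec$trend_shape_params
  rownames(shapes) <- shapes$sensor
  # subject-specific walking habit: jitter the canonical profile once
  cv <- spec$subject_profile_cv
  subj_amp  <- shapes$amp * exp(stats::rnorm(8, 0, cv))
  subj_peak <- pmin(0.95, pmax(0.05, shapes$peak_frac + stats::rnorm(8, 0, cv / 2)))
  subj_wid  <- shapes$width * exp(stats::rnorm(8, 0, cv))
  subj_flat <- shapes$flat
  names(subj_amp) <- names(subj_peak) <- names(subj_wid) <-
    names(subj_flat) <- shapes$sensor

  sched <- list(
    right = step_schedule(spec, offset = stats::runif(1, 0, 0.05)),
    left  = step_schedule(spec, offset = mean(spec$stance_duration_range) / 2 +
                            mean(spec$swing_duration_range) / 2 +
                            stats::runif(1, 0, 0.05))
  )

  channels <- matrix(0, nrow = n, ncol = 8L,
                     dimnames = list(NULL, sensor_names()))
  foot_of <- sensor_foot()
  for (foot in c("right", "left")) {
    steps <- sched[[foot]]
    sensors <- names(foot_of)[foot_of == foot]
    # per-step standard-normal jitter draw, shared by the foot's sensors
    z_step <- stats::rnorm(nrow(steps))
    for (s in sensors) {
      eff <- class_effect(spec, label, s)
      x <- swing_noise(spec, n)
      for (k in seq_len(nrow(steps))) {
        idx <- which(t >= steps$start[k] & t < steps$end[k])
        if (length(idx) == 0L) next
        u <- (t[idx] - steps$start[k]) / (steps$end[k] - steps$start[k])
        trend <- stance_profile(u, subj_amp[s], subj_peak[s], subj_wid[s],
                                subj_flat[s])
        sigma_k <- eff$sigma * exp(z_step[k] * eff$sdlog)
        x[idx] <- trend + ar1_noise(length(idx), spec$fluct_ar_coeff, sigma_k)
      }
      channels[, s] <- pmax(x, 0)
    }
  }

  structure(
    list(subject_id = subject_id,
         label = factor(label, levels = c("healthy", "diseased")),
         sample_rate = spec$sample_rate,
         units = "normalized",
         channels = channels),
    class = "walk_recording"
  )
}

# Smooth flat-topped unimodal pressure bump over stance fraction u.
stance_profile <- function(u, amp, peak, width, flat = 1) {
  amp * exp(-0.5 * ((u - peak) / width)^(2 * flat))
}

# Effective fluctuation parameters for one sensor: diseased subjects get
# larger sigma and wider per-step jitter; on the heel channels only a
# fraction heel_attenuation of the class difference survives.
class_effect <- function(spec, label, sensor) {
  att <- if (sensor %in% heel_sensors()) spec$heel_attenuation else 1
  if (label == "diseased") {
    sigma <- spec$fluct_sigma_healthy +
      att * (spec$fluct_sigma_diseased - spec$fluct_sigma_healthy)
    sdlog <- spec$step_scale_sdlog * (1 + att * (spec$step_jitter_diseased - 1))
  } else {
    sigma <- spec$fluct_sigma_healthy
    sdlog <- spec$step_scale_sdlog
  }
  list(sigma = sigma, sdlog = sdlog)
}

# Alternating stance/swing schedule for one foot over the walk.
step_schedule <- function(spec, offset = 0) {
  starts <- numeric(0)
  ends <- numeric(0)
  t0 <- offset
  while (t0 < spec$walk_duration) {
    stance <- stats::runif(1, spec$stance_duration_range[1], spec$stance_duration_range[2])
    swing <- stats::runif(1, spec$swing_duration_range[1], spec$swing_duration_range[2])
    starts <- c(starts, t0)
    ends <- c(ends, min(t0 + stance, spec$walk_duration))
    t0 <- t0 + stance + swing
  }
  data.frame(start = starts, end = ends)
}

# Stationary AR(1) series with marginal sd sigma.
ar1_noise <- function(n, phi, sigma) {
  innov_sd <- sigma * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  if (n > 1L) {
    e <- stats::rnorm(n - 1L, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1L] + e[i - 1L]
  }
  x
}

swing_noise <- function(spec, n) {
  spec$swing_noise_level * (0.5 + abs(stats::rnorm(n, 0, 0.5)))
}

#' @export
print.walk_recording <- function(x, ...) {
  cat(sprintf("Walk recording %s (%s): %d samples x 8 sensors @ %g Hz [%s]\n",
              x$subject_id, as.character(x$label), nrow(x$channels),
              x$sample_rate, x$units))
  invisible(x)
}

#' FSR force/voltage calibration
#'
#' The insole force-sensitive resistors, read through a 1 kOhm voltage
#' divider at 5 V, follow a lab-calibrated exponential characteristic:
#' the applied weight in newtons is `w = exp((vo + 0.2245) / 0.9265)`
#' for output voltage `vo` in volts. `weight_to_voltage()` is the exact
#' inverse, `vo = 0.9265 * log(w) - 0.2245`.
#'
#' @param vo Output voltage(s), volts.
#' @param w Applied weight(s), newtons; must be > 0.
#' @return Weight in newtons, resp. voltage in volts.
#' @examples
#' voltage_to_weight(-0.2245) # 1 N
#' weight_to_voltage(voltage_to_weight(0.5))
#' @export
voltage_to_weight <- function(vo) {
  exp((vo + 0.2245) / 0.9265)
}

#' @rdname voltage_to_weight
#' @export
weight_to_voltage <- function(w) {
  if (any(w <= 0)) stop("weight must be > 0 N", call. = FALSE)
  0.9265 * log(w) - 0.2245
}

#' Write / read a cohort as per-subject CSV files
#'
#' One CSV per subject with columns `t, S0, ..., S7`, plus a
#' `manifest.csv` with columns `subject_id, label, seed, file`.
#'
#' @param cohort List of `walk_recording`s as from [generate_cohort()].
#' @param dir Output (resp. input) directory.
#' @param seed Seed recorded in the manifest (informational).
#' @return `write_cohort()` the manifest data.frame, invisibly;
#'   `read_cohort()` a list of `walk_recording`s.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    label = vapply(cohort, function(r) as.character(r$label), ""),
    seed = seed,
    file = paste0(vapply(cohort, `[[`, "", "subject_id"), ".csv"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    df <- data.frame(t = (seq_len(nrow(rec$channels)) - 1L) / rec$sample_rate,
                     rec$channels, check.names = FALSE)
    utils::write.csv(df, file.path(dir, manifest$file[i]), row.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$file[i]), check.names = FALSE)
    stopifnot(all(c("t", sensor_names()) %in% names(df)))
    rate <- 1 / stats::median(diff(df$t))
    structure(
      list(subject_id = manifest$subject_id[i],
           label = factor(manifest$label[i], levels = c("healthy", "diseased")),
           sample_rate = round(rate, 6),
           units = "normalized",
           channels = as.matrix(df[, sensor_names()])),
      class = "walk_recording"
    )
  })
}
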