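# Small builders shared across the test files.

tiny_cohort <- function(n = 3L, seed = 42L, ...) {
  generate_cohort(cohort_spec(n_healthy = n, n_diseased = n, rng_seed = seed, ...))
}

# A walk_recording built directly from a channel matrix.
make_recording <- function(channels, rate = 20, label = "healthy", id = "T01") {
  colnames(channels) <- sensor_names()
  structure(list(subject_id = id,
                 label = factor(label, levels = c("healthy", "diseased")),
                 sample_rate = rate, units = "normalized",
                 channels = channels),
            class = "walk_recording")
}

# A step_series from a named list of per-sensor step lists.
make_step_series <- function(steps, rate = 400, factor = 20L) {
  structure(list(steps = steps, rate = rate, factor = factor),
            class = "step_series")
}

# Step series with the same step list under every sensor name.
uniform_step_series <- function(step_list) {
  make_step_series(stats::setNames(rep(list(step_list), 8L), sensor_names()))
}

random_pmf <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}

# Manual stationary AR(1), independent of the generator internals.
ar1_oracle <- function(n, phi, sigma) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  for (i in seq_len(n)[-1]) {
    x[i] <- phi * x[i - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - phi^2))
  }
  x
}

# Build a recording whose right-foot Smax equals a given curve (S0 carries
# the curve, S1-S3 stay at zero-ish, left foot mirrors it).
smax_recording <- function(curve) {
  ch <- matrix(0, nrow = length(curve), ncol = 8L)
  ch[, 1] <- curve
  ch[, 5] <- curve
  make_recording(ch)
}

# Independent linear-scan segmentation oracle.
scan_runs <- function(on, min_len) {
  starts <- ends <- integer(0)
  i <- 1L
  n <- length(on)
  while (i <= n) {
    if (on[i]) {
      j <- i
      while (j < n && on[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        starts <- c(starts, i)
        ends <- c(ends, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

# Literal alpha search: evaluate mean|alpha F + (1-alpha) T - F| on a
# coarse grid, then refine around the first alpha meeting the threshold.
grid_alpha_oracle <- function(f, t_scaled, alpha_max, thr, n_coarse = 2000L) {
  eps_at <- function(alphas) {
    vapply(alphas, function(a) mean(abs(a * f + (1 - a) * t_scaled - f)), 0)
  }
  coarse <- seq(0, alpha_max, length.out = n_coarse)
  e <- eps_at(coarse)
  hit <- which(e <= thr)
  if (length(hit) == 0L) return(alpha_max)
  lo <- if (hit[1] == 1L) 0 else coarse[hit[1] - 1L]
  fine <- seq(lo, coarse[hit[1]], length.out = 2000L)
  fine[which(eps_at(fine) <= thr)[1]]
}

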