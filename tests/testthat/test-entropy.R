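test_that("Tsallis entropy evaluates the q-deformed sum and its Shannon limit", {
  for (q in c(0.3, 0.82, 1, 1.7)) {
    expect_equal(tsallis_entropy(1, q), 0)
  }
  # frozen value of (1 - 2 * 0.5^0.82) / (0.82 - 1)
  expect_equal(tsallis_entropy(c(0.5, 0.5), 0.82), 0.7382438, tolerance = 1e-7)
  # empty states contribute nothing
  expect_equal(tsallis_entropy(c(0.5, 0, 0.5), 0.82),
               tsallis_entropy(c(0.5, 0.5), 0.82))
  # q -> 1 converges to Shannon
  expect_equal(tsallis_entropy(c(0.5, 0.5), 1), log(2))
  for (q1 in c(1 - 1e-6, 1 + 1e-6)) {
    expect_equal(tsallis_entropy(c(0.5, 0.5), q1), log(2), tolerance = 1e-5)
  }
  set.seed(4)
  p <- random_pmf(10)
  shannon <- -sum(p * log(p))
  expect_lt(abs(tsallis_entropy(p, 1 + 1e-6) - shannon), 1e-5)
  expect_error(tsallis_entropy(c(0.5, 0.6), 0.82), "probability")
  expect_error(tsallis_entropy(c(-0.1, 1.1), 0.82), "probability")
})

test_that("entropy is non-negative for q < 1 and maximal at the uniform distribution", {
  set.seed(9)
  for (N in 2:25) {
    closed <- (1 - N^(1 - 0.82)) / (0.82 - 1)
    expect_equal(tsallis_entropy(rep(1 / N, N), 0.82), closed, tolerance = 1e-12)
    p <- random_pmf(N)
    te <- tsallis_entropy(p, 0.82)
    expect_gte(te, 0)
    expect_lte(te, closed + 1e-12)
  }
  expect_equal(tsallis_entropy(c(1, 0, 0), 0.82), 0)
})

test_that("pseudo-additivity holds exactly for independent systems", {
  gap <- tsallis_additivity_gap(rep(0.5, 2), rep(1 / 3, 3), 0.82)
  expect_equal(gap$lhs, gap$rhs, tolerance = 1e-12)
  g1 <- tsallis_additivity_gap(c(0.2, 0.8), c(0.3, 0.7), 1)
  expect_equal(g1$lhs,
               tsallis_entropy(c(0.2, 0.8), 1) + tsallis_entropy(c(0.3, 0.7), 1),
               tolerance = 1e-12)
  set.seed(12)
  worst <- 0
  for (i in 1:100) {
    q <- stats::runif(1, 0.3, 1.7)
    if (abs(q - 1) < 1e-3) q <- 1
    g <- tsallis_additivity_gap(random_pmf(sample(2:8, 1)),
                                random_pmf(sample(2:8, 1)), q)
    worst <- max(worst, abs(g$lhs - g$rhs))
  }
  expect_lt(worst, 1e-10)
})

test_that("residual histograms form valid pmfs over [0, max]", {
  h0 <- build_histogram(rep(0, 50), 25)
  expect_equal(h0$probabilities, 1)
  expect_equal(tsallis_entropy(h0, 0.82), 0)
  hu <- build_histogram(0.1 * (0:24), 25)
  expect_equal(hu$probabilities, rep(1 / 25, 25))
  expect_length(hu$bin_edges, 26)
  expect_true(all(diff(hu$bin_edges) > 0))
  set.seed(6)
  hbig <- build_histogram(stats::runif(1e4), 25)
  expect_equal(sum(hbig$probabilities), 1, tolerance = 1e-12)
  closed_u25 <- (1 - 25 * (1 / 25)^0.82) / (0.82 - 1)
  expect_lt(abs(tsallis_entropy(hbig, 0.82) - closed_u25), 0.05)
  expect_error(build_histogram(numeric(0)), "empty")
  expect_error(build_histogram(c(-1, 2)), "non-negative")
  expect_error(build_histogram(c(0.5, 1), x_max = 0.8), "x_max")
})

test_that("activity masking removes exactly the unloaded samples", {
  r <- stats::rnorm(10)
  d <- rep(0.5, 10)
  expect_identical(mask_inactive(r, d, 0.05), r)
  expect_length(mask_inactive(r, rep(0.01, 10), 0.05), 0L)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    r <- stats::rnorm(n)
    d <- stats::runif(n)
    thr <- stats::runif(1, 0.05, 0.9)
    keep <- which(d >= thr) # index-set oracle
    expect_identical(mask_inactive(r, d, thr), r[keep])
  }
  expect_error(mask_inactive(1:3, 1:4), "length")
})

test_that("expanded-set deviation equals the RMS of the input", {
  expect_equal(sigma_e_prime(c(1, -1)), 1)
  expect_equal(sigma_e_prime(-2.5), 2.5)
  set.seed(19)
  for (i in 1:100) {
    e <- stats::rnorm(sample(1:30, 1), sd = 10^stats::runif(1, -3, 2))
    expect_equal(sigma_e_prime(e, "expand"), sigma_e_prime(e, "rms"),
                 tolerance = 1e-12)
    expect_equal(sigma_e_prime(e, "rms"), sqrt(mean(e^2)))
  }
  expect_error(sigma_e_prime(numeric(0)), "empty")
})

test_that("identical steps produce an all-zero 16-feature row in fixed order", {
  step <- 0.2 + 0.7 * sin(seq(0.1, pi - 0.1, length.out = 50))
  ss <- uniform_step_series(rep(list(step), 4))
  feats <- extract_features(detrend_walk(ss))
  row <- feature_row(feats)
  expect_length(row, 16L)
  expect_identical(names(row),
                   c(paste0(sensor_names(), "_te"),
                     paste0(sensor_names(), "_sigma")))
  expect_equal(unname(row), rep(0, 16))
  expect_false(any(feats$missing))
})

test_that("a never-loaded sensor is flagged missing, too few steps error out", {
  step <- rep(0.5, 30)
  steps <- stats::setNames(rep(list(rep(list(step), 4)), 8L), sensor_names())
  steps$S2 <- rep(list(rep(0.01, 30)), 4) # always below the activity threshold
  feats <- extract_features(detrend_walk(make_step_series(steps)))
  expect_true(feats$missing[["S2"]])
  expect_true(is.na(feats$te[["S2"]]))
  expect_false(any(feats$missing[c("S0", "S1", "S3")]))
  short <- uniform_step_series(rep(list(step), 2))
  expect_error(extract_features(detrend_walk(short)), "too few steps")
})

test_that("feature extraction is stable across repeated runs", {
  cohort <- tiny_cohort(n = 2, seed = 31)
  f1 <- feature_table(cohort)
  f2 <- feature_table(cohort)
  expect_identical(f1, f2)
  expect_identical(names(f1),
                   c("subject_id", "label", paste0(sensor_names(), "_te"),
                     paste0(sensor_names(), "_sigma")))
})

test_that("q sweep returns one row per q, handles q = 1, and tracks the argmax", {
  cohort <- tiny_cohort(n = 5, seed = 27)
  cfg <- eval_config(k = 3, rng_seed = 1, classifiers = "knn_cosine")
  tab1 <- q_sweep(cohort, 0.82, cfg)
  expect_equal(nrow(tab1), 1L)
  expect_equal(attr(tab1, "best_q"), 0.82)
  tab <- q_sweep(cohort, c(0.5, 1, 1.2), cfg)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$best_accuracy >= 0 & tab$best_accuracy <= 1))
  expect_true(attr(tab, "best_q") %in% tab$q)
  expect_error(q_sweep(cohort, numeric(0), cfg), "q_grid")
})
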