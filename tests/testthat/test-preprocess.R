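test_that("min-max normalization maps to [0,1], attains both ends, and is idempotent", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(c(0, 1)), c(0, 1))
  expect_error(normalize_minmax(c(5, 5, 5)), "degenerate")
  expect_error(normalize_minmax(3), "2 samples")
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rnorm(50, sd = runif(1, 0.1, 10))
    nx <- normalize_minmax(x)
    expect_true(all(nx >= 0 & nx <= 1))
    expect_equal(range(nx), c(0, 1))
    expect_equal(normalize_minmax(nx), nx)
  }
})

test_that("contact detection handles the elementary threshold patterns", {
  seg <- detect_contact(smax_recording(c(0.8, 0.02, 0.01, 0.9)),
                        contact_params(min_segment_samples = 1L))
  expect_equal(seg$right, data.frame(start = c(1L, 4L), end = c(1L, 4L)))
  seg2 <- detect_contact(smax_recording(c(0.8, 0.6, 0.7, 0.9)),
                         contact_params(min_segment_samples = 1L))
  expect_equal(seg2$right, data.frame(start = 1L, end = 4L))
  # short contact runs are discarded as noise
  seg3 <- detect_contact(smax_recording(c(0.8, 0.01, 0.9, 0.9, 0.9, 0.01)),
                         contact_params(min_segment_samples = 3L))
  expect_equal(seg3$right, data.frame(start = 3L, end = 5L))
  expect_error(detect_contact(smax_recording(rep(0.01, 10)),
                              contact_params(min_segment_samples = 1L)),
               "no steps")
})

test_that("contact detection matches a linear-scan oracle on random patterns", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    on <- stats::runif(n) < 0.6
    min_len <- sample(1:3, 1)
    curve <- ifelse(on, stats::runif(n, 0.06, 1), stats::runif(n, 0, 0.049))
    want <- scan_runs(curve >= 0.05, min_len)
    if (nrow(want) == 0L) {
      expect_error(detect_contact(smax_recording(curve),
                                  contact_params(min_segment_samples = min_len)),
                   "no steps")
      next
    }
    seg <- detect_contact(smax_recording(curve),
                          contact_params(min_segment_samples = min_len))
    expect_identical(unname(as.matrix(seg$right)), unname(as.matrix(want)))
  }
})

test_that("contact intervals are invariant to sub-threshold in-air noise", {
  set.seed(3)
  on <- rep(c(TRUE, FALSE), times = 10)[sample(20)]
  curve <- ifelse(on, 0.7, 0)
  base <- detect_contact(smax_recording(curve), contact_params(min_segment_samples = 1L))
  noisy <- curve
  noisy[!on] <- stats::runif(sum(!on), 0, 0.0499)
  pert <- detect_contact(smax_recording(noisy), contact_params(min_segment_samples = 1L))
  expect_identical(base$right, pert$right)
})

test_that("framing removes the first and last stance of each foot", {
  seg5 <- structure(list(right = data.frame(start = c(1, 10, 20, 30, 40),
                                            end = c(5, 14, 24, 34, 44)),
                         left = data.frame(start = c(3, 12, 22, 32, 42),
                                           end = c(7, 16, 26, 36, 46))),
                    n_samples = 50L, class = "stance_segmentation")
  framed <- frame_walk(seg5)
  expect_equal(framed$right$start, c(10, 20, 30))
  expect_equal(framed$left$end, c(16, 26, 36))
  seg3 <- seg5
  seg3$right <- seg3$right[1:3, ]
  seg3$left <- seg3$left[1:3, ]
  expect_equal(nrow(frame_walk(seg3)$right), 1L)
  seg2 <- seg5
  seg2$right <- seg2$right[1:2, ]
  expect_error(frame_walk(seg2), "too short to frame")
})

test_that("Hermite upsampling passes through originals, keeps linear data linear, and preserves extremes", {
  ch <- matrix(stats::runif(30 * 8), 30, 8)
  rec <- make_recording(ch)
  seg <- structure(list(right = data.frame(start = 3L, end = 12L),
                        left = data.frame(start = 5L, end = 9L)),
                   n_samples = 30L, class = "stance_segmentation")
  ss <- interpolate_steps(rec, seg, factor = 20L)
  # length formula: factor * (L - 1) + 1
  expect_length(ss$steps$S0[[1]], 20 * 9 + 1)
  expect_length(ss$steps$S4[[1]], 20 * 4 + 1)
  expect_equal(ss$rate, 400)
  # original samples appear unchanged every `factor` samples
  expect_equal(ss$steps$S0[[1]][seq(1, 181, by = 20)], ch[3:12, 1])
  expect_equal(ss$steps$S7[[1]][seq(1, 81, by = 20)], ch[5:9, 8])
  # a linear ramp stays exactly linear
  ramp <- matrix(rep(seq(0, 1, length.out = 30), 8), 30, 8)
  ssr <- interpolate_steps(make_recording(ramp), seg, factor = 20L)
  expect_equal(ssr$steps$S1[[1]], seq(ramp[3, 2], ramp[12, 2], length.out = 181),
               tolerance = 1e-12)
  # shape preservation: no overshoot beyond the step's own data range
  for (s in sensor_names()) {
    step <- ss$steps[[s]][[1]]
    iv <- seg[[sensor_foot()[[s]]]]
    orig <- ch[iv$start[1]:iv$end[1], match(s, sensor_names())]
    expect_gte(min(step), min(orig) - 1e-12)
    expect_lte(max(step), max(orig) + 1e-12)
  }
})

test_that("segment shorter than 2 samples is rejected", {
  rec <- make_recording(matrix(stats::runif(80), 10, 8))
  seg <- structure(list(right = data.frame(start = 4L, end = 4L),
                        left = data.frame(start = 2L, end = 6L)),
                   n_samples = 10L, class = "stance_segmentation")
  expect_error(interpolate_steps(rec, seg), "shorter than 2")
})

test_that("end-to-end preprocessing yields in-range step series for a generated walk", {
  rec <- tiny_cohort(n = 1, seed = 8)[[1]]
  ss <- preprocess_walk(rec)
  expect_s3_class(ss, "step_series")
  expect_identical(names(ss$steps), sensor_names())
  for (s in sensor_names()) {
    expect_gte(length(ss$steps[[s]]), 3L)
    vals <- unlist(ss$steps[[s]])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})
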