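#' Entropy feature-extraction parameters
#'
#' @param q Entropic index of the Tsallis entropy; q < 1 weights rare
#'   histogram states more heavily (super-extensive regime), q = 1
#'   recovers Shannon entropy. Default 0.82, the value that maximizes
#'   class discrimination in this pipeline.
#' @param n_bins Maximum number of histogram bins (cap 25, chosen for
#'   acceptable granularity at the available sample counts).
#' @param activity_threshold Normalized level below which a sensor is
#'   considered inactive within a step; such samples are removed before
#'   histogramming. Shared by default with the contact `air_threshold`.
#' @param stepwise_mode `"diff"` (default) applies the expanded-set
#'   deviation to step-to-step *changes* of the per-step entropy, for
#'   which the healthy ideal is zero; `"raw"` applies it to the
#'   per-step entropies themselves.
#' @param per_step_range `"shared"` (default) bins every step's
#'   histogram over the common range of the pooled absolute residuals,
#'   so a step with unusually large or small fluctuation shifts its
#'   entropy; `"own"` bins each step over its own \[0, max\] range,
#'   which makes per-step entropy invariant to the step's fluctuation
#'   scale.
#' @param exclude_first_step Drop the first step from the entropy
#'   features (its residual is structurally zero under the stepwise
#'   trend and would inflate the zero bin). Default TRUE.
#' @param min_samples_per_bin When fewer than
#'   `min_samples_per_bin * n_bins` samples are available the bin count
#'   shrinks to `max(2, floor(n / min_samples_per_bin))` so each bin
#'   keeps a workable occupancy.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(q = 0.82, n_bins = 25L,
                           activity_threshold = 0.05,
                           stepwise_mode = c("diff", "raw"),
                           per_step_range = c("shared", "own"),
                           exclude_first_step = TRUE,
                           min_samples_per_bin = 4L) {
  stepwise_mode <- match.arg(stepwise_mode)
  per_step_range <- match.arg(per_step_range)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L || n_bins > 25L) stop("n_bins must lie in [2, 25]", call. = FALSE)
  if (!is.finite(q)) stop("q must be finite", call. = FALSE)
  if (activity_threshold <= 0 || activity_threshold >= 1) {
    stop("activity_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(q = q, n_bins = n_bins,
                 activity_threshold = activity_threshold,
                 stepwise_mode = stepwise_mode,
                 per_step_range = per_step_range,
                 exclude_first_step = isTRUE(exclude_first_step),
                 min_samples_per_bin = as.integer(min_samples_per_bin)),
            class = "entropy_params")
}

#' Tsallis entropy of a discrete distribution
#'
#' `TE = (1 - sum(p_i^q)) / (q - 1)` for `q != 1` (empty states
#' contribute nothing); at `q = 1` the Shannon limit
#' `-sum(p_i * log(p_i))` is returned. With the Boltzmann constant
#' taken as 1, units are nats in the Shannon limit.
#'
#' @param pmf A `histogram_pmf` from [build_histogram()], or a bare
#'   numeric vector of probabilities summing to 1.
#' @param q Entropic index.
#' @return The entropy value (>= 0 for q <= 1).
#' @export
tsallis_entropy <- function(pmf, q = 0.82) {
  p <- as_probs(pmf)
  p <- p[p > 0]
  if (q == 1) return(-sum(p * log(p)))
  (1 - sum(p^q)) / (q - 1)
}

as_probs <- function(pmf) {
  p <- if (inherits(pmf, "histogram_pmf")) pmf$probabilities else as.numeric(pmf)
  if (length(p) == 0L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stop("invalid probability mass function", call. = FALSE)
  }
  p
}

#' Pseudo-additivity of the Tsallis entropy for independent systems
#'
#' For independent systems X and Y (joint probabilities `p_i * p_j`)
#' the Tsallis entropy satisfies
#' `TE(X+Y) = TE(X) + TE(Y) + (1 - q) TE(X) TE(Y)`, with `(1 - q)`
#' measuring the deviation from ordinary additivity. Returns both sides
#' so the identity can serve as a numerical oracle.
#'
#' @param pmf_x,pmf_y Two distributions (see [tsallis_entropy()]).
#' @param q Entropic index.
#' @return List with elements `lhs` (entropy of the product system) and
#'   `rhs` (the pseudo-additive combination).
#' @export
tsallis_additivity_gap <- function(pmf_x, pmf_y, q = 0.82) {
  px <- as_probs(pmf_x)
  py <- as_probs(pmf_y)
  joint <- as.numeric(outer(px, py))
  tx <- tsallis_entropy(px, q)
  ty <- tsallis_entropy(py, q)
  list(lhs = tsallis_entropy(joint, q),
       rhs = tx + ty + (1 - q) * tx * ty)
}

#' Histogram of absolute residuals as a probability mass function
#'
#' Equal-width bins over `[0, max(x)]` (or a supplied upper edge, so
#' several samples can share bin edges). If the range collapses to zero
#' a single bin carries the full mass.
#'
#' @param x Non-negative numeric vector (absolute residuals), non-empty.
#' @param n_bins Number of bins.
#' @param x_max Upper edge of the binning range; defaults to `max(x)`
#'   and must be at least that.
#' @return A `histogram_pmf`: list with `bin_edges` (length
#'   `n_bins + 1`), `probabilities` (length `n_bins`, summing to 1) and
#'   `n_samples`.
#' @export
build_histogram <- function(x, n_bins = 25L, x_max = max(x)) {
  if (length(x) == 0L) stop("cannot histogram an empty sample", call. = FALSE)
  if (any(x < 0)) stop("expected absolute (non-negative) values", call. = FALSE)
  if (x_max < max(x)) stop("x_max smaller than the largest sample", call. = FALSE)
  n_bins <- as.integer(n_bins)
  m <- x_max
  if (m == 0) {
    return(structure(list(bin_edges = c(0, 1),
                          probabilities = 1,
                          n_samples = length(x)),
                     class = "histogram_pmf"))
  }
  edges <- seq(0, m, length.out = n_bins + 1L)
  bin <- pmin(n_bins, floor(x / (m / n_bins)) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges,
                 probabilities = counts / length(x),
                 n_samples = length(x)),
            class = "histogram_pmf")
}

# Shrink the bin count when the sample is too small to occupy 25 bins
# meaningfully.
effective_n_bins <- function(n_samples, n_bins, min_per_bin) {
  if (n_samples < min_per_bin * n_bins) {
    max(2L, as.integer(floor(n_samples / min_per_bin)))
  } else {
    as.integer(n_bins)
  }
}

#' Drop samples where the sensor was not actively loaded
#'
#' A sensor can be unloaded while the foot is on the ground (e.g. the
#' heel sensor during toe-off); residuals from such intervals carry no
#' gait information. Samples whose own normalized sensor value is below
#' `activity_threshold` are removed before histogramming.
#'
#' @param residuals Residual samples of one step.
#' @param data The step's normalized sensor data, aligned with
#'   `residuals`.
#' @param activity_threshold Normalized activity level.
#' @return The residuals at actively-loaded samples (possibly empty).
#' @export
mask_inactive <- function(residuals, data, activity_threshold = 0.05) {
  if (length(residuals) != length(data)) {
    stop("residuals and step data differ in length", call. = FALSE)
  }
  residuals[data >= activity_threshold]
}

#' Expanded-set standard deviation (sigma E')
#'
#' Measures the deviation of a set of values from zero: the set is
#' expanded with the negatives of all its elements (forcing the mean to
#' exactly zero) and the population standard deviation of the expanded
#' set is returned. Algebraically this equals the root-mean-square of
#' the original values; both routes are implemented so they can
#' cross-check each other.
#'
#' @param e Non-empty numeric vector (e.g. step-to-step entropy changes).
#' @param method `"expand"` evaluates the literal expanded-set formula;
#'   `"rms"` the root-mean-square shortcut.
#' @return The deviation (>= 0).
#' @export
sigma_e_prime <- function(e, method = c("expand", "rms")) {
  method <- match.arg(method)
  if (length(e) == 0L) stop("empty entropy series", call. = FALSE)
  if (method == "rms") return(sqrt(mean(e^2)))
  ep <- c(e, -e)
  mu <- mean(ep)
  sqrt(mean((ep - mu)^2))
}

#' Extract the 16 Tsallis-entropy gait features of one walk
#'
#' Per sensor: (a) the entire-gait entropy — Tsallis entropy of the
#' histogram of all activity-masked absolute residuals pooled across
#' steps — and (b) the stepwise deviation — per-step entropies are
#' computed from per-step histograms, their step-to-step change series
#' is formed (mode `"diff"`), and its expanded-set deviation
#' [sigma_e_prime()] taken. The feature row is ordered
#' `S0_te .. S7_te, S0_sigma .. S7_sigma`. A sensor with no
#' actively-loaded samples yields `NA` features and is flagged missing.
#'
#' @param trend_result A `step_trend` from [detrend_walk()] or
#'   [detrend_polynomial()].
#' @param params An [entropy_params()].
#' @return An `entropy_features` object: list with named vectors `te`,
#'   `sigma`, `stepwise_max` (diagnostic: largest absolute step-to-step
#'   entropy change), logical `missing`, and `q`.
#' @export
extract_features <- function(trend_result, params = entropy_params()) {
  sensors <- trend_result$sensors
  n_steps <- vapply(sensors, length, 0L)
  if (any(n_steps < 3L)) {
    stop("too few steps: need at least 3 steps per sensor for stepwise features",
         call. = FALSE)
  }
  te <- sigma <- smax <- stats::setNames(rep(NA_real_, 8L), sensor_names())
  missing <- stats::setNames(rep(FALSE, 8L), sensor_names())
  for (s in sensor_names()) {
    st <- sensors[[s]]
    use <- if (params$exclude_first_step) st[-1L] else st
    active <- lapply(use, function(step) {
      abs(mask_inactive(step$residual, step$data, params$activity_threshold))
    })
    pooled <- unlist(active, use.names = FALSE)
    if (length(pooled) == 0L) {
      missing[s] <- TRUE
      next
    }
    nb <- effective_n_bins(length(pooled), params$n_bins, params$min_samples_per_bin)
    te[s] <- tsallis_entropy(build_histogram(pooled, nb), params$q)
    shared_max <- max(pooled)
    per_step <- vapply(active, function(a) {
      if (length(a) == 0L) return(NA_real_)
      nb_k <- effective_n_bins(length(a), params$n_bins, params$min_samples_per_bin)
      hk <- if (params$per_step_range == "shared") {
        build_histogram(a, nb_k, x_max = shared_max)
      } else {
        build_histogram(a, nb_k)
      }
      tsallis_entropy(hk, params$q)
    }, 0)
    ek <- per_step[!is.na(per_step)]
    series <- if (params$stepwise_mode == "diff") diff(ek) else ek
    if (length(series) == 0L) {
      missing[s] <- TRUE
      te[s] <- NA_real_
      next
    }
    sigma[s] <- sigma_e_prime(series)
    smax[s] <- max(abs(series))
  }
  structure(list(te = te, sigma = sigma, stepwise_max = smax,
                 missing = missing, q = params$q),
            class = "entropy_features")
}

#' @export
print.entropy_features <- function(x, ...) {
  cat(sprintf("Entropy features (q = %g):\n", x$q))
  print(round(rbind(te = x$te, sigma = x$sigma), 4))
  invisible(x)
}

#' Flatten entropy features to the 16-element row
#'
#' @param features An `entropy_features` object.
#' @return Named numeric vector `S0_te .. S7_te, S0_sigma .. S7_sigma`.
#' @export
feature_row <- function(features) {
  c(stats::setNames(features$te, paste0(sensor_names(), "_te")),
    stats::setNames(features$sigma, paste0(sensor_names(), "_sigma")))
}

#' Run the full feature pipeline over a cohort
#'
#' Preprocess, detrend and extract the 16 entropy features of every
#' recording in a cohort.
#'
#' @param cohort List of `walk_recording`s.
#' @param contact A [contact_params()].
#' @param trend A [trend_params()].
#' @param entropy An [entropy_params()].
#' @param method Trend method: `"stepwise"` (the adaptive algorithm) or
#'   `"poly2"`, `"poly3"`, `"poly4"` baselines.
#' @param factor Interpolation factor.
#' @return A tibble with `subject_id`, `label` and the 16 feature
#'   columns.
#' @export
feature_table <- function(cohort,
                          contact = contact_params(),
                          trend = trend_params(),
                          entropy = entropy_params(),
                          method = c("stepwise", "poly2", "poly3", "poly4"),
                          factor = 20L) {
  method <- match.arg(method)
  rows <- lapply(cohort, function(rec) {
    steps <- preprocess_walk(rec, contact, factor)
    tr <- if (method == "stepwise") {
      detrend_walk(steps, trend)
    } else {
      detrend_polynomial(steps, as.integer(sub("poly", "", method)))
    }
    fr <- feature_row(extract_features(tr, entropy))
    tibble::as_tibble(c(list(subject_id = rec$subject_id,
                             label = as.character(rec$label)),
                        as.list(fr)))
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("healthy", "diseased"))
  out
}

#' Sweep the entropic index q against classification accuracy
#'
#' Recomputes the feature table and the cross-validated accuracy of the
#' classifier suite for each candidate q, returning the full table and
#' the best-performing q.
#'
#' @param cohort List of `walk_recording`s.
#' @param q_grid Numeric vector of candidate q values.
#' @param config An [eval_config()].
#' @param ... Passed on to [feature_table()] (contact/trend params,
#'   method, factor).
#' @param entropy Base [entropy_params()] whose q is swept.
#' @return A tibble with columns `q`, `best_accuracy`,
#'   `best_classifier`; attribute `best_q` holds the argmax.
#' @export
q_sweep <- function(cohort, q_grid, config = eval_config(), ...,
                    entropy = entropy_params()) {
  if (length(q_grid) == 0L || any(!is.finite(q_grid))) {
    stop("q_grid must be a non-empty finite vector", call. = FALSE)
  }
  rows <- lapply(q_grid, function(qv) {
    ep <- entropy
    ep$q <- qv
    feats <- feature_table(cohort, entropy = ep, ...)
    rep_ <- train_evaluate(feats, config)
    acc <- vapply(rep_$classifiers, function(cl) cl$metrics$accuracy, 0)
    tibble::tibble(q = qv,
                   best_accuracy = max(acc),
                   best_classifier = names(acc)[which.max(acc)])
  })
  out <- do.call(rbind, rows)
  attr(out, "best_q") <- out$q[which.max(out$best_accuracy)]
  out
}
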