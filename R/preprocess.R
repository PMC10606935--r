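#' Ground-contact detection parameters
#'
#' @param air_threshold Fraction of the normalized range below which the
#'   foot-wise sensor maximum is interpreted as "foot in the air".
#' @param min_segment_samples Minimum run length (samples) for a contact
#'   run to count as a stance; shorter runs are discarded as noise.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(air_threshold = 0.05, min_segment_samples = 3L) {
  if (!is.finite(air_threshold) || air_threshold <= 0 || air_threshold >= 1) {
    stop("air_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (min_segment_samples < 1L) stop("min_segment_samples must be >= 1", call. = FALSE)
  structure(list(air_threshold = air_threshold,
                 min_segment_samples = as.integer(min_segment_samples)),
            class = "contact_params")
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min(x)) / (max(x) - min(x))`; the output attains both 0 and 1.
#' A constant sequence carries no information and raises an error.
#'
#' @param x Numeric vector, length >= 2.
#' @return Normalized vector in \[0, 1\].
#' @export
normalize_minmax <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples to normalize", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("degenerate input: constant sequence cannot be min-max normalized",
         call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Normalize every channel of a recording
#'
#' @param rec A `walk_recording`.
#' @param rows Optional integer vector of sample rows over which the
#'   per-channel min and max are taken (values outside are scaled with
#'   the same affine map). Default: all rows.
#' @return The recording with each sensor channel min-max normalized.
#' @export
normalize_recording <- function(rec, rows = NULL) {
  ch <- rec$channels
  if (is.null(rows)) rows <- seq_len(nrow(ch))
  for (j in seq_len(ncol(ch))) {
    rng <- range(ch[rows, j])
    if (rng[1] == rng[2]) {
      stop(sprintf("degenerate input: channel %s is constant", colnames(ch)[j]),
           call. = FALSE)
    }
    ch[, j] <- (ch[, j] - rng[1]) / (rng[2] - rng[1])
  }
  rec$channels <- ch
  rec$units <- "normalized"
  rec
}

#' Detect per-foot ground-contact (stance) intervals
#'
#' For each foot the pointwise maximum of its four normalized channels
#' (Smax) is compared with `air_threshold`: samples with Smax below the
#' threshold are "foot in the air". Maximal runs of ground-contact
#' samples at least `min_segment_samples` long become stance intervals.
#'
#' Intervals are 1-based closed integer sample ranges `[start, end]`.
#'
#' @param rec A `walk_recording` with normalized channels.
#' @param params A [contact_params()].
#' @return A `stance_segmentation`: list with data.frames `right` and
#'   `left` (columns `start`, `end`) and attribute `n_samples`.
#' @export
detect_contact <- function(rec, params = contact_params()) {
  n <- nrow(rec$channels)
  if (is.null(n) || n == 0L) stop("empty recording", call. = FALSE)
  foot_of <- sensor_foot()
  seg <- lapply(c(right = "right", left = "left"), function(foot) {
    cols <- names(foot_of)[foot_of == foot]
    smax <- do.call(pmax, as.data.frame(rec$channels[, cols, drop = FALSE]))
    contact_runs(smax >= params$air_threshold, params$min_segment_samples)
  })
  if (nrow(seg$right) == 0L && nrow(seg$left) == 0L) {
    stop("no steps detected: every sample is below the contact threshold",
         call. = FALSE)
  }
  structure(seg, n_samples = n, class = "stance_segmentation")
}

# Maximal TRUE runs of length >= min_len, as a data.frame of closed
# 1-based [start, end] sample intervals.
contact_runs <- function(on, min_len) {
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Frame the useful part of a walk
#'
#' Gait initiation and termination lack steady-state dynamics, so the
#' first and last stance interval of each foot are dropped.
#'
#' @param seg A `stance_segmentation` with at least 3 intervals per foot.
#' @return The framed `stance_segmentation`.
#' @export
frame_walk <- function(seg) {
  framed <- lapply(seg[c("right", "left")], function(iv) {
    if (nrow(iv) < 3L) {
      stop("walk too short to frame: need at least 3 stance intervals per foot",
           call. = FALSE)
    }
    iv[-c(1L, nrow(iv)), , drop = FALSE]
  })
  structure(framed, n_samples = attr(seg, "n_samples"),
            class = "stance_segmentation")
}

#' Upsample stance segments by shape-preserving cubic Hermite interpolation
#'
#' Each stance segment of length L becomes a step of length
#' `factor * (L - 1) + 1` on a refined grid that keeps every original
#' sample exactly. Piecewise cubic Hermite (pchip) interpolation is
#' monotonicity-preserving, so the upsampled step never overshoots the
#' local data range and normalized input stays within \[0, 1\].
#'
#' @param rec Normalized `walk_recording`.
#' @param seg (Framed) `stance_segmentation`.
#' @param factor Integer refinement factor (default 20, turning a 20 Hz
#'   record into an effective 400 Hz one).
#' @return A `step_series`: list with `steps` (per sensor, a list of
#'   numeric step vectors), `rate` (effective Hz) and `factor`.
#' @export
interpolate_steps <- function(rec, seg, factor = 20L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("interpolation factor must be >= 1", call. = FALSE)
  foot_of <- sensor_foot()
  steps <- lapply(stats::setNames(nm = sensor_names()), function(s) {
    iv <- seg[[foot_of[[s]]]]
    lapply(seq_len(nrow(iv)), function(k) {
      y <- rec$channels[iv$start[k]:iv$end[k], s]
      L <- length(y)
      if (L < 2L) stop("stance segment shorter than 2 samples", call. = FALSE)
      if (factor == 1L) return(as.numeric(y))
      xi <- seq(1, L, by = 1 / factor)
      out <- pracma::pchip(seq_len(L), as.numeric(y), xi)
      # pchip is non-overshooting up to floating dust; enforce exactly
      pmin(pmax(out, min(y)), max(y))
    })
  })
  structure(list(steps = steps,
                 rate = rec$sample_rate * factor,
                 factor = factor),
            class = "step_series")
}

#' Preprocess one walk end to end
#'
#' Stages: provisional full-record normalization, per-foot contact
#' detection, framing (drop first/last steps), optional renormalization
#' of each channel over the framed time span, then 20-fold
#' shape-preserving interpolation of the retained stance segments.
#'
#' @param rec A raw `walk_recording`.
#' @param params A [contact_params()].
#' @param factor Interpolation factor.
#' @param normalize_scope `"framed"` (default) rescales each channel
#'   over the framed walk before interpolating; `"full"` keeps the
#'   full-record normalization.
#' @return A `step_series` (see [interpolate_steps()]).
#' @export
preprocess_walk <- function(rec, params = contact_params(), factor = 20L,
                            normalize_scope = c("framed", "full")) {
  normalize_scope <- match.arg(normalize_scope)
  rec_n <- normalize_recording(rec)
  seg <- frame_walk(detect_contact(rec_n, params))
  if (normalize_scope == "framed") {
    span <- range(unlist(lapply(seg[c("right", "left")], function(iv) {
      c(iv$start, iv$end)
    })))
    rec_n <- normalize_recording(rec, rows = span[1]:span[2])
    rec_n$channels <- pmin(pmax(rec_n$channels, 0), 1)
  }
  interpolate_steps(rec_n, seg, factor)
}

#' @export
print.stance_segmentation <- function(x, ...) {
  cat(sprintf("Stance segmentation: %d right / %d left intervals over %d samples\n",
              nrow(x$right), nrow(x$left), attr(x, "n_samples")))
  invisible(x)
}

#' @export
print.step_series <- function(x, ...) {
  ns <- vapply(x$steps, length, 0L)
  cat(sprintf("Step series: %s steps per sensor @ %g Hz (factor %d)\n",
              paste(range(ns), collapse = "-"), x$rate, x$factor))
  invisible(x)
}
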