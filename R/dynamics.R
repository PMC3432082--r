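#' ROI fluorescence time series
#'
#' A single ROI's mean fluorescence over time.
#'
#' @param roi_id ROI identifier.
#' @param t_s Strictly increasing sampling times in seconds (length >= 2).
#' @param F Nonnegative mean fluorescence per timepoint.
#' @param meta List of metadata (baseline window, event time, ...).
#' @return An object of class `ts_trace`.
#' @export
ts_trace <- function(roi_id, t_s, F, meta = list()) {
  stopifnot(length(t_s) == length(F), length(t_s) >= 2L,
            all(is.finite(t_s)), all(is.finite(F)), all(F >= 0),
            all(diff(t_s) > 0))
  structure(list(roi_id = roi_id, t_s = as.numeric(t_s),
                 F = as.numeric(F), meta = meta),
            class = "ts_trace")
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("<ts_trace> roi %s: %d samples over [%g, %g] s, F in [%.4g, %.4g]\n",
              format(x$roi_id), length(x$t_s), min(x$t_s), max(x$t_s),
              min(x$F), max(x$F)))
  invisible(x)
}

#' @export
as.data.frame.ts_trace <- function(x, ...) {
  data.frame(roi_id = x$roi_id, t_s = x$t_s, F = x$F)
}

#' Extract per-ROI mean time series from a time-lapse stack
#'
#' For each labeled ROI and timepoint, the mean of the pixel intensities
#' over the ROI (averaged over z as well for 4-D input).
#'
#' @param stack_t An [image_stack()] with 4-D `(t, z, y, x)` data, or a
#'   plain 3-D `(t, y, x)` array.
#' @param rois A [label_map()] or integer matrix with ROI labels `1..K`.
#' @return List of [ts_trace()], one per label, sampled at `t_s = 0, 1,
#'   ...` frame units unless `dt_s` metadata is supplied via `attr`.
#' @param dt_s Seconds per frame (default 1).
#' @export
roi_mean_timeseries <- function(stack_t, rois, dt_s = 1) {
  a <- if (inherits(stack_t, "image_stack")) stack_t$data else stack_t
  stopifnot(is.array(a), length(dim(a)) %in% c(3L, 4L))
  labels <- if (inherits(rois, "label_map")) rois$labels else rois
  d <- dim(a)
  ny <- d[length(d) - 1L]; nx <- d[length(d)]
  if (!all(dim(labels) == c(ny, nx))) {
    stop("ROI map and stack spatial shapes differ", call. = FALSE)
  }
  k <- max(labels, 0L)
  if (k == 0L) stop("empty ROI map", call. = FALSE)
  npx <- tabulate(labels[labels > 0L], k)
  if (any(npx == 0L)) {
    stop(sprintf("empty ROI label(s): %s",
                 paste(which(npx == 0L), collapse = ", ")), call. = FALSE)
  }
  nt <- d[1]
  idx <- which(labels > 0L)
  lab <- labels[idx]
  means <- matrix(0, nt, k)
  for (t in seq_len(nt)) {
    frame <- if (length(d) == 4L) {
      apply(a[t, , , , drop = FALSE][1, , , ], c(2, 3), mean)
    } else {
      a[t, , ]
    }
    means[t, ] <- as.vector(rowsum(frame[idx], lab)) / npx
  }
  lapply(seq_len(k), function(j) {
    ts_trace(roi_id = j, t_s = (seq_len(nt) - 1) * dt_s, F = means[, j],
             meta = list(n_px = npx[j]))
  })
}

# Indices of samples with t_s inside the closed window [w[1], w[2]].
window_idx <- function(ts, window, what = "window") {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  idx <- which(ts$t_s >= window[1] & ts$t_s <= window[2])
  if (length(idx) == 0L) {
    stop(sprintf("%s [%g, %g] contains no samples", what,
                 window[1], window[2]), call. = FALSE)
  }
  idx
}

#' Baseline-normalize a trace
#'
#' Divides the fluorescence by its mean over the baseline window, so the
#' normalized baseline mean is exactly 1. Idempotent on already-normalized
#' traces.
#'
#' @param ts A [ts_trace()].
#' @param baseline_window Closed time window `c(t_lo, t_hi)` in seconds.
#' @return A normalized [ts_trace()] (metadata records the window and the
#'   baseline value `f0`).
#' @export
normalize_trace <- function(ts, baseline_window) {
  stopifnot(inherits(ts, "ts_trace"))
  idx <- window_idx(ts, baseline_window, "baseline window")
  f0 <- mean(ts$F[idx])
  if (f0 <= 0) stop("zero baseline: cannot normalize", call. = FALSE)
  meta <- ts$meta
  meta$baseline_window <- baseline_window
  meta$f0 <- f0
  ts_trace(ts$roi_id, ts$t_s, ts$F / f0, meta)
}

#' Photobleaching-control correction
#'
#' Pointwise ratio of a trace to a (normalized, strictly positive) control
#' trace measured in a light-insensitive region: a trace that decays
#' identically to the control becomes constant 1.
#'
#' @param ts A [ts_trace()].
#' @param control A [ts_trace()] on the identical time grid, strictly
#'   positive.
#' @return The corrected [ts_trace()].
#' @export
bleach_correct <- function(ts, control) {
  stopifnot(inherits(ts, "ts_trace"), inherits(control, "ts_trace"))
  if (length(ts$t_s) != length(control$t_s) ||
      !isTRUE(all.equal(ts$t_s, control$t_s))) {
    stop("trace and control are on different time grids", call. = FALSE)
  }
  if (any(control$F <= 0)) {
    stop("control trace must be strictly positive", call. = FALSE)
  }
  meta <- ts$meta
  meta$bleach_corrected <- TRUE
  ts_trace(ts$roi_id, ts$t_s, ts$F / control$F, meta)
}

#' Event-evoked fluorescence change (dF/F0)
#'
#' Baseline-normalized change `(mean(post) - mean(pre)) / mean(pre)`
#' between two non-overlapping time windows (default interpretation of the
#' evoked "mean increase"); `mode = "absolute"` returns the raw difference
#' instead.
#'
#' @param ts A [ts_trace()].
#' @param pre_window,post_window Closed time windows `c(t_lo, t_hi)` in
#'   seconds, non-overlapping, each containing at least one sample. If
#'   omitted and the trace metadata carries `event_time_s`, the pre window
#'   is everything before the event and the post window the first
#'   `post_samples` samples from the event on.
#' @param post_samples Width of the default post window, in samples
#'   (default 10).
#' @param mode `"ratio"` (dF/F0, default) or `"absolute"`.
#' @return A `delta_f_result`: `roi_id`, `f_pre`, `f_post`, `delta`,
#'   `mode`.
#' @export
delta_f <- function(ts, pre_window = NULL, post_window = NULL,
                    post_samples = 10L, mode = c("ratio", "absolute")) {
  stopifnot(inherits(ts, "ts_trace"))
  mode <- match.arg(mode)
  if (is.null(pre_window) || is.null(post_window)) {
    ev <- ts$meta$event_time_s
    if (is.null(ev)) {
      stop("windows not given and no event_time_s in trace metadata",
           call. = FALSE)
    }
    if (is.null(pre_window)) pre_window <- c(ts$t_s[1], max(ts$t_s[ts$t_s < ev]))
    if (is.null(post_window)) {
      post_t <- ts$t_s[ts$t_s >= ev]
      post_window <- c(post_t[1], post_t[min(length(post_t), post_samples)])
    }
  }
  if (pre_window[2] >= post_window[1]) {
    stop("pre and post windows must not overlap", call. = FALSE)
  }
  f_pre <- mean(ts$F[window_idx(ts, pre_window, "pre window")])
  f_post <- mean(ts$F[window_idx(ts, post_window, "post window")])
  if (mode == "ratio" && f_pre <= 0) {
    stop("nonpositive baseline mean: dF/F0 undefined", call. = FALSE)
  }
  structure(list(roi_id = ts$roi_id, f_pre = f_pre, f_post = f_post,
                 delta = if (mode == "ratio") (f_post - f_pre) / f_pre
                         else f_post - f_pre,
                 mode = mode),
            class = "delta_f_result")
}

#' @export
print.delta_f_result <- function(x, ...) {
  cat(sprintf("<delta_f_result> roi %s: f_pre = %.4g, f_post = %.4g, delta (%s) = %.4g\n",
              format(x$roi_id), x$f_pre, x$f_post, x$mode, x$delta))
  invisible(x)
}

#' Dye-unloading decay fraction
#'
#' Fractional fluorescence loss between the last sample at or before the
#' event and the sample nearest the measurement time:
#' `1 - F(t_measure) / F(t_event-)`. Nearest-sample lookup, no
#' interpolation.
#'
#' @param ts A [ts_trace()].
#' @param t_event Event time in seconds.
#' @param t_measure Measurement time in seconds (> `t_event`).
#' @return Decay fraction in `(-Inf, 1]`.
#' @export
unloading_decay <- function(ts, t_event, t_measure) {
  stopifnot(inherits(ts, "ts_trace"))
  rng <- range(ts$t_s)
  if (t_event < rng[1] || t_measure > rng[2] || t_event >= t_measure) {
    stop(sprintf("event/measure times (%g, %g) outside grid [%g, %g] or misordered",
                 t_event, t_measure, rng[1], rng[2]), call. = FALSE)
  }
  pre_idx <- which(ts$t_s <= t_event)
  if (length(pre_idx) == 0L) {
    stop("no sample at or before the event time", call. = FALSE)
  }
  f_event <- ts$F[max(pre_idx)]
  if (f_event <= 0) stop("zero fluorescence at event: decay undefined",
                         call. = FALSE)
  f_measure <- ts$F[which.min(abs(ts$t_s - t_measure))]
  1 - f_measure / f_event
}
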