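# Step detection: sliding two-window mean-difference detector with robust
# (MAD-based) noise scaling. The detection statistic at frame i is
#   d[i] = mean(x[i .. i+w-1]) - mean(x[i-w .. i-1]),
# i.e. i indexes the first frame at the candidate post-step level
# (half-open convention: pre-step frames are strictly before t_step).

# Split a frame-time vector into contiguous segments; the buffer-exchange
# gaps between periods break contiguity. Returns start/end index pairs.
trace_segments <- function(time_s) {
  if (length(time_s) < 2L) return(cbind(start = 1L, end = length(time_s)))
  dt <- stats::median(diff(time_s))
  brk <- which(diff(time_s) > 1.5 * dt)
  start <- c(1L, brk + 1L)
  end <- c(brk, length(time_s))
  cbind(start = start, end = end)
}

# Robust per-trace noise SD: scaled MAD of first differences taken within
# segments only (a cross-gap difference is not noise). Var(diff) = 2 sigma^2.
robust_noise_sd <- function(x, segs) {
  d <- unlist(lapply(seq_len(nrow(segs)), function(k) {
    i <- segs[k, 1L]:segs[k, 2L]
    if (length(i) > 1L) diff(x[i]) else numeric(0)
  }), use.names = FALSE)
  stats::mad(d) / sqrt(2)
}

# Two-window mean-difference statistic within one segment.
# Returns d indexed by the first post-window frame (positions w+1 .. m-w+1).
window_diff_stat <- function(x, window) {
  m <- length(x)
  cs <- c(0, cumsum(x))
  i <- (window + 1L):(m - window + 1L)
  post <- (cs[i + window] - cs[i]) / window
  pre <- (cs[i] - cs[i - window]) / window
  list(pos = i, d = post - pre)
}

# Greedy non-maximum suppression: keep highest-statistic candidates first,
# discard any candidate within `window` frames of an accepted one.
select_peaks <- function(pos, d, thr, window) {
  cand <- which(d > thr)
  if (length(cand) == 0L) return(integer(0))
  # local maxima of the statistic among threshold crossings
  keep <- cand[vapply(cand, function(j) {
    lo <- max(1L, j - 1L); hi <- min(length(d), j + 1L)
    d[j] >= max(d[lo:hi])
  }, logical(1))]
  keep <- keep[order(d[keep], decreasing = TRUE)]
  acc <- integer(0)
  for (j in keep) {
    if (all(abs(pos[j] - pos[acc]) >= window) || length(acc) == 0L)
      acc <- c(acc, j)
  }
  sort(pos[acc])
}

# Core detector: the two windows slide over the concatenated frame
# sequence. Fluorescence levels persist across the unsampled 5-s
# buffer-exchange gaps, so a pre-step window may validly end in the
# previous period; the reported step time is always a sampled frame, so
# no step is ever placed inside a gap. direction = +1 finds upward steps,
# -1 downward. Returns integer frame indices.
detect_steps_core <- function(x, window, thr, direction = 1) {
  st <- window_diff_stat(direction * x, window)
  select_peaks(st$pos, st$d, thr, window)
}

#' Detect stepwise intensity increases in a fluorescence trace
#'
#' Slides two adjacent `window`-frame means along the trace and reports
#' upward steps where the trailing-minus-leading mean difference exceeds
#' `max(threshold_k * sigma_hat, min_amplitude)`, with `sigma_hat` a robust
#' per-trace noise estimate (scaled median absolute deviation of first
#' differences, taken within periods). The windows slide over the
#' concatenated frames: fluorescence levels persist across the unsampled
#' buffer-exchange gaps, so a step just after a gap is still detected, and
#' a level change occurring during a gap is reported at the first frame of
#' the following period — a step time is always a sampled frame, never
#' inside a gap. Downward steps are detected internally and cause the
#' trace to be flagged for exclusion (attribute `flagged_down`), but are
#' never returned as events.
#'
#' @param trace Data frame with columns `time_s` (strictly increasing,
#'   uniformly sampled within each period) and `intensity` (finite).
#' @param window Frames per comparison window (>= 3).
#' @param threshold_k Detection threshold in noise-SD multiples (> 0).
#' @param min_amplitude Minimum step amplitude in intensity units.
#' @return Data frame with columns `t_step` (time of the first frame at the
#'   post-step level), `amplitude` (post-mean minus pre-mean over the local
#'   windows) and `score` (amplitude in noise-SD units), sorted by `t_step`,
#'   with attribute `flagged_down` (logical: a downward step above threshold
#'   was present).
#' @examples
#' tr <- data.frame(time_s = seq(0, 19.9, 0.1),
#'                  intensity = rep(c(100, 200), each = 100))
#' detect_steps(tr)   # one step at t = 10
#' @export
detect_steps <- function(trace, window = 10L, threshold_k = 4,
                         min_amplitude = 0) {
  if (!all(c("time_s", "intensity") %in% names(trace)))
    stop("trace must have columns 'time_s' and 'intensity'")
  x <- trace$intensity
  t <- trace$time_s
  if (length(x) < 2L) stop("trace must have at least 2 samples")
  if (any(!is.finite(x))) stop("non-finite intensities in trace")
  if (is.unsorted(t, strictly = TRUE)) stop("time_s must be strictly increasing")
  window <- as.integer(window)
  if (window < 3L) stop("window must be >= 3 frames")
  if (threshold_k <= 0) stop("threshold_k must be > 0")
  if (length(x) < 2L * window)
    stop("trace shorter than 2*window frames")

  segs <- trace_segments(t)
  sigma <- robust_noise_sd(x, segs)
  thr <- max(threshold_k * sigma, min_amplitude)

  up <- detect_steps_core(x, window, thr, direction = 1)
  down <- detect_steps_core(x, window, thr, direction = -1)

  amp <- vapply(up, function(i) {
    mean(x[i:(i + window - 1L)]) - mean(x[(i - window):(i - 1L)])
  }, numeric(1))
  res <- data.frame(t_step = t[up], amplitude = amp,
                    score = amp / max(sigma, .Machine$double.eps))
  res <- res[order(res$t_step), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "flagged_down") <- length(down) > 0L
  res
}

#' Detect the Ca2+/Cy5 arrival time in the injection-indicator channel
#'
#' The injected Ca2+ solution carries soluble Cy5 dye; its arrival in the
#' evanescent field appears as a sustained step in the Cy5 channel. The
#' baseline is estimated from the last `baseline_window` frames before the
#' triggered period (or the first `baseline_window` frames when no schedule
#' is given); the arrival time is the earliest frame whose intensity exceeds
#' baseline mean + `threshold_k` * baseline SD and whose next
#' `sustain_window` frames all remain above that threshold.
#'
#' @param cy5_trace Data frame with columns `time_s`, `intensity`.
#' @param baseline_window Frames used for the baseline estimate.
#' @param threshold_k Threshold in baseline-SD multiples.
#' @param sustain_window Frames of sustained elevation required after the
#'   candidate arrival frame.
#' @param schedule Optional [acquisition_schedule()]; when given, the
#'   baseline window ends at `trig_start` and only frames at or after
#'   `spont_end` are candidates.
#' @return Arrival time `t_Ca` in seconds (time of the first elevated frame).
#' @examples
#' t <- seq(125, 189.9, 0.1)
#' cy <- data.frame(time_s = t, intensity = ifelse(t >= 130, 250, 50))
#' detect_arrival_time(cy)
#' @export
detect_arrival_time <- function(cy5_trace, baseline_window = 50L,
                                threshold_k = 4, sustain_window = 10L,
                                schedule = NULL) {
  if (!all(c("time_s", "intensity") %in% names(cy5_trace)))
    stop("cy5_trace must have columns 'time_s' and 'intensity'")
  x <- cy5_trace$intensity
  t <- cy5_trace$time_s
  if (any(!is.finite(x))) stop("non-finite intensities in cy5 trace")

  if (!is.null(schedule)) {
    pre <- which(t < schedule$trig_start)
    cand_from <- schedule$spont_end
  } else {
    pre <- seq_len(min(baseline_window, length(x)))
    cand_from <- t[min(baseline_window + 1L, length(t))]
  }
  if (length(pre) < baseline_window)
    stop("fewer than baseline_window frames available before the triggered period")
  pre <- utils::tail(pre, baseline_window)
  mu <- mean(x[pre])
  sdv <- stats::sd(x[pre])
  thr <- mu + threshold_k * max(sdv, .Machine$double.eps)

  cand <- which(t >= cand_from & x > thr)
  cand <- cand[cand > max(pre)]
  for (i in cand) {
    j <- (i + 1L):min(i + sustain_window, length(x))
    if (i == length(x) || all(x[j] > thr)) return(t[i])
  }
  stop("no injection detected")
}
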