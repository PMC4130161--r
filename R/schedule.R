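#' Acquisition schedule for a three-period single-vesicle experiment
#'
#' Defines the timing of the assay: a 1-min vesicle association period,
#' a 1-min spontaneous-fusion observation period, and a 1-min
#' Ca2+-triggered-fusion period, separated by short buffer-exchange gaps
#' during which no frames are recorded. The Ca2+/Cy5 injection time
#' `t_inject` falls in the boundary region between the end of the
#' spontaneous period and the start of the triggered period.
#'
#' @param frame_interval Seconds per frame (default 0.1 s, i.e. 10 Hz).
#' @param period_length Length of each observation period in seconds.
#' @param gap Buffer-exchange gap between periods in seconds (no frames).
#' @param assoc_start Start time of the association period, seconds.
#' @param t_inject Injection time in seconds; must lie in
#'   `[spont_end, trig_start]` and before `trig_end`. Defaults to
#'   `trig_start`.
#'
#' @return An object of class `"sv_schedule"`: a list with fields
#'   `frame_interval`, `assoc_start`, `assoc_end`, `spont_start`,
#'   `spont_end`, `trig_start`, `trig_end`, `gap`, `t_inject`.
#' @examples
#' sched <- acquisition_schedule()
#' sched$trig_start   # 130 s with the defaults
#' @export
acquisition_schedule <- function(frame_interval = 0.1,
                                 period_length = 60,
                                 gap = 5,
                                 assoc_start = 0,
                                 t_inject = NULL) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("invalid schedule field 'frame_interval': must be a positive number")
  if (!is.numeric(period_length) || period_length <= 0)
    stop("invalid schedule field 'period_length': must be positive")
  if (!is.numeric(gap) || gap < 0)
    stop("invalid schedule field 'gap': must be non-negative")

  assoc_end   <- assoc_start + period_length
  spont_start <- assoc_end + gap
  spont_end   <- spont_start + period_length
  trig_start  <- spont_end + gap
  trig_end    <- trig_start + period_length
  if (is.null(t_inject)) t_inject <- trig_start

  s <- structure(list(
    frame_interval = frame_interval,
    assoc_start = assoc_start, assoc_end = assoc_end,
    spont_start = spont_start, spont_end = spont_end,
    trig_start = trig_start, trig_end = trig_end,
    gap = gap, t_inject = t_inject
  ), class = "sv_schedule")
  validate_schedule(s)
  s
}

validate_schedule <- function(s) {
  stopifnot(inherits(s, "sv_schedule") || is.list(s))
  num1 <- function(field) {
    v <- s[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("invalid schedule field '%s'", field))
    v
  }
  for (f in c("frame_interval", "assoc_start", "assoc_end", "spont_start",
              "spont_end", "trig_start", "trig_end", "gap", "t_inject"))
    num1(f)
  if (s$frame_interval <= 0)
    stop("invalid schedule field 'frame_interval': must be > 0")
  if (!(s$assoc_start < s$assoc_end && s$assoc_end <= s$spont_start &&
        s$spont_start < s$spont_end && s$spont_end <= s$trig_start &&
        s$trig_start < s$trig_end))
    stop("invalid schedule: period boundaries must be ordered ",
         "assoc_start < assoc_end <= spont_start < spont_end <= trig_start < trig_end")
  if (s$t_inject < s$spont_end || s$t_inject > s$trig_start)
    stop("invalid schedule field 't_inject': must lie in [spont_end, trig_start]")
  if (s$t_inject >= s$trig_end)
    stop("invalid schedule field 't_inject': must be < trig_end")
  invisible(s)
}

#' @export
print.sv_schedule <- function(x, ...) {
  cat("Acquisition schedule (seconds):\n")
  cat(sprintf("  association period: [%g, %g)\n", x$assoc_start, x$assoc_end))
  cat(sprintf("  spontaneous period: [%g, %g)\n", x$spont_start, x$spont_end))
  cat(sprintf("  triggered period:   [%g, %g)\n", x$trig_start, x$trig_end))
  cat(sprintf("  gap %g s, frame interval %g s, injection at %g s\n",
              x$gap, x$frame_interval, x$t_inject))
  invisible(x)
}

# Frame times for the three sampled periods (no frames inside the gaps).
# Each period is sampled half-open: [start, end).
schedule_times <- function(s) {
  per <- function(a, b) seq(a, b - s$frame_interval / 2, by = s$frame_interval)
  list(assoc = per(s$assoc_start, s$assoc_end),
       spont = per(s$spont_start, s$spont_end),
       trig  = per(s$trig_start, s$trig_end))
}

# Which period does a time point fall in? Returns "assoc", "spont", "trig"
# or NA (gap / outside).
period_of <- function(t, s) {
  out <- rep(NA_character_, length(t))
  out[t >= s$assoc_start & t < s$assoc_end] <- "assoc"
  out[t >= s$spont_start & t < s$spont_end] <- "spont"
  out[t >= s$trig_start  & t < s$trig_end]  <- "trig"
  out
}
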