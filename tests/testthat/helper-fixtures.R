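# Shared fixture builders: all synthetic, generated in code at test time.

default_sched <- acquisition_schedule()

# A uniformly sampled single-period trace.
flat_trace <- function(n = 200, level = 100, dt = 0.1, t0 = 0) {
  data.frame(time_s = t0 + (seq_len(n) - 1) * dt,
             intensity = rep(level, n))
}

# Plant upward steps: `at` are 1-based frame indices of the first elevated
# frame; each step adds `amp` from that frame onward.
plant_steps <- function(trace, at, amp) {
  for (k in seq_along(at))
    trace$intensity[at[k]:nrow(trace)] <-
      trace$intensity[at[k]:nrow(trace)] + amp[k]
  trace
}

# One-row vesicle record matching the classify_trace output schema.
make_record <- function(spot_id, fate, assoc_time = 20,
                        fusion_time = NA_real_, latency = NA_real_,
                        reason = NA_character_) {
  data.frame(spot_id = spot_id, assoc_time = assoc_time, fate = fate,
             fusion_time = fusion_time, latency = latency,
             exclusion_reason = reason, n_extra_steps = 0L,
             stringsAsFactors = FALSE)
}

# Event table with given triggered latencies / spontaneous offsets among
# n_assoc associated vesicles, built through the package constructor.
table_from_events <- function(n_assoc, trig_latency = numeric(0),
                              spont_offset = numeric(0),
                              sched = default_sched,
                              t_Ca = sched$trig_start) {
  n_ev <- length(trig_latency) + length(spont_offset)
  stopifnot(n_ev <= n_assoc)
  recs <- list()
  id <- 0
  for (lat in trig_latency) {
    id <- id + 1
    recs[[id]] <- make_record(id, "triggered",
                              fusion_time = t_Ca + lat, latency = lat)
  }
  for (off in spont_offset) {
    id <- id + 1
    recs[[id]] <- make_record(id, "spontaneous",
                              fusion_time = sched$spont_start + off)
  }
  for (k in seq_len(n_assoc - n_ev)) {
    id <- id + 1
    recs[[id]] <- make_record(id, "no_fusion")
  }
  build_event_table(do.call(rbind, recs), condition = "fixture",
                    round_id = "r1", t_Ca = t_Ca, schedule = sched)
}

# Histogram object holding an exact model curve (for noiseless fit tests).
model_histogram <- function(A, lambda, n_bins = 60, bin_width = 1,
                            which = "triggered") {
  k <- 0:(n_bins - 1)
  y <- A * exp(-lambda * k * bin_width)
  structure(list(which = which, bin_width = bin_width, left = k * bin_width,
                 counts = y, normalized = y,
                 n_associated = 1L, n_events = n_bins),
            class = "fusion_histogram")
}
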