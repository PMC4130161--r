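step_df <- function(t) data.frame(t_step = t, amplitude = rep(100, length(t)),
                                  score = rep(10, length(t)))

test_that("cascade rules assign the documented fates", {
  s <- default_sched
  tca <- 130.2

  r <- classify_trace(step_df(20), s, tca)
  expect_equal(r$fate, "no_fusion")
  expect_equal(r$assoc_time, 20)

  r <- classify_trace(step_df(c(20, 90)), s, tca)
  expect_equal(r$fate, "spontaneous")
  expect_equal(r$fusion_time, 90)

  r <- classify_trace(step_df(c(20, 131.5)), s, tca)
  expect_equal(r$fate, "triggered")
  expect_equal(r$latency, 1.3, tolerance = 1e-9)
})

test_that("exclusion rules fire with their reasons", {
  s <- default_sched
  r <- classify_trace(step_df(numeric(0)), s, 130.2)
  expect_equal(r$fate, "excluded")
  expect_equal(r$exclusion_reason, "no association")

  r <- classify_trace(step_df(c(10, 40)), s, 130.2)
  expect_equal(r$exclusion_reason, "multiple association-period steps")

  r <- classify_trace(step_df(c(20, 130.05)), s, 130.2)
  expect_equal(r$exclusion_reason, "pre-injection step in triggered period")
})

test_that("spontaneous fusion wins over later triggered-period steps", {
  r <- classify_trace(step_df(c(20, 90, 135)), default_sched, 130.2)
  expect_equal(r$fate, "spontaneous")
  expect_equal(r$fusion_time, 90)
  expect_equal(r$n_extra_steps, 1L)
})

test_that("invalid classification inputs are rejected", {
  expect_error(classify_trace(step_df(20), default_sched, 100), "t_Ca")
  expect_error(classify_trace(step_df(c(90, 20)), default_sched, 130.2),
               "sorted")
})

test_that("every random step list yields exactly one fate (partition property)", {
  set.seed(314)
  s <- default_sched
  fates <- character(2000)
  for (i in 1:2000) {
    n <- sample(0:5, 1)
    t <- sort(runif(n, 0, 190))
    tca <- runif(1, s$trig_start, s$trig_start + 5)
    r <- classify_trace(step_df(t), s, tca)
    fates[i] <- r$fate
    # excluded iff a reason is recorded
    expect_identical(r$fate == "excluded", !is.na(r$exclusion_reason))
    if (r$fate == "spontaneous")
      expect_true(r$fusion_time >= s$spont_start && r$fusion_time < s$spont_end)
    if (r$fate == "triggered") {
      expect_gte(r$latency, 0)
      expect_true(r$fusion_time >= tca && r$fusion_time < s$trig_end)
    }
  }
  expect_true(all(fates %in% c("excluded", "no_fusion", "spontaneous",
                               "triggered")))
  expect_equal(sum(table(fates)), 2000)
})

test_that("event tables tally fates and keep excluded records for audit", {
  recs <- rbind(
    do.call(rbind, lapply(1:6, make_record, fate = "no_fusion")),
    make_record(7, "spontaneous", fusion_time = 90),
    make_record(8, "triggered", fusion_time = 131, latency = 1),
    make_record(9, "triggered", fusion_time = 132, latency = 2),
    make_record(10, "excluded", assoc_time = NA_real_,
                reason = "no association"))
  tab <- build_event_table(recs, "cond", "r1", t_Ca = 130,
                           schedule = default_sched)
  expect_equal(tab$n_associated, 9)
  expect_equal(tab$n_spontaneous, 1)
  expect_equal(tab$n_triggered, 2)
  expect_equal(tab$n_excluded, 1)
  expect_equal(nrow(tab$records), 10)

  empty <- build_event_table(recs[0, ], "cond", "r1", t_Ca = 130,
                             schedule = default_sched)
  expect_equal(empty$n_associated, 0)
  expect_error(build_event_table(rbind(recs, recs[1, ]), "cond", "r1", 130,
                                 default_sched), "duplicate")
})

test_that("merging rounds sums counts and preserves provenance", {
  t1 <- table_from_events(50, trig_latency = c(1, 2))
  t2 <- local({
    recs <- do.call(rbind, lapply(1:40, make_record, fate = "no_fusion"))
    build_event_table(recs, "fixture", "r2", t_Ca = default_sched$trig_start,
                      schedule = default_sched)
  })
  m <- merge_rounds(list(t1, t2))
  expect_equal(m$n_associated, 90)
  expect_equal(m$n_triggered, 2)
  expect_equal(sort(names(m$t_Ca)), c("r1", "r2"))
  expect_equal(nrow(per_round_counts(m)), 2)

  expect_identical(merge_rounds(list(t1)), t1)
  t3 <- t2; t3$condition <- "other"
  expect_error(merge_rounds(list(t1, t3)), "mixed conditions")
})

test_that("five synthetic rounds merge to the sum of their truth tallies", {
  tabs <- lapply(1:5, function(r) {
    ex <- simulate_experiment(
      ground_truth(n_spots = 60, p_assoc = 1, k_spont = 0.005, p_trig = 0.4,
                   seed = 100 + r))
    analyze_experiment(ex, condition = "merge-check",
                       round_id = paste0("r", r))
  })
  m <- merge_rounds(tabs)
  expect_equal(m$n_associated, sum(vapply(tabs, `[[`, numeric(1), "n_associated")))
  expect_equal(m$n_spontaneous, sum(vapply(tabs, `[[`, numeric(1), "n_spontaneous")))
  expect_equal(nrow(m$records), 300)
})

test_that("noiseless synthetic fates are recovered away from period edges", {
  tr <- ground_truth(n_spots = 300, p_assoc = 0.8, k_spont = 0.01,
                     p_trig = 0.5, sigma_noise = 0, seed = 55)
  ex <- simulate_experiment(tr)
  tab <- analyze_experiment(ex, condition = "noiseless")
  s <- ex$schedule
  w <- 10L   # detection window, frames
  # a windowed detector needs w frames on both sides of a step in the
  # concatenated frame grid, and two steps closer than w frames cannot
  # both be resolved
  # first frame at or after the true event time (the first elevated frame)
  first_frame <- function(t) {
    i <- findInterval(t, ex$time_s)
    ifelse(!is.na(t) & t > ex$time_s[pmax(i, 1L)], i + 1L, i)
  }
  n_frames <- length(ex$time_s)
  # an event is clean when its step manifests inside the same period it
  # occurred in (not carried across a gap to the next period's first frame)
  same_period <- function(ff, t)
    !is.na(t) & ff <= n_frames &
      svfusion:::period_of(ex$time_s[pmin(ff, n_frames)], s) ==
        svfusion:::period_of(t, s)
  ok <- with(ex$truth, {
    fa <- first_frame(truth_assoc_time)
    ff <- first_frame(truth_fusion_time)
    ifelse(truth_fate == "never_associated", TRUE,
           fa > w & fa <= n_frames - w & same_period(fa, truth_assoc_time) &
             (is.na(ff) |
                (ff > w & ff <= n_frames - w & ff - fa >= w &
                   same_period(ff, truth_fusion_time))))
  })
  got <- tab$records$fate
  want <- ifelse(ex$truth$truth_fate == "never_associated", "excluded",
                 ex$truth$truth_fate)
  expect_true(all(got[ok] == want[ok]))
  # events are rarely near an edge, so recovery is near-total overall
  expect_gte(mean(ok), 0.95)
})
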