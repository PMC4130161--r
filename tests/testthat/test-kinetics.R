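test_that("histogram counts and normalizes events per associated vesicle", {
  tab <- table_from_events(100, trig_latency = c(0.4, 0.7))
  h <- fusion_histogram(tab, "triggered")
  expect_equal(h$normalized[1], 0.02)
  expect_equal(sum(h$normalized[-1]), 0)
  expect_equal(length(h$counts), 60)

  # conservation: sum of normalized bins = events / n_associated exactly
  tab2 <- table_from_events(80, trig_latency = runif(12, 0, 59),
                            spont_offset = runif(5, 0, 59))
  expect_equal(sum(fusion_histogram(tab2, "triggered")$normalized), 12 / 80)
  expect_equal(sum(fusion_histogram(tab2, "spontaneous")$normalized), 5 / 80)

  empty <- table_from_events(50)
  expect_equal(sum(fusion_histogram(empty, "triggered")$counts), 0)
  expect_error(fusion_histogram(build_event_table(
    make_record(1, "excluded", reason = "no association")[0, ], "c", "r1",
    130, default_sched), "triggered"), "n_associated")
})

test_that("an event exactly at the origin falls in bin 0 (half-open bins)", {
  tab <- table_from_events(10, trig_latency = c(0, 0.999, 1.0))
  h <- fusion_histogram(tab, "triggered")
  expect_equal(h$counts[1:2], c(2, 1))
})

test_that("exponential latencies fill bins with the closed-form mass", {
  lam <- 0.5; n <- 10000
  set.seed(8)
  lat <- rexp(n * 1.2, lam); lat <- lat[lat < 60][1:n]
  tab <- table_from_events(n, trig_latency = lat)
  h <- fusion_histogram(tab, "triggered")
  k <- 0:19
  p <- exp(-lam * k) - exp(-lam * (k + 1))
  for (j in seq_along(k)) {
    tol <- 3 * sqrt(p[j] * (1 - p[j]) / n)
    expect_lt(abs(h$normalized[j] - p[j]), tol)
  }
})

test_that("noiseless model histograms are recovered to machine precision", {
  # generating values from the two printed experimental conditions
  for (par in list(c(A = 0.017, lambda = 0.43), c(A = 0.006, lambda = 0.11))) {
    fit <- fit_exponential_decay(model_histogram(par["A"], par["lambda"]))
    expect_equal(fit$lambda, unname(par["lambda"]), tolerance = 1e-6)
    expect_equal(fit$A, unname(par["A"]), tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("fitted rate agrees with the exponential MLE on sampled latencies", {
  set.seed(15)
  lat <- rexp(1000, 0.5); lat <- lat[lat < 60]
  tab <- table_from_events(length(lat), trig_latency = lat)
  fit <- fit_exponential_decay(fusion_histogram(tab, "triggered"))
  mle <- 1 / mean(lat)    # closed-form exponential MLE as oracle
  expect_lt(abs(fit$lambda - mle), 3 * fit$se_lambda)
  expect_gt(fit$se_lambda, 0)
  expect_gt(fit$se_A, 0)
})

test_that("sparse histograms are rejected as insufficient", {
  tab <- table_from_events(100, trig_latency = c(0.5, 0.6, 1.5))
  expect_error(fit_exponential_decay(fusion_histogram(tab, "triggered")),
               "insufficient events")
})

test_that("decay-fit methods expose coefficients, predictions and residuals", {
  h <- model_histogram(0.017, 0.43)
  fit <- fit_exponential_decay(h)
  expect_equal(unname(coef(fit)), c(fit$A, fit$lambda))
  expect_equal(predict(fit, 0), fit$A, tolerance = 1e-9)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_output(print(fit), "lambda")
})

test_that("spontaneous rate reproduces the per-second and per-period forms", {
  tab <- table_from_events(1000, spont_offset = runif(12, 0, 59))
  r <- spontaneous_rate(tab)
  expect_equal(r$per_second, 0.0002)          # 12 / (1000 * 60 s)
  expect_equal(r$percent_per_second, 0.02)
  expect_equal(r$per_period, 0.012)

  expect_equal(spontaneous_rate(table_from_events(50))$per_second, 0)
})

test_that("spontaneous rate estimates a small hazard within binomial error", {
  k <- 1e-3; n <- 5000
  ex <- simulate_experiment(
    ground_truth(n_spots = n, p_assoc = 1, k_spont = k, p_trig = 0, seed = 9))
  # classify from ground truth (sampling error only, no detection error)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    f <- ex$truth$truth_fate[i]
    make_record(i, ifelse(f == "spontaneous", "spontaneous", "no_fusion"),
                assoc_time = ex$truth$truth_assoc_time[i],
                fusion_time = ex$truth$truth_fusion_time[i])
  }))
  tab <- build_event_table(recs, "sim", "r1", default_sched$trig_start,
                           default_sched)
  p60 <- 1 - exp(-k * 60)
  tol <- 3 * sqrt(p60 * (1 - p60) / n) / 60
  expect_lt(abs(spontaneous_rate(tab)$per_second - k), tol)
})

test_that("first-bin amplitude returns both normalizations", {
  tab <- table_from_events(100, trig_latency = c(0.4, 0.7, 1.5, 2.5))
  a <- first_bin_amplitude(fusion_histogram(tab, "triggered"))
  expect_equal(a$per_associated, 0.02)
  expect_equal(a$per_fusion_event, 0.5)
  expect_equal(first_bin_amplitude(model_histogram(0.017, 0.43))$per_associated,
               0.017)
  expect_error(first_bin_amplitude(fusion_histogram(table_from_events(10),
                                                    "triggered")),
               "empty histogram")
})

test_that("triggered-to-spontaneous ratios reproduce the worked arithmetic", {
  expect_equal(triggered_to_spontaneous_ratio(0.017, 0.0002), 85)
  expect_equal(triggered_to_spontaneous_ratio(0.006, 0.001), 6)
  expect_equal(triggered_to_spontaneous_ratio(0.3, 0.3), 1)
  expect_error(triggered_to_spontaneous_ratio(0.017, 0), "undefined ratio")
  # identity: ratio(a, b, 1) * b = a
  set.seed(2)
  for (i in 1:50) {
    a <- runif(1); b <- runif(1, 1e-6, 1)
    expect_equal(triggered_to_spontaneous_ratio(a, b, 1) * b, a)
  }
})

test_that("condition comparison behaves at the degenerate extremes", {
  same <- compare_conditions(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  set.seed(4)
  sep <- compare_conditions(10 + rnorm(3, 0, 1e-3), rnorm(3, 0, 1e-3))
  expect_lt(sep$p_value, 0.01)
  expect_true(sep$significant)

  expect_error(compare_conditions(1, c(1, 2)), "2 replicates")
})

test_that("comparison matches the pooled-variance t.test", {
  set.seed(5)
  a <- rnorm(8); b <- rnorm(6, 0.5)
  cmp <- compare_conditions(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$t, unname(ref$statistic))
  expect_equal(cmp$p_value, ref$p.value)
  expect_equal(cmp$df, 12)
  expect_equal(cmp$sd_a, sd(a))
})
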