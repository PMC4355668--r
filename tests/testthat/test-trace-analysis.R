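flat_trace <- function(n = 30, dt = 3.3, noise = 0, seed = 1, slope_nm_min = 0) {
  tt <- (0:(n - 1)) * dt
  len <- slope_nm_min * tt / 1000
  if (noise > 0) len <- len + withr::with_seed(seed, stats::rnorm(n, 0, noise / 1000))
  data.frame(fibril_id = "f1", time_min = tt, length_um = len)
}

test_that("segmentation classifies pure stop and pure go traces", {
  seg_stop <- segment_trace(flat_trace(), v_thresh = 10)
  expect_equal(nrow(seg_stop), 1L)
  expect_equal(seg_stop$state, "stop")

  seg_go <- segment_trace(flat_trace(slope_nm_min = 100), v_thresh = 10)
  expect_equal(nrow(seg_go), 1L)
  expect_equal(seg_go$state, "go")
  expect_gt(seg_go$delta_length, 0)

  expect_error(segment_trace(flat_trace(n = 3)))
  expect_error(segment_trace(flat_trace(n = 10), smooth_window = 4))
  tr_bad <- flat_trace()
  tr_bad$time_min[5] <- tr_bad$time_min[5] + 0.5
  expect_error(segment_trace(tr_bad))
})

test_that("segments tile the trace without gaps or overlap", {
  sim <- gen_two_state_trace(0.1, 0.03, v_go = 100, total_t = 2000, seed = 6)
  seg <- segment_trace(sim$trace)
  expect_equal(seg$t_start[1], min(sim$trace$time_min))
  expect_equal(seg$t_end[nrow(seg)], max(sim$trace$time_min))
  if (nrow(seg) > 1) {
    expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])
  }
  expect_true(all(seg$duration > 0))
  # alternating states after run merging
  expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
})

test_that("segmentation recovers the realized go fraction of a synthetic trace", {
  sim <- gen_two_state_trace(0.1, 0.03, v_go = 100, total_t = 3000,
                             noise_sd = 50, seed = 42)
  # threshold midway between the stasis and growth speeds (the pipeline's
  # adaptive rule lands here too)
  seg <- segment_trace(sim$trace, v_thresh = 50)
  go_frac <- sum(seg$duration[seg$state == "go"]) / sum(seg$duration)
  expect_lt(abs(go_frac - sim$truth$go_fraction), 0.05)
})

test_that("dwell fit recovers exact and sampled exponential rates", {
  # survival counts in exact geometric progression: a line through exact
  # points, slope recovered to machine precision
  dur <- rep(1:6, times = c(16, 8, 4, 2, 1, 1))
  f_exact <- suppressWarnings(fit_dwell_exponential(dur))
  expect_equal(f_exact$k, log(2), tolerance = 1e-10)
  expect_equal(f_exact$a, 64, tolerance = 1e-8)

  d <- gen_dwell_sample(0.1, 1000, seed = 5)
  f <- fit_dwell_exponential(d)
  expect_lt(abs(f$k - 0.1) / 0.1, 0.10)
  f_mle <- fit_dwell_exponential(d, method = "mle")
  expect_lt(abs(f_mle$k - 0.1) / 0.1, 0.10)

  # stop durations at the 1.5 mg/mL published rate are recovered within
  # the fit uncertainty
  d2 <- gen_dwell_sample(0.113, 800, seed = 9)
  f2 <- fit_dwell_exponential(d2)
  expect_lt(abs(f2$k - 0.113), 3 * max(f2$k_err, 0.113 / sqrt(800)))

  expect_error(fit_dwell_exponential(c(1, 2, 3)))          # too few
  expect_error(fit_dwell_exponential(rep(2, 50)))          # all equal
})

test_that("growth probability and its error match the published arithmetic", {
  # consistent rows of the published switching-rate table
  expect_equal(round(growth_probability(0.113, 0.0268), 3), 0.808)
  expect_equal(round(growth_probability(0.306, 0.0444), 3), 0.873)
  expect_equal(growth_probability(0.3, 0.3), 0.5)
  expect_error(growth_probability(0, 0))

  expect_equal(round(growth_probability_error(0.113, 0.025, 0.0268, 0.0005), 3), 0.034)
  expect_equal(round(growth_probability_error(0.046, 0.020, 0.0113, 0.0002), 3), 0.069)
  expect_equal(growth_probability_error(0.1, 0, 0.05, 0), 0)

  # scale invariance of both formulas under k -> c k, sigma -> c sigma
  for (c_scale in c(0.1, 3, 42)) {
    expect_equal(growth_probability(0.08 * c_scale, 0.03 * c_scale),
                 growth_probability(0.08, 0.03))
    expect_equal(growth_probability_error(0.08 * c_scale, 0.01 * c_scale,
                                          0.03 * c_scale, 0.004 * c_scale),
                 growth_probability_error(0.08, 0.01, 0.03, 0.004))
  }
})

test_that("segment speeds and histograms follow their conventions", {
  seg <- tibble::tibble(state = c("go", "stop", "go"),
                        t_start = c(0, 10, 40), t_end = c(10, 40, 50),
                        duration = c(10, 30, 10),
                        delta_length = c(1, 0.01, 0.25))
  sp <- segment_speeds(seg)
  expect_equal(sp, c(100, 25))  # stop segments contribute nothing

  h <- speed_histogram(c(5, 15, 15))
  expect_equal(h$count[h$bin_left == 0], 1L)
  expect_equal(h$count[h$bin_left == 10], 2L)
  expect_equal(nrow(speed_histogram(numeric(0))), 0L)
  expect_warning(segment_speeds(seg[seg$state == "stop", ]))

  # conservation under random inputs, negatives excluded
  sp_r <- withr::with_seed(3, stats::rnorm(500, 60, 60))
  h_r <- suppressMessages(speed_histogram(sp_r))
  expect_equal(sum(h_r$count), sum(sp_r >= 0))
})

test_that("long-pause trimming is explicit and count-accurate", {
  r0 <- trim_long_pauses(c(1, 2, 3), max_duration = Inf)
  expect_equal(r0$removed_count, 0)
  expect_equal(r0$kept, c(1, 2, 3))

  r1 <- suppressMessages(trim_long_pauses(c(1, 2, 3, 1000), max_duration = 100))
  expect_equal(r1$kept, c(1, 2, 3))
  expect_equal(r1$removed_count, 1)

  # three injected outliers at 50/k removed under the 0.995 quantile policy
  d <- c(gen_dwell_sample(0.1, 600, seed = 2), rep(50 / 0.1, 3))
  r2 <- suppressMessages(trim_long_pauses(d, quantile_policy = 0.995))
  expect_equal(r2$removed_count, 3)
})

test_that("the full pipeline recovers p_G across switching-rate ratios", {
  # ratios k_sg/k_gs of 0.3, 1, 3, 10 at scales slow enough for ~200+
  # events per state within a modest simulated cohort
  cases <- list(c(0.009, 0.03), c(0.03, 0.03), c(0.06, 0.02), c(0.1, 0.01))
  for (i in seq_along(cases)) {
    k_sg <- cases[[i]][1]
    k_gs <- cases[[i]][2]
    traces <- two_state_traces(k_sg, k_gs, v_go = 100, cycles = 550,
                               n_fib = 8, seed0 = 500 * i)
    rs <- stopgo_rates(traces, calib_n_rep = 80, calib_seed = 17,
                       refine_iterations = 2, refine_cycles = 2500)
    expect_lt(abs(rs$p_g - k_sg / (k_sg + k_gs)), 0.03)
    expect_gte(rs$n_stop, 200)
    expect_gte(rs$n_go, 200)
  }
})
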