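test_that("two-state generator matches renewal theory and its own truth record", {
  # forced single go dwell: linear trace of slope v_go
  sim_lin <- gen_two_state_trace(k_sg = 50, k_gs = 1e-9, v_go = 80,
                                 total_t = 500, noise_sd = 0, seed = 2)
  sp <- diff(sim_lin$trace$length_um) * 1000 / diff(sim_lin$trace$time_min)
  expect_equal(max(abs(sp - 80)), 0, tolerance = 1e-6)

  # long-run go fraction at the published 1.5 mg/mL rates ~ 0.808
  reps <- vapply(1:30, function(s) {
    gen_two_state_trace(0.113, 0.0268, v_go = 50, total_t = 1e4,
                        noise_sd = 0, seed = s)$truth$go_fraction
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.808) , 3 * se + 0.003)

  # truth record and trace agree: noiseless length at the last frame equals
  # v_go times the go time accumulated up to that frame (recomputed here
  # directly from the truth dwell table)
  sim <- gen_two_state_trace(0.1, 0.03, v_go = 100, total_t = 2000,
                             noise_sd = 0, seed = 4)
  t_last <- max(sim$trace$time_min)
  go <- sim$truth$states[sim$truth$states$state == "go", ]
  go_time <- sum(pmax(0, pmin(go$t_end, t_last) - pmin(go$t_start, t_last)))
  expect_equal(max(sim$trace$length_um) * 1000, 100 * go_time, tolerance = 1e-6)

  # reproducibility
  a <- gen_two_state_trace(0.1, 0.03, 100, seed = 11)
  b <- gen_two_state_trace(0.1, 0.03, 100, seed = 11)
  expect_identical(a$trace$length_um, b$trace$length_um)
})

test_that("population generator mixes classes by the equilibrium weight", {
  pop <- gen_population(15, k0 = 1, n_fibrils = 2000, total_t = 40,
                        noise_sd = 0, seed = 3)
  frac_tw <- mean(pop$truth$class == "twisted")
  w <- pop$w_twisted
  expect_equal(w, 0.269824, tolerance = 1e-4)   # 1.645/(1.645+4.452)
  expect_lt(abs(frac_tw - w), 3 * sqrt(w * (1 - w) / 2000))

  # dilute: nearly all twisted
  pop_d <- gen_population(0.05, k0 = 1, n_fibrils = 300, total_t = 40,
                          noise_sd = 0, seed = 5)
  expect_gt(mean(pop_d$truth$class == "twisted"), 0.99)

  pop2 <- gen_population(15, k0 = 1, n_fibrils = 50, total_t = 40, seed = 9)
  pop3 <- gen_population(15, k0 = 1, n_fibrils = 50, total_t = 40, seed = 9)
  expect_identical(pop2$truth$class, pop3$truth$class)
})

test_that("speed distribution of a concentrated population sits near the fast peak", {
  pop <- gen_population(15, k0 = 1, n_fibrils = 30, total_t = 2000,
                        noise_sd = 50, seed = 21)
  seg <- do.call(rbind, lapply(split(pop$traces, pop$traces$fibril_id),
                               segment_trace, v_thresh = 50))
  sp <- segment_speeds(seg)
  h <- suppressMessages(speed_histogram(sp, 10))
  # more mass near 100 nm/min than near 25 nm/min
  mass_fast <- sum(h$count[h$bin_left >= 70 & h$bin_left < 130])
  mass_slow <- sum(h$count[h$bin_left < 40])
  expect_gt(mass_fast, mass_slow)
})

test_that("dwell sampler is exponential with the requested mean", {
  d <- gen_dwell_sample(0.1, 1e4, seed = 6)
  expect_lt(abs(mean(d) - 10), 3 * 10 / sqrt(1e4))
  expect_length(gen_dwell_sample(2, 1, seed = 1), 1)
  expect_gt(gen_dwell_sample(2, 1, seed = 1), 0)
  expect_identical(gen_dwell_sample(1, 5, seed = 3), gen_dwell_sample(1, 5, seed = 3))
})

test_that("discrete chains honour the worm-like-chain statistics", {
  # rigid limit
  ch <- sample_wlc_chain(10, Inf, step = 0.1, seed = 1)
  expect_equal(sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2)), 10, tolerance = 1e-9)

  # ensemble <R^2> matches the closed form within 3 SE
  sam <- gen_wlc_samples(600, 60, c(29.999, 30.001), step = 0.6, seed = 13)
  r2 <- sam$ree_um^2
  se <- stats::sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - expected_ree_sq(30, 60)), 3 * se)

  # tangent autocorrelation over one step is exp(-step/lp)
  steps <- t(apply(sample_wlc_chain(200, 40, step = 0.5, seed = 8), 2, diff))
  tang <- steps / sqrt(colSums(steps^2))[col(steps)]
  dots <- colSums(tang[, -1] * tang[, -ncol(tang)])
  expect_lt(abs(mean(dots) - exp(-0.5 / 40)),
            3 * stats::sd(dots) / sqrt(length(dots)))

  expect_error(sample_wlc_chain(10, 5, step = 2, strict = TRUE))
  expect_warning(sample_wlc_chain(10, 5, step = 2, strict = FALSE))
  expect_identical(sample_wlc_chain(5, 60, seed = 2), sample_wlc_chain(5, 60, seed = 2))
})
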