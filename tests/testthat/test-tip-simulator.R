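test_that("simulation is reproducible and event logs are well formed", {
  rc <- generic_rc()
  st <- solve_partition(3, 1)
  cfg <- sim_config(seed = 4, t_max = 2000)
  log1 <- simulate_tip(rc, st, "twisted", cfg)
  log2 <- simulate_tip(rc, st, "twisted", cfg)
  expect_identical(as.data.frame(log1), as.data.frame(log2))
  expect_true(all(diff(log1$t) > 0))
  expect_true(all(log1$incorporated[log1$from != "BOUND_GROW"] == FALSE))
  # allowed transitions only
  expect_true(all(log1$from[log1$to == "FREE"] %in% c("BOUND_GROW", "BLOCKED")))
  expect_true(all(log1$from[log1$to != "FREE"] == "FREE"))
})

test_that("incorporation counting reduces to a Poisson process without blockers", {
  rc <- rate_constants(1, 0, 1e6, 0, 1, 1, 0, 1e6, 0, 1)
  st <- tibble::tibble(g_tot = 1, g_mono = 1, g_tri = 0)
  log <- simulate_tip(rc, st, "twisted", sim_config(seed = 8, t_max = 1e4))
  n_inc <- sum(log$incorporated)
  expect_lt(abs(n_inc - 1e4), 3 * sqrt(1e4) + 50)
})

test_that("dwell times are exponential and branching follows the rates", {
  rc <- generic_rc()
  st <- solve_partition(3, 1)
  log <- simulate_tip(rc, st, "twisted", sim_config(seed = 12, t_max = 6e4))

  blocked_in <- log$t[log$to == "BLOCKED"]
  blocked_out <- log$t[log$from == "BLOCKED"]
  n <- min(length(blocked_in), length(blocked_out), 1000)
  dw <- (blocked_out[seq_len(n)] - blocked_in[seq_len(n)])
  expect_gte(n, 1000)
  ks <- stats::ks.test(dw, "pexp", rate = rc$twisted$ku_block)
  expect_gt(ks$p.value, 0.01)
  # mean blocked dwell ~ 1/ku_block
  expect_lt(abs(mean(dw) - 1 / rc$twisted$ku_block),
            3 * stats::sd(dw) / sqrt(n))

  # branch ratio FREE->BOUND : FREE->BLOCKED proportional to the rates
  n_b <- sum(log$to == "BOUND_GROW")
  n_k <- sum(log$to == "BLOCKED")
  p_exp <- with(rc$twisted, kb_grow * st$g_mono /
                  (kb_grow * st$g_mono + kb_block * st$g_tri))
  p_obs <- n_b / (n_b + n_k)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / (n_b + n_k)))
})

test_that("occupancy fraction handles edge cases", {
  cfg <- sim_config(seed = 1, t_max = 100)
  empty <- tibble::tibble(t = numeric(0), from = character(0),
                          to = character(0), incorporated = logical(0))
  attr(empty, "t_max") <- 100
  expect_equal(occupancy_growth_fraction(empty), 1)  # never leaves FREE

  # blocked immediately and forever: occupancy -> 0 as horizon grows
  one_block <- tibble::tibble(t = 0.5, from = "FREE", to = "BLOCKED",
                              incorporated = FALSE)
  attr(one_block, "t_max") <- 1000
  expect_lt(occupancy_growth_fraction(one_block), 0.001)
  expect_error(occupancy_growth_fraction(empty, t_max = 0))
})

test_that("rendered traces are cumulative step functions plus noise", {
  rc <- generic_rc()
  st <- solve_partition(3, 1)
  cfg <- sim_config(seed = 3, t_max = 1500)
  log <- simulate_tip(rc, st, "twisted", cfg)
  tr0 <- render_trace(log, cfg, frame_dt = 3.3, noise_sd = 0)
  expect_true(all(diff(tr0$length_um) >= 0))
  expect_equal(max(tr0$length_um) * 1000,
               sum(log$incorporated[log$t <= max(tr0$time_min)]) * cfg$delta_twisted,
               tolerance = 1e-9)

  # no incorporations -> flat at zero
  no_inc <- log
  no_inc$incorporated <- FALSE
  tr_flat <- render_trace(no_inc, cfg, noise_sd = 0)
  expect_true(all(tr_flat$length_um == 0))

  # with noise, the underlying mean go-speed matches the renewal rate
  tr <- render_trace(log, cfg, noise_sd = 50, seed = 2)
  expect_equal(nrow(tr), length(seq(0, cfg$t_max, by = 3.3)))
})
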