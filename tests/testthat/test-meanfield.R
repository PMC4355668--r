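test_that("growth probabilities hit their no-blocker limits", {
  st <- solve_partition(5, 1)
  rc_nb <- rate_constants(1, 0.5, 2, 0, 0.4, 2, 0.3, 1.5, 0, 0.6)
  expect_equal(growth_prob_twisted(rc_nb, st), 1)
  expect_equal(growth_prob_nontwisted(rc_nb, st), 1)

  rc <- generic_rc()
  no_tri <- tibble::tibble(g_tot = 1, g_mono = 1, g_tri = 0)
  expect_equal(growth_prob_twisted(rc, no_tri), 1)
  no_mono <- tibble::tibble(g_tot = 3, g_mono = 0, g_tri = 1)
  expect_equal(growth_prob_nontwisted(rc, no_mono), 1)

  # permanently blocked tip
  rc_abs <- rate_constants(1, 0.5, 2, 1, 0, 2, 0.3, 1.5, 1.2, 0.6)
  expect_warning(p <- growth_prob_twisted(rc_abs, st))
  expect_equal(p, 0)
})

test_that("probabilities stay in [0,1] and the mixture is bracketed", {
  for (seed in 1:20) {
    rc <- make_rc(seed)
    g <- withr::with_seed(seed + 1000, 10^stats::runif(1, -1, 1.5))
    pr <- combined_growth_prob(rc, g, 1)
    expect_true(all(unlist(pr[, -1]) >= 0 & unlist(pr[, -1]) <= 1))
    expect_gte(pr$p_combined, min(pr$p_twisted, pr$p_nontwisted) - 1e-12)
    expect_lte(pr$p_combined, max(pr$p_twisted, pr$p_nontwisted) + 1e-12)
  }
  expect_error(combined_growth_prob(generic_rc(), 0, 1))
})

test_that("weights collapse correctly in the dilute limit and at symmetry", {
  rc <- generic_rc()
  pr <- combined_growth_prob(rc, 1e-4, 1)
  expect_equal(pr$p_combined, pr$p_twisted, tolerance = 1e-6)

  st_eq <- tibble::tibble(g_tot = 4, g_mono = 1, g_tri = 1)
  p_tw <- growth_prob_twisted(rc, st_eq)
  p_nt <- growth_prob_nontwisted(rc, st_eq)
  w <- trimer_number_fraction(st_eq)
  expect_equal((1 - w) * p_tw + w * p_nt, (p_tw + p_nt) / 2)
})

test_that("twisted growth probability responds monotonically to blocking rates", {
  st <- solve_partition(3, 1)
  base <- generic_rc()
  p0 <- growth_prob_twisted(base, st)
  up_block <- rate_constants(1, 0.5, 2, 0.8 * 1.3, 0.4, 2, 0.3, 1.5, 1.2, 0.6)
  expect_lt(growth_prob_twisted(up_block, st), p0)
  up_unblock <- rate_constants(1, 0.5, 2, 0.8, 0.4 * 1.3, 2, 0.3, 1.5, 1.2, 0.6)
  expect_gt(growth_prob_twisted(up_unblock, st), p0)
})

test_that("closed form matches the exact stochastic simulation", {
  st <- solve_partition(3, 1)
  for (seed in c(2, 5, 9)) {
    rc <- make_rc(seed)
    p_cf <- growth_prob_twisted(rc, st)
    est <- estimate_growth_occupancy(rc, st, "twisted", se_target = 0.008,
                                     seed = seed, t_max_init = 3e4)
    expect_lt(abs(p_cf - est$p), 3 * max(est$se, 1e-4))
  }
  # mirrored class once
  rc <- make_rc(3)
  est <- estimate_growth_occupancy(rc, st, "nontwisted", se_target = 0.008,
                                   seed = 31, t_max_init = 3e4)
  expect_lt(abs(growth_prob_nontwisted(rc, st) - est$p), 3 * max(est$se, 1e-4))
})

test_that("asymptotic forms converge to the exact expression in their limits", {
  rc <- generic_rc()
  exact <- function(g) combined_growth_prob(rc, g, 1)$p_combined

  low_err <- vapply(c(0.3, 0.1, 0.03), function(g) {
    abs(asymptotic_low(rc, g, 1) - exact(g)) / exact(g)
  }, numeric(1))
  expect_true(all(diff(low_err) < 0))
  expect_lt(abs(asymptotic_low(rc, 1e-3, 1) - exact(1e-3)) / exact(1e-3), 0.01)
  expect_equal(asymptotic_low(rc, 1e-9, 1), 1, tolerance = 1e-6)

  high_err <- vapply(c(10, 100, 1000), function(g) {
    abs(asymptotic_high(rc, g, 1) - exact(g)) / exact(g)
  }, numeric(1))
  expect_true(all(diff(high_err) < 0))
  expect_lt(abs(asymptotic_high(rc, 1e3, 1) - exact(1e3)) / exact(1e3), 0.01)
  expect_equal(high_conc_weight_approx(3, 1), 0)
})
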