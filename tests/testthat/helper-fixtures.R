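# random but reproducible rate sets for property tests
make_rc <- function(seed, lo = 10^-1.3, hi = 10^1.3) {
  withr::with_seed(seed, {
    v <- exp(stats::runif(10, log(lo), log(hi)))
    rate_constants(v[1], v[2], v[3], v[4], v[5],
                   v[6], v[7], v[8], v[9], v[10])
  })
}

# a fixed generic rate set used across oracle checks
generic_rc <- function() {
  rate_constants(1, 0.5, 2, 0.8, 0.4,
                 2, 0.3, 1.5, 1.2, 0.6)
}

# independent bisection oracle for the monomer concentration:
# the monotone cubic g + 3 g^3 / k0^2 = g_tot on [0, g_tot]
bisect_partition <- function(g_tot, k0 = 1, iter = 200) {
  if (g_tot == 0) return(0)
  lo <- 0
  hi <- g_tot
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mid + 3 * mid^3 / k0^2 < g_tot) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# build traces for a two-state recovery experiment
two_state_traces <- function(k_sg, k_gs, v_go, cycles, n_fib = 12,
                             noise_sd = 50, frame_dt = 3.3, seed0 = 0) {
  total_t <- cycles * (1 / k_sg + 1 / k_gs)
  tt <- total_t / n_fib
  do.call(rbind, lapply(seq_len(n_fib), function(j) {
    gen_two_state_trace(k_sg, k_gs, v_go = v_go, frame_dt = frame_dt,
                        total_t = tt, noise_sd = noise_sd, seed = seed0 + j,
                        fibril_id = sprintf("fib_%02d", j))$trace
  }))
}
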