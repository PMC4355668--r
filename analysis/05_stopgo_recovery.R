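#!/usr/bin/env Rscript
# Stop-go pipeline validation on synthetic traces with known ground truth.
#
# For each measured switching-rate pair, two-state traces are generated at
# the 3.3-min confocal frame interval with 50 nm tracking noise, then pushed
# through segmentation, censored dwell fitting, and the missed-event
# correction. The recovered p_G is compared with the generator's.

suppressPackageStartupMessages(library(stopgo))
dir.create("results", showWarnings = FALSE)

tab <- glucagon_switching_rates()
v_go <- c(25, 25, 100, 100, 100)         # dominant class speed per regime
cycles <- c(1500, 1200, 1200, 1200, 6000)

rows <- list()
for (i in seq_len(nrow(tab))) {
  k_sg <- tab$k_sg[i]; k_gs <- tab$k_gs[i]
  total_t <- cycles[i] * (1 / k_sg + 1 / k_gs)
  n_fib <- 12
  traces <- do.call(rbind, lapply(seq_len(n_fib), function(j) {
    gen_two_state_trace(k_sg, k_gs, v_go = v_go[i], total_t = total_t / n_fib,
                        noise_sd = 50, seed = 100 * i + j,
                        fibril_id = sprintf("f%d_%02d", i, j))$trace
  }))
  rs <- stopgo_rates(traces, g_tot = tab$g_tot[i], calib_n_rep = 150, calib_seed = 5)
  rows[[i]] <- tibble::tibble(
    g_tot = tab$g_tot[i], p_true = growth_probability(k_sg, k_gs),
    p_recovered = rs$p_g, error = rs$p_g - growth_probability(k_sg, k_gs),
    k_sg_true = k_sg, k_sg_rec = rs$k_sg, k_gs_true = k_gs, k_gs_rec = rs$k_gs,
    n_stop = rs$n_stop, n_go = rs$n_go,
    p_detect_stop = rs$p_detect, p_detect_go = rs$p_detect_go)
  cat(sprintf("  %4.1f mg/mL: true p_G %.3f, recovered %.3f (err %+.3f; %d/%d dwells)\n",
              tab$g_tot[i], rows[[i]]$p_true, rs$p_g, rows[[i]]$error,
              rs$n_stop, rs$n_go))
}
rec <- do.call(rbind, rows)
utils::write.csv(signif(rec, 6), "results/stopgo_recovery.csv",
                 row.names = FALSE, quote = FALSE)
cat(sprintf("  max |error| = %.3f; missed-event correction is essential at this frame interval\n",
            max(abs(rec$error))))
cat("  wrote results/stopgo_recovery.csv\n")
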