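#!/usr/bin/env Rscript
# Exact stochastic simulation of single fibril tips vs the closed form.
#
# For a spread of rate sets the Gillespie occupancy of the growing state is
# compared with the stationary three-state expression, and one simulated
# twisted/non-twisted trace pair is rendered at the confocal frame interval.

suppressPackageStartupMessages(library(stopgo))
dir.create("results", showWarnings = FALSE)

st <- solve_partition(3, 1)
rows <- list()
for (i in 1:8) {
  rc <- withr::with_seed(400 + i, {
    v <- exp(stats::runif(10, log(0.1), log(10)))
    rate_constants(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8], v[9], v[10])
  })
  cls <- if (i %% 2 == 0) "twisted" else "nontwisted"
  p_cf <- if (cls == "twisted") growth_prob_twisted(rc, st) else growth_prob_nontwisted(rc, st)
  est <- estimate_growth_occupancy(rc, st, cls, se_target = 0.005,
                                   seed = 500 + i, t_max_init = 5e4)
  rows[[i]] <- tibble::tibble(set = i, class = cls, p_closed_form = p_cf,
                              p_gillespie = est$p, se = est$se,
                              t_max_min = est$t_max,
                              z = (est$p - p_cf) / est$se)
}
comp <- do.call(rbind, rows)
num <- vapply(comp, is.numeric, logical(1))
comp[num] <- lapply(comp[num], signif, digits = 6)
utils::write.csv(comp, "results/occupancy_comparison.csv",
                 row.names = FALSE, quote = FALSE)

cat("Gillespie occupancy vs closed form (8 random rate sets, 3 mg/mL):\n")
cat(sprintf("  max |z| = %.2f (all within 3 SE: %s)\n",
            max(abs(comp$z)), all(abs(comp$z) < 3)))

# rendered example traces at the two class speeds
cfg <- sim_config(seed = 7, t_max = 1500)
rc_demo <- rate_constants(60, 0.1, 1, 1.2, 0.1, 80, 0.1, 1, 1.5, 0.1)
tr_tw <- render_trace(simulate_tip(rc_demo, st, "twisted", cfg), cfg,
                      frame_dt = 3.3, noise_sd = 50, seed = 1, fibril_id = "twisted_demo")
tr_nt <- render_trace(simulate_tip(rc_demo, st, "nontwisted", cfg), cfg,
                      frame_dt = 3.3, noise_sd = 50, seed = 2, fibril_id = "nontwisted_demo")
demo <- rbind(tr_tw, tr_nt)
demo$length_um <- signif(demo$length_um, 6)
demo$time_min <- signif(demo$time_min, 6)
write_traces(demo, "results/simulated_traces.csv")
cat(sprintf("  demo traces: twisted reaches %.2f um, non-twisted %.2f um over %d min\n",
            max(tr_tw$length_um), max(tr_nt$length_um), cfg$t_max))
cat("  wrote results/occupancy_comparison.csv, results/simulated_traces.csv\n")
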