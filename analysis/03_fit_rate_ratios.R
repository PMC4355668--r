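#!/usr/bin/env Rscript
# Fit the monomer-trimer model's eight free rate ratios to the measured
# growth probabilities (K0 = 1 mg/mL fixed; gauge k13 = kr_tw = kr_nt = 1).
#
# The 5-point/8-parameter problem is underdetermined, so the product is the
# fitted curve and its chi-square, not a unique parameter set. The model
# reproduces the U shape (interior minimum near 3 mg/mL ~ K0) but cannot
# pass within 2 sigma of both the 3 and 6 mg/mL points: between those
# concentrations the trimer pool grows only 2.3-fold, which caps how fast
# the non-twisted blocking odds can fall.

suppressPackageStartupMessages(library(stopgo))
dir.create("results", showWarnings = FALSE)

tab <- glucagon_switching_rates()
dat <- tibble::tibble(g_tot = tab$g_tot, p_g = tab$p_g_published,
                      sigma_g = tab$sigma_g_published)

fit <- fit_rate_ratios(dat, k0 = 1, n_starts = 64, seed = 11)
grid <- predict_curve(fit$rc, 1, 10^seq(log10(0.5), log10(25), length.out = 120))
utils::write.csv(signif(grid, 6), "results/model_curve.csv",
                 row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(rate_constants = unclass(fit$rc), chi2 = fit$chi2,
       residuals_weighted = fit$residuals, k0 = 1,
       gauge = "k13 = kr_twisted = kr_nontwisted = 1 min^-1",
       n_starts = fit$n_starts_used),
  "results/rate_fit.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

pred <- predict_curve(fit$rc, 1, dat$g_tot)$p_combined
cat(sprintf("Rate-ratio fit: chi2 = %.2f over %d points\n", fit$chi2, nrow(dat)))
for (i in seq_len(nrow(dat))) {
  cat(sprintf("  %4.1f mg/mL: data %.3f +/- %.3f, model %.3f (%+.1f sigma)\n",
              dat$g_tot[i], dat$p_g[i], dat$sigma_g[i], pred[i],
              (pred[i] - dat$p_g[i]) / dat$sigma_g[i]))
}
i_min <- which.min(grid$p_combined)
cat(sprintf("  model minimum at %.2f mg/mL (near K0, as observed)\n", grid$g_tot[i_min]))
cat("  wrote results/model_curve.csv, results/rate_fit.json\n")
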