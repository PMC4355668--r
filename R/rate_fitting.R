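#' Fit the model's free rate-constant ratios to growth-probability data
#'
#' The stationary growth probability is invariant under rescaling all rates
#' of one fibril class together, and under the absolute monomer/trimer
#' interconversion scale, so of the twelve constants only ratios matter. We
#' fix the gauge `k13 = kr_twisted = kr_nontwisted = 1` min^-1 and fit the
#' remaining eight constants (two binding and two unbinding rates per class)
#' by weighted least squares,
#' \deqn{\chi^2 = \sum_i \left(\frac{p_{model}(G_i) - p_i}{\sigma_i}\right)^2,}
#' with `p_model` from [combined_growth_prob()]. Parameters are optimized in
#' log10 space within `[1e-12, 1e12]` from `n_starts` random log-uniform
#' initializations (seeded, reproducible); the best run is returned. With
#' five data points and eight parameters the problem is underdetermined: the
#' deliverable is the fitted curve and its chi-square, not a unique
#' parameter set.
#'
#' @param data Data frame with columns `g_tot`, `p_g`, `sigma_g` (at least
#'   two rows, all `sigma_g > 0`).
#' @param k0 Equilibrium scale, mg/mL (fixed, not fitted).
#' @param n_starts Number of random multistarts.
#' @param seed Integer seed for the starts.
#' @param log10_bounds Box constraints on log10 of each ratio.
#' @param start_range Log10 range from which starts are drawn.
#' @return A `rate_fit` list: `rc` (best-fit [rate_constants()]), `chi2`,
#'   `residuals` (weighted, one per data point), `converged`,
#'   `n_starts_used`, `start_chi2` (all multistart objectives), `data`, `k0`.
#' @export
fit_rate_ratios <- function(data, k0 = 1, n_starts = 64, seed = 1L,
                            log10_bounds = c(-12, 12), start_range = c(-6, 6)) {
  stopifnot(is.data.frame(data),
            all(c("g_tot", "p_g", "sigma_g") %in% names(data)),
            nrow(data) >= 2, all(data$sigma_g > 0), all(data$g_tot > 0))
  par_names <- c("kb_grow_tw", "ku_grow_tw", "kb_block_tw", "ku_block_tw",
                 "kb_grow_nt", "ku_grow_nt", "kb_block_nt", "ku_block_nt")
  build_rc <- function(th) {
    v <- 10^th
    names(v) <- par_names
    rate_constants(
      kb_grow_tw = v[["kb_grow_tw"]], ku_grow_tw = v[["ku_grow_tw"]], kr_tw = 1,
      kb_block_tw = v[["kb_block_tw"]], ku_block_tw = v[["ku_block_tw"]],
      kb_grow_nt = v[["kb_grow_nt"]], ku_grow_nt = v[["ku_grow_nt"]], kr_nt = 1,
      kb_block_nt = v[["kb_block_nt"]], ku_block_nt = v[["ku_block_nt"]],
      k13 = 1, k31 = 1
    )
  }
  state <- solve_partition(data$g_tot, k0)
  w_nt <- trimer_number_fraction(state)
  objective <- function(th) {
    rc <- build_rc(th)
    p <- (1 - w_nt) * growth_prob_twisted(rc, state) +
      w_nt * growth_prob_nontwisted(rc, state)
    sum(((p - data$p_g) / data$sigma_g)^2)
  }
  best <- NULL
  start_chi2 <- numeric(n_starts)
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- stats::runif(8, start_range[1], start_range[2])
      opt <- stats::nlminb(th0, objective,
                           lower = log10_bounds[1], upper = log10_bounds[2],
                           control = list(iter.max = 500, eval.max = 1000))
      start_chi2[s] <- opt$objective
      if (is.null(best) || opt$objective < best$objective) best <- opt
    }
  })
  rc <- build_rc(best$par)
  pred <- combined_growth_prob(rc, data$g_tot, k0)$p_combined
  structure(list(
    rc = rc, chi2 = best$objective,
    residuals = (pred - data$p_g) / data$sigma_g,
    converged = best$convergence == 0,
    n_starts_used = n_starts, start_chi2 = start_chi2,
    data = data, k0 = k0
  ), class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Rate-ratio fit: chi2 = %.3g over %d points (%d multistarts)\n",
              x$chi2, nrow(x$data), x$n_starts_used))
  print(x$rc)
  invisible(x)
}

#' Predicted growth-probability curve
#'
#' [combined_growth_prob()] evaluated on a concentration grid; convenience
#' wrapper for plotting a fitted model against measured growth
#' probabilities.
#'
#' @param rc A [rate_constants()] object.
#' @param k0 Equilibrium scale, mg/mL.
#' @param conc_grid Total concentrations, mg/mL (positive).
#' @return Tibble from [combined_growth_prob()].
#' @export
predict_curve <- function(rc, k0 = 1, conc_grid) {
  stopifnot(all(conc_grid > 0))
  combined_growth_prob(rc, conc_grid, k0)
}
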