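#' Measured stop-go switching rates for glucagon fibrils
#'
#' Previously reported switching rates between the stop and go states of
#' individual glucagon fibrils at five total concentrations (aqueous buffer,
#' 50 mM glycine HCl, pH 2.5; confocal microscopy at a 3.3-min frame
#' interval), obtained from exponential fits to cumulative dwell-time
#' distributions. These are the observations the rate-ratio fit consumes.
#'
#' `p_g_published`/`sigma_g_published` are the growth probabilities and
#' uncertainties as published alongside the rates. Note that at 6 and 10 mg/mL
#' the published probability differs in the third decimal from
#' `growth_probability()` applied to the published (rounded) rates, and at 3
#' mg/mL the published uncertainty differs from
#' [growth_probability_error()] on the published inputs; the published values
#' were evidently computed from the unrounded fit results.
#'
#' @return Tibble with one row per concentration: `g_tot` (mg/mL), `k_sg`,
#'   `sigma_sg`, `k_gs`, `sigma_gs` (min^-1), `p_g_published`,
#'   `sigma_g_published`.
#' @export
glucagon_switching_rates <- function() {
  tibble::tibble(
    g_tot = c(1.5, 3, 6, 10, 15),
    k_sg = c(0.113, 0.037, 0.091, 0.046, 0.306),
    sigma_sg = c(0.025, 0.002, 0.006, 0.020, 0.096),
    k_gs = c(0.0268, 0.0215, 0.0292, 0.0113, 0.0444),
    sigma_gs = c(0.0005, 0.0003, 0.0012, 0.0002, 0.0024),
    p_g_published = c(0.808, 0.632, 0.756, 0.805, 0.873),
    sigma_g_published = c(0.034, 0.015, 0.014, 0.069, 0.035)
  )
}
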