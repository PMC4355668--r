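#' Solve the glucagon monomer-trimer equilibrium partition
#'
#' In solution, glucagon monomers (concentration `[G]`) coexist with trimers
#' (`[G3]`) under mass action. We use the convention
#' \deqn{[G]^3 = K_0^2 \, [G_3],}
#' where the equilibrium scale \eqn{K_0} (about 1 mg/mL for glucagon) marks
#' the crossover from monomer- to trimer-dominated solutions, and the total
#' concentration is \eqn{[G_{tot}] = [G] + 3[G_3]}. The exponent-2 convention
#' for \eqn{K_0} is the unique one for which the trimer number fraction
#' approaches \eqn{1 - (3K_0/[G_{tot}])^{2/3}} at high concentration (see
#' [high_conc_weight_approx()]). All concentrations are mg/mL.
#'
#' The monomer concentration is the unique non-negative root of the monotone
#' cubic \eqn{G + 3G^3/K_0^2 = G_{tot}}, found by bracketed root finding on
#' `[0, G_tot]`.
#'
#' @param g_tot Total glucagon concentration(s), mg/mL (non-negative).
#' @param k0 Monomer-trimer equilibrium scale, mg/mL (positive scalar).
#' @return A `solution_state` tibble with columns `g_tot`, `g_mono`, `g_tri`
#'   (all mg/mL) and the `k0` used stored as an attribute.
#' @examples
#' solve_partition(c(0.5, 1.5, 15))
#' @export
solve_partition <- function(g_tot, k0 = 1) {
  stopifnot(is.numeric(g_tot), is.numeric(k0), length(k0) == 1L)
  if (!is.finite(k0) || k0 <= 0) stop("`k0` must be a positive, finite concentration")
  if (any(!is.finite(g_tot)) || any(g_tot < 0)) {
    stop("`g_tot` must be non-negative and finite")
  }
  g_mono <- vapply(g_tot, function(gt) {
    if (gt == 0) return(0)
    f <- function(g) g + 3 * g^3 / k0^2 - gt
    g <- stats::uniroot(f, lower = 0, upper = gt, tol = 1e-12 * max(gt, 1))$root
    # Newton polish to machine precision (the bracket tolerance is absolute,
    # which is too loose for very dilute solutions)
    for (i in 1:3) g <- g - f(g) / (1 + 9 * g^2 / k0^2)
    min(g, gt)
  }, numeric(1))
  # trimers from the mass-action law (avoids catastrophic cancellation of
  # (g_tot - g_mono)/3 in the dilute limit)
  g_tri <- g_mono^3 / k0^2
  out <- tibble::tibble(g_tot = g_tot, g_mono = g_mono, g_tri = g_tri)
  attr(out, "k0") <- k0
  class(out) <- c("solution_state", class(out))
  out
}

#' Number fraction of trimers among free building blocks
#'
#' Returns \eqn{[G_3] / ([G] + [G_3])}, the probability that a randomly chosen
#' free building block (and hence, in the model, a randomly chosen fibril) is
#' a trimer (non-twisted). Defined as 0 at `g_tot = 0` (the limit from below).
#'
#' @param state A `solution_state` from [solve_partition()].
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
trimer_number_fraction <- function(state) {
  stopifnot(is.data.frame(state), all(c("g_mono", "g_tri") %in% names(state)))
  tot <- state$g_mono + state$g_tri
  ifelse(tot > 0, state$g_tri / tot, 0)
}

#' High-concentration approximation to the trimer number fraction
#'
#' At `g_tot >> k0` nearly all glucagon is trimeric and the trimer number
#' fraction approaches \eqn{1 - (3 K_0 / [G_{tot}])^{2/3}}; the value is
#' clipped to `[0, 1]` (the raw expression goes negative below
#' `g_tot = 3 k0`).
#'
#' @inheritParams solve_partition
#' @return Numeric vector of approximate fractions.
#' @export
high_conc_weight_approx <- function(g_tot, k0 = 1) {
  stopifnot(is.numeric(g_tot), is.numeric(k0), length(k0) == 1L, k0 > 0)
  if (any(g_tot <= 0)) stop("`g_tot` must be strictly positive")
  pmin(pmax(1 - (3 * k0 / g_tot)^(2 / 3), 0), 1)
}
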