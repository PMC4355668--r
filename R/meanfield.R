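#' Rate constants of the monomer-trimer fibril growth model
#'
#' Bundles the per-class kinetic constants of the fibril-tip model. Each
#' fibril class (twisted, built from monomers; non-twisted, built from
#' trimers) has five constants:
#'
#' * `kb_grow`: binding rate of the cognate building block,
#'   (mg/mL)^-1 min^-1;
#' * `ku_grow`: unbinding rate of a bound cognate block before it is
#'   incorporated, min^-1;
#' * `kr`: conformational rearrangement rate (irreversible incorporation),
#'   min^-1;
#' * `kb_block`: binding rate of the opposite (blocking) species,
#'   (mg/mL)^-1 min^-1;
#' * `ku_block`: unbinding rate of the blocker, min^-1.
#'
#' `k13`/`k31` are the monomer <-> trimer interconversion scales (min^-1);
#' they do not enter the stationary growth probability and are carried for
#' completeness.
#'
#' @param kb_grow_tw,ku_grow_tw,kr_tw,kb_block_tw,ku_block_tw Twisted-class
#'   constants (cognate species: monomer, blocker: trimer).
#' @param kb_grow_nt,ku_grow_nt,kr_nt,kb_block_nt,ku_block_nt Non-twisted
#'   constants (cognate: trimer, blocker: monomer).
#' @param k13,k31 Interconversion scales, min^-1.
#' @return A `rate_constants` object (list with `twisted`, `nontwisted`,
#'   `k13`, `k31`).
#' @export
rate_constants <- function(kb_grow_tw, ku_grow_tw, kr_tw, kb_block_tw, ku_block_tw,
                           kb_grow_nt, ku_grow_nt, kr_nt, kb_block_nt, ku_block_nt,
                           k13 = 1, k31 = 1) {
  rc <- list(
    twisted = list(kb_grow = kb_grow_tw, ku_grow = ku_grow_tw, kr = kr_tw,
                   kb_block = kb_block_tw, ku_block = ku_block_tw),
    nontwisted = list(kb_grow = kb_grow_nt, ku_grow = ku_grow_nt, kr = kr_nt,
                      kb_block = kb_block_nt, ku_block = ku_block_nt),
    k13 = k13, k31 = k31
  )
  vals <- unlist(rc)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rate constants must be finite and non-negative")
  }
  if (rc$twisted$kb_grow <= 0 || rc$twisted$kr <= 0 ||
      rc$nontwisted$kb_grow <= 0 || rc$nontwisted$kr <= 0) {
    stop("a usable model needs kb_grow > 0 and kr > 0 for both fibril classes")
  }
  structure(rc, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Monomer-trimer model rate constants (min^-1; binding per mg/mL)\n")
  for (cl in c("twisted", "nontwisted")) {
    cat(sprintf("  %-10s kb_grow=%.4g ku_grow=%.4g kr=%.4g kb_block=%.4g ku_block=%.4g\n",
                cl, x[[cl]]$kb_grow, x[[cl]]$ku_grow, x[[cl]]$kr,
                x[[cl]]$kb_block, x[[cl]]$ku_block))
  }
  cat(sprintf("  k13=%.4g k31=%.4g\n", x$k13, x$k31))
  invisible(x)
}

# Stationary growing-state occupancy of the three-state tip chain
# (free / cognate-bound / blocked). r_g, r_b are pseudo-first-order binding
# rates; tau_g = 1/(ku_grow + kr), tau_b = 1/ku_block. The growing state is
# {free, cognate-bound}: p = (1 + r_g tau_g) / (1 + r_g tau_g + r_b tau_b).
.tip_growth_prob <- function(cl, conc_grow, conc_block) {
  r_g <- cl$kb_grow * conc_grow
  r_b <- cl$kb_block * conc_block
  a <- r_g / (cl$ku_grow + cl$kr)
  if (cl$ku_block == 0) {
    out <- ifelse(r_b > 0, 0, 1)
    if (any(r_b > 0)) {
      warning("ku_block = 0 with blocker present: tip is permanently blocked, p = 0")
    }
    return(out)
  }
  b <- r_b / cl$ku_block
  (1 + a) / (1 + a + b)
}

#' Stationary growth probability of a twisted (monomer-built) fibril
#'
#' Fraction of time the tip of a twisted fibril spends in the growing state
#' (free or with a cognate monomer bound, i.e. not blocked by a trimer),
#' computed in closed form from the stationary distribution of the
#' three-state tip chain:
#' \deqn{p_G^{(M)} = \frac{1 + r_g\tau_g}{1 + r_g\tau_g + r_b\tau_b},}
#' with \eqn{r_g = k_{b}^{grow}[G]}, \eqn{r_b = k_b^{block}[G_3]},
#' \eqn{\tau_g = 1/(k_u^{grow}+k_r)} and \eqn{\tau_b = 1/k_u^{block}}.
#'
#' @param rc A [rate_constants()] object.
#' @param state A `solution_state` from [solve_partition()].
#' @return Probabilities in `[0, 1]`, one per row of `state`.
#' @export
growth_prob_twisted <- function(rc, state) {
  stopifnot(inherits(rc, "rate_constants"))
  .tip_growth_prob(rc$twisted, state$g_mono, state$g_tri)
}

#' Stationary growth probability of a non-twisted (trimer-built) fibril
#'
#' Mirror of [growth_prob_twisted()] with the roles of monomers and trimers
#' reversed: trimers are the cognate building block, monomers block.
#'
#' @inheritParams growth_prob_twisted
#' @return Probabilities in `[0, 1]`.
#' @export
growth_prob_nontwisted <- function(rc, state) {
  stopifnot(inherits(rc, "rate_constants"))
  .tip_growth_prob(rc$nontwisted, state$g_tri, state$g_mono)
}

#' Population growth probability at a given total concentration
#'
#' The probability that a randomly chosen fibril is growing. Fibril numbers
#' are proportional to the numbers of their building blocks, so the two class
#' probabilities are combined with number weights \eqn{[G]} and \eqn{[G_3]}:
#' \deqn{p_G = \frac{[G]\,p_G^{(M)} + [G_3]\,p_G^{(T)}}{[G] + [G_3]}.}
#'
#' @inheritParams solve_partition
#' @param rc A [rate_constants()] object.
#' @return A tibble with columns `g_tot`, `p_twisted`, `p_nontwisted`,
#'   `p_combined`.
#' @export
combined_growth_prob <- function(rc, g_tot, k0 = 1) {
  if (any(g_tot <= 0)) stop("`g_tot` must be positive: no fibrils to weight at zero concentration")
  state <- solve_partition(g_tot, k0)
  p_tw <- growth_prob_twisted(rc, state)
  p_nt <- growth_prob_nontwisted(rc, state)
  w_nt <- trimer_number_fraction(state)
  tibble::tibble(
    g_tot = g_tot,
    p_twisted = p_tw,
    p_nontwisted = p_nt,
    p_combined = (1 - w_nt) * p_tw + w_nt * p_nt
  )
}

#' Low-concentration asymptotic growth probability
#'
#' For `g_tot << k0` the solution is monomer-dominated and binding events are
#' the slow timescales: the time a tip spends resolving a bound cognate block
#' is negligible next to the wait for the next arrival, so only blocked time
#' reduces growth. Using the dilute partition `[G] ~ g_tot`,
#' `[G3] ~ g_tot^3/k0^2`:
#' \deqn{p^{(M)} \approx \frac{1}{1 + r_b^{(M)}\tau_b^{(M)}}, \quad
#'       p^{(T)} \approx \frac{1}{1 + r_b^{(T)}\tau_b^{(T)}},}
#' combined with the dilute number weights. Converges to
#' [combined_growth_prob()] as `g_tot/k0 -> 0`; both tend to 1 because the
#' blocker of the dominant (twisted) class vanishes as `[G]^3`.
#'
#' @inheritParams combined_growth_prob
#' @return Approximate probabilities.
#' @export
asymptotic_low <- function(rc, g_tot, k0 = 1) {
  stopifnot(all(g_tot > 0))
  g <- g_tot
  g3 <- g_tot^3 / k0^2
  blocked_tw <- rc$twisted$kb_block * g3 / rc$twisted$ku_block
  blocked_nt <- rc$nontwisted$kb_block * g / rc$nontwisted$ku_block
  p_tw <- 1 / (1 + blocked_tw)
  p_nt <- 1 / (1 + blocked_nt)
  (g * p_tw + g3 * p_nt) / (g + g3)
}

#' High-concentration asymptotic growth probability
#'
#' For `g_tot >> k0` the solution is trimer-dominated; binding is fast and
#' the slow steps are unbinding and rearrangement, so the free-tip waiting
#' time drops out:
#' \deqn{p^{(F)} \approx \frac{r_g\tau_g}{r_g\tau_g + r_b\tau_b}}
#' for each class, combined with the published weight approximation
#' \eqn{[G_3]/([G]+[G_3]) \approx 1 - (3K_0/[G_{tot}])^{2/3}} and the
#' asymptotic concentrations `[G3] ~ g_tot/3`, `[G] ~ (k0^2 g_tot/3)^(1/3)`.
#'
#' @inheritParams combined_growth_prob
#' @return Approximate probabilities.
#' @export
asymptotic_high <- function(rc, g_tot, k0 = 1) {
  stopifnot(all(g_tot > 0))
  g3 <- g_tot / 3
  g <- (k0^2 * g_tot / 3)^(1 / 3)
  a_tw <- rc$twisted$kb_grow * g / (rc$twisted$ku_grow + rc$twisted$kr)
  b_tw <- rc$twisted$kb_block * g3 / rc$twisted$ku_block
  a_nt <- rc$nontwisted$kb_grow * g3 / (rc$nontwisted$ku_grow + rc$nontwisted$kr)
  b_nt <- rc$nontwisted$kb_block * g / rc$nontwisted$ku_block
  p_tw <- a_tw / (a_tw + b_tw)
  p_nt <- a_nt / (a_nt + b_nt)
  w_nt <- high_conc_weight_approx(g_tot, k0)
  (1 - w_nt) * p_tw + w_nt * p_nt
}
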