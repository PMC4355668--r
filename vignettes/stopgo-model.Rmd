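---
title: "A monomer-trimer model of intermittent glucagon fibril growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A monomer-trimer model of intermittent glucagon fibril growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopgo)
```

## The scientific problem

Individual glucagon fibrils observed by confocal microscopy do not elongate
steadily: growth episodes ("go") alternate with plateaus ("stop"), both with
exponentially distributed durations. The fraction of time a fibril spends
growing — the growth probability $p_G$ — is high at low and high glucagon
concentrations and dips at intermediate ones (~3 mg/mL). `stopgo` implements
a mechanistic explanation: glucagon exists as monomers and trimers in
mass-action equilibrium; monomers build *twisted* fibrils and trimers build
*non-twisted* fibrils; and each species reversibly caps the tip of the
opposite fibril class, arresting it until the blocker detaches. The dip
falls near the monomer/trimer crossover, where both fibril classes face a
substantial pool of their blocker.

## Solution equilibrium

With $[G]$ the monomer and $[G_3]$ the trimer concentration (mg/mL
throughout; the experimental literature for this system works in mass
concentrations, so no molar conversion is introduced), we impose

$$[G]^3 = K_0^2\,[G_3], \qquad [G_{tot}] = [G] + 3[G_3].$$

The exponent convention for $K_0$ deserves a note: the defining relation is
fixed by requiring that the trimer *number* fraction approach the
high-concentration form $1 - (3K_0/[G_{tot}])^{2/3}$, which is the published
asymptote this package reproduces; with $K_{eq} = [G]^3/[G_3] = K_0^2$ in
(mg/mL)$^2$ that follows directly, and $K_0 \approx 1$ mg/mL is the
experimentally known crossover scale. At the fitted value $K_0 = 1$ the
distinction between $K_0$ and $K_0^2$ conventions is numerically moot, but
the package documents and tests the convention explicitly. The monomer
concentration is the unique root of the monotone cubic
$G + 3G^3/K_0^2 = G_{tot}$, found by bracketed root finding on
$[0, G_{tot}]$ with $10^{-12}$ relative tolerance; `trimer_number_fraction`
is defined as 0 at $G_{tot} = 0$ (its limit from below).

## Growth probabilities from a three-state tip chain

A fibril tip is FREE, has a cognate block bound but not yet incorporated
(BOUND), or is BLOCKED by the opposite species. With pseudo-first-order
binding rates $r_g = k_b^{grow}[c_{grow}]$, $r_b = k_b^{block}[c_{block}]$,
resolution time $\tau_g = 1/(k_u^{grow} + k_r)$ and blocker dwell
$\tau_b = 1/k_u^{block}$, the stationary weights of the chain are
$1 : r_g\tau_g : r_b\tau_b$, giving

$$p_G^{(class)} = \frac{1 + r_g\tau_g}{1 + r_g\tau_g + r_b\tau_b}.$$

Two modelling commitments are made here. First, the growth probability is
defined as the *stationary occupancy* of the non-blocked states — the
long-run fraction of time the tip is free or resolving a cognate block.
The equivalent renewal-reward form (mean growing time per cycle over mean
cycle time) is algebraically identical. Second, the unproductive
cognate-bound intermediate counts as *growing*: at a frames-per-minutes
timescale it does not visually arrest the fibril, unlike the blocked state.
Both commitments are validated against an exact stochastic simulation (below)
rather than against published algebra.

A randomly chosen fibril is twisted with probability
$[G]/([G]+[G_3])$ — fibril numbers follow building-block numbers — so the
population growth probability is the number-weighted mixture implemented in
`combined_growth_prob()`.

Two closed-form limits are provided. At $G_{tot} \ll K_0$ binding waits
dominate all tip timescales, so only blocked time subtracts from growth and
$p^{(class)} \approx 1/(1 + r_b\tau_b)$ with the dilute partition
$[G] \approx G_{tot}$, $[G_3] \approx G_{tot}^3/K_0^2$; growth probability
tends to 1 because the twisted class dominates and its blocker vanishes as
$[G]^3$. At $G_{tot} \gg K_0$ binding is fast and resolution/unbinding
dominate, the free-tip wait drops out,
$p^{(class)} \approx r_g\tau_g/(r_g\tau_g + r_b\tau_b)$, and the trimer
weight takes the $1-(3K_0/G_{tot})^{2/3}$ form. Both are tested for
three-point monotone convergence to the exact expression and agree with it
to better than 1% by $G_{tot}/K_0 = 10^{\mp 3}$.

## Exact stochastic tip simulation

`simulate_tip()` draws the continuous-time Markov chain exactly: waiting
times are exponential in the total exit rate and branches are chosen
proportionally to rates. Because the chain alternates FREE → occupied →
FREE, whole cycles are drawn in vectorized blocks — statistically identical
to the event-by-event formulation and orders of magnitude faster in R. Bulk
concentrations are held constant during a simulation: a single tip consumes
monomer at a rate that is negligible against the bulk pool, so feedback on
$[G]$, $[G_3]$ is ignored. A blocked state with $k_u^{block} = 0$ is
absorbing and is reported with a warning rather than an error, since the
permanent-block limit is a legitimate boundary case of the model.

The simulator doubles as the mechanistic trace generator: `render_trace()`
samples the cumulative number of incorporations on a uniform frame grid
(default 3.3 min, the confocal acquisition interval) and adds Gaussian
tracking noise. Length increments default to 0.47 nm per incorporated
monomer — the cross-beta stacking distance of one molecular layer — and
three layers (1.41 nm) per trimer; both are configuration options, since the
model itself fixes only event counts, not geometry. Occupancy standard
errors use batch means over 50 equal time bins, and
`estimate_growth_occupancy()` grows the horizon until a target SE is met;
this is the oracle used to cross-check the closed form (each validates the
other, as the two routes are independent implementations of the same chain).

## Segmenting traces and estimating switching rates

The experimental record is a length-versus-time trace per fibril. The
stop/go calling criterion is not something the raw data dictate uniquely;
the package uses a declared, simple rule (`segment_trace()`): per-interval
speeds, a centered moving average (default 3 intervals), a speed threshold,
and a minimum run length (default 2 intervals) with short runs merged into
the flanking state. The default threshold of 10 nm/min keeps the slow
(~25 nm/min) growth mode classified as "go" under 50 nm noise at 3.3
min/frame. The pipeline (`stopgo_rates()`) instead uses an adaptive
threshold — half the estimated go speed, found by a two-pass scheme — which
balances missed plateaus against false ones across both speed regimes.

Dwell-time fitting follows the cumulative-count procedure used for the
published dwell distributions: a least-squares line on
$(t, \ln N(t))$ where $N(t)$ counts dwells at least $t$ long
(`fit_dwell_exponential()`, the default method). Durations below a censor
(shorter than the frame interval, or within the segmentation's resolution)
are excluded; by memorylessness this truncation does not bias the slope. A
shifted-exponential MLE, $k = 1/(\overline{d} - t_{min})$, is provided as
`method = "mle"`; the *pipeline* uses it internally because the survival
line's variance is dominated by the sparse deep tail, while the truncated
mean has clean $1/\sqrt{n}$ behaviour. Removal of extreme pauses
(`trim_long_pauses()`) is off by default and always reports what it removed;
the quantile policy uses the inverse-ECDF quantile so the threshold is an
observed duration.

### The missed-event problem, and why the correction is not optional

At a 3.3-min frame interval, the measured stop→go rates imply that 31–64%
of stop dwells are *shorter than one frame*. No plateau classifier can see
them. A missed stop fuses the go dwells around it; a missed short go dwell
symmetrically fuses two stops. Left uncorrected, this biases $p_G$ upward
by 0.05–0.15 at the measured rate scales — far beyond the accuracy the
validation targets. The pipeline therefore applies a two-stage correction
in the spirit of missed-event corrections in single-channel
electrophysiology:

1. **Analytic stage.** The classifier's detection probability
   $P(\text{detect}\mid d)$ and boundary erosion are measured by Monte
   Carlo insertion of single events into clean backgrounds
   (`detection_curve()`), under the speed and noise estimated from the data
   (noise from the lag-1 autocovariance of frame displacements). If an
   observed dwell is a geometric chain of true dwells joined by missed
   dwells of the opposite state, its apparent rate is
   $\lambda = k\,p/(1 + k(1-p)\bar m)$, where $p$ is the duration-weighted
   detection probability of the *opposite* state's dwells and $\bar m$ the
   mean missed duration. The two relations (one per state) are inverted
   jointly by fixed-point iteration, with the correction capped at 6x —
   beyond that the first-order chain picture is unreliable.
2. **Indirect-inference stage.** Single-event calibration cannot capture
   context effects (erosion overlapping neighbouring dwells, false calls at
   low speed). The estimates are therefore refined by simulation matching:
   two-state traces are simulated at the current estimates, pushed through
   the *identical* segmentation and censored fits, and the rates (plus the
   apparent speed and noise statistics) are updated multiplicatively until
   simulated observables match measured ones. A common random-number seed
   makes the map deterministic, and per-step updates are clamped for
   robustness.

On synthetic ground truth spanning the measured rate pairs this recovers
$p_G$ to within ±0.005 (typical) and ±0.03 (worst case, at the fastest
switching where the mean stop dwell equals one frame), with a few hundred
detected dwells per state. What these validations do *not* establish is
robustness to features absent from the generator: speed heterogeneity
within a class, drift, non-exponential dwells, or correlated noise.

## Persistence length

Fibril stiffness is summarized by the 3D Kratky–Porod relation
$\langle R_{ee}^2\rangle = 2\ell_p L - 2\ell_p^2(1 - e^{-L/\ell_p})$,
fitted to squared end-to-end versus contour length. The observed fibrils
grew along the coverslip but arrive from 3D conformations and a single
formula is fitted to all data, so the 3D form is the default; the 2D
variant ($\ell_p \to 2\ell_p$ effective) is available behind `dim = 2` and
the choice is recorded in the fit object. The fluctuation of $R^2$ grows
roughly as $\langle R^2\rangle\cdot L$ in the weak-bending regime, so the
fit iteratively reweights with $1/(\langle R^2\rangle L)^2$; this halves
the estimator's spread relative to ordinary least squares at no cost in
bias. Cohorts whose best $\ell_p$ exceeds ten times the longest sampled
contour (rigid-rod limit) are flagged as unidentifiable rather than
reported at face value.

The matching generator, `sample_wlc_chain()`, draws unit tangents whose
per-step turning angle follows a von Mises–Fisher distribution with the
concentration chosen (by numerically inverting the Langevin function) so
that $\langle\cos\theta\rangle = e^{-h/\ell_p}$ *exactly*; the tangent
autocorrelation is then exactly exponential at the nodes and the ensemble
$\langle R^2\rangle$ matches the continuous formula up to an $O((h/\ell_p)^2)$
discretization term. The default step is $\ell_p/100$ (0.6 µm at the
fibril stiffness), at which that term is invisible next to sampling noise;
steps coarser than $\ell_p/10$ are refused by default.

## Fitting the rate ratios

Only ratios of the twelve model constants affect $p_G(G_{tot})$ — the
probability is invariant under rescaling all rates of one class together
and under the monomer↔trimer interconversion scale (both invariances are
tested numerically). The gauge is fixed as
$k_{13} = k_r^{(M)} = k_r^{(T)} = 1\ \text{min}^{-1}$ and the remaining
eight constants are fitted by weighted least squares in log10 space
(bounds $10^{\pm 12}$) from 64 random multistarts. Because the closed form
depends on the eight constants only through four effective combinations
($r_g\tau_g$ and $r_b\tau_b$ coefficients per class), the problem is
underdetermined: the deliverable is the fitted curve and its $\chi^2$,
never a unique parameter set, and the directions the data do not constrain
come out wherever the optimizer's winning start left them.

The fitted curve reproduces the qualitative signature — an interior minimum
near 3 mg/mL, i.e. near $K_0$ — but a sharp quantitative limit exists and
is worth stating because it is a property of the model, not of the
optimizer: between 3 and 6 mg/mL the trimer pool grows only 2.29-fold while
the monomer pool grows 1.32-fold, so the non-twisted class's odds of being
blocked can fall by at most the ratio of those factors. Propagating this
through the number weights caps the model's achievable rise in $p_G$ from
3 to 6 mg/mL below what the measured values (0.632 ± 0.015 →
0.756 ± 0.014) demand; the best reachable $\chi^2$ is ≈ 40 over five
points, with individual residuals up to ±4σ at the two tightest points.

## Numerical choices and degenerate inputs

* Root finding, dwell fits and the WLC fit delegate to `stats::uniroot`,
  `stats::lm`/closed-form MLE, and `minpack.lm::nlsLM` respectively;
  multistart optimization uses `stats::nlminb`.
* Ties in segmentation run-merging are broken toward the earlier run;
  single-run traces are returned as one segment.
* Zero blocker concentration, zero blocking rate, and the absorbing-block
  limit all short-circuit to their exact limits (1, 1, 0) rather than
  relying on floating-point division.
* Every stochastic routine takes an explicit integer seed and restores the
  caller's RNG state (`withr::with_seed`); identical seeds give identical
  output, which the suite asserts.

## Problem sizes used in validation

The shipped validation uses cohorts sized for statistical decisiveness:
200-chain WLC cohorts with 50 replicates; stochastic-oracle comparisons at
a 0.005 standard-error target (horizons up to ~10^6 min of simulated tip
time per rate set); and stop-go recovery cohorts of 1200–6000 dwell cycles
per switching-rate pair, giving at least 200 detected dwells per state
after censoring. These sizes are the package's validation design; all are
arguments, so heavier studies only require changing a number in the
`analysis/` drivers.

## Known limitations

* The segmentation rule is a declared stand-in for whatever event calling
  was used on the real microscopy data; its defaults were chosen for the
  two observed speed modes and validated only on the synthetic generator.
* The missed-event machinery assumes the two-state exponential model in
  its correction stage; if real dwells were heavy-tailed the correction
  would inherit the misspecification.
* The rate-ratio fit cannot and does not claim parameter identification;
  only the curve is meaningful.
* Fibril nucleation, fragmentation, secondary nucleation, multi-fibril
  competition for monomer, and imaging physics are out of scope.
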