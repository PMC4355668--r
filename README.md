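# stopgo

Intermittent ("stop-go") growth of glucagon amyloid fibrils under a
monomer-trimer model.

Individual glucagon fibrils watched by confocal microscopy do not elongate
steadily: growth runs are interrupted by plateaus, with exponentially
distributed dwell times in both states. The probability of finding a fibril
growing,

```
p_G = k_s->g / (k_s->g + k_g->s),
```

is high at low *and* high glucagon concentration and dips near 3 mg/mL.
`stopgo` implements the model that explains this: glucagon monomers ([G])
and trimers ([G3]) coexist under mass action, `[G]^3 = K0^2 [G3]` with
`[G_tot] = [G] + 3[G3]` and `K0 ~ 1 mg/mL`; monomers build twisted fibrils
and trimers non-twisted ones; and each species reversibly caps the tip of
the opposite fibril class. A tip is free, resolving a bound cognate block,
or blocked, and its stationary growing-state occupancy is

```
p_G^(class) = (1 + r_g t_g) / (1 + r_g t_g + r_b t_b),
```

with `r_g = kb_grow [cognate]`, `r_b = kb_block [blocker]`,
`t_g = 1/(ku_grow + kr)`, `t_b = 1/ku_block`; fibril classes are mixed with
number weights `[G]` and `[G3]`. The dip sits at the monomer/trimer
crossover, where both classes see plenty of their blocker.

The package is organised as an analysis workflow: every computation lives in
the package (`R/`), and the numbered drivers under `analysis/` run the
individual studies and write tables to `results/`.

What is implemented:

* `solve_partition()`, `trimer_number_fraction()`,
  `high_conc_weight_approx()` — the bulk equilibrium and its
  high-concentration asymptote;
* `growth_prob_twisted()` / `growth_prob_nontwisted()` /
  `combined_growth_prob()`, with `asymptotic_low()` / `asymptotic_high()` —
  closed-form growth probabilities;
* `simulate_tip()`, `occupancy_growth_fraction()`, `render_trace()` — exact
  (Gillespie) simulation of the tip state machine, used as the stochastic
  oracle for the closed forms and as a mechanistic trace generator;
* `segment_trace()`, `fit_dwell_exponential()`, `growth_probability()`,
  `growth_probability_error()`, `segment_speeds()`, `speed_histogram()`,
  `trim_long_pauses()`, `stopgo_rates()` — the trace-analysis pipeline,
  including a missed-event (dead-time) correction that is essential at the
  3.3-min frame interval;
* `expected_ree_sq()`, `fit_persistence_length()` — worm-like-chain
  end-to-end statistics and persistence-length fitting;
* `fit_rate_ratios()`, `predict_curve()` — weighted least-squares fitting
  of the model's eight free rate ratios to measured growth probabilities;
* `gen_two_state_trace()`, `gen_population()`, `gen_dwell_sample()`,
  `sample_wlc_chain()`, `gen_wlc_samples()` — synthetic-data generators
  that return their ground truth, replacing the unavailable microscopy raw
  data;
* `glucagon_switching_rates()` — the previously reported switching-rate
  table the rate fit consumes;
* `read_traces()`, `write_traces()`, `write_report()` — CSV/JSON I/O.

## Worked example

Switching rates to growth probabilities, and the model fit:

```r
library(stopgo)
tab <- glucagon_switching_rates()
growth_probability(tab$k_sg, tab$k_gs)
#> [1] 0.8083 0.6325 0.7571 0.8028 0.8733
```

Growth is likeliest at the concentration extremes; the minimum sits at
3 mg/mL, the monomer/trimer crossover. Running
`Rscript analysis/03_fit_rate_ratios.R` fits the eight free rate ratios
(gauge `k13 = kr = 1/min`, `K0 = 1 mg/mL`) and prints:

```
Rate-ratio fit: chi2 = 39.59 over 5 points
   1.5 mg/mL: data 0.808 +/- 0.034, model 0.720 (-2.6 sigma)
   3.0 mg/mL: data 0.632 +/- 0.015, model 0.692 (+4.0 sigma)
   6.0 mg/mL: data 0.756 +/- 0.014, model 0.713 (-3.1 sigma)
  10.0 mg/mL: data 0.805 +/- 0.069, model 0.749 (-0.8 sigma)
  15.0 mg/mL: data 0.873 +/- 0.035, model 0.782 (-2.6 sigma)
  model minimum at 3.05 mg/mL (near K0, as observed)
```

The curve reproduces the observed U shape with its interior minimum near
`K0`; the residuals at the two tightest points reflect a structural limit of
the model (between 3 and 6 mg/mL the trimer pool grows only 2.3-fold, which
caps how fast the non-twisted blocking odds can fall — see the methods
vignette).

Validating the trace pipeline on synthetic ground truth
(`Rscript analysis/05_stopgo_recovery.R`):

```
   1.5 mg/mL: true p_G 0.808, recovered 0.808 (err -0.001; 397/639 dwells)
   3.0 mg/mL: true p_G 0.632, recovered 0.635 (err +0.002; 683/793 dwells)
   6.0 mg/mL: true p_G 0.757, recovered 0.755 (err -0.003; 503/606 dwells)
  10.0 mg/mL: true p_G 0.803, recovered 0.806 (err +0.004; 754/839 dwells)
  15.0 mg/mL: true p_G 0.873, recovered 0.861 (err -0.012; 456/922 dwells)
```

At this frame interval 30-60% of stop dwells are shorter than one frame and
invisible to any plateau classifier; the recovery above is only possible
because `stopgo_rates()` corrects for missed events (calibrated detection
curves plus an indirect-inference refinement).

Fibril stiffness (`Rscript analysis/06_persistence_length.R`):

```
Persistence length fit on one cohort of 200 chains: 60.8 +/- 2.8 um (truth 60)
  50 replicate cohorts: mean 59.71 um, sd 2.84 um, bias -0.48%
```

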