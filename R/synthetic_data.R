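#' Synthetic data generators with known ground truth
#'
#' Every generator in this file returns (or can return) the ground truth it
#' sampled from, so pipeline tests can consume only the data and compare the
#' recovered quantities against the withheld truth.
#'
#' @name synthetic_data
NULL

# alternating exponential stop/go dwells covering [0, total_t]; consumes RNG
.two_state_realization <- function(k_sg, k_gs, total_t) {
  p_go <- k_sg / (k_sg + k_gs)
  state <- if (stats::runif(1) < p_go) "go" else "stop"
  t <- 0
  st <- t0 <- t1 <- character(0)
  starts <- ends <- numeric(0)
  states <- character(0)
  while (t < total_t) {
    rate <- if (state == "go") k_gs else k_sg
    d <- stats::rexp(1, rate)
    starts <- c(starts, t)
    ends <- c(ends, min(t + d, total_t))
    states <- c(states, state)
    t <- t + d
    state <- if (state == "go") "stop" else "go"
  }
  tibble::tibble(state = states, t_start = starts, t_end = ends)
}

# cumulative go-time at arbitrary times, from a dwell table
.cum_go_time <- function(states, at) {
  nodes <- c(states$t_start[1], states$t_end)
  cum <- c(0, cumsum(ifelse(states$state == "go",
                            states$t_end - states$t_start, 0)))
  stats::approx(nodes, cum, xout = at, rule = 2)$y
}

#' Generate a two-state (stop/go) length trace
#'
#' Alternating exponential dwells (go -> stop at `k_gs`, stop -> go at
#' `k_sg`), starting from the stationary state. Fibril length integrates the
#' go-state speed `v_go` and is sampled on a uniform frame grid with Gaussian
#' tracking noise, emulating a confocal length-versus-time record.
#'
#' @param k_sg Stop -> go switching rate, min^-1.
#' @param k_gs Go -> stop switching rate, min^-1.
#' @param v_go Elongation speed while growing, nm/min.
#' @param frame_dt Frame interval, min.
#' @param total_t Total observation time, min.
#' @param noise_sd Tracking noise, nm (50 nm ~ sub-pixel confocal
#'   localization).
#' @param seed Integer seed.
#' @param fibril_id Identifier placed in the trace.
#' @return List with `trace` (tibble `fibril_id`, `time_min`, `length_um`)
#'   and `truth` (dwell table, realized go fraction, the parameters).
#' @export
gen_two_state_trace <- function(k_sg, k_gs, v_go, frame_dt = 3.3,
                                total_t = 3000, noise_sd = 50, seed = 1L,
                                fibril_id = "syn_1") {
  stopifnot(k_sg > 0, k_gs > 0, v_go > 0, frame_dt > 0, total_t > frame_dt)
  withr::with_seed(seed, {
    states <- .two_state_realization(k_sg, k_gs, total_t)
    frames <- seq(0, total_t, by = frame_dt)
    len_nm <- v_go * .cum_go_time(states, frames)
    if (noise_sd > 0) len_nm <- len_nm + stats::rnorm(length(frames), 0, noise_sd)
    trace <- tibble::tibble(fibril_id = fibril_id, time_min = frames,
                            length_um = len_nm / 1000)
    go_frac <- .cum_go_time(states, total_t) / total_t
    list(trace = trace,
         truth = list(states = states, go_fraction = go_frac,
                      p_go = k_sg / (k_sg + k_gs),
                      params = list(k_sg = k_sg, k_gs = k_gs, v_go = v_go,
                                    frame_dt = frame_dt, total_t = total_t,
                                    noise_sd = noise_sd, seed = seed)))
  })
}

#' Generate a mixed population of twisted and non-twisted fibril traces
#'
#' Each fibril is twisted with probability `[G]/([G] + [G3])` from the
#' monomer-trimer equilibrium at `g_tot` (and non-twisted otherwise), then
#' simulated as a two-state trace with its class's speed and switching rates.
#' Class speeds default to the two observed growth-speed peaks (~25 nm/min
#' for twisted, ~100 nm/min for non-twisted).
#'
#' @inheritParams gen_two_state_trace
#' @param g_tot,k0 Total concentration and equilibrium scale, mg/mL.
#' @param n_fibrils Number of fibrils.
#' @param v_twisted,v_nontwisted Class go-speeds, nm/min.
#' @param rates_twisted,rates_nontwisted Lists with `k_sg`, `k_gs` per class
#'   (defaults representative of the measured switching rates).
#' @return List with `traces` (long tibble) and `truth` (per-fibril class
#'   labels and realized go fractions, plus the twisted-class weight used).
#' @export
gen_population <- function(g_tot, k0 = 1, n_fibrils = 20,
                           v_twisted = 25, v_nontwisted = 100,
                           rates_twisted = list(k_sg = 0.1, k_gs = 0.03),
                           rates_nontwisted = list(k_sg = 0.1, k_gs = 0.03),
                           frame_dt = 3.3, total_t = 3000, noise_sd = 50,
                           seed = 1L) {
  stopifnot(n_fibrils >= 1)
  state <- solve_partition(g_tot, k0)
  w_tw <- 1 - trimer_number_fraction(state)
  withr::with_seed(seed, {
    twisted <- stats::runif(n_fibrils) < w_tw
    traces <- vector("list", n_fibrils)
    go_frac <- numeric(n_fibrils)
    for (i in seq_len(n_fibrils)) {
      p <- if (twisted[i]) rates_twisted else rates_nontwisted
      v <- if (twisted[i]) v_twisted else v_nontwisted
      states <- .two_state_realization(p$k_sg, p$k_gs, total_t)
      frames <- seq(0, total_t, by = frame_dt)
      len_nm <- v * .cum_go_time(states, frames)
      if (noise_sd > 0) len_nm <- len_nm + stats::rnorm(length(frames), 0, noise_sd)
      traces[[i]] <- tibble::tibble(fibril_id = sprintf("fib_%03d", i),
                                    time_min = frames, length_um = len_nm / 1000)
      go_frac[i] <- .cum_go_time(states, total_t) / total_t
    }
    list(traces = do.call(rbind, traces),
         truth = tibble::tibble(fibril_id = sprintf("fib_%03d", seq_len(n_fibrils)),
                                class = ifelse(twisted, "twisted", "nontwisted"),
                                go_fraction = go_frac),
         w_twisted = w_tw)
  })
}

#' Sample i.i.d. exponential dwell durations
#'
#' @param k Rate, min^-1.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of durations (min); sample mean tends to `1/k`.
#' @export
gen_dwell_sample <- function(k, n, seed = 1L) {
  stopifnot(k > 0, n >= 1)
  withr::with_seed(seed, stats::rexp(n, k))
}

# discrete WLC tangent walk; consumes RNG. Per-step turning angles are drawn
# so that <cos(theta)> = exp(-step/lp) EXACTLY (von Mises-Fisher step on the
# sphere with numerically inverted Langevin concentration), making the
# tangent autocorrelation <t(0).t(s)> = exp(-s/lp) at the nodes.
.wlc_chain <- function(L, lp, step) {
  n <- max(1L, round(L / step))
  h <- L / n
  if (is.infinite(lp)) {
    return(cbind(x = numeric(n + 1), y = numeric(n + 1), z = h * (0:n)))
  }
  rho <- exp(-h / lp)
  langevin <- function(k) ifelse(k > 20, 1 - 1 / k, 1 / tanh(k) - 1 / k)
  kappa <- stats::uniroot(function(k) langevin(k) - rho,
                          lower = 1e-8, upper = 1e16, tol = 1e-12)$root
  u <- stats::runif(n)
  # inverse CDF of cos(theta) under density ~ exp(kappa * cos)
  cos_t <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  cos_t <- pmax(-1, pmin(1, cos_t))
  sin_t <- sqrt(1 - cos_t^2)
  phi <- stats::runif(n, 0, 2 * pi)
  tang <- matrix(0, n, 3)
  t_cur <- c(0, 0, 1)
  for (i in seq_len(n)) {
    ref <- if (abs(t_cur[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n1 <- c(t_cur[2] * ref[3] - t_cur[3] * ref[2],
            t_cur[3] * ref[1] - t_cur[1] * ref[3],
            t_cur[1] * ref[2] - t_cur[2] * ref[1])
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(t_cur[2] * n1[3] - t_cur[3] * n1[2],
            t_cur[3] * n1[1] - t_cur[1] * n1[3],
            t_cur[1] * n1[2] - t_cur[2] * n1[1])
    t_cur <- cos_t[i] * t_cur + sin_t[i] * (cos(phi[i]) * n1 + sin(phi[i]) * n2)
    t_cur <- t_cur / sqrt(sum(t_cur^2))
    tang[i, ] <- t_cur
  }
  pos <- apply(tang * h, 2, cumsum)
  if (n == 1L) pos <- matrix(pos, 1, 3)
  rbind(c(0, 0, 0), pos)
}

#' Sample one discrete worm-like chain
#'
#' Discretized 3D worm-like chain of contour length `L` and persistence
#' length `lp`: unit tangents turn by von Mises-Fisher angles chosen so the
#' tangent autocorrelation is exactly `exp(-s/lp)` at the chain nodes. The
#' ensemble mean-square end-to-end distance matches [expected_ree_sq()] up to
#' a discretization term of order `(step/lp)^2`.
#'
#' @param L Contour length, um.
#' @param lp Persistence length, um (`Inf` gives a straight rod).
#' @param step Segment length, um; must satisfy `step <= lp/10`.
#' @param seed Integer seed.
#' @param strict If `TRUE` (default) refuse a too-coarse `step`; otherwise
#'   warn and continue.
#' @return An `(n+1) x 3` matrix of node coordinates (um) with attributes
#'   `L`, `lp`, `step`.
#' @export
sample_wlc_chain <- function(L, lp, step = lp / 100, seed = 1L, strict = TRUE) {
  stopifnot(L > 0, lp > 0, step > 0)
  if (step > lp / 10) {
    msg <- sprintf("step = %g um is coarser than lp/10 = %g um; discretization inadequate", step, lp / 10)
    if (strict) stop(msg) else warning(msg)
  }
  chain <- withr::with_seed(seed, .wlc_chain(L, lp, step))
  attr(chain, "L") <- L
  attr(chain, "lp") <- lp
  attr(chain, "step") <- step
  chain
}

#' Sample an ensemble of chains as contour / end-to-end pairs
#'
#' @inheritParams sample_wlc_chain
#' @param n_chains Number of chains.
#' @param L_range Contour lengths are drawn uniformly from this range (um).
#' @return Tibble with `fibril_id`, `contour_length_um`, `ree_um`, ready for
#'   [fit_persistence_length()].
#' @export
gen_wlc_samples <- function(n_chains, lp, L_range = c(5, 40), step = lp / 100,
                            seed = 1L) {
  stopifnot(n_chains >= 1, length(L_range) == 2, all(L_range > 0))
  withr::with_seed(seed, {
    Ls <- stats::runif(n_chains, L_range[1], L_range[2])
    ree <- vapply(Ls, function(L) {
      ch <- .wlc_chain(L, lp, step)
      sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2))
    }, numeric(1))
    tibble::tibble(fibril_id = sprintf("chain_%04d", seq_len(n_chains)),
                   contour_length_um = Ls, ree_um = ree)
  })
}
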