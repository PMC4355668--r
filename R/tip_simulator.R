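#' Configuration for stochastic tip simulations
#'
#' @param seed Integer seed; every random draw in a simulation derives from it.
#' @param t_max Simulated time horizon, min.
#' @param delta_twisted Length added per incorporated monomer, nm. Default
#'   0.47 nm, the cross-beta stacking distance of one molecular layer.
#' @param delta_nontwisted Length added per incorporated trimer, nm (three
#'   layers).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, t_max = 1e4, delta_twisted = 0.47,
                       delta_nontwisted = 1.41) {
  stopifnot(t_max > 0, delta_twisted > 0, delta_nontwisted > 0)
  structure(list(seed = as.integer(seed), t_max = t_max,
                 delta_twisted = delta_twisted,
                 delta_nontwisted = delta_nontwisted),
            class = "sim_config")
}

#' Exact stochastic simulation of a fibril tip
#'
#' Simulates the continuous-time Markov chain of one fibril tip: from FREE
#' the cognate block binds at rate `kb_grow * [cognate]` (-> BOUND_GROW) or
#' the opposite block binds at rate `kb_block * [blocker]` (-> BLOCKED); a
#' bound cognate either unbinds (rate `ku_grow`) or is incorporated by
#' conformational rearrangement (rate `kr`), both returning the tip to FREE;
#' a blocker unbinds at `ku_block`. Waiting times are exponential with the
#' total exit rate and branches are chosen proportionally to rates, so the
#' simulation is exact (Gillespie). Bulk concentrations are held constant:
#' a single fibril consumes a negligible share of the monomer/trimer pools.
#'
#' The chain alternates FREE -> occupied -> FREE, so whole cycles are drawn
#' in vectorized blocks; this is statistically identical to the event-by-event
#' formulation.
#'
#' @param rc A [rate_constants()] object.
#' @param state One row of a `solution_state` (bulk concentrations).
#' @param fibril_class `"twisted"` (cognate: monomer) or `"nontwisted"`.
#' @param config A [sim_config()].
#' @return An `event_log` tibble with columns `t` (min), `from`, `to`,
#'   `incorporated` (TRUE only for BOUND_GROW -> FREE via rearrangement),
#'   plus attributes `fibril_class`, `seed`, `t_max`.
#' @export
simulate_tip <- function(rc, state, fibril_class = c("twisted", "nontwisted"),
                         config = sim_config()) {
  stopifnot(inherits(rc, "rate_constants"), nrow(state) == 1L)
  fibril_class <- match.arg(fibril_class)
  cl <- if (fibril_class == "twisted") rc$twisted else rc$nontwisted
  conc_grow <- if (fibril_class == "twisted") state$g_mono else state$g_tri
  conc_block <- if (fibril_class == "twisted") state$g_tri else state$g_mono
  r_g <- cl$kb_grow * conc_grow
  r_b <- cl$kb_block * conc_block
  k_exit <- cl$ku_grow + cl$kr
  p_inc <- cl$kr / k_exit
  t_max <- config$t_max

  empty <- tibble::tibble(t = numeric(0), from = character(0),
                          to = character(0), incorporated = logical(0))
  if (r_g + r_b == 0) {
    warning("no binding possible (r_g + r_b = 0): tip stays FREE for all of t_max")
    return(.as_event_log(empty, fibril_class, config))
  }
  if (cl$ku_block == 0 && r_b > 0) {
    warning("ku_block = 0: BLOCKED is absorbing; simulation ends at t_max")
  }

  arr <- dep <- numeric(0)
  bound <- inc <- logical(0)
  withr::with_seed(config$seed, {
    mean_cycle <- 1 / (r_g + r_b) +
      (r_g / (r_g + r_b)) / k_exit +
      if (cl$ku_block > 0) (r_b / (r_g + r_b)) / cl$ku_block else 0
    t_cur <- 0
    while (t_cur < t_max) {
      n <- max(1000L, ceiling((t_max - t_cur) / mean_cycle * 1.15))
      wait <- stats::rexp(n, r_g + r_b)
      to_bound <- stats::runif(n) < r_g / (r_g + r_b)
      dwell <- numeric(n)
      dwell[to_bound] <- stats::rexp(sum(to_bound), k_exit)
      if (cl$ku_block > 0) {
        dwell[!to_bound] <- stats::rexp(sum(!to_bound), cl$ku_block)
      } else {
        dwell[!to_bound] <- Inf
      }
      inc_i <- to_bound & (stats::runif(n) < p_inc)
      cyc_end <- t_cur + cumsum(wait + dwell)
      arr <- c(arr, cyc_end - dwell)
      dep <- c(dep, cyc_end)
      bound <- c(bound, to_bound)
      inc <- c(inc, inc_i)
      t_cur <- cyc_end[n]
      if (!is.finite(t_cur)) break
    }
  })

  occ_state <- ifelse(bound, "BOUND_GROW", "BLOCKED")
  log <- tibble::tibble(
    t = as.vector(rbind(arr, dep)),
    from = as.vector(rbind("FREE", occ_state)),
    to = as.vector(rbind(occ_state, "FREE")),
    incorporated = as.vector(rbind(FALSE, inc))
  )
  log <- log[log$t <= t_max & is.finite(log$t), , drop = FALSE]
  .as_event_log(log, fibril_class, config)
}

.as_event_log <- function(log, fibril_class, config) {
  attr(log, "fibril_class") <- fibril_class
  attr(log, "seed") <- config$seed
  attr(log, "t_max") <- config$t_max
  class(log) <- c("event_log", class(log))
  log
}

#' Fraction of simulated time spent in the growing state
#'
#' Total time in FREE or BOUND_GROW divided by the simulated horizon. The tip
#' starts FREE at t = 0; an episode still open at `t_max` is truncated there.
#'
#' @param log An `event_log` from [simulate_tip()].
#' @param t_max Horizon; defaults to the log's `t_max` attribute.
#' @return A probability in `[0, 1]`.
#' @export
occupancy_growth_fraction <- function(log, t_max = attr(log, "t_max")) {
  if (is.null(t_max) || !is.finite(t_max) || t_max <= 0) {
    stop("zero-duration log: t_max must be positive")
  }
  ep <- .blocked_episodes(log, t_max)
  1 - sum(ep$end - ep$start) / t_max
}

# blocked intervals [start, end) clipped to [0, t_max]
.blocked_episodes <- function(log, t_max) {
  starts <- log$t[log$to == "BLOCKED"]
  ends <- log$t[log$from == "BLOCKED"]
  if (length(ends) < length(starts)) ends <- c(ends, t_max)  # open at horizon
  data.frame(start = pmin(starts, t_max), end = pmin(ends, t_max))
}

#' Simulated growth occupancy with a batch-means standard error
#'
#' Runs [simulate_tip()] over increasing horizons until the batch-means
#' standard error of the growing-state occupancy falls below `se_target`
#' (or `t_max_cap` is hit). Used as the stochastic cross-check of the
#' closed-form growth probabilities.
#'
#' @inheritParams simulate_tip
#' @param se_target Target standard error of the occupancy estimate.
#' @param t_max_init Initial horizon, min.
#' @param t_max_cap Largest horizon attempted, min.
#' @param n_batches Batches for the batch-means SE.
#' @param seed Integer seed.
#' @return List with `p` (occupancy), `se`, `t_max`.
#' @export
estimate_growth_occupancy <- function(rc, state, fibril_class = "twisted",
                                      se_target = 0.005, seed = 1L,
                                      t_max_init = 2e4, t_max_cap = 2e7,
                                      n_batches = 50L) {
  t_max <- t_max_init
  repeat {
    log <- simulate_tip(rc, state, fibril_class,
                        sim_config(seed = seed, t_max = t_max))
    ep <- .blocked_episodes(log, t_max)
    edges <- seq(0, t_max, length.out = n_batches + 1L)
    blocked_cum <- vapply(edges, function(e) {
      sum(pmax(0, pmin(ep$end, e) - pmin(ep$start, e)))
    }, numeric(1))
    p_bin <- 1 - diff(blocked_cum) / diff(edges)
    se <- stats::sd(p_bin) / sqrt(n_batches)
    if (se <= se_target || t_max >= t_max_cap) {
      return(list(p = 1 - blocked_cum[n_batches + 1L] / t_max,
                  se = se, t_max = t_max))
    }
    # batch-means variance scales ~ 1/T; aim with 40% headroom
    t_max <- min(t_max_cap, max(2 * t_max, 1.4 * t_max * (se / se_target)^2))
  }
}

#' Render an event log as a length-versus-time trace
#'
#' Samples cumulative fibril length on a uniform frame grid: length at frame
#' time t is (number of incorporations up to t) times the class length
#' increment, plus Gaussian tracking noise. Before noise the trace is a
#' non-decreasing step function.
#'
#' @param log An `event_log` from [simulate_tip()].
#' @param config The [sim_config()] used (provides length increments).
#' @param frame_dt Frame interval, min (3.3 matches the confocal acquisition
#'   the model describes).
#' @param noise_sd Tracking noise standard deviation, nm.
#' @param seed Seed for the noise draws.
#' @param fibril_id Identifier placed in the output.
#' @return A trace tibble with columns `fibril_id`, `time_min`, `length_um`.
#' @export
render_trace <- function(log, config, frame_dt = 3.3, noise_sd = 50,
                         seed = 1L, fibril_id = "sim_1") {
  stopifnot(frame_dt > 0, noise_sd >= 0)
  t_max <- attr(log, "t_max")
  cls <- attr(log, "fibril_class")
  delta <- if (identical(cls, "twisted")) config$delta_twisted else config$delta_nontwisted
  frames <- seq(0, t_max, by = frame_dt)
  inc_t <- sort(log$t[log$incorporated])
  n_inc <- findInterval(frames, inc_t)
  len_nm <- n_inc * delta
  if (noise_sd > 0) {
    len_nm <- len_nm + withr::with_seed(seed, stats::rnorm(length(frames), 0, noise_sd))
  }
  tibble::tibble(fibril_id = fibril_id, time_min = frames, length_um = len_nm / 1000)
}
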