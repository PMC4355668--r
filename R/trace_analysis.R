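#' Segment a length-versus-time trace into stop and go dwells
#'
#' Frame-to-frame speeds are smoothed with a centered moving average
#' (`smooth_window` intervals, shrinking at the edges) and each interval is
#' classified `stop` when the smoothed speed is below `v_thresh`. Runs of
#' intervals shorter than `min_run` are merged into the flanking state
#' (shortest runs first; ties broken toward the earlier run), so isolated
#' noise flips do not create spurious dwells. Segments tile the trace
#' exactly.
#'
#' @param trace Data frame for one fibril with columns `time_min`
#'   (strictly increasing, uniformly spaced) and `length_um`; at least 4
#'   frames.
#' @param v_thresh Stop/go speed threshold, nm/min.
#' @param smooth_window Centered moving-average window, odd number of
#'   intervals.
#' @param min_run Minimum run length, intervals.
#' @return Tibble of segments: `state`, `t_start`, `t_end`, `duration`
#'   (min), `delta_length` (um), plus `fibril_id` when present in `trace`.
#' @export
segment_trace <- function(trace, v_thresh = 10, smooth_window = 3, min_run = 2) {
  stopifnot(is.data.frame(trace),
            all(c("time_min", "length_um") %in% names(trace)),
            v_thresh > 0, min_run >= 1,
            smooth_window >= 1, smooth_window %% 2 == 1)
  tt <- trace$time_min
  ll <- trace$length_um
  if (length(tt) < 4) stop("trace must have at least 4 frames")
  dts <- diff(tt)
  if (any(dts <= 0) || diff(range(dts)) > 1e-6) {
    stop("trace times must be strictly increasing and uniformly spaced")
  }
  if (length(tt) <= smooth_window) stop("trace shorter than the smoothing window")
  dt <- dts[1]
  speed <- diff(ll) * 1000 / dt  # nm/min per interval
  m <- length(speed)
  h <- (smooth_window - 1L) %/% 2L
  cs <- c(0, cumsum(speed))
  lo <- pmax(seq_len(m) - h, 1L)
  hi <- pmin(seq_len(m) + h, m)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  is_stop <- sm < v_thresh

  # merge short runs, shortest first, into the (opposite) flanking state
  repeat {
    r <- rle(is_stop)
    short <- which(r$lengths < min_run)
    if (length(short) == 0L || length(r$lengths) == 1L) break
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[j] - r$lengths[j] + 1L):ends[j]
    is_stop[idx] <- !r$values[j]
  }

  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- tibble::tibble(
    state = ifelse(r$values, "stop", "go"),
    t_start = tt[starts],
    t_end = tt[ends + 1L],
    duration = tt[ends + 1L] - tt[starts],
    delta_length = ll[ends + 1L] - ll[starts]
  )
  if ("fibril_id" %in% names(trace)) {
    seg <- tibble::tibble(fibril_id = trace$fibril_id[1], seg)
  }
  seg
}

#' Fit an exponential dwell-time distribution
#'
#' Default (`method = "survival"`) follows the cumulative-count procedure
#' used for the published dwell histograms: the unnormalized survival counts
#' `N(t) = #(duration >= t)` are evaluated at the observed durations at or
#' above `t_min_censor` and a least-squares line is fitted to
#' `(t, log N(t))`; the rate is minus the slope, the amplitude
#' `a = exp(intercept)`, and `k_err` is the slope's standard error. Because
#' the exponential is memoryless, left-censoring at `t_min_censor` (dwells
#' shorter than the frame interval cannot be observed) does not bias the
#' slope. `method = "mle"` gives the shifted-exponential maximum-likelihood
#' alternative `k = 1/(mean(d) - t_min_censor)`.
#'
#' @param durations Dwell durations, min.
#' @param t_min_censor Left-censoring threshold, min; durations below it are
#'   dropped before fitting.
#' @param method `"survival"` (default) or `"mle"`.
#' @return A `dwell_fit` list: `a`, `k` (min^-1), `k_err`, `n_events`,
#'   `method`, `t_min_censor`.
#' @export
fit_dwell_exponential <- function(durations, t_min_censor = 0,
                                  method = c("survival", "mle")) {
  method <- match.arg(method)
  stopifnot(is.numeric(durations), t_min_censor >= 0)
  d <- durations[is.finite(durations) & durations >= t_min_censor]
  if (length(d) < 5) stop("insufficient data: need at least 5 durations above t_min_censor")
  if (diff(range(d)) <= 1e-12 * max(d)) stop("singular fit: all durations are equal")
  if (method == "survival") {
    ds <- sort(d)
    u <- unique(ds)
    n_ge <- length(ds) - findInterval(u, ds, left.open = TRUE)
    fit <- stats::lm(log(n_ge) ~ u)
    k <- -unname(stats::coef(fit)[2])
    if (k <= 0) stop("singular fit: survival counts do not decay")
    out <- list(a = exp(unname(stats::coef(fit)[1])), k = k,
                k_err = unname(summary(fit)$coefficients[2, "Std. Error"]),
                n_events = length(d))
  } else {
    k <- 1 / (mean(d) - t_min_censor)
    if (!is.finite(k) || k <= 0) stop("singular fit: mean duration at or below censor")
    out <- list(a = length(d), k = k, k_err = k / sqrt(length(d)),
                n_events = length(d))
  }
  structure(c(out, list(method = method, t_min_censor = t_min_censor)),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Exponential dwell fit (%s): k = %.4g +/- %.2g min^-1, n = %d\n",
              x$method, x$k, x$k_err, x$n_events))
  invisible(x)
}

#' Growth probability from switching rates
#'
#' The long-run probability of finding a fibril in the growing state,
#' \eqn{p_G = k_{s\to g} / (k_{s\to g} + k_{g\to s})}.
#'
#' @param k_sg Stop -> go rate, min^-1.
#' @param k_gs Go -> stop rate, min^-1.
#' @return Probability in `[0, 1]`. Vectorized.
#' @examples
#' growth_probability(0.113, 0.0268)  # 0.808
#' @export
growth_probability <- function(k_sg, k_gs) {
  stopifnot(all(k_sg >= 0), all(k_gs >= 0))
  if (any(k_sg + k_gs == 0)) stop("k_sg + k_gs must be positive")
  k_sg / (k_sg + k_gs)
}

#' Propagated uncertainty of the growth probability
#'
#' Treating the switching-rate uncertainties as uncorrelated,
#' \deqn{\sigma_G = \frac{\sqrt{(k_{g\to s}\sigma_{s\to g})^2 +
#'   (k_{s\to g}\sigma_{g\to s})^2}}{(k_{s\to g}+k_{g\to s})^2}.}
#'
#' @inheritParams growth_probability
#' @param sigma_sg,sigma_gs Standard errors of the rates, min^-1.
#' @return Standard error of the growth probability. Vectorized.
#' @export
growth_probability_error <- function(k_sg, sigma_sg, k_gs, sigma_gs) {
  stopifnot(all(k_sg > 0), all(k_gs > 0), all(sigma_sg >= 0), all(sigma_gs >= 0))
  sqrt((k_gs * sigma_sg)^2 + (k_sg * sigma_gs)^2) / (k_sg + k_gs)^2
}

#' Speeds of go segments
#'
#' @param segments Segment table from [segment_trace()].
#' @return Speeds `delta_length/duration` of the go segments, nm/min.
#' @export
segment_speeds <- function(segments) {
  go <- segments[segments$state == "go", , drop = FALSE]
  if (nrow(go) == 0L) {
    warning("no go segments: returning an empty speed vector")
    return(numeric(0))
  }
  go$delta_length * 1000 / go$duration
}

#' Histogram of growth speeds
#'
#' Left-closed, right-open bins of width `bin_width` starting at 0 (the bin
#' convention of the published speed distributions). Negative speeds are
#' excluded with a message.
#'
#' @param speeds Speeds, nm/min.
#' @param bin_width Bin width, nm/min.
#' @return Tibble with `bin_left`, `bin_right`, `count`; counts sum to the
#'   number of non-negative speeds.
#' @export
speed_histogram <- function(speeds, bin_width = 10) {
  stopifnot(bin_width > 0)
  neg <- sum(speeds < 0)
  if (neg > 0) message(sprintf("excluded %d negative speed(s)", neg))
  s <- speeds[speeds >= 0]
  if (length(s) == 0L) {
    return(tibble::tibble(bin_left = numeric(0), bin_right = numeric(0),
                          count = integer(0)))
  }
  idx <- floor(s / bin_width)
  tab <- table(idx)
  lefts <- as.numeric(names(tab)) * bin_width
  tibble::tibble(bin_left = lefts, bin_right = lefts + bin_width,
                 count = as.integer(tab))
}

#' Remove extremely long pauses, transparently
#'
#' Dwell-duration outlier removal is off by default; when a threshold (or a
#' quantile policy) is given, durations above it are removed and the count is
#' reported, never silently.
#'
#' @param durations Dwell durations, min.
#' @param max_duration Absolute threshold, min (default `Inf`: no trimming).
#' @param quantile_policy Optional quantile in (0, 1); when given, the
#'   threshold is the empirical quantile of `durations`.
#' @return List with `kept`, `removed_count`, `threshold`.
#' @export
trim_long_pauses <- function(durations, max_duration = Inf, quantile_policy = NULL) {
  thr <- if (!is.null(quantile_policy)) {
    stopifnot(quantile_policy > 0, quantile_policy < 1)
    # inverse-ECDF quantile: the threshold is an observed duration
    as.numeric(stats::quantile(durations, quantile_policy, type = 1))
  } else max_duration
  kept <- durations[durations <= thr]
  removed <- length(durations) - length(kept)
  if (removed > 0) message(sprintf("trim_long_pauses: removed %d duration(s) above %.4g min", removed, thr))
  list(kept = kept, removed_count = removed, threshold = thr)
}

# ---- missed-event (dead-time) correction ---------------------------------

#' Detection probability of stop dwells for a given segmentation
#'
#' Plateau segmentation at a finite frame interval cannot see short stops: a
#' stop shorter than roughly `(min_run + smooth_window - 1)` frames never
#' produces enough below-threshold intervals. This function measures the
#' classifier's detection curve directly: for each stop duration on a grid it
#' inserts a stop of that duration (random frame phase) into a growing trace
#' with the given speed and noise, segments it, and records whether any stop
#' segment overlaps the truth, together with the measured-minus-true duration
#' of detected stops (boundary erosion).
#'
#' @param v_go Go-state speed, nm/min.
#' @param noise_sd Tracking noise, nm.
#' @param frame_dt Frame interval, min.
#' @param v_thresh,smooth_window,min_run Segmentation parameters (see
#'   [segment_trace()]).
#' @param event `"stop"` probes a stop plateau inserted in a growing
#'   background; `"go"` probes a growth burst inserted in a flat background
#'   (short go dwells are missed too, merging the stops around them).
#' @param d_grid Event durations to probe, min; defaults to 0.5-10 frames.
#' @param n_rep Replicates per grid point.
#' @param seed Integer seed.
#' @return Tibble with `duration`, `p_detect`, `erosion` (mean true minus
#'   measured duration among detected events, min).
#' @export
detection_curve <- function(v_go, noise_sd, frame_dt = 3.3, v_thresh = 10,
                            smooth_window = 3, min_run = 2,
                            event = c("stop", "go"),
                            d_grid = frame_dt * seq(0.5, 10, by = 0.5),
                            n_rep = 200, seed = 1L) {
  event <- match.arg(event)
  pad <- 30L  # background frames on each side
  withr::with_seed(seed, {
    res <- lapply(d_grid, function(d) {
      det <- logical(n_rep)
      ero <- rep(NA_real_, n_rep)
      for (r in seq_len(n_rep)) {
        phase <- stats::runif(1, 0, frame_dt)
        t_ev0 <- pad * frame_dt + phase
        n_frames <- pad + ceiling((d + phase) / frame_dt) + pad
        tt <- (0:n_frames) * frame_dt
        if (event == "stop") {
          go_time <- pmin(tt, t_ev0) + pmax(0, tt - (t_ev0 + d))
        } else {
          go_time <- pmin(pmax(0, tt - t_ev0), d)
        }
        len <- (v_go * go_time + stats::rnorm(n_frames + 1, 0, noise_sd)) / 1000
        seg <- segment_trace(data.frame(time_min = tt, length_um = len),
                             v_thresh = v_thresh, smooth_window = smooth_window,
                             min_run = min_run)
        st <- seg[seg$state == event &
                    seg$t_end > t_ev0 & seg$t_start < t_ev0 + d, , drop = FALSE]
        det[r] <- nrow(st) > 0
        if (det[r]) ero[r] <- d - sum(st$duration)
      }
      c(p = mean(det), e = mean(ero, na.rm = TRUE))
    })
    res <- do.call(rbind, res)
    tibble::tibble(duration = d_grid, p_detect = res[, "p"],
                   erosion = ifelse(is.nan(res[, "e"]), NA_real_, res[, "e"]))
  })
}

# tracking noise from the lag-1 autocovariance of frame displacements
# (diff = signal + e[i+1] - e[i] => lag-1 autocovariance ~= -var(e); the
# signal's own positive autocorrelation makes this an underestimate, which
# the indirect-inference refinement compensates by matching the same
# statistic on simulated traces)
.noise_from_traces <- function(by_fib) {
  acov <- mean(unlist(lapply(by_fib, function(tr) {
    d <- diff(tr$length_um)
    if (length(d) < 3) return(NA_real_)
    mean((d[-1] - mean(d)) * (d[-length(d)] - mean(d)))
  })), na.rm = TRUE)
  sqrt(max(0, -acov)) * 1000
}

# integrate g(d) * k exp(-k d) over the calibration grid, with g
# linearly interpolated, g = g_lo below the grid and g = g_hi above it.
.exp_weighted_mean <- function(curve_d, curve_g, k, g_lo, g_hi, what = c("mean", "dmean")) {
  what <- match.arg(what)
  dd <- seq(0, max(curve_d), length.out = 2000L)
  g <- stats::approx(c(0, curve_d), c(g_lo, curve_g), xout = dd, rule = 2)$y
  w <- k * exp(-k * dd)
  integrand <- if (what == "mean") g * w else dd * g * w
  core <- sum((integrand[-1] + integrand[-length(dd)]) / 2 * diff(dd))
  # analytic tail beyond the grid where g = g_hi
  tail <- if (what == "mean") {
    g_hi * exp(-k * max(curve_d))
  } else {
    g_hi * exp(-k * max(curve_d)) * (max(curve_d) + 1 / k)
  }
  core + tail
}

#' Switching rates, growth probability and error from a set of traces
#'
#' The full stop-go analysis pipeline: segment every trace, pool interior
#' dwell durations (segments touching a trace boundary are censored and
#' dropped), fit exponential survival lines to the stop and go durations, and
#' convert the switching rates into a growth probability with propagated
#' uncertainty.
#'
#' Two estimator details matter at a 3.3-min frame interval:
#'
#' * **Adaptive threshold.** With `v_thresh = NULL` the traces are first
#'   segmented at 10 nm/min, the go speed is estimated, and segmentation is
#'   repeated with the threshold at half the estimated go speed (bounded
#'   below by 5 nm/min), which balances missed stops against false ones.
#' * **Missed-event correction** (`correct_missed = TRUE`). Dwells shorter
#'   than a few frames are invisible to any plateau classifier: a missed
#'   stop fuses the go dwells around it (inflating apparent go durations and
#'   thinning the go -> stop count), and a missed go dwell symmetrically
#'   fuses its neighbouring stops. Both detection curves are measured by
#'   [detection_curve()] under the estimated speed and noise. If an observed
#'   dwell of one state is a geometric chain of true dwells joined by missed
#'   dwells of the other state, its survival-tail rate is
#'   \eqn{\lambda = k\,p /(1 + k (1-p)\bar{m})} where \eqn{k} is the true
#'   rate, \eqn{p} the (duration-weighted) probability that the *other*
#'   state's dwell is detected, and \eqn{\bar{m}} the mean duration of a
#'   missed dwell of the other state. Inverting both relations, which couple
#'   through the detection weights, gives the corrected rate pair; the
#'   coupled system is solved by fixed-point iteration. Boundary erosion
#'   shifts measured durations but not survival-tail slopes, so it only
#'   enters through the censoring thresholds.
#' * **Indirect-inference refinement** (`refine_iterations > 0`). The
#'   single-event calibration cannot see context effects (e.g. a short go
#'   dwell squeezed between two eroded stops is missed more often than an
#'   isolated one). The analytically corrected rates are therefore refined
#'   by simulation matching: two-state traces are simulated at the current
#'   estimates (same frame interval, speed, noise), pushed through the
#'   identical segmentation and tail fits, and the rates are updated
#'   multiplicatively until the simulated observed tail rates match the
#'   measured ones. The apparent go speed is matched the same way.
#'
#' @param traces Long-format trace table (`fibril_id`, `time_min`,
#'   `length_um`), one or more fibrils.
#' @param g_tot Optional concentration label copied into the output, mg/mL.
#' @param v_thresh Segmentation threshold, nm/min, or `NULL` for the
#'   adaptive two-pass rule.
#' @param smooth_window,min_run See [segment_trace()].
#' @param correct_missed Apply the missed-event correction.
#' @param calib_n_rep,calib_seed Calibration effort and seed for
#'   [detection_curve()].
#' @param refine_iterations Indirect-inference iterations (0 disables the
#'   simulation-matching refinement).
#' @param refine_cycles Number of stop/go cycles per refinement simulation.
#' @return A one-row `rate_summary` tibble: `g_tot`, `k_sg`, `sigma_sg`,
#'   `k_gs`, `sigma_gs`, `p_g`, `sigma_g`, `n_stop`, `n_go`, `p_detect`,
#'   `v_go_nm_min`, `noise_nm`, `v_thresh`; the segment table and settings
#'   ride along as attributes `segments` and `settings`.
#' @export
stopgo_rates <- function(traces, g_tot = NA_real_, v_thresh = NULL,
                         smooth_window = 3, min_run = 2,
                         correct_missed = TRUE,
                         calib_n_rep = 200, calib_seed = 1L,
                         refine_iterations = 4, refine_cycles = 6000) {
  stopifnot(is.data.frame(traces),
            all(c("fibril_id", "time_min", "length_um") %in% names(traces)))
  by_fib <- split(traces, traces$fibril_id)
  frame_dt <- diff(by_fib[[1]]$time_min[1:2])

  seg_all <- function(vt) {
    do.call(rbind, lapply(by_fib, segment_trace, v_thresh = vt,
                          smooth_window = smooth_window, min_run = min_run))
  }
  est_v_go <- function(seg) {
    go <- seg[seg$state == "go", , drop = FALSE]
    if (nrow(go) == 0L) return(NA_real_)
    sum(go$delta_length) * 1000 / sum(go$duration)
  }

  if (is.null(v_thresh)) {
    seg0 <- seg_all(10)
    v0 <- est_v_go(seg0)
    v_thresh <- if (is.finite(v0)) max(5, v0 / 2) else 10
  }
  seg <- seg_all(v_thresh)
  v_go_hat <- est_v_go(seg)

  noise_hat <- .noise_from_traces(by_fib)

  # interior dwells only: boundary segments are right/left-censored
  interior <- do.call(rbind, lapply(split(seg, seg$fibril_id), function(s) {
    if (nrow(s) <= 2) return(s[0, , drop = FALSE])
    s[-c(1, nrow(s)), , drop = FALSE]
  }))
  stop_dur <- interior$duration[interior$state == "stop"]
  go_dur <- interior$duration[interior$state == "go"]

  cal_stop <- cal_go <- NULL
  stop_censor <- go_censor <- (min_run + 1) * frame_dt
  censor_from <- function(cal) {
    sat <- cal$duration[cal$p_detect >= 0.95]
    ero <- stats::weighted.mean(cal$erosion, cal$p_detect, na.rm = TRUE)
    if (length(sat) > 0) max(frame_dt, min(sat) - max(0, ero)) else (min_run + 1) * frame_dt
  }
  if (correct_missed) {
    cal_stop <- detection_curve(v_go = v_go_hat, noise_sd = noise_hat,
                                frame_dt = frame_dt, v_thresh = v_thresh,
                                smooth_window = smooth_window, min_run = min_run,
                                event = "stop", n_rep = calib_n_rep,
                                seed = calib_seed)
    cal_go <- detection_curve(v_go = v_go_hat, noise_sd = noise_hat,
                              frame_dt = frame_dt, v_thresh = v_thresh,
                              smooth_window = smooth_window, min_run = min_run,
                              event = "go", n_rep = calib_n_rep,
                              seed = calib_seed + 1L)
    stop_censor <- censor_from(cal_stop)
    go_censor <- censor_from(cal_go)
  }

  # censored MLE rather than the log-survival line: same estimand, but the
  # survival line's variance is dominated by the sparse deep tail while the
  # truncated-mean MLE has clean 1/sqrt(n) behaviour
  fit_sg <- fit_dwell_exponential(stop_dur, t_min_censor = stop_censor,
                                  method = "mle")
  fit_gs <- fit_dwell_exponential(go_dur, t_min_censor = go_censor,
                                  method = "mle")
  lambda_s <- fit_sg$k  # observed stop-duration rate
  lambda_g <- fit_gs$k  # observed go-duration rate

  p_det_stop <- p_det_go <- 1
  if (correct_missed) {
    detect_stats <- function(cal, k) {
      p <- .exp_weighted_mean(cal$duration, cal$p_detect, k,
                              g_lo = 0, g_hi = 1, what = "mean")
      miss <- 1 - p
      m <- if (miss > 1e-9) {
        .exp_weighted_mean(cal$duration, 1 - cal$p_detect, k,
                           g_lo = 1, g_hi = 0, what = "dmean") / miss
      } else 0
      list(p = p, m = m)
    }
    # observed dwell = geometric chain of true dwells joined by missed dwells
    # of the opposite state: lambda = k p_opp / (1 + k (1 - p_opp) m_opp).
    # Invert both relations jointly by fixed-point iteration.
    k_sg <- lambda_s
    k_gs <- lambda_g
    for (it in 1:25) {
      ds_go <- detect_stats(cal_go, k_gs)     # detection of go dwells
      ds_stop <- detect_stats(cal_stop, k_sg) # detection of stop dwells
      den_s <- ds_go$p - lambda_s * (1 - ds_go$p) * ds_go$m
      den_g <- ds_stop$p - lambda_g * (1 - ds_stop$p) * ds_stop$m
      # corrections beyond ~6x are outside the regime the first-order chain
      # formula supports; cap them (the refinement stage takes over there)
      k_sg_new <- lambda_s / min(1, max(1 / 6, den_s))
      k_gs_new <- lambda_g / min(1, max(1 / 6, den_g))
      conv <- abs(k_sg_new - k_sg) < 1e-10 + 1e-8 * k_sg &&
        abs(k_gs_new - k_gs) < 1e-10 + 1e-8 * k_gs
      k_sg <- k_sg_new
      k_gs <- k_gs_new
      if (conv) break
    }
    p_det_stop <- detect_stats(cal_stop, k_sg)$p
    p_det_go <- detect_stats(cal_go, k_gs)$p
    sigma_sg <- fit_sg$k_err * k_sg / lambda_s
    sigma_gs <- fit_gs$k_err * k_gs / lambda_g
  } else {
    k_sg <- lambda_s
    k_gs <- lambda_g
    sigma_sg <- fit_sg$k_err
    sigma_gs <- fit_gs$k_err
  }

  if (correct_missed && refine_iterations > 0) {
    measure_sim <- function(k_sg_s, k_gs_s, v_s, noise_s, seed_s) {
      total_t <- refine_cycles * (1 / k_sg_s + 1 / k_gs_s)
      n_fib <- 10L
      tt <- total_t / n_fib
      sim_tr <- withr::with_seed(seed_s, {
        do.call(rbind, lapply(seq_len(n_fib), function(j) {
          states <- .two_state_realization(k_sg_s, k_gs_s, tt)
          frames <- seq(0, tt, by = frame_dt)
          len <- v_s * .cum_go_time(states, frames)
          if (noise_s > 0) len <- len + stats::rnorm(length(frames), 0, noise_s)
          tibble::tibble(fibril_id = sprintf("sim_%d", j),
                         time_min = frames, length_um = len / 1000)
        }))
      })
      sim_by <- split(sim_tr, sim_tr$fibril_id)
      seg_s <- do.call(rbind, lapply(sim_by, segment_trace, v_thresh = v_thresh,
                                     smooth_window = smooth_window,
                                     min_run = min_run))
      int_s <- do.call(rbind, lapply(split(seg_s, seg_s$fibril_id), function(s) {
        if (nrow(s) <= 2) return(s[0, , drop = FALSE])
        s[-c(1, nrow(s)), , drop = FALSE]
      }))
      go_s <- int_s[int_s$state == "go", , drop = FALSE]
      list(ls = fit_dwell_exponential(int_s$duration[int_s$state == "stop"],
                                      t_min_censor = stop_censor, method = "mle")$k,
           lg = fit_dwell_exponential(go_s$duration, t_min_censor = go_censor,
                                      method = "mle")$k,
           v = sum(go_s$delta_length) * 1000 / sum(go_s$duration),
           noise = .noise_from_traces(sim_by))
    }
    # stochastic-approximation matching with common random numbers: the same
    # simulation seed is reused, so the map is a fixed deterministic function
    # and the multiplicative updates converge to its fixed point
    v_sim <- v_go_hat
    noise_sim <- max(noise_hat, 1)
    k_sg0 <- k_sg
    k_gs0 <- k_gs
    clamp <- function(x) min(2, max(0.5, x))
    refined <- try({
      for (it in seq_len(refine_iterations)) {
        ms <- measure_sim(k_sg, k_gs, v_sim, noise_sim, calib_seed + 101L)
        stopifnot(is.finite(ms$ls), is.finite(ms$lg), ms$ls > 0, ms$lg > 0)
        k_sg <- min(5 * k_sg0, max(k_sg0 / 5, k_sg * clamp(lambda_s / ms$ls)))
        k_gs <- min(5 * k_gs0, max(k_gs0 / 5, k_gs * clamp(lambda_g / ms$lg)))
        if (is.finite(ms$v) && ms$v > 0) v_sim <- v_sim * clamp(v_go_hat / ms$v)
        if (is.finite(ms$noise) && ms$noise > 0 && noise_hat > 0) {
          noise_sim <- noise_sim * clamp(noise_hat / ms$noise)
        }
      }
    }, silent = TRUE)
    if (inherits(refined, "try-error")) {
      k_sg <- k_sg0
      k_gs <- k_gs0
      warning("indirect-inference refinement failed; keeping analytically corrected rates")
    }
    sigma_sg <- fit_sg$k_err * k_sg / lambda_s
    sigma_gs <- fit_gs$k_err * k_gs / lambda_g
  }

  out <- tibble::tibble(
    g_tot = g_tot, k_sg = k_sg, sigma_sg = sigma_sg,
    k_gs = k_gs, sigma_gs = sigma_gs,
    p_g = growth_probability(k_sg, k_gs),
    sigma_g = growth_probability_error(k_sg, sigma_sg, k_gs, sigma_gs),
    n_stop = fit_sg$n_events, n_go = fit_gs$n_events,
    p_detect = p_det_stop, p_detect_go = p_det_go,
    v_go_nm_min = v_go_hat, noise_nm = noise_hat,
    v_thresh = v_thresh
  )
  attr(out, "segments") <- seg
  attr(out, "settings") <- list(v_thresh = v_thresh, smooth_window = smooth_window,
                                min_run = min_run, frame_dt = frame_dt,
                                stop_censor = stop_censor,
                                correct_missed = correct_missed)
  class(out) <- c("rate_summary", class(out))
  out
}
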