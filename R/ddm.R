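#' Drift-diffusion model parameters
#'
#' The one-parameter reduction of the search: the decision variable
#' `x = ln(1 - p_t(A))` accumulates from a start value (default -100, the
#' initial log-probability that food is elsewhere) toward an absorbing
#' boundary fixed at 0, following `dx = A dt + c dW`. The boundary is not
#' adjustable because the variable is a log-probability; the start value has
#' only weak influence on first-passage times.
#'
#' @param drift_A Mean drift rate per unit time (>= 0).
#' @param noise_c Diffusion scale per sqrt(unit time) (>= 0).
#' @param x0 Start value (default -100; must be below the boundary).
#' @param dt Euler-Maruyama step size.
#' @param max_time Simulation budget in time units.
#' @return Object of class `ddm_params`. The absorbing boundary is 0.
#' @export
ddm_params <- function(drift_A, noise_c, x0 = -100, dt = 1, max_time = 1e4) {
  stopifnot(drift_A >= 0, noise_c >= 0, x0 < 0, dt > 0, max_time > 0)
  structure(list(drift_A = drift_A, noise_c = noise_c, x0 = x0,
                 boundary = 0, dt = dt, max_time = max_time),
            class = "ddm_params")
}

#' Simulate one drift-diffusion path to the absorbing boundary
#'
#' Euler-Maruyama integration `x <- x + A dt + c sqrt(dt) N(0,1)`, stopping
#' at the first step with `x >= 0`. The crossing time is linearly
#' interpolated inside the crossing step to reduce discretization bias.
#'
#' @param params A [ddm_params()].
#' @param keep_path Return the full path (memory grows with `max_time/dt`).
#' @return List with `first_passage_time` (or `NA` if the budget is reached
#'   first) and, if requested, `path`.
#' @export
simulate_ddm <- function(params, keep_path = FALSE) {
  A <- params$drift_A; cc <- params$noise_c
  dt <- params$dt
  if (A == 0 && cc == 0) {
    warning("simulate_ddm: zero drift and zero noise never cross the boundary")
    return(list(first_passage_time = NA_real_,
                path = if (keep_path) params$x0 else NULL))
  }
  n <- ceiling(params$max_time / dt)
  sq <- cc * sqrt(dt)
  x <- params$x0
  path <- if (keep_path) numeric(n + 1L) else NULL
  if (keep_path) path[1L] <- x
  # simulate in blocks so the normal draws are vectorized
  block <- 4096L
  t_steps <- 0L
  repeat {
    m <- min(block, n - t_steps)
    if (m <= 0L) break
    incr <- A * dt + sq * stats::rnorm(m)
    xs <- x + cumsum(incr)
    if (keep_path) path[t_steps + 1L + seq_len(m)] <- xs
    crossed <- which(xs >= 0)
    if (length(crossed)) {
      k <- crossed[1L]
      x_prev <- if (k == 1L) x else xs[k - 1L]
      frac <- if (xs[k] == x_prev) 1 else (0 - x_prev) / (xs[k] - x_prev)
      tfp <- (t_steps + k - 1L + frac) * dt
      if (keep_path) path <- path[seq_len(t_steps + k + 1L)]
      return(list(first_passage_time = tfp, path = path))
    }
    x <- xs[m]
    t_steps <- t_steps + m
  }
  list(first_passage_time = NA_real_, path = path)
}

#' Sample the first-passage-time distribution
#'
#' @param params A [ddm_params()].
#' @param n Number of independent paths.
#' @param seed Integer seed.
#' @return Numeric vector of crossing times (non-crossing runs excluded,
#'   with their count in attribute `"n_no_crossing"`). More than half
#'   non-crossers is an error (under-drifted configuration).
#' @export
first_passage_distribution <- function(params, n, seed) {
  stopifnot(n >= 1L)
  set.seed(seed)
  times <- vapply(seq_len(n),
                  function(i) simulate_ddm(params)$first_passage_time,
                  numeric(1))
  miss <- sum(is.na(times))
  if (miss > n / 2)
    stop(sprintf("first_passage_distribution: %d/%d runs never crossed; configuration under-drifted", miss, n))
  structure(times[!is.na(times)], n_no_crossing = miss)
}

#' Extract the drift rate from a ln(1 - p_A) trace
#'
#' The log-probability that food is elsewhere rises approximately linearly
#' over most of the local search (after an initial supra-linear phase).
#' This fits an ordinary least-squares line to the trace restricted to a
#' window of the local-search span and returns the slope as the drift rate,
#' together with the fit's R^2 and a diffusion estimate `noise_c`: the
#' standard deviation of the detrended per-step increments, the natural
#' moment estimator of `c sqrt(dt)` for a drift-diffusion path sampled at
#' unit steps.
#'
#' @param logprob_trace Numeric vector, `ln(1 - p_A)` per step (steps
#'   assumed unit-spaced), or a two-column matrix `(step, value)`.
#' @param window Fraction pair of the local-search span to fit (default
#'   `c(0.2, 0.9)`, excluding the supra-linear start and the saturated end).
#' @param transition_step Optional end of the local search; defaults to the
#'   last point of the trace.
#' @return List with `drift_A`, `r_squared`, `noise_c`.
#' @export
extract_drift_rate <- function(logprob_trace, window = c(0.2, 0.9),
                               transition_step = NULL) {
  if (is.matrix(logprob_trace)) {
    steps <- logprob_trace[, 1L]; y <- logprob_trace[, 2L]
  } else {
    y <- as.numeric(logprob_trace); steps <- seq_along(y) - 1
  }
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  span <- if (is.null(transition_step)) max(steps) else transition_step
  keep <- steps >= window[1] * span & steps <= window[2] * span &
    is.finite(y)
  if (sum(keep) < 5L)
    stop("extract_drift_rate: fewer than 5 points in the fit window")
  fit <- stats::lm(y[keep] ~ steps[keep])
  res <- stats::residuals(fit)
  list(drift_A = stats::coef(fit)[[2]],
       intercept = stats::coef(fit)[[1]],
       r_squared = summary(fit)$r.squared,
       noise_c = stats::sd(diff(res)) / sqrt(mean(diff(steps[keep]))))
}

#' Drift-rate scaling across prior widths and filter lengths
#'
#' Runs infotaxis ensembles over the (sigma, L) product grid, extracts a
#' drift rate from each run's `ln(1 - p_A)` trace, and tabulates per-cell
#' means and spreads. The table supports the downstream regressions: drift
#' varies linearly with the prior width sigma at fixed L, and collapses
#' approximately onto a function of the sigma/L ratio.
#'
#' @param sigmas Prior widths (grid units).
#' @param Ls Filter lengths (grid units; `tau` is set to `L^2 / D`).
#' @param config Base [search_config()].
#' @param n_per_cell Runs per (sigma, L) cell.
#' @param seed Integer seed.
#' @return Data frame with columns `sigma`, `L`, `n`, `mean_drift`,
#'   `sd_drift`, `mean_transition_step`; cells whose runs never reached the
#'   transition have `n = 0` and `NA` statistics.
#' @export
drift_scaling_experiment <- function(sigmas, Ls, config, n_per_cell = 8L,
                                     seed = 1L) {
  stopifnot(length(sigmas) >= 1L, length(Ls) >= 1L)
  cells <- expand.grid(sigma = sigmas, L = Ls)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    od <- config$odor
    cfg <- search_config(grid = config$grid,
                         prior = gaussian_prior(config$prior$center,
                                                cells$sigma[i]),
                         odor = odor_params(od$a, od$rho, od$D,
                                            cells$L[i]^2 / od$D),
                         log_one_minus_p0 = config$log_one_minus_p0,
                         pnohit_mode = config$pnohit_mode,
                         max_steps = config$max_steps,
                         stall_limit = config$stall_limit,
                         border_margin = config$border_margin,
                         transition_epsilon = config$transition_epsilon,
                         start_offset_sigma = config$start_offset_sigma,
                         speed_mm_s = config$speed_mm_s)
    ens <- run_ensemble(cfg, n_per_cell, seed + i)
    drifts <- vapply(seq_along(ens$trajectories), function(j) {
      tr <- ens$trajectories[[j]]
      if (is.na(tr$transition_step)) return(NA_real_)
      extract_drift_rate(tr$log1m_pA_series,
                         transition_step = tr$transition_step)$drift_A
    }, numeric(1))
    drifts <- drifts[!is.na(drifts)]
    out[[i]] <- data.frame(
      sigma = cells$sigma[i], L = cells$L[i], n = length(drifts),
      mean_drift = if (length(drifts)) mean(drifts) else NA_real_,
      sd_drift = if (length(drifts) > 1) stats::sd(drifts) else NA_real_,
      mean_transition_step = if (length(ens$transition_steps))
        mean(ens$transition_steps) else NA_real_)
  }
  do.call(rbind, out)
}

#' Reduce an infotaxis ensemble to drift-diffusion parameters
#'
#' The reduction used when the drift-diffusion model stands in for the full
#' search: the drift is the maximum-likelihood estimate for a diffusion
#' observed over the whole local search — the net accumulation of
#' `ln(1 - p_A)` divided by the number of steps — and the noise is the
#' standard deviation of the detrended per-step increments (from
#' [extract_drift_rate()]), averaged across runs. The window-restricted
#' OLS slope of [extract_drift_rate()] measures linearity and scaling; the
#' net rate is the right drift for first-passage comparison because the
#' accumulation is mildly convex at both ends, which an extrapolated
#' window slope would mis-center.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param start_value Accumulator start (default -100).
#' @return List with `drift_A`, `noise_c`, `n_runs_used`.
#' @export
ddm_reduction <- function(ensemble, start_value = -100) {
  ts <- ensemble$transition_steps
  if (!length(ts)) stop("ddm_reduction: ensemble has no transitions")
  ccs <- vapply(ensemble$trajectories, function(tr) {
    if (is.na(tr$transition_step)) return(NA_real_)
    extract_drift_rate(tr$log1m_pA_series,
                       transition_step = tr$transition_step)$noise_c
  }, numeric(1))
  list(drift_A = mean(abs(start_value) / ts),
       noise_c = mean(ccs, na.rm = TRUE),
       n_runs_used = length(ts))
}

#' Repeated KS comparison of drift-diffusion and infotaxis durations
#'
#' The central approximation claim of the reduced model: local-search
#' durations simulated from the drift-diffusion model with parameters
#' extracted from an infotaxis ensemble should be statistically
#' indistinguishable from that ensemble's own durations. Each repeat runs a
#' fresh infotaxis ensemble, extracts (A, c) with [ddm_reduction()],
#' samples first-passage times from `x0 = -100`, and applies the two-sample
#' KS test (in step units; the fixed speed conversion cancels).
#'
#' @param config A [search_config()].
#' @param n_repeats Number of independent experiments (default 20).
#' @param n_runs Infotaxis runs per repeat.
#' @param n_ddm First-passage samples per repeat.
#' @param seed Integer seed.
#' @param alpha Rejection level (default 0.05).
#' @return List with `n_reject`, `reject_rate`, and a per-repeat data
#'   frame (`drift_A`, `noise_c`, `ks_D`, `ks_p`).
#' @export
ddm_infotaxis_consistency <- function(config, n_repeats = 20L, n_runs = 12L,
                                      n_ddm = 200L, seed = 1L,
                                      alpha = 0.05) {
  rows <- vector("list", n_repeats)
  for (rep in seq_len(n_repeats)) {
    ens <- run_ensemble(config, n_runs, seed + rep)
    red <- ddm_reduction(ens)
    fpt <- first_passage_distribution(
      ddm_params(red$drift_A, red$noise_c, x0 = -100,
                 max_time = 20 * mean(ens$transition_steps)),
      n_ddm, seed + 10000L + rep)
    k <- ks_two_sample(ens$transition_steps, fpt)
    rows[[rep]] <- data.frame(drift_A = red$drift_A, noise_c = red$noise_c,
                              ks_D = k$D, ks_p = k$p)
  }
  tab <- do.call(rbind, rows)
  list(n_reject = sum(tab$ks_p < alpha),
       reject_rate = mean(tab$ks_p < alpha),
       repeats = tab)
}
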