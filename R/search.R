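#' Configuration for an infotaxis search run
#'
#' Bundles the arena, prior, odor model, and loop-control settings. The
#' defaults are the study conditions: a 128 x 128 grid of 0.2 mm cells
#' (approximately a 1-inch square arena), a centered Gaussian prior, and an
#' initial `ln(1 - p0(A)) = -100`.
#'
#' @param grid A [grid_spec()].
#' @param prior A [gaussian_prior()]; `NULL` places the mode at the grid
#'   center with width `sigma`.
#' @param odor An [odor_params()].
#' @param sigma Prior width in grid units, used when `prior` is `NULL`.
#' @param log_one_minus_p0 Initial `ln(1 - p0(A))` (default -100).
#' @param pnohit_mode How `P(n = 0 | A)` is computed for the p(A) update:
#'   `"averaged"` (posterior-averaged Poisson zero probability, exact under
#'   the model and consistent with joint Bayes) or `"exp_minus_h"`
#'   (`exp(-h)`, the first-order form).
#' @param rho1_as_printed Logical; weight the lookahead hit probability by
#'   `(1 - p_A)` instead of `p_A`. Off by default: detections require a
#'   source, so the physically consistent weight is `p_A`.
#' @param max_steps Step budget.
#' @param stall_limit Consecutive non-moves before halting (default 15).
#' @param border_margin Halt when within this many cells of the border
#'   (default 1).
#' @param transition_epsilon Declare the local-to-global transition at the
#'   first step with `p_A <= transition_epsilon` (default 1e-3).
#' @param start_offset_sigma Std dev (grid units) of the Gaussian
#'   displacement of the start position from the prior center; the only
#'   across-run variability besides tie-breaking.
#' @param speed_mm_s Animal speed used for the fixed space-to-time
#'   conversion (default 0.17 mm/s).
#' @return Object of class `search_config`.
#' @export
search_config <- function(grid = grid_spec(),
                          prior = NULL,
                          odor = odor_params(),
                          sigma = 6,
                          log_one_minus_p0 = -100,
                          pnohit_mode = c("averaged", "exp_minus_h"),
                          rho1_as_printed = FALSE,
                          max_steps = 2500L,
                          stall_limit = 15L,
                          border_margin = 1L,
                          transition_epsilon = 1e-3,
                          start_offset_sigma = 2,
                          speed_mm_s = 0.17) {
  pnohit_mode <- match.arg(pnohit_mode)
  if (is.null(prior))
    prior <- gaussian_prior(c((grid$n_x + 1) / 2, (grid$n_y + 1) / 2), sigma)
  stopifnot(max_steps > 0, stall_limit >= 1L,
            transition_epsilon > 0, transition_epsilon < 1,
            start_offset_sigma >= 0, speed_mm_s > 0)
  structure(list(grid = grid, prior = prior, odor = odor,
                 log_one_minus_p0 = log_one_minus_p0,
                 pnohit_mode = pnohit_mode,
                 rho1_as_printed = rho1_as_printed,
                 max_steps = as.integer(max_steps),
                 stall_limit = as.integer(stall_limit),
                 border_margin = as.integer(border_margin),
                 transition_epsilon = transition_epsilon,
                 start_offset_sigma = start_offset_sigma,
                 speed_mm_s = speed_mm_s),
            class = "search_config")
}

#' Expected change in posterior entropy for a candidate move
#'
#' Implements the one-step lookahead
#' \deqn{\Delta S(r \to r_j) = P_t(r_j)\,[-S] + [1 - P_t(r_j)]\,[\rho_0 \Delta S_0 + \rho_1 \Delta S_1]}
#' where `rho_1 = p_A (1 - e^{-h(r_j)})` is the probability of at least one
#' hit during the step (binary coding), `rho_0 = 1 - rho_1`, and
#' `Delta S_0`, `Delta S_1` are the entropy changes after the corresponding
#' Bayes update combined with visited-cell zeroing at `r_j`. Negative values
#' are expected information gains.
#'
#' @param belief A `belief` object.
#' @param odor An [odor_params()].
#' @param r_j Candidate cell (length-2, 1-based).
#' @param rho1_as_printed See [search_config()].
#' @param kernels Optional precomputed [odor_kernels()].
#' @return Scalar expected entropy change (nats).
#' @export
expected_entropy_change <- function(belief, odor, r_j,
                                    rho1_as_printed = FALSE, kernels = NULL) {
  g <- belief$grid
  ix <- as.integer(r_j[1]); iy <- as.integer(r_j[2])
  stopifnot(ix >= 1L, ix <= g$n_x, iy >= 1L, iy <= g$n_y)
  S <- belief_entropy(belief)
  pfound <- belief$posterior[ix, iy]
  if (pfound >= 1) return(-S)
  if (is.null(kernels)) {
    gx <- seq_len(g$n_x); gy <- seq_len(g$n_y)
    rate <- hit_rate_dist(odor, sqrt(outer((gx - ix)^2, (gy - iy)^2, "+")))
  } else {
    rate <- kernel_block(kernels$rate, g, ix, iy)
  }
  e <- exp(-rate)
  h <- sum(belief$posterior * rate)
  pA <- p_area(belief)
  rho1 <- (if (rho1_as_printed) 1 - pA else pA) * (-expm1(-h))
  branch_entropy <- function(w) {
    w[ix, iy] <- 0
    q <- sum(w)
    if (q <= 0) return(S)                    # impossible branch: no change
    belief_entropy(w / q)
  }
  S0 <- branch_entropy(belief$posterior * e)
  S1 <- if (rho1 > 0) branch_entropy(belief$posterior * (1 - e)) else S
  pfound * (-S) + (1 - pfound) * ((1 - rho1) * (S0 - S) + rho1 * (S1 - S))
}

# candidate set: stay + in-grid 8-connected neighbors, as a k x 2 matrix
candidate_moves <- function(grid, r, border_margin = 0L) {
  dx <- rep(-1:1, times = 3); dy <- rep(-1:1, each = 3)
  cx <- r[1] + dx; cy <- r[2] + dy
  ok <- cx >= 1L & cx <= grid$n_x & cy >= 1L & cy <= grid$n_y
  cbind(cx[ok], cy[ok])
}

#' Choose the maximally informative move
#'
#' Evaluates the expected entropy change for staying and for each in-grid
#' 8-connected neighbor, and returns the candidate with the minimal
#' (most negative) expected change. Ties (within 1e-12 nats) are broken
#' uniformly at random using R's current RNG stream, so runs are
#' reproducible under `set.seed()`.
#'
#' @param belief A `belief` object.
#' @param odor An [odor_params()].
#' @param r Current cell (length-2, 1-based).
#' @param rho1_as_printed See [search_config()].
#' @param kernels Optional precomputed [odor_kernels()].
#' @return Length-2 integer vector; attribute `"delta_s"` carries the
#'   candidate table.
#' @export
choose_move <- function(belief, odor, r, rho1_as_printed = FALSE,
                        kernels = NULL) {
  if (is.null(kernels)) kernels <- odor_kernels(belief$grid, odor)
  cand <- candidate_moves(belief$grid, as.integer(r))
  ds <- delta_s_candidates_cpp(belief$posterior, log(belief$posterior),
                               kernels$rate, kernels$exp_neg,
                               kernels$log1m_exp_neg,
                               cand, p_area(belief), belief_entropy(belief),
                               rho1_as_printed)
  ties <- which(ds <= min(ds) + 1e-12)
  pick <- if (length(ties) == 1L) ties else ties[sample.int(length(ties), 1L)]
  structure(c(cand[pick, 1L], cand[pick, 2L]),
            delta_s = cbind(cand, delta_s = ds))
}

#' Simulate a source-absent infotaxis search
#'
#' Runs the entropy-greedy loop in an arena that contains no odor source, so
#' the realized observation at every step is "no hit". Each step: choose the
#' move minimizing expected entropy, move, zero the visited cell, apply the
#' no-hit Bayes update, and update p(A). Because a visited cell without food
#' is itself evidence against the source being in the area, the evidence
#' term for the p(A) update is `sum_{r0 != r} P_t(r0) exp(-R(r | r0))`
#' (mode `"averaged"`), which makes the sequential update exactly equal to
#' joint Bayes over \{source in each cell\} and \{source absent\}.
#'
#' The run halts on border proximity, on `stall_limit` consecutive
#' non-moves, or when the step budget is exhausted. The local-to-global
#' transition is the first step at which `p_A` falls to
#' `transition_epsilon`.
#'
#' @param config A [search_config()].
#' @param start Optional length-2 start cell; by default the prior center
#'   plus a Gaussian offset of std `start_offset_sigma`.
#' @return Object of class `infotaxis_trajectory` with elements `positions`
#'   ((T+1) x 2), `p_A_series`, `log1m_pA_series`, `entropy_series`
#'   (all length T+1, entry t+1 being the state after step t),
#'   `halt_reason` ("border", "stall", or "budget"), `transition_step`
#'   (step index or NA), and the config.
#' @export
simulate_search <- function(config, start = NULL) {
  g <- config$grid
  belief <- init_prior(g, config$prior, config$log_one_minus_p0)
  kernels <- odor_kernels(g, config$odor)
  lo <- config$border_margin + 1L
  if (is.null(start)) {
    start <- round(config$prior$center +
                     stats::rnorm(2, 0, config$start_offset_sigma))
    start <- pmin(pmax(as.integer(start), lo + 1L),
                  c(g$n_x, g$n_y) - lo)
  }
  pos <- as.integer(start)
  n_steps <- config$max_steps
  positions <- matrix(NA_integer_, n_steps + 1L, 2L)
  l_series <- S_series <- numeric(n_steps + 1L)
  l <- belief$log1m_pA
  logP <- log(belief$posterior)
  averaged <- config$pnohit_mode == "averaged"

  observe <- function(p) {
    st <- posterior_step_cpp(belief$posterior, logP, kernels$rate,
                             kernels$exp_neg, p[1], p[2])
    belief$posterior <<- st$posterior
    logP <<- st$log_posterior
    belief$visited[p[1], p[2]] <<- TRUE
    q <- if (averaged) st$q else exp(-st$h)
    l <<- update_log1m_pA(l, q)
    st$entropy
  }

  positions[1L, ] <- pos
  S_series[1L] <- observe(pos)
  l_series[1L] <- l
  halt_reason <- "budget"
  t_used <- 0L
  stall <- 0L
  for (t in seq_len(n_steps)) {
    cand <- candidate_moves(g, pos)
    belief$log1m_pA <- l
    ds <- delta_s_candidates_cpp(belief$posterior, logP, kernels$rate,
                                 kernels$exp_neg, kernels$log1m_exp_neg,
                                 cand, p_area(belief),
                                 S_series[t], config$rho1_as_printed)
    ties <- which(ds <= min(ds) + 1e-12)
    pick <- if (length(ties) == 1L) ties else ties[sample.int(length(ties), 1L)]
    newpos <- cand[pick, ]
    stall <- if (all(newpos == pos)) stall + 1L else 0L
    pos <- newpos
    positions[t + 1L, ] <- pos
    S_series[t + 1L] <- observe(pos)
    l_series[t + 1L] <- l
    t_used <- t
    if (min(pos[1] - 1L, g$n_x - pos[1], pos[2] - 1L, g$n_y - pos[2]) <=
        config$border_margin) { halt_reason <- "border"; break }
    if (stall >= config$stall_limit) { halt_reason <- "stall"; break }
  }
  keep <- seq_len(t_used + 1L)
  l_series <- l_series[keep]
  thresh <- log1p(-config$transition_epsilon)   # p_A <= eps  <=>  l >= log(1-eps)
  hit <- which(l_series >= thresh)
  structure(list(positions = positions[keep, , drop = FALSE],
                 p_A_series = 1 - exp(l_series),
                 log1m_pA_series = l_series,
                 entropy_series = S_series[keep],
                 halt_reason = halt_reason,
                 transition_step = if (length(hit)) hit[1L] - 1L else NA_integer_,
                 start = as.integer(start),
                 config = config),
            class = "infotaxis_trajectory")
}

#' @export
print.infotaxis_trajectory <- function(x, ...) {
  cat(sprintf("<infotaxis_trajectory> %d steps | halt: %s | transition at step %s | final p(A) = %.3g\n",
              nrow(x$positions) - 1L, x$halt_reason,
              ifelse(is.na(x$transition_step), "none", x$transition_step),
              utils::tail(x$p_A_series, 1)))
  invisible(x)
}

#' Local-search duration in seconds
#'
#' The fixed, non-adjustable space-to-time conversion: one grid step covers
#' one cell width at the animal's speed, so
#' `duration = transition_step * cell_size_mm / speed_mm_s`.
#'
#' @param traj An `infotaxis_trajectory`.
#' @param speed_mm_s Speed (defaults to the run's configured value).
#' @param cell_size_mm Cell width (defaults to the run's grid).
#' @export
search_duration_seconds <- function(traj,
                                    speed_mm_s = traj$config$speed_mm_s,
                                    cell_size_mm = traj$config$grid$cell_size_mm) {
  if (is.na(traj$transition_step))
    stop("search_duration_seconds: trajectory has no local-to-global transition")
  stopifnot(speed_mm_s > 0)
  traj$transition_step * cell_size_mm / speed_mm_s
}

#' Run an ensemble of infotaxis searches
#'
#' Draws start positions from the start-offset distribution and runs `n`
#' independent searches. Runs that never reach the transition are excluded
#' from the duration and displacement statistics and counted.
#'
#' @param config A [search_config()].
#' @param n Number of runs.
#' @param seed Integer seed governing all randomness.
#' @return List with `durations` (s), `displacements` (mm, start to position
#'   at the transition step), `logprob_traces` (list of `ln(1 - p_A)`
#'   series), `transition_steps`, `n_no_transition`, and `trajectories`.
#' @export
run_ensemble <- function(config, n, seed) {
  stopifnot(n >= 1L)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n)
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(run_seeds[i])
    trajs[[i]] <- simulate_search(config)
  }
  ts <- vapply(trajs, function(tr) tr$transition_step, integer(1))
  ok <- !is.na(ts)
  cell <- config$grid$cell_size_mm
  disp <- vapply(trajs[ok], function(tr) {
    p0 <- tr$positions[1L, ]
    p1 <- tr$positions[tr$transition_step + 1L, ]
    sqrt(sum((p1 - p0)^2)) * cell
  }, numeric(1))
  list(durations = ts[ok] * cell / config$speed_mm_s,
       displacements = disp,
       logprob_traces = lapply(trajs, function(tr) tr$log1m_pA_series),
       transition_steps = ts[ok],
       n_no_transition = sum(!ok),
       trajectories = trajs)
}

#' Fit the three search-model parameters to observed distributions
#'
#' Grid search over (prior width sigma, filter length L, initial
#' `ln(1 - p0)`): at each point an ensemble is simulated and compared to the
#' observed displacement distribution by the two-sample KS statistic; the
#' minimizer is returned. As a consistency check in the spirit of the
#' model's headline test, the duration distribution at the chosen point is
#' then compared to the observed durations by a KS test *without* any
#' re-fitting.
#'
#' @param observed_displacements Observed end-of-local-search displacements
#'   (mm).
#' @param observed_durations Observed local-search durations (s).
#' @param search_space Data frame with columns `sigma`, `L`,
#'   `log_one_minus_p0` (grid units / negative reals).
#' @param config Base [search_config()]; each search point overrides its
#'   prior width, odor `tau` (via `L^2 / D`), and initial belief.
#' @param n_per_point Ensemble size per parameter point.
#' @param seed Integer seed.
#' @return List: `best` (row of `search_space`), `table` (per-point KS
#'   statistics), `duration_ks` (`D`, `p` of the held-out duration check).
#' @export
fit_parameters <- function(observed_displacements, observed_durations,
                           search_space, config, n_per_point = 50L,
                           seed = 1L) {
  stopifnot(length(observed_displacements) > 0, nrow(search_space) > 0,
            all(c("sigma", "L", "log_one_minus_p0") %in% names(search_space)))
  cfg_at <- function(row) {
    od <- config$odor
    search_config(grid = config$grid,
                  prior = gaussian_prior(config$prior$center, row$sigma),
                  odor = odor_params(od$a, od$rho, od$D, row$L^2 / od$D),
                  log_one_minus_p0 = row$log_one_minus_p0,
                  pnohit_mode = config$pnohit_mode,
                  rho1_as_printed = config$rho1_as_printed,
                  max_steps = config$max_steps,
                  stall_limit = config$stall_limit,
                  border_margin = config$border_margin,
                  transition_epsilon = config$transition_epsilon,
                  start_offset_sigma = config$start_offset_sigma,
                  speed_mm_s = config$speed_mm_s)
  }
  ks_d <- numeric(nrow(search_space))
  for (i in seq_len(nrow(search_space))) {
    ens <- run_ensemble(cfg_at(search_space[i, ]), n_per_point, seed + i)
    ks_d[i] <- if (length(ens$displacements) == 0) Inf else
      ks_two_sample(ens$displacements, observed_displacements)$D
  }
  if (all(!is.finite(ks_d)))
    stop("fit_parameters: every search point degenerate (no transitions)")
  best_i <- which.min(ks_d)
  held <- run_ensemble(cfg_at(search_space[best_i, ]), n_per_point,
                       seed + nrow(search_space) + 1L)
  dk <- ks_two_sample(held$durations, observed_durations)
  list(best = search_space[best_i, ],
       table = cbind(search_space, ks_D = ks_d),
       duration_ks = dk)
}
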