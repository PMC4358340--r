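#' Chemotaxis-adaptation null model parameters
#'
#' The alternative account of the post-removal turn-rate decay: an animal
#' removed from food experiences a large downward concentration step, turns
#' at an elevated rate, and relaxes to a basal rate by sensory adaptation
#' with a single time constant:
#' \deqn{\lambda(t) = \lambda_{ss} + (\lambda_{max} - \lambda_{ss}) e^{-t/\tau}}
#'
#' @param lambda_max Peak turn rate just after removal (turns/min).
#' @param lambda_ss Steady-state (basal) turn rate (turns/min).
#' @param tau_adapt Adaptation time constant (s).
#' @param concentration_gain Scaling of the excess rate
#'   `lambda_max - lambda_ss` with the food-concentration step (default 1).
#' @return Object of class `adaptation_params`.
#' @export
adaptation_params <- function(lambda_max = 4, lambda_ss = 0.5,
                              tau_adapt = 300, concentration_gain = 1) {
  stopifnot(lambda_max >= lambda_ss, lambda_ss >= 0, tau_adapt > 0,
            concentration_gain >= 0)
  structure(list(lambda_max = lambda_max, lambda_ss = lambda_ss,
                 tau_adapt = tau_adapt,
                 concentration_gain = concentration_gain),
            class = "adaptation_params")
}

#' Instantaneous turn rate under adaptation
#'
#' @param params An [adaptation_params()].
#' @param t Time since removal from food (s); vectorized.
#' @return Turn rate in turns/min.
#' @export
turn_rate_at <- function(params, t) {
  stopifnot(all(t >= 0))
  params$lambda_ss +
    (params$lambda_max - params$lambda_ss) * exp(-t / params$tau_adapt)
}

#' Simulate a run-and-tumble track under chemotaxis adaptation
#'
#' Turn times follow an inhomogeneous Poisson process with rate
#' `turn_rate_at()` (thinning algorithm); motion is constant-speed between
#' turns with uniformly random post-turn headings, inside a reflecting
#' square arena.
#'
#' @param params An [adaptation_params()].
#' @param duration_s Track duration (s).
#' @param speed_mm_s Speed (default 0.17).
#' @param fps Frames per second (default 3).
#' @param arena_mm Side of the square arena (default 25.4).
#' @return List with `track` (a [worm_track()]) and `turn_times` (s).
#' @export
simulate_chemotaxis_walk <- function(params, duration_s,
                                     speed_mm_s = 0.17, fps = 3,
                                     arena_mm = 25.4) {
  stopifnot(duration_s > 0)
  lam_max_s <- params$lambda_max / 60   # thinning envelope, per second
  tt <- numeric(0)
  t <- 0
  while (TRUE) {
    t <- t + stats::rexp(1, lam_max_s)
    if (t > duration_s) break
    if (stats::runif(1) < turn_rate_at(params, t) / params$lambda_max)
      tt <- c(tt, t)
  }
  track <- run_and_tumble_track(turn_times = tt, duration_s = duration_s,
                                speed_mm_s = speed_mm_s, fps = fps,
                                arena_mm = arena_mm,
                                turn_kernel = "uniform",
                                heading_jitter_deg = 3)
  list(track = track, turn_times = tt)
}

#' Predicted local-search duration under adaptation
#'
#' The chemotaxis account identifies the end of local search with the decay
#' of the excess turn rate to a small fraction of its initial value, giving
#' the closed form `tau_adapt * ln(1/fraction)`. Because the 90-to-10
#' percent transition width is `tau_adapt * ln 9`, the ratio of transition
#' width to duration is the constant `ln 9 / ln 10 ~ 0.954` for every
#' adaptation time constant: a single-exponential model can be slow or
#' sharp, never both.
#'
#' @param params An [adaptation_params()].
#' @param fraction Residual excess-rate fraction defining the end of local
#'   search (default 0.1).
#' @return Duration in seconds.
#' @export
predicted_duration <- function(params, fraction = 0.1) {
  stopifnot(fraction > 0, fraction < 1)
  if (params$lambda_max <= params$lambda_ss)
    stop("predicted_duration: requires lambda_max > lambda_ss")
  params$tau_adapt * log(1 / fraction)
}

#' Rescale the model for a diluted food patch
#'
#' Chemotaxis responds to the size of the concentration step: dilution
#' scales the excess turn rate by `concentration_gain * dilution`, so the
#' model predicts fewer turns after dilution. The infotaxis pipeline has no
#' concentration input at all, which is the structural contrast between the
#' two accounts.
#'
#' @param params An [adaptation_params()].
#' @param dilution Concentration factor in (0, 1].
#' @return New [adaptation_params()] with the scaled excess rate.
#' @export
concentration_effect <- function(params, dilution) {
  stopifnot(dilution > 0, dilution <= 1)
  excess <- (params$lambda_max - params$lambda_ss) *
    params$concentration_gain * dilution
  adaptation_params(lambda_max = params$lambda_ss + excess,
                    lambda_ss = params$lambda_ss,
                    tau_adapt = params$tau_adapt,
                    concentration_gain = params$concentration_gain)
}

#' Expected number of turns over an interval
#'
#' Closed-form integral of the adaptation turn-rate profile from 0 to
#' `t_end` seconds: `lambda_ss t + (lambda_max - lambda_ss) tau (1 - e^{-t/tau})`
#' (rates in turns/min, integral converted from minutes).
#'
#' @param params An [adaptation_params()].
#' @param t_end End of the interval (s).
#' @export
expected_turns <- function(params, t_end) {
  stopifnot(t_end >= 0)
  (params$lambda_ss * t_end +
     (params$lambda_max - params$lambda_ss) * params$tau_adapt *
     (1 - exp(-t_end / params$tau_adapt))) / 60
}
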