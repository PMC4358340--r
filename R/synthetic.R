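#' Configuration for synthetic worm tracks
#'
#' The generator emulates the acquisition conditions of the recordings the
#' pipeline is built for: 30-minute sessions at 3 frames/s in a 1-inch
#' (25.4 mm) square arena with an aversive boundary, roughly 0.17 mm/s
#' locomotion, a high-turn-rate local search, and an abrupt switch to a
#' low-turn-rate global search around 15 minutes. The first two minutes
#' (carried-over forward locomotion) are excluded from analysis and are not
#' generated, so the default track is 28 minutes long.
#'
#' @param speed_mm_s Constant speed (default 0.17).
#' @param fps Frames per second (default 3).
#' @param duration_s Track length in seconds (default 1680 = 30 min - 2 min).
#' @param arena_mm Side of the square arena (default 25.4). The boundary is
#'   aversive, not absorbing: within a short margin the animal steers away
#'   at a bounded turning rate, the smooth avoidance seen at a repellent
#'   barrier.
#' @param local_rate,global_rate Turn rates before/after the transition
#'   (turns/min; defaults 4 and 0.5).
#' @param transition_source Either `list(type = "fixed", t = seconds)` or
#'   `list(type = "ddm", drift = A, noise = c, x0 = -100)`: per-track
#'   transition times drawn from the drift-diffusion first-passage
#'   distribution, linking the generator to the reduced decision model the
#'   same way the full pipeline does. Default: ddm with drift 1/9 per s
#'   (mean first passage 900 s, i.e. a median transition near 15 min) and
#'   noise 0.5 (a spread of roughly plus or minus two minutes across
#'   animals).
#' @param turn_kernel `"sharp"` (default): post-turn heading change of
#'   magnitude uniform on 60-180 degrees, either sign — the large
#'   reorientations (omega turns/pirouettes) that centroid-level turn
#'   counting measures. `"uniform"`: new heading uniform on the circle.
#' @param heading_jitter_deg Per-frame Gaussian heading jitter (default 3).
#' @param ramp_s Optional linear rate ramp width around the transition
#'   (default 0 = instantaneous switch); nonzero values exist to probe the
#'   transition-duration estimator.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(speed_mm_s = 0.17, fps = 3, duration_s = 1680,
                         arena_mm = 25.4, local_rate = 4, global_rate = 0.5,
                         transition_source = list(type = "ddm", drift = 1 / 9,
                                                  noise = 0.5, x0 = -100),
                         turn_kernel = c("sharp", "uniform"),
                         heading_jitter_deg = 3, ramp_s = 0) {
  turn_kernel <- match.arg(turn_kernel)
  stopifnot(speed_mm_s > 0, fps > 0, duration_s > 0, arena_mm > 0,
            local_rate > global_rate, global_rate >= 0,
            heading_jitter_deg >= 0, ramp_s >= 0,
            transition_source$type %in% c("fixed", "ddm"))
  structure(list(speed_mm_s = speed_mm_s, fps = fps, duration_s = duration_s,
                 arena_mm = arena_mm, local_rate = local_rate,
                 global_rate = global_rate,
                 transition_source = transition_source,
                 turn_kernel = turn_kernel,
                 heading_jitter_deg = heading_jitter_deg, ramp_s = ramp_s),
            class = "synth_config")
}

# planted turn-rate profile in turns/min at time t (vectorized)
planted_rate <- function(config, t, t_transition) {
  if (config$ramp_s <= 0) {
    ifelse(t < t_transition, config$local_rate, config$global_rate)
  } else {
    f <- pmin(pmax((t - (t_transition - config$ramp_s / 2)) / config$ramp_s,
                   0), 1)
    config$local_rate + f * (config$global_rate - config$local_rate)
  }
}

# Constant-speed run-and-tumble integrator in a non-absorbing square arena.
# The aversive boundary is modeled as gradual steering: inside a margin the
# heading rotates away from the wall at a bounded rate, so wall encounters
# reorient the animal smoothly instead of producing instantaneous bounces
# that a turn detector would misread as planted turn events. A hard fold
# keeps positions inside the square as a safety net.
run_and_tumble_track <- function(turn_times, duration_s, speed_mm_s, fps,
                                 arena_mm, turn_kernel, heading_jitter_deg,
                                 start_xy = NULL, avoid_margin_mm = 1.5,
                                 avoid_rate_deg = 12) {
  dt <- 1 / fps
  n <- floor(duration_s * fps) + 1L
  times <- (seq_len(n) - 1L) * dt
  if (is.null(start_xy))
    start_xy <- arena_mm / 2 + stats::runif(2, -arena_mm / 10, arena_mm / 10)
  x <- y <- numeric(n)
  x[1L] <- start_xy[1L]; y[1L] <- start_xy[2L]
  heading <- stats::runif(1, -pi, pi)
  jit_sd <- heading_jitter_deg * pi / 180
  step_len <- speed_mm_s * dt
  max_rot <- avoid_rate_deg * pi / 180
  turn_idx <- 1L
  nt <- length(turn_times)
  jitter <- if (jit_sd > 0) stats::rnorm(n, 0, jit_sd) else numeric(n)
  steer <- function(heading, pos) {
    # rotate toward the inward normal of any wall closer than the margin,
    # at most max_rot per frame
    nx_ <- 0; ny_ <- 0
    if (pos[1] < avoid_margin_mm) nx_ <- 1
    if (pos[1] > arena_mm - avoid_margin_mm) nx_ <- -1
    if (pos[2] < avoid_margin_mm) ny_ <- 1
    if (pos[2] > arena_mm - avoid_margin_mm) ny_ <- -1
    if (nx_ == 0 && ny_ == 0) return(heading)
    target <- atan2(ny_, nx_)
    d <- wrap_to_pi(target - heading)
    if (cos(heading - target) > 0.95) return(heading)   # already inward
    heading + sign(d) * min(abs(d), max_rot)
  }
  for (i in 2:n) {
    t_now <- times[i]
    while (turn_idx <= nt && turn_times[turn_idx] <= t_now) {
      heading <- if (turn_kernel == "uniform") stats::runif(1, -pi, pi) else
        heading + sample(c(-1, 1), 1L) * stats::runif(1, pi / 3, pi)
      turn_idx <- turn_idx + 1L
    }
    heading <- steer(heading + jitter[i], c(x[i - 1L], y[i - 1L]))
    xn <- x[i - 1L] + step_len * cos(heading)
    yn <- y[i - 1L] + step_len * sin(heading)
    # safety fold (sub-millimeter, heading untouched)
    if (xn < 0) xn <- -xn else if (xn > arena_mm) xn <- 2 * arena_mm - xn
    if (yn < 0) yn <- -yn else if (yn > arena_mm) yn <- 2 * arena_mm - yn
    x[i] <- xn; y[i] <- yn
  }
  worm_track(times, x, y, fps = fps)
}

#' Generate one synthetic worm track with planted ground truth
#'
#' Constant-speed run-and-tumble motion: Poisson-timed turns at
#' `local_rate` before the planted transition and `global_rate` after
#' (inhomogeneous Poisson thinning when a ramp is configured), large
#' reorientations at turns, small per-frame heading jitter, and smooth
#' steering away from the arena walls.
#'
#' @param config A [synth_config()].
#' @return List with `track` (a [worm_track()]) and `truth`
#'   (`t_transition` in seconds — `Inf` when the drift-diffusion draw never
#'   crossed within the track — and `turn_times`).
#' @export
generate_track <- function(config) {
  ts <- config$transition_source
  t_transition <- if (ts$type == "fixed") ts$t else {
    p <- ddm_params(ts$drift, ts$noise,
                    x0 = if (is.null(ts$x0)) -100 else ts$x0,
                    dt = 1, max_time = 4 * config$duration_s)
    ft <- simulate_ddm(p)$first_passage_time
    if (is.na(ft)) Inf else ft
  }
  # thinning with the local rate as envelope
  env_s <- config$local_rate / 60
  tt <- numeric(0); t <- 0
  repeat {
    t <- t + stats::rexp(1, env_s)
    if (t > config$duration_s) break
    if (stats::runif(1) < planted_rate(config, t, t_transition) /
        config$local_rate)
      tt <- c(tt, t)
  }
  track <- run_and_tumble_track(tt, config$duration_s, config$speed_mm_s,
                                config$fps, config$arena_mm,
                                config$turn_kernel,
                                config$heading_jitter_deg)
  list(track = track, truth = list(t_transition = t_transition,
                                   turn_times = tt))
}

#' Generate a cohort of synthetic worm tracks
#'
#' @param config A [synth_config()].
#' @param n Number of tracks.
#' @param seed Integer seed; the cohort is reproducible.
#' @return List with `tracks` (list of [worm_track()]) and `truths`.
#' @export
generate_cohort <- function(config, n, seed) {
  stopifnot(n >= 1L)
  set.seed(seed)
  track_seeds <- sample.int(.Machine$integer.max - 1L, n)
  tracks <- truths <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(track_seeds[i])
    g <- generate_track(config)
    tracks[[i]] <- g$track
    truths[[i]] <- g$truth
  }
  list(tracks = tracks, truths = truths)
}
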