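#' A uniformly sampled 2-D centroid track
#'
#' @param times Strictly increasing times (s) with constant step `1/fps`.
#' @param x,y Coordinates (mm), finite.
#' @param fps Frames per second; inferred from the median time step when
#'   omitted.
#' @return Object of class `worm_track`.
#' @export
worm_track <- function(times, x, y, fps = NULL) {
  stopifnot(length(times) == length(x), length(times) == length(y),
            length(times) >= 2L)
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("worm_track: non-finite times or coordinates")
  dts <- diff(times)
  if (any(dts <= 0))
    stop(sprintf("worm_track: times not strictly increasing at row %d",
                 which(dts <= 0)[1L] + 1L))
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6))
    stop(sprintf("worm_track: non-uniform sampling at row %d",
                 which(abs(dts - dt) > 1e-6)[1L] + 1L))
  if (is.null(fps)) fps <- 1 / dt
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), fps = fps),
            class = "worm_track")
}

#' @export
print.worm_track <- function(x, ...) {
  cat(sprintf("<worm_track> %d frames @ %.3g fps | %.1f s | x [%.2f, %.2f] y [%.2f, %.2f] mm\n",
              length(x$times), x$fps, diff(range(x$times)),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

wrap_to_pi <- function(a) (a + pi) %% (2 * pi) - pi

#' Frame-by-frame headings of a track
#'
#' Heading per frame from centered displacement differences; frames whose
#' centered displacement is below a noise floor carry the previous heading
#' (stationary wobble should not register as reorientation).
#'
#' @param track A [worm_track()].
#' @param noise_floor_mm Minimum centered displacement (default 0.01 mm).
#' @return Numeric vector of headings (rad, in (-pi, pi]).
#' @export
compute_headings <- function(track, noise_floor_mm = 0.01) {
  n <- length(track$x)
  stopifnot(n >= 3L)
  dx <- track$x[c(2:n, n)] - track$x[c(1, 1:(n - 1))]
  dy <- track$y[c(2:n, n)] - track$y[c(1, 1:(n - 1))]
  ok <- sqrt(dx^2 + dy^2) >= noise_floor_mm
  if (!any(ok))
    stop("compute_headings: degenerate track (no displacement above the noise floor)")
  h <- atan2(dy, dx)
  # carry the previous valid heading through sub-noise frames
  first_ok <- which(ok)[1L]
  if (first_ok > 1L) { h[1:(first_ok - 1L)] <- h[first_ok]; ok[1:(first_ok - 1L)] <- TRUE }
  idx <- cummax(ifelse(ok, seq_len(n), 0L))
  h[idx]
}

#' Detect abrupt turns in a track
#'
#' A turn is a change of unwrapped heading exceeding `angle_threshold_deg`
#' within a sliding window of `window_s` seconds; after each event one
#' refractory window is skipped so a single reorientation is not counted
#' repeatedly.
#'
#' @param track A [worm_track()].
#' @param angle_threshold_deg Heading-change threshold (default 50).
#' @param window_s Window and refractory length in seconds (default 1).
#' @param noise_floor_mm Passed to [compute_headings()].
#' @return Numeric vector of event times (s, window centers).
#' @export
detect_turns <- function(track, angle_threshold_deg = 50, window_s = 1,
                         noise_floor_mm = 0.01) {
  h <- compute_headings(track, noise_floor_mm)
  u <- h[1L] + c(0, cumsum(wrap_to_pi(diff(h))))
  w <- max(1L, round(window_s * track$fps))
  n <- length(u)
  if (n <= w) return(numeric(0))
  thr <- angle_threshold_deg * pi / 180
  jump <- abs(u[(w + 1L):n] - u[1L:(n - w)])   # change over the window
  events <- numeric(0)
  i <- 1L
  nw <- n - w
  while (i <= nw) {
    if (jump[i] > thr) {
      events <- c(events, track$times[i] + window_s / 2)
      # one reorientation excites a run of overlapping windows: step past
      # the whole above-threshold stretch, then one refractory window
      i <- i + 1L
      while (i <= nw && jump[i] > thr) i <- i + 1L
      i <- i + w
    } else i <- i + 1L
  }
  events
}

#' Binned turn-count series
#'
#' @param events Turn event times (s).
#' @param duration_s Total observed duration (s).
#' @param bin_width Bin width in seconds (default 60).
#' @param t0 Series start time (default 0).
#' @return Object of class `turn_series`: `bin_edges`, `counts`,
#'   `bin_width`.
#' @export
turn_rate_series <- function(events, duration_s, bin_width = 60, t0 = 0) {
  stopifnot(duration_s > bin_width)
  edges <- seq(t0, t0 + ceiling(duration_s / bin_width) * bin_width,
               by = bin_width)
  counts <- as.integer(table(cut(events, edges, right = TRUE,
                                 include.lowest = TRUE)))
  structure(list(bin_edges = edges, counts = counts, bin_width = bin_width),
            class = "turn_series")
}

#' Population mean turn-rate curve with SEM
#'
#' Detects turns in each track, bins them on a common time base, and
#' returns the across-track mean and standard error per bin.
#'
#' @param tracks List of [worm_track()] objects.
#' @param bin_width Bin width (s).
#' @param ... Passed to [detect_turns()].
#' @return Data frame with `t_mid`, `mean_count`, `sem`, `n_tracks`.
#' @export
mean_turn_rate_curve <- function(tracks, bin_width = 60, ...) {
  stopifnot(length(tracks) >= 1L)
  dur <- min(vapply(tracks, function(tr) diff(range(tr$times)), numeric(1)))
  mat <- vapply(tracks, function(tr) {
    ev <- detect_turns(tr, ...)
    turn_rate_series(ev - tr$times[1L], dur, bin_width)$counts
  }, integer(ceiling(dur / bin_width)))
  mat <- matrix(mat, ncol = length(tracks))
  edges <- seq(0, ceiling(dur / bin_width) * bin_width, by = bin_width)
  data.frame(t_mid = (edges[-1] + edges[-length(edges)]) / 2,
             mean_count = rowMeans(mat),
             sem = apply(mat, 1L, stats::sd) / sqrt(ncol(mat)),
             n_tracks = ncol(mat))
}

#' Displacement at the end of the local search
#'
#' Euclidean distance from the track's first frame to its (interpolated)
#' position at the transition time.
#'
#' @param track A [worm_track()].
#' @param t_transition Transition time (s), within the track.
#' @return Displacement in mm.
#' @export
end_of_local_displacement <- function(track, t_transition) {
  stopifnot(t_transition >= track$times[1L],
            t_transition <= track$times[length(track$times)])
  xt <- stats::approx(track$times, track$x, t_transition)$y
  yt <- stats::approx(track$times, track$y, t_transition)$y
  sqrt((xt - track$x[1L])^2 + (yt - track$y[1L])^2)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Classical two-sample KS statistic (maximum ECDF distance) with the
#' asymptotic p-value.
#'
#' @param xs,ys Nonempty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(xs, ys) {
  stopifnot(length(xs) > 0, length(ys) > 0)
  kt <- suppressWarnings(stats::ks.test(xs, ys, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
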