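#' Fit a two-state Poisson hidden Markov model to a turn-count series
#'
#' Baum-Welch (EM) fitting of a 2-state HMM with Poisson emissions on
#' binned turn counts, the observable in which the local-to-global
#' behavioral switch is most visible. The best of `n_restarts` random
#' initializations by log-likelihood is returned, with forward-backward
#' state posteriors. States are relabeled after fitting so that state 1 is
#' always the higher-rate (local-search) state.
#'
#' @param series A [turn_rate_series()] object, or a bare vector of counts.
#' @param n_restarts Number of EM restarts (default 5).
#' @param seed Integer seed for the restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return Object of class `hmm_fit`: `state_rates` (decreasing),
#'   `transition_matrix` (row-stochastic), `initial_probs`,
#'   `state_posterior` (per-bin probability of the high-rate state),
#'   `log_likelihood`, `loglik_trace` (per-iteration, non-decreasing),
#'   `degenerate` (TRUE when both states converge to the same rate),
#'   and the bin metadata when a `turn_series` was supplied.
#' @export
fit_two_state_hmm <- function(series, n_restarts = 5L, seed = 1L,
                              max_iter = 200L, tol = 1e-8) {
  y <- if (inherits(series, "turn_series")) series$counts else
    as.integer(series)
  stopifnot(length(y) >= 10L, all(y >= 0))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init_rates <- pmax(stats::quantile(y, c(0.85, 0.15)) *
                         stats::runif(2, 0.6, 1.4), 0.05)
    fit <- baum_welch_poisson2(y, init_rates, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood)
      best <- fit
  }
  # label: state 1 = higher rate
  if (best$state_rates[1L] < best$state_rates[2L]) {
    perm <- c(2L, 1L)
    best$state_rates <- best$state_rates[perm]
    best$transition_matrix <- best$transition_matrix[perm, perm]
    best$initial_probs <- best$initial_probs[perm]
    best$gamma <- best$gamma[, perm, drop = FALSE]
  }
  best$state_posterior <- best$gamma[, 1L]
  best$degenerate <- abs(diff(best$state_rates)) < 1e-6
  if (inherits(series, "turn_series")) {
    best$bin_edges <- series$bin_edges
    best$bin_width <- series$bin_width
  }
  class(best) <- "hmm_fit"
  best
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> rates %.3g / %.3g per bin | logLik %.3f%s\n",
              x$state_rates[1L], x$state_rates[2L], x$log_likelihood,
              if (isTRUE(x$degenerate)) " | DEGENERATE (equal rates)" else ""))
  invisible(x)
}

# 2-state Poisson Baum-Welch with scaled forward-backward
baum_welch_poisson2 <- function(y, init_rates, max_iter, tol) {
  T_ <- length(y)
  lam <- pmax(as.numeric(init_rates), 1e-6)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    B <- cbind(stats::dpois(y, lam[1L]), stats::dpois(y, lam[2L]))
    B[B < 1e-300] <- 1e-300
    # forward (scaled)
    alpha <- matrix(0, T_, 2L); cvec <- numeric(T_)
    a <- pi0 * B[1L, ]; cvec[1L] <- sum(a); alpha[1L, ] <- a / cvec[1L]
    for (t in 2:T_) {
      a <- (alpha[t - 1L, ] %*% A) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    ll <- sum(log(cvec))
    ll_trace <- c(ll_trace, ll)
    # backward (scaled)
    beta <- matrix(0, T_, 2L); beta[T_, ] <- 1
    for (t in (T_ - 1L):1L)
      beta[t, ] <- (A %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    # pairwise state probabilities
    xi <- matrix(0, 2L, 2L)
    for (t in 1:(T_ - 1L))
      xi <- xi + (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * A /
        cvec[t + 1L]
    # M-step
    pi0 <- gam[1L, ]
    A <- xi / rowSums(xi)
    lam <- pmax(colSums(gam * y) / colSums(gam), 1e-6)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(state_rates = lam, transition_matrix = A, initial_probs = pi0,
       gamma = gam, log_likelihood = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace)
}

#' Transition time and transition duration from an HMM fit
#'
#' The transition time is where the posterior probability of the
#' global-search (low-rate) state crosses 0.5 going upward; if it crosses
#' more than once the last crossing is used (with a message). The
#' transition duration measures sharpness: the time for that posterior to
#' move from `lo` to `hi` (defaults 0.1 to 0.9) around the crossing, with
#' linear interpolation between bin centers.
#'
#' @param fit An `hmm_fit` from [fit_two_state_hmm()] on a
#'   [turn_rate_series()] (bin metadata required for the time axis).
#' @param lo,hi Posterior bounds defining the transition span.
#' @return List with `t_transition` and `duration_s` (seconds).
#' @export
transition_time_and_duration <- function(fit, lo = 0.1, hi = 0.9) {
  stopifnot(inherits(fit, "hmm_fit"), lo > 0, hi < 1, lo < hi)
  if (is.null(fit$bin_edges))
    stop("transition_time_and_duration: fit carries no bin metadata; fit on a turn_rate_series")
  g <- 1 - fit$state_posterior          # posterior of the global state
  tm <- (fit$bin_edges[-1] + fit$bin_edges[-length(fit$bin_edges)]) / 2
  cross_up <- function(level) {
    idx <- which(g[-length(g)] < level & g[-1L] >= level)
    if (!length(idx)) return(NULL)
    i <- idx[length(idx)]
    tm[i] + (level - g[i]) / (g[i + 1L] - g[i]) * (tm[i + 1L] - tm[i])
  }
  # handle posteriors that start above/end below the level
  if (all(g >= 0.5) || all(g < 0.5))
    stop("transition_time_and_duration: state posterior never crosses 0.5 (no transition)")
  idx5 <- which(g[-length(g)] < 0.5 & g[-1L] >= 0.5)
  if (length(idx5) > 1L)
    message("transition_time_and_duration: multiple 0.5 crossings; using the last")
  t_tr <- cross_up(0.5)
  t_lo <- cross_up(lo)
  t_hi <- cross_up(hi)
  if (is.null(t_lo)) t_lo <- tm[1L]     # already past `lo` at series start
  if (is.null(t_hi)) t_hi <- tm[length(tm)]
  list(t_transition = t_tr, duration_s = max(t_hi - t_lo, 0))
}

#' Segment one track into local and global search
#'
#' The full single-track pipeline: detect turns, bin them, fit the
#' two-state HMM, locate the transition, and measure the end-of-local
#' displacement.
#'
#' @param track A [worm_track()].
#' @param bin_width Bin width for the turn series (s).
#' @param angle_threshold_deg,window_s Turn-detection parameters.
#' @param n_restarts,seed HMM fitting parameters.
#' @return List with `t_transition`, `duration_s`, `displacement_mm`,
#'   `fit`, `events`.
#' @export
segment_track <- function(track, bin_width = 60, angle_threshold_deg = 50,
                          window_s = 1, n_restarts = 5L, seed = 1L) {
  dur <- diff(range(track$times))
  ev <- detect_turns(track, angle_threshold_deg, window_s)
  ser <- turn_rate_series(ev - track$times[1L], dur, bin_width)
  fit <- fit_two_state_hmm(ser, n_restarts = n_restarts, seed = seed)
  tr <- transition_time_and_duration(fit)
  disp <- end_of_local_displacement(
    track, min(track$times[1L] + tr$t_transition,
               track$times[length(track$times)]))
  list(t_transition = tr$t_transition, duration_s = tr$duration_s,
       displacement_mm = disp, fit = fit, events = ev)
}
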