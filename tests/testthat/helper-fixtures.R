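# Shared fixtures. The heavy search experiments run on a half-resolution
# version of the study arena (64 x 64 cells of 0.4 mm) with the odor and
# prior scales halved to match; one default ensemble is computed lazily and
# reused across test files.

test_grid64 <- function() grid_spec(64, 64, 0.4)

test_config64 <- function(sigma = 3, L = 50, rho = 0.45,
                          max_steps = 1500L, ...) {
  search_config(grid = test_grid64(), sigma = sigma,
                odor = odor_params(a = 2.5, rho = rho, D = 1, tau = L^2),
                max_steps = max_steps, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_ensemble64 <- function(n = 20L, seed = 424242L) {
  key <- sprintf("ens_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_ensemble(test_config64(), n, seed)
  .fixture_cache[[key]]
}

# step-to-step heading autocorrelation of a cell path at a given lag
heading_autocorr <- function(positions, lag = 10L) {
  dx <- diff(positions[, 1]); dy <- diff(positions[, 2])
  keep <- dx != 0 | dy != 0
  h <- atan2(dy[keep], dx[keep])
  if (length(h) <= lag) return(NA_real_)
  mean(cos(h[(lag + 1):length(h)] - h[1:(length(h) - lag)]))
}

# dense rate field seen from cell r, by direct evaluation (test-side oracle)
rate_field <- function(odor, grid, r) {
  f <- matrix(0, grid$n_x, grid$n_y)
  for (ix in seq_len(grid$n_x))
    for (iy in seq_len(grid$n_y))
      f[ix, iy] <- hit_rate(odor, r, c(ix, iy))
  f
}

# random normalized belief on a small grid
random_belief <- function(grid, log1m_pA = -100) {
  b <- init_prior(grid, gaussian_prior(c((grid$n_x + 1) / 2,
                                         (grid$n_y + 1) / 2), 2),
                  log1m_pA)
  w <- matrix(stats::runif(grid$n_x * grid$n_y), grid$n_x, grid$n_y)
  b$posterior <- w / sum(w)
  b
}

# straight-line worm track along +x
straight_track <- function(n = 200L, fps = 3, speed = 0.17) {
  t <- (seq_len(n) - 1) / fps
  worm_track(t, speed * t, rep(0, n), fps = fps)
}

# track with instantaneous planted turns of given angles (deg) at given times
planted_turn_track <- function(turn_times, angles_deg, duration_s = 120,
                               fps = 3, speed = 0.2) {
  n <- floor(duration_s * fps) + 1L
  t <- (seq_len(n) - 1) / fps
  heading <- 0
  x <- y <- numeric(n)
  for (i in 2:n) {
    k <- which(turn_times > t[i - 1] & turn_times <= t[i])
    if (length(k)) heading <- heading + sum(angles_deg[k]) * pi / 180
    x[i] <- x[i - 1] + speed / fps * cos(heading)
    y[i] <- y[i - 1] + speed / fps * sin(heading)
  }
  worm_track(t, x, y, fps = fps)
}
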