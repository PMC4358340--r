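#' Grid specification for the search arena
#'
#' Defines the discrete arena on which the searcher's belief lives. Cell
#' indices are 1-based and positions are taken at cell centers; all distances
#' inside the model are in grid units, and `cell_size_mm` converts to
#' physical units only at the I/O boundary.
#'
#' @param n_x,n_y Number of cells along each axis (default 128).
#' @param cell_size_mm Physical width of one cell in mm (default 0.2, so the
#'   default 128-cell span approximately tiles a 1-inch, 25.4 mm arena).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_x = 128L, n_y = 128L, cell_size_mm = 0.2) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  stopifnot(n_x >= 3L, n_y >= 3L, cell_size_mm > 0)
  structure(list(n_x = n_x, n_y = n_y, cell_size_mm = cell_size_mm),
            class = "grid_spec")
}

#' Physical odor-encounter parameters
#'
#' Parameters of the two-dimensional diffusion model for odorant detection.
#' A source at `r0` emitting particles at rate `rho`, with diffusivity `D`
#' and finite particle lifetime `tau`, produces a mean hit rate at position
#' `r` of
#' \deqn{R(r | r_0) = \frac{\rho}{\ln(\sqrt{D\tau}/a)} K_0\!\left(\frac{|r - r_0|}{\sqrt{D\tau}}\right)}
#' where `a` is the size of the searcher and `K0` the modified Bessel
#' function of the second kind, order zero. The spatial decay scale is the
#' filter length `L = sqrt(D * tau)`.
#'
#' @param a Searcher size in grid units.
#' @param rho Particle emission rate (expected hits per time step at unit
#'   Bessel factor).
#' @param D Particle diffusivity (grid units^2 per time step).
#' @param tau Particle lifetime (time steps).
#' @return An object of class `odor_params` with derived element `L`.
#' @export
odor_params <- function(a = 5, rho = 0.35, D = 1, tau = 10000) {
  stopifnot(a > 0, rho > 0, D > 0, tau > 0)
  L <- sqrt(D * tau)
  if (L / a <= 1)
    stop("odor_params: require sqrt(D*tau)/a > 1 so that ln(sqrt(D*tau)/a) > 0")
  structure(list(a = a, rho = rho, D = D, tau = tau, L = L),
            class = "odor_params")
}

#' Gaussian prior over the source location
#'
#' @param center Numeric length-2, cell indices (1-based, cell-center
#'   convention) of the prior mode.
#' @param sigma Standard deviation in grid units.
#' @export
gaussian_prior <- function(center, sigma) {
  stopifnot(length(center) == 2L, sigma > 0)
  structure(list(center = as.numeric(center), sigma = sigma),
            class = "gaussian_prior")
}

#' Mean hit rate R(r | r0)
#'
#' Evaluates the odor-encounter rate at position `r` for a source at `r0`.
#' The Bessel profile diverges at zero separation; distances below the
#' searcher size `a` are clamped to `a` (the physical scale already present
#' in the model's logarithm), which regularizes the self-distance case.
#'
#' @param odor An [odor_params()] object.
#' @param r,r0 Numeric length-2 grid coordinates.
#' @return Nonnegative scalar rate (expected hits per time step).
#' @export
hit_rate <- function(odor, r, r0) {
  d <- sqrt(sum((as.numeric(r) - as.numeric(r0))^2))
  hit_rate_dist(odor, d)
}

# vectorized over distance, with the a-clamp regularization
hit_rate_dist <- function(odor, d) {
  d <- pmax(d, odor$a)
  odor$rho / log(odor$L / odor$a) * besselK(d / odor$L, 0)
}

#' Precompute shifted hit-rate kernels for a grid
#'
#' Builds the (2 n_x - 1) x (2 n_y - 1) kernel of rates indexed by cell
#' offset, plus its elementwise `exp(-K)`, so the rate field seen from any
#' searcher position is a contiguous sub-block (no per-step Bessel calls).
#'
#' @param grid A [grid_spec()].
#' @param odor An [odor_params()].
#' @return List with matrices `rate` and `exp_neg`.
#' @export
odor_kernels <- function(grid, odor) {
  dx <- seq(-(grid$n_x - 1L), grid$n_x - 1L)
  dy <- seq(-(grid$n_y - 1L), grid$n_y - 1L)
  d <- sqrt(outer(dx^2, dy^2, "+"))
  rate <- hit_rate_dist(odor, d)
  list(rate = rate, exp_neg = exp(-rate),
       log1m_exp_neg = log(-expm1(-rate)))
}

# sub-block of a shifted kernel for searcher cell (ix, iy)
kernel_block <- function(kernel, grid, ix, iy) {
  kernel[(grid$n_x - ix + 1L):(2L * grid$n_x - ix),
         (grid$n_y - iy + 1L):(2L * grid$n_y - iy)]
}

#' Initialize the searcher's belief
#'
#' The belief has two parts: a per-cell posterior over the source location
#' conditional on the source being inside the known area, and the scalar
#' probability `p_A` that a source is present at all. `p_A` is held
#' internally as `ln(1 - p_A)` because the model starts with
#' `ln(1 - p0) = -100`, far below what the probability scale can represent
#' in double precision.
#'
#' @param grid A [grid_spec()].
#' @param prior A [gaussian_prior()]; truncated to the grid and renormalized.
#' @param log_one_minus_p0 Nonpositive scalar, initial `ln(1 - p0(A))`
#'   (default -100). `-Inf` encodes certainty `p0(A) = 1`, which is an exact
#'   fixed point of the update.
#' @return Object of class `belief`: `posterior` (n_x x n_y matrix summing
#'   to 1), `log1m_pA`, `visited` (logical matrix), `grid`.
#' @export
init_prior <- function(grid, prior, log_one_minus_p0 = -100) {
  stopifnot(inherits(grid, "grid_spec"), inherits(prior, "gaussian_prior"))
  if (log_one_minus_p0 > 0)
    stop("init_prior: log_one_minus_p0 must be <= 0")
  if (prior$center[1] < 1 || prior$center[1] > grid$n_x ||
      prior$center[2] < 1 || prior$center[2] > grid$n_y)
    stop("init_prior: prior center outside grid")
  gx <- seq_len(grid$n_x); gy <- seq_len(grid$n_y)
  logw <- outer(-(gx - prior$center[1])^2, -(gy - prior$center[2])^2, "+") /
    (2 * prior$sigma^2)
  w <- exp(logw - max(logw))
  post <- w / sum(w)
  if (sum(post > 0) < 2L)
    stop("init_prior: degenerate prior (all mass in a single cell); increase sigma")
  structure(list(posterior = post,
                 log1m_pA = log_one_minus_p0,
                 visited = matrix(FALSE, grid$n_x, grid$n_y),
                 grid = grid),
            class = "belief")
}

#' @export
print.belief <- function(x, ...) {
  cat(sprintf("<belief> %d x %d grid | p(A) = %.6g | entropy = %.4f nats | %d visited cells\n",
              x$grid$n_x, x$grid$n_y, p_area(x), belief_entropy(x),
              sum(x$visited)))
  invisible(x)
}

#' Probability that the source is inside the known area
#' @param belief A `belief` object.
#' @export
p_area <- function(belief) 1 - exp(belief$log1m_pA)

#' ln(1 - p(A)), the accumulating log-probability that food is elsewhere
#' @param belief A `belief` object.
#' @export
log1m_p_area <- function(belief) belief$log1m_pA

#' Expected number of hits at a candidate position
#'
#' `h(r_j) = sum_r0 P_t(r0) R(r_j | r0)`, the posterior-weighted mean hit
#' rate. (The discrete sum ranges over the source location `r0`; a printed
#' form with the candidate position inside the integrand is read as a typo
#' since it does not involve the integration variable.)
#'
#' @param belief A `belief` object.
#' @param odor An [odor_params()].
#' @param r_j Numeric length-2 grid coordinate.
#' @param kernels Optional precomputed [odor_kernels()] (for speed).
#' @export
expected_hits <- function(belief, odor, r_j, kernels = NULL) {
  g <- belief$grid
  if (is.null(kernels)) {
    gx <- seq_len(g$n_x); gy <- seq_len(g$n_y)
    d <- sqrt(outer((gx - r_j[1])^2, (gy - r_j[2])^2, "+"))
    rate <- hit_rate_dist(odor, d)
  } else {
    rate <- kernel_block(kernels$rate, g, as.integer(r_j[1]), as.integer(r_j[2]))
  }
  sum(belief$posterior * rate)
}

# shared: multiply posterior by a likelihood field and renormalize
reweight_posterior <- function(belief, lik, what) {
  w <- belief$posterior * lik
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop(sprintf("%s: posterior weights underflowed to zero; belief is numerically exhausted", what))
  belief$posterior <- w / s
  belief
}

#' Bayes update of the grid posterior after observing no hit
#'
#' Pointwise product with the Poisson zero-count likelihood
#' `exp(-R(r | r0))`, then renormalization.
#'
#' @inheritParams expected_hits
#' @param r Searcher position (length-2 grid coordinate).
#' @export
update_grid_no_hit <- function(belief, odor, r, kernels = NULL) {
  g <- belief$grid
  lik <- if (is.null(kernels)) {
    gx <- seq_len(g$n_x); gy <- seq_len(g$n_y)
    exp(-hit_rate_dist(odor, sqrt(outer((gx - r[1])^2, (gy - r[2])^2, "+"))))
  } else kernel_block(kernels$exp_neg, g, as.integer(r[1]), as.integer(r[2]))
  reweight_posterior(belief, lik, "update_grid_no_hit")
}

#' Bayes update of the grid posterior after observing a hit
#'
#' Binary hit coding: the likelihood of "a non-zero number of hits" under
#' Poisson counts is `1 - exp(-R(r | r0))`. In a source-absent simulation no
#' real hits occur; this update is exercised only inside the expected-entropy
#' lookahead.
#'
#' @inheritParams update_grid_no_hit
#' @export
update_grid_hit <- function(belief, odor, r, kernels = NULL) {
  g <- belief$grid
  lik <- if (is.null(kernels)) {
    gx <- seq_len(g$n_x); gy <- seq_len(g$n_y)
    1 - exp(-hit_rate_dist(odor, sqrt(outer((gx - r[1])^2, (gy - r[2])^2, "+"))))
  } else 1 - kernel_block(kernels$exp_neg, g, as.integer(r[1]), as.integer(r[2]))
  reweight_posterior(belief, lik, "update_grid_hit")
}

#' Bayes update of the probability that the source is in the area
#'
#' \deqn{p_{t+1}(A) = \frac{p_t(A)\,P(n=0 | A)}{p_t(A)\,P(n=0 | A) + (1 - p_t(A))}}
#' using `P(n=0 | not A) = 1` (no source, no hits). `p_A = 1` is an exact
#' fixed point: certainty that food is present cannot be revised by
#' non-detections.
#'
#' @param p_A Current probability, in (0, 1].
#' @param p_nohit_given_A Probability of the observed non-detection given
#'   the source is in the area.
#' @return Updated probability.
#' @export
update_pA <- function(p_A, p_nohit_given_A) {
  stopifnot(p_A > 0, p_A <= 1, p_nohit_given_A >= 0, p_nohit_given_A <= 1)
  den <- p_A * p_nohit_given_A + (1 - p_A)
  if (den == 0)
    stop("update_pA: inconsistent belief (p_A = 1 with impossible observation)")
  p_A * p_nohit_given_A / den
}

# numerically stable update on the ln(1 - p_A) scale:
# l' = l - log(q + exp(l) * (1 - q)), exact fixed point at l = -Inf
update_log1m_pA <- function(l, q) {
  if (l == -Inf) {
    if (q == 0) stop("update_pA: inconsistent belief (p_A = 1 with impossible observation)")
    return(-Inf)
  }
  l - log(q + exp(l) * (1 - q))
}

#' Mark the searcher's cell as visited
#'
#' A visited cell without a source found there has posterior probability
#' exactly 0 from then on; remaining mass is renormalized.
#'
#' @param belief A `belief` object.
#' @param r Length-2 grid coordinate of the visited cell.
#' @export
mark_visited <- function(belief, r) {
  ix <- as.integer(r[1]); iy <- as.integer(r[2])
  q <- belief$posterior[ix, iy]
  belief$visited[ix, iy] <- TRUE
  if (q > 0) {
    if (q >= 1 || sum(belief$posterior) - q <= 0)
      stop("mark_visited: visiting the last cell with posterior mass exhausts the belief")
    belief$posterior[ix, iy] <- 0
    belief$posterior <- belief$posterior / sum(belief$posterior)
  }
  belief
}

#' Shannon entropy of the grid posterior (nats)
#'
#' `S = -sum p ln p` with the convention `0 ln 0 = 0`. Natural logarithms
#' throughout, matching the natural-log scale of `ln(1 - p_A)` and the
#' drift-diffusion start value.
#'
#' @param belief A `belief` object (or a bare nonnegative matrix/vector of
#'   weights summing to 1).
#' @export
belief_entropy <- function(belief) {
  p <- if (inherits(belief, "belief")) belief$posterior else belief
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Effective length scale of the no-hit filter
#'
#' The non-detection update suppresses posterior mass near the searcher by
#' the factor `exp(-R(x))`. The suppression profile `1 - exp(-R(x))`,
#' normalized to 1 at the regularized origin, decays approximately
#' exponentially; this fits `exp(-x / L_fit)` by least squares on the log
#' profile and returns `L_fit`, which tracks the nominal filter length
#' `L = sqrt(D tau)` (empirically about 0.75-0.85 of it, the Bessel
#' profile's algebraic prefactor making the apparent decay slightly faster).
#'
#' @param odor An [odor_params()].
#' @param max_radius Outer radius of the fitted profile, in grid units;
#'   should be several filter lengths.
#' @param n_points Number of radial samples.
#' @return List with `L_fit`, `r_squared`, and the nominal `L`.
#' @export
effective_filter_length <- function(odor, max_radius = 4 * odor$L,
                                    n_points = 500L) {
  if (max_radius < 2 * odor$L)
    stop("effective_filter_length: max_radius should span several filter lengths")
  x <- seq(odor$a, max_radius, length.out = n_points)
  prof <- 1 - exp(-hit_rate_dist(odor, x))
  prof <- prof / prof[1]
  keep <- prof > 0
  if (sum(keep) < 10L)
    stop("effective_filter_length: profile underflows; reduce max_radius")
  fit <- stats::lm(log(prof[keep]) ~ x[keep])
  slope <- stats::coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0)
    stop(sprintf("effective_filter_length: fit failed (slope %g, residual sd %g)",
                 slope, stats::sigma(fit)))
  list(L_fit = -1 / slope,
       r_squared = summary(fit)$r.squared,
       L = odor$L)
}

#' Write a belief posterior snapshot as dense text
#'
#' Row-major dense matrix with a `#`-prefixed header carrying the grid
#' metadata and current scalar state; for plotting and debugging.
#'
#' @param belief A `belief` object.
#' @param path Output file path.
#' @export
write_belief_snapshot <- function(belief, path) {
  g <- belief$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_x=%d n_y=%d cell_size_mm=%g", g$n_x, g$n_y, g$cell_size_mm),
    sprintf("# log1m_pA=%.17g entropy=%.17g", belief$log1m_pA,
            belief_entropy(belief))), con)
  utils::write.table(t(belief$posterior), con, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a belief posterior snapshot written by [write_belief_snapshot()]
#' @param path File path.
#' @return List with `posterior`, `log1m_pA`, and grid fields.
#' @export
read_belief_snapshot <- function(path) {
  hdr <- readLines(path, n = 2L)
  kv <- function(line, key) as.numeric(sub(sprintf(".*%s=([^ ]+).*", key), "\\1", line))
  m <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t"))
  dimnames(m) <- NULL
  list(posterior = t(m),
       n_x = as.integer(kv(hdr[1], "n_x")), n_y = as.integer(kv(hdr[1], "n_y")),
       cell_size_mm = kv(hdr[1], "cell_size_mm"),
       log1m_pA = kv(hdr[2], "log1m_pA"))
}
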