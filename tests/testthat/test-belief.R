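test_that("prior initialization matches the Gaussian form and its limits", {
  g <- grid_spec(5, 5, 1)
  b <- init_prior(g, gaussian_prior(c(3, 3), 1), -100)
  expect_equal(sum(b$posterior), 1, tolerance = 1e-12)
  expect_equal(log1m_p_area(b), -100)
  # 90-degree rotational symmetry about the center
  expect_equal(b$posterior, t(b$posterior), tolerance = 1e-12)
  expect_equal(b$posterior, b$posterior[5:1, ], tolerance = 1e-12)
  # direct evaluation at cell centers
  w <- outer(exp(-((1:5) - 3)^2 / 2), exp(-((1:5) - 3)^2 / 2))
  expect_equal(b$posterior, w / sum(w), tolerance = 1e-12)
  # flat limit: entropy approaches log of the cell count
  bf <- init_prior(g, gaussian_prior(c(3, 3), 1e4), -100)
  expect_equal(belief_entropy(bf), log(25), tolerance = 1e-4)
  # degenerate prior rejected
  expect_error(init_prior(g, gaussian_prior(c(3, 3), 1e-4), -100),
               "degenerate")
  expect_error(init_prior(g, gaussian_prior(c(3, 3), 1), 1), "<= 0")
})

test_that("hit rate follows the Bessel form with radial symmetry and decay", {
  od <- odor_params(a = 0.1, rho = 1, D = 1, tau = 2500)
  expect_equal(od$L, 50)
  # frozen from direct evaluation: K0(1) / ln(500)
  expect_equal(hit_rate(od, c(1, 1), c(51, 1)), 0.0677475,
               tolerance = 1e-6)
  # radial symmetry: equal distances give equal rates
  expect_equal(hit_rate(od, c(10, 10), c(13, 14)),
               hit_rate(od, c(10, 10), c(14, 13)))
  # monotone decay with distance
  d <- c(1, 2, 5, 10, 20, 50, 100)
  r <- vapply(d, function(dd) hit_rate(od, c(0, 0), c(dd, 0)), numeric(1))
  expect_true(all(diff(r) < 0))
  # self-distance regularized by the searcher size
  expect_equal(hit_rate(od, c(3, 3), c(3, 3)),
               hit_rate(od, c(3, 3), c(3 + od$a, 3)))
  expect_error(odor_params(a = 10, D = 1, tau = 25), "sqrt")
})

test_that("expected hits is the posterior-weighted rate (brute force 3x3)", {
  g <- grid_spec(3, 3, 1)
  od <- odor_params(a = 0.4, rho = 0.7, D = 1, tau = 9)
  set.seed(3)
  b <- random_belief(g)
  rj <- c(2, 1)
  h_bf <- sum(b$posterior * rate_field(od, g, rj))
  expect_equal(expected_hits(b, od, rj), h_bf, tolerance = 1e-14)
  # delta posterior reduces to the single-source rate
  b$posterior <- matrix(0, 3, 3); b$posterior[3, 3] <- 1
  expect_equal(expected_hits(b, od, rj), hit_rate(od, rj, c(3, 3)))
  # two-cell uniform posterior gives the mean of the two rates
  b$posterior <- matrix(0, 3, 3); b$posterior[c(1, 9)] <- 0.5
  expect_equal(expected_hits(b, od, rj),
               mean(c(hit_rate(od, rj, c(1, 1)), hit_rate(od, rj, c(3, 3)))))
})

test_that("no-hit and hit updates implement pointwise Poisson Bayes", {
  g <- grid_spec(3, 3, 1)
  od <- odor_params(a = 0.4, rho = 0.9, D = 1, tau = 9)
  set.seed(4)
  b <- random_belief(g)
  r <- c(2, 2)
  R <- rate_field(od, g, r)
  b0 <- update_grid_no_hit(b, od, r)
  w <- b$posterior * exp(-R)
  expect_equal(b0$posterior, w / sum(w), tolerance = 1e-14)
  b1 <- update_grid_hit(b, od, r)
  w1 <- b$posterior * (1 - exp(-R))
  expect_equal(b1$posterior, w1 / sum(w1), tolerance = 1e-14)
  # posterior odds between two cells move by the likelihood ratio:
  # for cells with rates (R1, R2) and equal prior, the no-hit posterior is
  # proportional to (e^-R1, e^-R2) — the two-cell hand-Bayes case
  i <- c(1, 1); j <- c(3, 2)
  expect_equal(b0$posterior[i[1], i[2]] / b0$posterior[j[1], j[2]],
               (b$posterior[i[1], i[2]] / b$posterior[j[1], j[2]]) *
                 exp(-(R[i[1], i[2]] - R[j[1], j[2]])),
               tolerance = 1e-12)
  # equidistant cells are reweighted identically by the hit update
  b$posterior <- matrix(1 / 9, 3, 3)
  bh <- update_grid_hit(b, od, c(2, 2))
  expect_equal(bh$posterior[1, 2], bh$posterior[2, 1], tolerance = 1e-14)
  expect_equal(bh$posterior[1, 1], bh$posterior[3, 3], tolerance = 1e-14)
})

test_that("p(A) update follows Bayes with absorbing certainty", {
  # hand evaluation: 0.9 * 0.5 / (0.9 * 0.5 + 0.1)
  expect_equal(update_pA(0.9, 0.5), 0.45 / 0.55, tolerance = 1e-12)
  # certainty is a fixed point, exactly
  expect_identical(update_pA(1, 0.5), 1)
  expect_identical(update_pA(1, 1e-12), 1)
  # uninformative observation leaves p(A) unchanged
  expect_equal(update_pA(0.37, 1), 0.37)
  # impossible observation under certainty is inconsistent
  expect_error(update_pA(1, 0), "inconsistent")
  # monotone decrease under repeated informative non-detection
  p <- 0.99
  ps <- numeric(150)
  for (i in 1:150) { p <- update_pA(p, 0.9); ps[i] <- p }
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[150], 0.01)
})

test_that("visited cells are zeroed permanently and mass renormalizes", {
  g <- grid_spec(3, 3, 1)
  od <- odor_params(a = 0.4, rho = 0.9, D = 1, tau = 9)
  set.seed(5)
  b <- random_belief(g)
  q <- b$posterior[2, 3]
  bm <- mark_visited(b, c(2, 3))
  expect_identical(bm$posterior[2, 3], 0)
  expect_true(bm$visited[2, 3])
  # every other cell scaled by 1/(1-q)
  lin <- (3 - 1) * 3 + 2                 # column-major index of cell (2, 3)
  expect_equal(bm$posterior[-lin], b$posterior[-lin] / (1 - q),
               tolerance = 1e-12)
  # zero stays zero through later updates
  bm2 <- update_grid_no_hit(bm, od, c(1, 1))
  bm2 <- update_grid_hit(bm2, od, c(3, 1))
  expect_identical(bm2$posterior[2, 3], 0)
  # visiting a zero-mass cell changes only the mask
  bz <- mark_visited(bm, c(2, 3))
  expect_equal(bz$posterior, bm$posterior)
  # exhausting the belief is an error
  bd <- b; bd$posterior <- matrix(0, 3, 3); bd$posterior[1, 1] <- 1
  expect_error(mark_visited(bd, c(1, 1)), "exhausts")
})

test_that("entropy follows the Shannon form in nats", {
  g <- grid_spec(3, 3, 1)
  b <- random_belief(g)
  b$posterior <- matrix(0, 3, 3); b$posterior[2, 2] <- 1
  expect_identical(belief_entropy(b), 0)
  b$posterior <- matrix(1 / 9, 3, 3)
  expect_equal(belief_entropy(b), log(9), tolerance = 1e-12)
  expect_equal(belief_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(belief_entropy(matrix(1 / 16384, 128, 128)), log(16384),
               tolerance = 1e-9)
})

test_that("normalization survives arbitrary update sequences", {
  g <- grid_spec(4, 4, 1)
  od <- odor_params(a = 0.5, rho = 1.2, D = 1, tau = 16)
  set.seed(6)
  for (case in 1:20) {
    b <- random_belief(g)
    for (k in 1:6) {
      r <- c(sample(4, 1), sample(4, 1))
      op <- sample(3, 1)
      b <- tryCatch(switch(op, update_grid_no_hit(b, od, r),
                           update_grid_hit(b, od, r),
                           mark_visited(b, r)),
                    error = function(e) b)   # belief-exhausted toys skipped
      expect_equal(sum(b$posterior), 1, tolerance = 1e-9)
    }
  }
})

test_that("fitted filter length tracks sqrt(D*tau) across two decades", {
  for (a in c(0.1, 1)) for (tau in c(100, 1000, 10000)) {
    od <- odor_params(a = a, rho = 1, D = 1, tau = tau)
    f <- effective_filter_length(od)
    expect_gt(f$L_fit / od$L, 0.7)
    expect_lt(f$L_fit / od$L, 1.3)
  }
  # doubling tau at fixed D scales the fitted length by ~sqrt(2)
  f1 <- effective_filter_length(odor_params(a = 1, rho = 1, D = 1, tau = 800))
  f2 <- effective_filter_length(odor_params(a = 1, rho = 1, D = 1, tau = 1600))
  expect_equal(f2$L_fit / f1$L_fit, sqrt(2), tolerance = 0.15)
  # amplitude (rho) changes the profile height but the length only weakly;
  # recorded as a documented behavior, not a tight bound
  fr1 <- effective_filter_length(odor_params(a = 1, rho = 0.5, D = 1, tau = 800))
  fr2 <- effective_filter_length(odor_params(a = 1, rho = 2, D = 1, tau = 800))
  expect_true(is.finite(fr1$L_fit) && is.finite(fr2$L_fit))
  expect_error(effective_filter_length(odor_params(a = 1, rho = 1, D = 1,
                                                   tau = 800),
                                       max_radius = 10),
               "max_radius")
})

test_that("belief snapshots round-trip through the dense text format", {
  g <- grid_spec(4, 5, 0.3)
  set.seed(7)
  b <- random_belief(g, log1m_pA = -12.5)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_belief_snapshot(b, f)
  s <- read_belief_snapshot(f)
  expect_equal(s$posterior, b$posterior, tolerance = 1e-12)
  expect_equal(s$log1m_pA, -12.5)
  expect_identical(s$n_x, 4L)
  expect_equal(s$cell_size_mm, 0.3)
})
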