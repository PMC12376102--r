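test_that("bias evaluation matches closed forms at and away from a hill centre", {
  h <- toy_hills(n = 1, height = 0.8, x = 5, theta = 90)
  expect_equal(evaluate_bias(h, 5, 90), 0.8)
  # 3 sigma away in X only
  expect_equal(evaluate_bias(h, 5 + 3 * 0.25, 90), 0.8 * exp(-4.5))
  # empty hills give zero
  expect_equal(evaluate_bias(h[0, ], c(1, 2), c(3, 4)), c(0, 0))
  # time cutoff excludes later hills
  h2 <- toy_hills(n = 3, height = 0.5)
  expect_equal(evaluate_bias(h2, 5, 90, up_to_time = 2), 0.5)
})

test_that("bias summation matches a naive double-loop oracle and is linear", {
  set.seed(13)
  nh <- 10000; np <- 1000
  h <- data.frame(time = seq_len(nh), X = runif(nh, 0, 14),
                  theta = runif(nh, 0, 180), sigma_X = runif(nh, 0.2, 0.5),
                  sigma_theta = runif(nh, 1, 4),
                  height = runif(nh, 0.01, 0.25), biasf = 17.5)
  px <- runif(np, 0, 14); pt <- runif(np, 0, 180)
  v <- evaluate_bias(h, px, pt)
  # oracle: outer-product summation, independent of the C++ path
  oracle <- colSums(h$height * exp(-outer(h$X, px, "-")^2 /
                                     (2 * h$sigma_X^2) -
                                   outer(h$theta, pt, "-")^2 /
                                     (2 * h$sigma_theta^2)))
  expect_equal(v, oracle, tolerance = 1e-9)
  # linearity in hills; adding hills never decreases the bias
  half1 <- evaluate_bias(h[1:5000, ], px, pt)
  half2 <- evaluate_bias(h[5001:nh, ], px, pt)
  expect_equal(half1 + half2, v, tolerance = 1e-12)
  expect_true(all(v >= half1))
})

test_that("well-tempered estimator applies the (T+dT)/dT prefactor and zero shift", {
  expect_equal((310 + 5115) / 5115, 1.060606, tolerance = 1e-6)
  h <- toy_hills(n = 1, height = 1, x = 2, theta = 160)
  x <- seq(0, 14, by = 0.5); th <- seq(0, 180, by = 5)
  fes <- reconstruct_fes(h, x, th,
                         unbound_mask = function(X, T_) X >= 10)
  gam <- 17.5
  v <- evaluate_bias(h, 2, 160)
  # bias is negligible on the unbound mask, so no shift is needed there
  expect_lt(abs(fes$shift), 1e-9)
  expect_equal(fes$G[which(x == 2), which(th == 160)],
               -gam / (gam - 1) * v, tolerance = 1e-9)
})

test_that("mixed bias factors are rejected", {
  h <- toy_hills(n = 2)
  h$biasf <- c(17.5, 12)
  expect_error(reconstruct_fes(h), "mixed bias factors")
})

test_that("minima detection finds planted basins and ignores constant grids", {
  x <- seq(0, 14, by = 0.1); th <- seq(0, 180, by = 1)
  g <- outer(x, th, function(X, T_)
    -10 * exp(-((X - 2)^2 / 0.8) - ((T_ - 160)^2 / 200)) -
      5 * exp(-((X - 8)^2 / 0.8) - ((T_ - 95)^2 / 200)))
  fes <- fes_grid(x, th, g, outer(x, th, function(X, T_) X >= 12))
  m <- find_minima(fes)
  expect_equal(nrow(m), 2)
  expect_lt(abs(m$X[1] - 2) + abs(m$X[2] - 8), 0.2 + 0.2)
  expect_lt(abs(m$theta[1] - 160) + abs(m$theta[2] - 95), 2 + 2)
  # saddle estimate lies between the basin depths and the plateau
  expect_gt(attr(m, "saddle"), m$G[1])
  expect_lt(attr(m, "saddle"), 0.5)

  flat <- fes_grid(x, th, matrix(0, length(x), length(th)),
                   outer(x, th, function(X, T_) X >= 12))
  expect_equal(nrow(find_minima(flat)), 0)
})

test_that("deintercalation-like defaults put basins at the canonical coordinates", {
  pot <- default_landscape("production")
  x <- seq(0, 14, by = 0.1); th <- seq(0, 180, by = 1)
  g <- outer(x, th, function(a, b) potential_energy(pot, a, b))
  fes <- fes_grid(x, th, g, outer(x, th, function(X, T_) X >= 13))
  m <- find_minima(fes)
  expect_gte(nrow(m), 2)
  expect_lt(abs(m$X[1] - 2.04), 0.2)
  expect_lt(abs(m$theta[1] - 162), 2)
  expect_lt(abs(m$X[2] - 8.20), 0.2)
  expect_lt(abs(m$theta[2] - 95.4), 2)
})

test_that("1D PMF reduces theta by Boltzmann integration", {
  x <- seq(0, 14, by = 0.1); th <- seq(0, 180, by = 0.5)
  # G independent of theta: profile recovered up to the removed constant
  gx <- -6 * exp(-(x - 3)^2)
  fes <- fes_grid(x, th, matrix(rep(gx, length(th)), nrow = length(x)),
                  outer(x, th, function(X, T_) X >= 10))
  p <- pmf_1d(fes, 310)
  expect_equal(p$G, gx - mean(gx[x >= 10]), tolerance = 1e-9)

  # Gaussian well in theta at fixed X: closed-form Gaussian integral
  rt <- kBT_kJmol(310)
  a <- 5; s <- 12; t0 <- 90
  g2 <- outer(x, th, function(X, T_)
    -a * exp(-((X - 3)^2 / 0.5) - ((T_ - t0)^2 / (2 * s^2))))
  fes2 <- fes_grid(x, th, g2, outer(x, th, function(X, T_) X >= 10))
  p2 <- pmf_1d(fes2, 310)
  # independent oracle: dense trapezoid of exp(-G/RT) at the well row
  i3 <- which.min(abs(x - 3))
  oracle <- -rt * log(pracma::trapz(th, exp(-g2[i3, ] / rt)))
  shift <- -rt * log(diff(range(th)))  # plateau level of the same reduction
  expect_equal(p2$G[i3], oracle - shift, tolerance = 1e-6)

  # two-basin surface: deep basin at small X, shallow at larger X
  g3 <- outer(x, th, smooth_fes_fun) +
    outer(x, th, function(X, T_)
      -4 * exp(-((X - 8)^2 / (2 * 1^2)) - ((T_ - 95)^2 / (2 * 15^2))))
  fes3 <- fes_grid(x, th, g3, outer(x, th, function(X, T_) X >= 12))
  p3 <- pmf_1d(fes3, 310)
  g_small <- min(p3$G[x < 5]); g_large <- min(p3$G[x >= 5 & x < 11])
  expect_lt(g_small, g_large)
  expect_lt(g_large, 0)
})

test_that("square-well binding free energy is exact and zero surfaces give zero", {
  x <- seq(0, 10, by = 0.1); th <- seq(0, 100, by = 1)
  g <- matrix(0, length(x), length(th))
  bound <- outer(x, th, function(X, T_) X <= 2)
  unbound <- outer(x, th, function(X, T_) X >= 8 & X <= 10)
  gval <- 7.3
  g[bound] <- -gval
  # equal areas: both spans cover 2 angstrom in X and the full theta range
  fes <- fes_grid(x, th, g, unbound)
  ctx <- thermo_context(310, C_site = 1)
  b <- binding_free_energy(fes, region_mask(bound, unbound), ctx)
  expect_equal(b$dG, -gval, tolerance = 1e-9)

  g0 <- fes_grid(x, th, matrix(0, length(x), length(th)), unbound)
  b0 <- binding_free_energy(g0, region_mask(bound, unbound), ctx)
  expect_equal(b0$dG, 0, tolerance = 1e-12)
})

test_that("smooth-surface binding free energy matches the refined quadrature oracle", {
  fes <- make_smooth_fes()
  b <- binding_free_energy(fes, smooth_fes_masks(fes),
                           thermo_context(310, C_site = 1))
  oracle <- binding_refined_oracle(refine = 10)
  expect_lt(abs(b$dG - oracle), 1e-4)
})

test_that("binding free energy is shift invariant and monotone in basin depth", {
  fes <- make_smooth_fes(dx = 0.1, dtheta = 1)
  mask <- smooth_fes_masks(fes)
  ctx <- thermo_context(310, C_site = 1)
  b <- binding_free_energy(fes, mask, ctx)
  for (shift in c(-20, 3, 55)) {
    # apply the shift underneath the constructor to exercise the property
    fes3 <- fes_grid(fes$x, fes$theta, fes$G + shift, fes$unbound_mask)
    b3 <- binding_free_energy(fes3, mask, ctx)
    expect_equal(b3$dG, b$dG, tolerance = 1e-9)
  }
  # deepening the bound basin strictly decreases the binding energy
  deeper <- fes_grid(fes$x, fes$theta,
                     fes$G + outer(fes$x, fes$theta, function(X, T_)
                       -2 * exp(-((X - 3)^2 / 2) - ((T_ - 140)^2 / 400))),
                     fes$unbound_mask)
  bd <- binding_free_energy(deeper, mask, ctx)
  expect_lt(bd$dG, b$dG)
})

test_that("doubling the grid resolution moves the binding energy by < 0.1 kJ/mol", {
  f1 <- make_smooth_fes(dx = 0.1, dtheta = 1)
  f2 <- make_smooth_fes(dx = 0.05, dtheta = 0.5)
  ctx <- thermo_context(310, C_site = 1)
  b1 <- binding_free_energy(f1, smooth_fes_masks(f1), ctx)
  b2 <- binding_free_energy(f2, smooth_fes_masks(f2), ctx)
  expect_lt(abs(b1$dG - b2$dG), 0.1)
})

test_that("standard-state correction enters through the site concentration", {
  fes <- make_smooth_fes(dx = 0.1, dtheta = 1)
  mask <- smooth_fes_masks(fes)
  rt <- kBT_kJmol(310)
  b1 <- binding_free_energy(fes, mask, thermo_context(310, C_site = 1))
  b2 <- binding_free_energy(fes, mask, thermo_context(310, C_site = 0.1))
  expect_equal(b2$dG - b1$dG, -rt * log(1 / 0.1) - (-rt * log(1)),
               tolerance = 1e-12)
})

test_that("mask validation rejects overlap and empty regions", {
  m <- matrix(TRUE, 4, 4)
  expect_error(region_mask(m, m), "overlap")
  expect_error(region_mask(matrix(FALSE, 4, 4),
                           matrix(c(TRUE, rep(FALSE, 15)), 4, 4)), "empty")
  # exclusion is applied before the disjointness/emptiness checks
  b <- matrix(FALSE, 4, 4); b[1:2, ] <- TRUE
  u <- matrix(FALSE, 4, 4); u[4, ] <- TRUE
  ex <- matrix(FALSE, 4, 4); ex[1, 1] <- TRUE
  rm <- region_mask(b, u, ex)
  expect_false(rm$bound[1, 1])
})

test_that("run aggregation yields the textbook mean and SEM", {
  a <- aggregate_runs(c(2, 2, 2))
  expect_equal(a$sem, 0)
  b <- aggregate_runs(c(1, 2, 3))
  expect_equal(b$mean, 2)
  expect_equal(b$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(b$sem, 0.5773503, tolerance = 1e-6)
  s <- aggregate_runs(5)
  expect_true(s$single_run)
  expect_true(is.na(s$sem))
  set.seed(2)
  v <- rnorm(6)
  g <- aggregate_runs(v)
  expect_equal(g$sem, sd(v) / sqrt(6), tolerance = 1e-12)
})
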