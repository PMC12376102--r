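test_that("three-state builder places minima at the requested coordinates", {
  pot <- build_three_state_potential(-5 * kT310, -2.5 * kT310, kT310)
  mins <- potential_minima(pot)
  expect_equal(nrow(mins), 2)
  expect_lt(abs(mins$X[1] - 2.04), 0.2)
  expect_lt(abs(mins$theta[1] - 162.0), 2)
  expect_lt(abs(mins$X[2] - 8.20), 0.2)
  expect_lt(abs(mins$theta[2] - 95.4), 2)
  # unbound plateau sits at the declared baseline
  expect_lt(max(abs(potential_energy(pot, c(14, 16, 18), c(30, 90, 150)))),
            0.1)
})

test_that("degenerate flat landscape has zero energy and gradient", {
  pot <- build_three_state_potential(0, 0, 0)
  xs <- c(1, 5, 9, 13); ts <- c(20, 80, 140, 170)
  expect_equal(potential_energy(pot, xs, ts), rep(0, 4))
  expect_equal(unname(potential_gradient(pot, xs, ts)),
               matrix(0, 4, 2), ignore_attr = TRUE)
})

test_that("scaled landscape minima match a dense-grid minimisation oracle", {
  pot <- build_three_state_potential(-10 * kT310, -5 * kT310, 8 * kT310)
  mins <- potential_minima(pot)
  # oracle: plain 500x500 grid scan, no refinement
  xs <- seq(0, 20, length.out = 500)
  ts <- seq(0, 180, length.out = 500)
  g <- outer(xs, ts, function(a, b) potential_energy(pot, a, b))
  expect_lt(abs(min(g) - min(mins$G)), 0.05)
  # second basin depth: oracle restricted to the large-X half
  g2 <- g[xs > 6, ]
  expect_lt(abs(min(g2) - mins$G[2]), 0.05)
})

test_that("geometry outside the domain is rejected with the coordinate named", {
  expect_error(build_three_state_potential(-10, -5, 3,
    geometry = list(min1 = c(-1, 162), min2 = c(8.2, 95.4),
                    trans = c(5, 146))), "min1.*X = -1")
  expect_error(build_three_state_potential(-10, -5, 3,
    geometry = list(min1 = c(2, 162), min2 = c(8.2, 200),
                    trans = c(5, 146))), "min2.*theta = 200")
})

test_that("free diffusion follows the 2 D t law", {
  pot <- flat_potential()
  for (seed in 1:3) {
    cfg <- langevin_config(dt = 0.05, D_x = 1, D_theta = 1, n_steps = 1e5,
                           seed = seed, x_bounds = c(-1e4, 1e4),
                           theta_bounds = c(-1e4, 1e4), sample_stride = 10)
    tr <- simulate_unbiased(pot, cfg, c(0, 0))
    lag <- 5  # frames; 2.5 ps
    idx <- seq(1, nrow(tr) - lag, by = lag)
    dx <- tr$X[idx + lag] - tr$X[idx]
    msd <- mean(dx^2)
    expect_lt(abs(msd / (2 * 1 * lag * 10 * 0.05) - 1), 0.05 * 3)
  }
})

test_that("stationary variance in a stiff well satisfies equipartition", {
  # deep wide Gaussian: near-quadratic with curvature amp/sigma^2
  pot <- model_potential(data.frame(amp = -400, cx = 0, ct = 0, sx = 4,
                                    st = 4),
                         x_range = c(-8, 8), theta_range = c(-8, 8))
  kap <- 400 / 16
  for (seed in 1:3) {
    cfg <- langevin_config(dt = 0.002, D_x = 1, D_theta = 1,
                           temperature = 310, n_steps = 1e6, seed = seed,
                           x_bounds = c(-8, 8), theta_bounds = c(-8, 8),
                           sample_stride = 10)
    tr <- simulate_unbiased(pot, cfg, c(0, 0))
    expect_lt(abs(var(tr$X) / (kT310 / kap) - 1), 0.05)
  }
})

test_that("unbiased trajectories have zero bias and respect the walls", {
  pot <- default_landscape("test")
  cfg <- langevin_config(n_steps = 2e4, seed = 3)
  tr <- simulate_unbiased(pot, cfg, c(2.04, 162))
  expect_true(all(tr$bias == 0))
  expect_true(all(tr$X >= 0 & tr$X <= 20))
  expect_true(all(tr$theta >= 0 & tr$theta <= 180))
})

test_that("first deposited hill has height h0 and gamma matches Table-style arithmetic", {
  md <- metad_params(h0 = 0.25, deltaT = 5115)
  expect_identical(bias_factor(md, 310), (310 + 5115) / 310)
  pot <- default_landscape("test")
  sim <- simulate_wtmetad(pot, langevin_config(n_steps = 1200, seed = 4),
                          md, c(2.04, 162))
  expect_equal(sim$hills$height[1], 0.25)
  expect_equal(unique(sim$hills$biasf), 17.5)
})

test_that("hill heights stay in (0, h0], decay on average, and follow the tempering rule", {
  # single well in a confined domain so the bias fills everywhere; a
  # strongly tempered run (small deltaT) shows the decay clearly
  pot <- model_potential(data.frame(amp = -8 * kT310, cx = 5, ct = 90,
                                    sx = 1.2, st = 14),
                         x_range = c(2, 8), theta_range = c(40, 140))
  md <- metad_params(stride = 10, deltaT = 300)
  cfg <- langevin_config(n_steps = 4e5, seed = 7, x_bounds = c(2, 8),
                         theta_bounds = c(40, 140))  # 2000 hills
  sim <- simulate_wtmetad(pot, cfg, md, c(5, 90))
  h <- sim$hills$height
  expect_true(all(h > 0 & h <= md$h0 + 1e-12))
  # running average decays toward the tempered-height regime h0/gamma
  run_mean <- cumsum(h) / seq_along(h)
  expect_true(all(diff(run_mean[c(10, 100, 500, 2000)]) < 0))
  gam <- bias_factor(md, 310)
  late <- mean(h[1751:2000])
  expect_lt(late, 0.6 * md$h0)
  expect_gt(late, md$h0 / gam / 2.5)
  expect_lt(late, md$h0 / gam * 2.5)
  # each height equals h0 exp(-V/kB deltaT) with V the exact hill sum at
  # the deposition point (grid interpolation allows a small tolerance)
  kB_dT <- phys_constants$R * md$deltaT / 1000
  v <- vapply(seq_len(nrow(sim$hills)), function(i)
    evaluate_bias(sim$hills[seq_len(i - 1), , drop = FALSE],
                  sim$hills$X[i], sim$hills$theta[i]), 0)
  expect_lt(max(abs(h / (md$h0 * exp(-v / kB_dT)) - 1)), 0.01)
})

test_that("deposition stride below the integration step is rejected", {
  pot <- default_landscape("test")
  expect_error(simulate_wtmetad(pot, langevin_config(dt = 0.05),
                                metad_params(stride = 0.01), c(2, 160)),
               "stride")
})

test_that("same seed regenerates trajectories and HILLS byte-identically", {
  pot <- default_landscape("test")
  cfg <- langevin_config(n_steps = 2e4, seed = 11)
  md <- metad_params(stride = 10)
  s1 <- simulate_wtmetad(pot, cfg, md, c(2.04, 162))
  s2 <- simulate_wtmetad(pot, cfg, md, c(2.04, 162))
  expect_identical(s1$traj, s2$traj)
  f1 <- tempfile(); f2 <- tempfile()
  write_hills(s1$hills, f1); write_hills(s2$hills, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("flat-landscape first-passage times follow the diffusive L^2/2D scale", {
  pot <- model_potential(data.frame(amp = numeric(0), cx = numeric(0),
                                    ct = numeric(0), sx = numeric(0),
                                    st = numeric(0)),
                         x_range = c(0, 50), theta_range = c(0, 180))
  L <- 5; D <- 1
  cfg <- langevin_config(dt = 0.01, D_x = D, D_theta = 1, seed = 21,
                         x_bounds = c(0, 50))
  fpt <- first_passage_oracle(pot, cfg,
                              boundary = structure(L, start = c(0, 90)),
                              n_runs = 200, max_steps = 1e6)
  # reflecting wall at 0, absorbing at L, start 0: MFPT = L^2 / (2D)
  expect_lt(abs(mean(fpt) / (L^2 / (2 * D)) - 1), 0.2)
})

test_that("double-well escape matches the Kramers estimate within a factor of two", {
  pot <- double_well_1d()
  xs <- seq(0, 12, by = 0.01)
  g <- potential_energy(pot, xs, 90)
  i_min <- which.min(g)
  seg <- which(xs > 3 & xs < 9)
  i_sad <- seg[which.max(g[seg])]
  d2 <- function(i) (g[i + 1] - 2 * g[i] + g[i - 1]) / 0.01^2
  tau_kr <- 2 * pi * kT310 / (0.1 * sqrt(d2(i_min) * abs(d2(i_sad)))) *
    exp((g[i_sad] - g[i_min]) / kT310)
  cfg <- langevin_config(seed = 31)
  fpt <- suppressWarnings(first_passage_oracle(
    pot, cfg, boundary = structure(7.5, start = c(xs[i_min], 90)),
    n_runs = 100, max_steps = 4e6))
  ratio <- mean(fpt) / tau_kr
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("first-passage oracle is deterministic under a fixed seed and reports censoring", {
  pot <- default_landscape("test")
  cfg <- langevin_config(seed = 41)
  f1 <- first_passage_oracle(pot, cfg, boundary = 6.5, n_runs = 5,
                             max_steps = 2e6)
  f2 <- first_passage_oracle(pot, cfg, boundary = 6.5, n_runs = 5,
                             max_steps = 2e6)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_warning(
    short <- first_passage_oracle(pot, cfg, boundary = 6.5, n_runs = 4,
                                  max_steps = 100),
    "censored")
  expect_equal(attr(short, "n_censored"), 4)
})
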