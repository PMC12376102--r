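# shared fixtures: all inputs are generated in code, nothing is read from
# disk except files the tests themselves write

kT310 <- kBT_kJmol(310)

# unbounded flat landscape for free-diffusion checks
flat_potential <- function(extent = 1e4) {
  model_potential(data.frame(amp = numeric(0), cx = numeric(0),
                             ct = numeric(0), sx = numeric(0),
                             st = numeric(0)),
                  x_range = c(-extent, extent),
                  theta_range = c(-extent, extent))
}

# quasi-1D double well (uniform in theta): basin at X = 3, barrier bump at
# X = 6; with both amplitudes 4 kBT the escape barrier is close to 8 kBT
double_well_1d <- function(kT = kT310) {
  model_potential(data.frame(amp = c(-4 * kT, 4 * kT),
                             cx = c(3, 6), ct = c(90, 90),
                             sx = c(1, 0.8), st = c(Inf, Inf)),
                  x_range = c(0, 20), theta_range = c(0, 180))
}

# small hills table built by hand
toy_hills <- function(n = 1, height = 1, x = 5, theta = 90,
                      sx = 0.25, st = 2.06, biasf = 17.5) {
  h <- data.frame(time = seq_len(n) * 2.0, X = rep_len(x, n),
                  theta = rep_len(theta, n), sigma_X = sx, sigma_theta = st,
                  height = rep_len(height, n), biasf = biasf)
  class(h) <- c("hills", "data.frame")
  h
}

# analytic smooth FES used by the binding-energy oracle comparisons
smooth_fes_fun <- function(X, theta) {
  -12 * exp(-((X - 3)^2 / (2 * 1.5^2)) - ((theta - 140)^2 / (2 * 20^2)))
}

make_smooth_fes <- function(dx = 0.05, dtheta = 0.5) {
  x <- seq(0, 14, by = dx)
  th <- seq(0, 180, by = dtheta)
  fes_grid(x, th, outer(x, th, smooth_fes_fun),
           outer(x, th, function(X, T_) X >= 10))
}

smooth_fes_masks <- function(fes) {
  region_mask(outer(fes$x, fes$theta, function(X, T_) X <= 7),
              fes$unbound_mask)
}

# independent fine-grid quadrature for the binding free energy (separate
# code path: pracma trapezoids on a refined grid, same region boundaries)
binding_refined_oracle <- function(refine = 10, dx = 0.05, dtheta = 0.5,
                                   temperature = 310) {
  rt <- kBT_kJmol(temperature)
  xf <- seq(0, 14, by = dx / refine)
  tf <- seq(0, 180, by = dtheta / refine)
  f <- function(X, T_) exp(-smooth_fes_fun(X, T_) / rt)
  int2d <- function(xs) {
    M <- outer(xs, tf, f)
    pracma::trapz(xs, apply(M, 1, function(r) pracma::trapz(tf, r)))
  }
  -rt * log(int2d(xf[xf <= 7]) / int2d(xf[xf >= 10]))
}
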