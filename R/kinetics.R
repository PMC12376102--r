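#' Acceleration factor along a biased trajectory
#'
#' The running average of the exponentiated bias,
#' `alpha(t_n) = (1/n) * sum_{i<=n} exp(V_i / kBT)`,
#' which multiplies metadynamics time to recover physical time.  Frames
#' are assumed equally spaced; for unequal spacing a time-weighted running
#' mean is used.
#'
#' @param traj a `biased_trajectory` (columns time, X, theta, bias).
#' @param temperature temperature, K.
#' @return data frame (class `acceleration_series`) with columns time,
#'   alpha.
#' @export
acceleration_series <- function(traj, temperature = 310) {
  stopifnot(temperature > 0, nrow(traj) >= 1)
  if (any(traj$bias < -1e-9)) stop("negative bias values in trajectory")
  w <- exp(traj$bias / kBT_kJmol(temperature))
  dt <- diff(traj$time)
  if (length(dt) > 0 && diff(range(dt)) > 1e-8 * mean(dt)) {
    # unequal spacing: time-weighted running mean (left-interval weights)
    wt <- c(dt[1], dt)
    alpha <- cumsum(wt * w) / cumsum(wt)
  } else {
    alpha <- cumsum(w) / seq_along(w)
  }
  out <- data.frame(time = traj$time, alpha = alpha)
  class(out) <- c("acceleration_series", "data.frame")
  out
}

# SSR of least-squares lines over all split points, via cumulative sums;
# returns list(ssr0, best_split, ssr2) where ssr2[k] is the two-segment
# SSR splitting after index k
segment_scan <- function(x, y, min_seg = 5) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg_ssr <- function(i, j) {
    # SSR of the LS line fitted to points i..j
    m <- j - i + 1
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
    syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
    vxx <- sxx - sx * sx / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy * sy / m
    if (vxx <= 0) return(max(vyy, 0))
    max(vyy - vxy * vxy / vxx, 0)
  }
  ssr0 <- seg_ssr(1, n)
  ks <- seq(min_seg, n - min_seg)
  if (length(ks) == 0) return(list(ssr0 = ssr0, split = NA, ssr2 = NA))
  ssr2 <- vapply(ks, function(k) seg_ssr(1, k) + seg_ssr(k + 1, n), 0)
  best <- which.min(ssr2)
  list(ssr0 = ssr0, split = ks[best], ssr2 = ssr2[best])
}

#' Detect the kinetic transition from the acceleration-factor kink
#'
#' A kinetic transition appears as an abrupt kink in log(alpha) versus
#' time: the bias stops growing under the trajectory once the system has
#' left the biased basin.  The change point of a two-segment piecewise
#' linear fit to log(alpha) (the split maximising the SSR reduction) is
#' taken as the transition time when the reduction relative to a single
#' line exceeds `significance` (fraction); it is cross-checked against the
#' first frame at which the CVs leave the bound region.  The rescaled
#' physical residence time is `t* = t_trans * alpha(t_trans)`.
#'
#' @param series an `acceleration_series`.
#' @param traj the matching `biased_trajectory`.
#' @param bound_predicate `function(X, theta)` returning TRUE while the
#'   system is in the bound state.
#' @param significance minimum fractional SSR reduction for a kink.
#' @return An object of class `transition_event` (fields `found`, `time`,
#'   `alpha`, `X`, `theta`, `t_rescaled`, `kink_time`, `crossing_time`,
#'   `ssr_reduction`), with `found = FALSE` when neither a significant
#'   kink nor a boundary crossing exists.
#' @export
detect_transition <- function(series, traj, bound_predicate,
                              significance = 0.2) {
  stopifnot(nrow(series) >= 10, nrow(series) == nrow(traj))
  outside <- which(!bound_predicate(traj$X, traj$theta))
  crossing_i <- if (length(outside) > 0) outside[1] else NA
  # restrict the kink scan to the trajectory up to (just past) the first
  # boundary crossing; after escape alpha is flat and adds no information
  n_scan <- if (is.na(crossing_i)) nrow(series) else
    min(nrow(series), crossing_i + max(10, round(0.1 * crossing_i)))
  scan <- segment_scan(series$time[1:n_scan], log(series$alpha[1:n_scan]))
  red <- if (scan$ssr0 > 0 && !is.na(scan$split))
    1 - scan$ssr2 / scan$ssr0 else 0
  kink_i <- if (!is.na(scan$split) && red >= significance) scan$split else NA
  event_i <- if (!is.na(kink_i)) kink_i else crossing_i
  if (is.na(event_i))
    return(structure(list(found = FALSE), class = "transition_event"))
  t_tr <- series$time[event_i]
  a_tr <- series$alpha[event_i]
  structure(list(found = TRUE, time = t_tr, alpha = a_tr,
                 X = traj$X[event_i], theta = traj$theta[event_i],
                 t_rescaled = t_tr * a_tr,
                 kink_time = if (is.na(kink_i)) NA else series$time[kink_i],
                 crossing_time = if (is.na(crossing_i)) NA else
                   series$time[crossing_i],
                 ssr_reduction = red),
            class = "transition_event")
}

#' @export
print.transition_event <- function(x, ...) {
  if (!x$found) { cat("no transition detected\n"); return(invisible(x)) }
  cat(sprintf("transition at t = %.1f ps (alpha = %.3g)\n", x$time, x$alpha))
  cat(sprintf("  CVs (%.2f A, %.1f deg); rescaled residence time %.4g ps\n",
              x$X, x$theta, x$t_rescaled))
  invisible(x)
}

#' Fit the mean residence time by SSR against the exponential CDF
#'
#' The empirical CDF of the rescaled residence times is compared with the
#' exponential CDF `1 - exp(-t/tau)` at the sample points; the sum of
#' squared residuals is scanned over a logarithmic tau grid (1000 points
#' spanning 0.01x to 100x the sample mean, refined once around the
#' argmin), and its global minimum gives the mean residence time.  The fit
#' is validated with a two-sample Kolmogorov--Smirnov test between the
#' samples and an equal-size synthetic draw from the fitted exponential
#' (fixed internal seed, so p-values are reproducible).
#'
#' @param samples positive rescaled residence times (>= 5 values).
#' @param tau_grid optional explicit tau grid.
#' @param ks_reference optional reference sample for the KS step instead
#'   of synthetic exponential draws.
#' @param ks_seed internal seed for the synthetic KS draws.
#' @return An object of class `expfit_result`: `tau`, `ssr_curve`
#'   (data frame tau, ssr), `ks_stat`, `ks_p`, `n`.
#' @export
fit_residence_times <- function(samples, tau_grid = NULL,
                                ks_reference = NULL, ks_seed = 42L) {
  samples <- as.numeric(samples)
  if (length(samples) < 5) stop("at least 5 residence times are required")
  if (any(samples <= 0)) stop("residence times must be positive")
  s <- sort(samples)
  n <- length(s)
  emp <- seq_len(n) / n
  ssr_of <- function(tau)
    vapply(tau, function(tt) sum((emp - (1 - exp(-s / tt)))^2), 0)
  if (is.null(tau_grid)) {
    m <- mean(s)
    grid1 <- exp(seq(log(0.01 * m), log(100 * m), length.out = 1000))
    ssr1 <- ssr_of(grid1)
    i1 <- which.min(ssr1)
    lo <- grid1[max(1, i1 - 2)]; hi <- grid1[min(length(grid1), i1 + 2)]
    grid2 <- exp(seq(log(lo), log(hi), length.out = 1000))
    ssr2 <- ssr_of(grid2)
    tau_grid <- c(grid1, grid2)
    ssr <- c(ssr1, ssr2)
  } else {
    ssr <- ssr_of(tau_grid)
  }
  ord <- order(tau_grid)
  tau_grid <- tau_grid[ord]; ssr <- ssr[ord]
  tau_hat <- tau_grid[which.min(ssr)]
  if (is.null(ks_reference)) {
    ks_reference <- withr::with_seed(ks_seed, stats::rexp(n, 1 / tau_hat))
  }
  ks <- suppressWarnings(stats::ks.test(samples, ks_reference))
  structure(list(tau = tau_hat,
                 ssr_curve = data.frame(tau = tau_grid, ssr = ssr),
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value, n = n),
            class = "expfit_result")
}

#' @export
print.expfit_result <- function(x, ...) {
  cat(sprintf("exponential fit: tau = %.4g (n = %d)\n", x$tau, x$n))
  cat(sprintf("  KS statistic %.3f, p = %.3f\n", x$ks_stat, x$ks_p))
  invisible(x)
}

#' Activation free energy from a mean residence time (Eyring relation)
#'
#' Inverts `k = kappa * (kB T / h) * exp(-dG / RT)` with `k = 1/tau`:
#' `dG = -RT ln( k h / (kappa kB T) )`.
#'
#' @param tau mean residence time, s.
#' @param temperature temperature, K.
#' @param kappa transmission coefficient (default 1: every arrival at the
#'   transition state crosses).
#' @return An object of class `eyring_result`: `dG` (kJ/mol), `k` (1/s),
#'   `kappa`, `temperature`.
#' @export
activation_from_tau <- function(tau, temperature, kappa = 1) {
  stopifnot(tau > 0, temperature > 0, kappa > 0)
  k <- 1 / tau
  pre <- kappa * phys_constants$kB * temperature / phys_constants$h
  dG <- -phys_constants$R * temperature * log(k / pre) / 1000
  structure(list(dG = dG, k = k, kappa = kappa, temperature = temperature),
            class = "eyring_result")
}

#' Eyring rate from an activation free energy
#'
#' @param dG activation Gibbs energy, kJ/mol.
#' @inheritParams activation_from_tau
#' @return Rate constant, 1/s.
#' @export
eyring_rate <- function(dG, temperature, kappa = 1) {
  kappa * phys_constants$kB * temperature / phys_constants$h *
    exp(-dG * 1000 / (phys_constants$R * temperature))
}

#' @export
print.eyring_result <- function(x, ...) {
  cat(sprintf("dG_activation = %.2f kJ/mol (k = %.3g 1/s at %g K, kappa = %g)\n",
              x$dG, x$k, x$temperature, x$kappa))
  invisible(x)
}

#' Transfer a residence time to another temperature
#'
#' Applies the Eyring relation at both temperatures with the same
#' activation free energy and transmission coefficient:
#' `tau2 = tau1 * k(T1)/k(T2)`, algebraically identical to
#' `tau2 = tau1 * (T1/T2) * exp[-(dG/R) (1/T1 - 1/T2)]`.
#'
#' @param tau1 residence time at `T1`, s.
#' @param T1,T2 temperatures, K.
#' @param dG activation Gibbs energy, kJ/mol (e.g. from
#'   [activation_from_tau()]).
#' @return Residence time at `T2`, s.
#' @export
temperature_transfer <- function(tau1, T1, T2, dG) {
  stopifnot(tau1 > 0, T1 > 0, T2 > 0)
  tau1 * eyring_rate(dG, T1) / eyring_rate(dG, T2)
}

#' Link the binding free energy to on/off rates
#'
#' `K_eq = exp(-dG_bind/RT)`; `k_on = K_eq * k_off`.
#'
#' @param dG_bind standard binding Gibbs energy, kJ/mol.
#' @param temperature temperature, K.
#' @param k_off dissociation rate constant, 1/s.
#' @return List with `K_eq`, `k_on`, `k_off`.
#' @export
equilibrium_link <- function(dG_bind, temperature, k_off) {
  stopifnot(temperature > 0, k_off > 0)
  K_eq <- exp(-dG_bind * 1000 / (phys_constants$R * temperature))
  list(K_eq = K_eq, k_on = K_eq * k_off, k_off = k_off)
}
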