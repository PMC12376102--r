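#' Langevin integrator configuration
#'
#' Settings for the overdamped (position) Langevin dynamics used as the
#' sampling engine: per-CV update
#' `ds = -(D/kBT) * dG/ds * dt + sqrt(2 D dt) * N(0,1)`,
#' with reflective walls on both coordinates.  The collective variables are
#' slow diffusive modes, so inertial dynamics adds nothing here; only the
#' stationary distribution and escape statistics matter.
#'
#' @param dt integration step, ps.
#' @param D_x diffusion coefficient along X, angstrom^2/ps.
#' @param D_theta diffusion coefficient along theta, deg^2/ps.
#' @param temperature temperature, K.
#' @param n_steps number of integration steps.
#' @param seed integer seed recorded in all outputs.
#' @param x_bounds,theta_bounds reflective walls.
#' @param sample_stride record every this many steps.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(dt = 0.05, D_x = 0.1, D_theta = 10,
                            temperature = 310, n_steps = 2e5, seed = 1,
                            x_bounds = c(0, 20), theta_bounds = c(0, 180),
                            sample_stride = 10) {
  stopifnot(dt > 0, D_x > 0, D_theta > 0, temperature > 0, n_steps >= 1,
            length(x_bounds) == 2, x_bounds[1] < x_bounds[2],
            length(theta_bounds) == 2, theta_bounds[1] < theta_bounds[2],
            sample_stride >= 1)
  structure(list(dt = dt, D_x = D_x, D_theta = D_theta,
                 temperature = temperature, n_steps = as.numeric(n_steps),
                 seed = as.integer(seed),
                 x_bounds = as.numeric(x_bounds),
                 theta_bounds = as.numeric(theta_bounds),
                 sample_stride = as.integer(sample_stride)),
            class = "langevin_config")
}

#' Well-tempered metadynamics parameters
#'
#' Hill deposition settings.  Defaults keep the hill geometry and
#' well-tempering of the reference production setup (initial height
#' 0.25 kJ/mol, widths 0.25 angstrom and 2.06 deg, Delta T = 5115 K,
#' 6 runs) but use a deposition stride appropriate for the desk-scale
#' Langevin time base: hills every 20 ps, several times the basin
#' correlation time, as required for reliable residence-time rescaling.
#'
#' @param h0 initial hill height, kJ/mol.
#' @param stride deposition period, ps.
#' @param deltaT well-tempering temperature boost, K.
#' @param sigma_x,sigma_theta hill widths (angstrom, deg).
#' @param n_run number of independent runs for averaging.
#' @return An object of class `metad_params`.
#' @export
metad_params <- function(h0 = 0.25, stride = 20, deltaT = 5115,
                         sigma_x = 0.25, sigma_theta = 2.06, n_run = 6) {
  stopifnot(h0 > 0, stride > 0, deltaT > 0, sigma_x > 0, sigma_theta > 0,
            n_run >= 1)
  structure(list(h0 = h0, stride = stride, deltaT = deltaT,
                 sigma_x = sigma_x, sigma_theta = sigma_theta,
                 n_run = as.integer(n_run)),
            class = "metad_params")
}

#' Well-tempering bias factor gamma = (T + deltaT) / T
#'
#' @param metad a `metad_params`.
#' @param temperature temperature, K.
#' @return The dimensionless bias factor (> 1).
#' @export
bias_factor <- function(metad, temperature) {
  (temperature + metad$deltaT) / temperature
}

as_biased_trajectory <- function(df, seed) {
  attr(df, "seed") <- seed
  class(df) <- c("biased_trajectory", "data.frame")
  df
}

check_start <- function(start, config) {
  stopifnot(length(start) == 2)
  if (start[1] < config$x_bounds[1] || start[1] > config$x_bounds[2] ||
      start[2] < config$theta_bounds[1] || start[2] > config$theta_bounds[2])
    stop("start point (", start[1], ", ", start[2], ") outside the domain")
}

#' Unbiased Langevin trajectory on a model landscape
#'
#' @param potential a `model_potential`.
#' @param config a `langevin_config`.
#' @param start c(X, theta) starting point.
#' @return A `biased_trajectory` data frame (time, X, theta, bias), with
#'   the bias column identically zero.
#' @export
simulate_unbiased <- function(potential, config, start) {
  check_start(start, config)
  set.seed(config$seed)
  out <- .simulate_cpp(comp_matrix(potential), potential$baseline,
                       start[1], start[2], config$dt, config$D_x,
                       config$D_theta, kBT_kJmol(config$temperature),
                       config$n_steps,
                       config$x_bounds[1], config$x_bounds[2],
                       config$theta_bounds[1], config$theta_bounds[2],
                       config$sample_stride,
                       FALSE, 0, 1L, 1, 1, 1, 1, 1, 1)
  as_biased_trajectory(out$traj, config$seed)
}

#' Well-tempered metadynamics run on a model landscape
#'
#' Every `metad$stride` ps a Gaussian hill of height
#' `h0 * exp(-V(s)/(kB deltaT))` is deposited at the current CVs; the
#' trajectory's bias column holds the instantaneous bias V(s(t), t) at each
#' recorded frame, and the returned hills share the trajectory time base.
#'
#' @inheritParams simulate_unbiased
#' @param metad a `metad_params`.
#' @return List with elements `traj` (a `biased_trajectory`) and `hills`
#'   (a hills data frame, see [read_hills()]).
#' @export
simulate_wtmetad <- function(potential, config, metad, start) {
  check_start(start, config)
  dep_stride <- metad$stride / config$dt
  if (dep_stride < 1)
    stop("deposition stride (", metad$stride,
         " ps) is smaller than the integration step (", config$dt, " ps)")
  if (abs(dep_stride - round(dep_stride)) > 1e-9)
    stop("deposition stride must be a multiple of the integration step")
  gamma <- bias_factor(metad, config$temperature)
  kB_dT <- phys_constants$R * metad$deltaT / 1000
  set.seed(config$seed)
  out <- .simulate_cpp(comp_matrix(potential), potential$baseline,
                       start[1], start[2], config$dt, config$D_x,
                       config$D_theta, kBT_kJmol(config$temperature),
                       config$n_steps,
                       config$x_bounds[1], config$x_bounds[2],
                       config$theta_bounds[1], config$theta_bounds[2],
                       config$sample_stride,
                       TRUE, metad$h0, as.integer(round(dep_stride)), kB_dT,
                       gamma, metad$sigma_x, metad$sigma_theta,
                       metad$sigma_x / 5, metad$sigma_theta / 5)
  hills <- as.data.frame(out$hills)
  names(hills) <- c("time", "X", "theta", "sigma_X", "sigma_theta",
                    "height", "biasf")
  class(hills) <- c("hills", "data.frame")
  attr(hills, "seed") <- config$seed
  list(traj = as_biased_trajectory(out$traj, config$seed), hills = hills)
}

#' Unbiased first-passage times to an absorbing boundary
#'
#' Ground-truth residence times on desk-scale landscapes, for validating
#' the metadynamics residence-time rescaling.  Run `k` uses seed
#' `config$seed + k - 1`.
#'
#' @inheritParams simulate_unbiased
#' @param boundary either a single number, interpreted as an absorbing
#'   boundary at `X >= boundary` (checked every step), or a predicate
#'   `function(X, theta)` checked every `config$sample_stride` steps.
#' @param n_runs number of independent runs.
#' @param max_steps per-run step cap; runs hitting it are censored and
#'   excluded with a warning.
#' @return Numeric vector of first-passage times (ps), with attributes
#'   `seeds` (per-run seeds) and `n_censored`.
#' @export
first_passage_oracle <- function(potential, config, boundary, n_runs = 200,
                                 max_steps = 1e7) {
  stopifnot(n_runs >= 1)
  start <- attr(boundary, "start")
  if (is.null(start)) {
    mins <- potential_minima(potential)
    if (nrow(mins) == 0) stop("potential has no minimum to start from")
    start <- c(mins$X[1], mins$theta[1])
  }
  seeds <- config$seed + seq_len(n_runs) - 1L
  times <- numeric(n_runs)
  censored <- logical(n_runs)
  cm <- comp_matrix(potential)
  kt <- kBT_kJmol(config$temperature)
  for (k in seq_len(n_runs)) {
    set.seed(seeds[k])
    if (is.function(boundary)) {
      # chunked simulation; predicate checked at sampling resolution
      t_off <- 0; pos <- start; hit <- FALSE
      chunk <- langevin_config(dt = config$dt, D_x = config$D_x,
                               D_theta = config$D_theta,
                               temperature = config$temperature,
                               n_steps = min(config$n_steps, 1e5),
                               seed = seeds[k], x_bounds = config$x_bounds,
                               theta_bounds = config$theta_bounds,
                               sample_stride = config$sample_stride)
      while (t_off / config$dt < max_steps) {
        tr <- .simulate_cpp(cm, potential$baseline, pos[1], pos[2],
                            config$dt, config$D_x, config$D_theta, kt,
                            chunk$n_steps,
                            config$x_bounds[1], config$x_bounds[2],
                            config$theta_bounds[1], config$theta_bounds[2],
                            config$sample_stride,
                            FALSE, 0, 1L, 1, 1, 1, 1, 1, 1)$traj
        esc <- which(boundary(tr$X, tr$theta))
        if (length(esc) > 0) {
          times[k] <- t_off + tr$time[esc[1]]; hit <- TRUE; break
        }
        n <- nrow(tr)
        pos <- c(tr$X[n], tr$theta[n]); t_off <- t_off + tr$time[n]
      }
      censored[k] <- !hit
      if (!hit) times[k] <- t_off
    } else {
      fp <- .first_passage_cpp(cm, start[1], start[2], config$dt,
                               config$D_x, config$D_theta, kt,
                               boundary, max_steps,
                               config$x_bounds[1], config$x_bounds[2],
                               config$theta_bounds[1], config$theta_bounds[2])
      times[k] <- fp$time
      censored[k] <- fp$censored
    }
  }
  if (any(censored))
    warning(sum(censored), " run(s) exceeded the step cap and were censored")
  out <- times[!censored]
  attr(out, "seeds") <- seeds[!censored]
  attr(out, "n_censored") <- sum(censored)
  out
}
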