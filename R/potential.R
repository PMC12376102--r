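#' Analytic model landscapes over the two collective variables
#'
#' A `model_potential` is a sum of 2D Gaussian components plus a constant
#' baseline, defined over the (X, theta) plane: X is the projection of the
#' ligand--site vector onto the groove-directed unit vector (angstrom) and
#' theta the angle between that vector and the ligand's long axis (degrees).
#' These landscapes drive the built-in Langevin engine and serve as exact
#' oracles for the free-energy reconstruction: minima, saddle heights and
#' basin-to-basin differences are all available analytically.
#'
#' A component width may be `Inf` in either coordinate, in which case the
#' component is uniform along that coordinate (used for ridge-like barriers).
#'
#' @param components data frame (or matrix) with columns `amp` (kJ/mol),
#'   `cx` (angstrom), `ct` (deg), `sx` (angstrom), `st` (deg).
#' @param baseline constant offset, kJ/mol; the unbound plateau level.
#' @param x_range,theta_range numeric length-2 domains.
#' @return An object of class `model_potential`.
#' @export
model_potential <- function(components, baseline = 0,
                            x_range = c(0, 20), theta_range = c(0, 180)) {
  components <- as.data.frame(components)
  needed <- c("amp", "cx", "ct", "sx", "st")
  if (!all(needed %in% names(components)))
    stop("components must have columns: ", paste(needed, collapse = ", "))
  components <- components[needed]
  stopifnot(length(x_range) == 2, x_range[1] < x_range[2],
            length(theta_range) == 2, theta_range[1] < theta_range[2])
  if (nrow(components) > 0) {
    if (any(!is.finite(components$amp)))
      stop("component amplitudes must be finite")
    if (any(components$sx <= 0 | components$st <= 0, na.rm = TRUE))
      stop("component widths must be positive")
  }
  structure(list(components = components, baseline = baseline,
                 x_range = as.numeric(x_range),
                 theta_range = as.numeric(theta_range)),
            class = "model_potential")
}

comp_matrix <- function(pot) {
  m <- as.matrix(pot$components)
  if (nrow(m) == 0) m <- matrix(numeric(0), 0, 5)
  storage.mode(m) <- "double"
  m
}

#' Evaluate a model potential
#'
#' @param pot a `model_potential`.
#' @param x,theta coordinates (recycled to common length).
#' @return Potential energy in kJ/mol.
#' @export
potential_energy <- function(pot, x, theta) {
  n <- max(length(x), length(theta))
  x <- rep_len(as.numeric(x), n); theta <- rep_len(as.numeric(theta), n)
  .potential_eval_cpp(comp_matrix(pot), pot$baseline, x, theta)
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return Two-column matrix: dG/dX (kJ/mol/angstrom), dG/dtheta
#'   (kJ/mol/deg).
#' @export
potential_gradient <- function(pot, x, theta) {
  n <- max(length(x), length(theta))
  x <- rep_len(as.numeric(x), n); theta <- rep_len(as.numeric(theta), n)
  g <- .potential_grad_cpp(comp_matrix(pot), x, theta)
  colnames(g) <- c("dG_dX", "dG_dtheta")
  g
}

#' @export
print.model_potential <- function(x, ...) {
  cat("Model potential over X in [", x$x_range[1], ",", x$x_range[2],
      "] A, theta in [", x$theta_range[1], ",", x$theta_range[2], "] deg\n")
  cat(nrow(x$components), "Gaussian component(s), baseline",
      x$baseline, "kJ/mol\n")
  if (nrow(x$components)) print(x$components, digits = 4)
  invisible(x)
}

#' Three-state deintercalation landscape
#'
#' Builds the canonical landscape of drug--DNA deintercalation: a deep
#' intercalated basin at small X / high theta, a shallower minor-groove
#' basin at larger X / lower theta, and a barrier ridge between them with
#' its saddle at the transition coordinates.  Default basin and transition
#' placements follow the intercalated / minor-groove minima and transition
#' point of the 5'-d(ACGTAC|GT)-3' complex.  The barrier is realised as an
#' X-ridge (uniform in theta, amplitude `2*barrier`) plus a negative notch
#' (`-barrier`) at the transition point, so the saddle sits at the requested
#' coordinates, about `barrier` kJ/mol above the unbound plateau (which is
#' at 0).
#'
#' @param depth_intercalated,depth_minor_groove basin amplitudes, kJ/mol
#'   (negative; 0 allowed for the degenerate flat case).
#' @param barrier saddle height above the plateau, kJ/mol (non-negative).
#' @param geometry list with `min1`, `min2`, `trans`, each c(X, theta);
#'   defaults to the intercalated/minor-groove geometry above.
#' @param basin_sigma,barrier_sigma c(X, theta) Gaussian widths.
#' @param x_range,theta_range domain.
#' @return A `model_potential`.
#' @export
build_three_state_potential <- function(depth_intercalated,
                                        depth_minor_groove,
                                        barrier,
                                        geometry = NULL,
                                        basin_sigma = c(1.2, 14),
                                        barrier_sigma = c(1.1, 25),
                                        x_range = c(0, 20),
                                        theta_range = c(0, 180)) {
  if (depth_intercalated > 0 || depth_minor_groove > 0)
    stop("basin depths must be <= 0")
  if (barrier < 0) stop("barrier must be >= 0")
  if (is.null(geometry))
    geometry <- list(min1 = c(2.04, 162.0), min2 = c(8.20, 95.4),
                     trans = c(5.04, 146.2))
  for (nm in c("min1", "min2", "trans")) {
    p <- geometry[[nm]]
    if (is.null(p) || length(p) != 2)
      stop("geometry$", nm, " must be c(X, theta)")
    if (p[1] < x_range[1] || p[1] > x_range[2])
      stop("geometry$", nm, ": X = ", p[1], " outside the domain [",
           x_range[1], ", ", x_range[2], "]")
    if (p[2] < theta_range[1] || p[2] > theta_range[2])
      stop("geometry$", nm, ": theta = ", p[2], " outside the domain [",
           theta_range[1], ", ", theta_range[2], "]")
  }
  comp <- data.frame(
    amp = c(depth_intercalated, depth_minor_groove, 2 * barrier, -barrier),
    cx  = c(geometry$min1[1], geometry$min2[1], geometry$trans[1],
            geometry$trans[1]),
    ct  = c(geometry$min1[2], geometry$min2[2], geometry$trans[2],
            geometry$trans[2]),
    sx  = c(basin_sigma[1], basin_sigma[1], barrier_sigma[1],
            barrier_sigma[1]),
    st  = c(basin_sigma[2], basin_sigma[2], Inf, barrier_sigma[2]))
  comp <- comp[comp$amp != 0, , drop = FALSE]
  model_potential(comp, baseline = 0, x_range = x_range,
                  theta_range = theta_range)
}

#' Bundled default landscapes
#'
#' `"test"`: desk-scale landscape with basin depths of -5 and -2.5 kBT and
#' a saddle about 1 kBT above the plateau (escape barrier about 6 kBT at
#' 310 K), small enough that unbiased escape is observable; used by the
#' validation suite.  `"production"`: basin depths and barrier of the
#' magnitude found for drug--DNA deintercalation (tens of kJ/mol), for
#' demonstrations only -- unbiased escape from it is unobservable at desk
#' scale.
#'
#' @param name `"test"` or `"production"`.
#' @param temperature temperature in K fixing kBT for the `"test"` depths.
#' @return A `model_potential`.
#' @export
default_landscape <- function(name = c("test", "production"),
                              temperature = 310) {
  name <- match.arg(name)
  kt <- kBT_kJmol(temperature)
  if (name == "test")
    build_three_state_potential(depth_intercalated = -5 * kt,
                                depth_minor_groove = -2.5 * kt,
                                barrier = 1 * kt)
  else
    build_three_state_potential(depth_intercalated = -63,
                                depth_minor_groove = -31.5,
                                barrier = 13)
}

#' Locate the minima of a model potential by dense grid search plus
#' local refinement
#'
#' @param pot a `model_potential`.
#' @param n grid points per axis for the initial search.
#' @return data frame with columns X, theta, G, one row per local minimum,
#'   ordered by depth.
#' @export
potential_minima <- function(pot, n = 200) {
  xs <- seq(pot$x_range[1], pot$x_range[2], length.out = n)
  ts <- seq(pot$theta_range[1], pot$theta_range[2], length.out = n)
  g <- outer(xs, ts, function(a, b) potential_energy(pot, a, b))
  cand <- which_local_minima(g)
  if (nrow(cand) == 0) return(data.frame(X = numeric(0), theta = numeric(0),
                                         G = numeric(0)))
  res <- lapply(seq_len(nrow(cand)), function(i) {
    p0 <- c(xs[cand[i, 1]], ts[cand[i, 2]])
    o <- stats::optim(p0, function(p) potential_energy(pot, p[1], p[2]),
                      method = "L-BFGS-B",
                      lower = c(pot$x_range[1], pot$theta_range[1]),
                      upper = c(pot$x_range[2], pot$theta_range[2]))
    c(o$par, o$value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(X = res[, 1], theta = res[, 2], G = res[, 3])
  # merge refined duplicates
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) if (keep[i]) for (j in seq_len(nrow(out))) {
    if (j != i && keep[j] &&
        abs(out$X[i] - out$X[j]) < 0.3 && abs(out$theta[i] - out$theta[j]) < 3)
      keep[j] <- out$G[j] < out$G[i] && i > j
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$G), , drop = FALSE]
}

# strict 8-neighbourhood local minima of a matrix; returns index pairs,
# excluding the outer frame
which_local_minima <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 3 || nc < 3) return(matrix(integer(0), 0, 2))
  core <- g[2:(nr - 1), 2:(nc - 1)]
  lower_than <- function(di, dj)
    core < g[2:(nr - 1) + di, 2:(nc - 1) + dj]
  ok <- lower_than(-1, -1) & lower_than(-1, 0) & lower_than(-1, 1) &
        lower_than(0, -1)  & lower_than(0, 1) &
        lower_than(1, -1)  & lower_than(1, 0)  & lower_than(1, 1)
  idx <- which(ok, arr.ind = TRUE)
  if (length(idx) == 0) return(matrix(integer(0), 0, 2))
  idx + 1L  # shift back to full-matrix indices
}
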