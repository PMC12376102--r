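#' Thermodynamic context for binding free energies
#'
#' Bundles the temperature and concentration inputs of the standard-state
#' correction.  The binding-site concentration depends on the simulation
#' box and is not derivable from the FES, so it is a required input; the
#' default corresponds to one site per 10^6 cubic angstrom of solution
#' (about 1.66 mM) and is documented as a placeholder to be replaced by
#' the actual box volume.
#'
#' @param temperature temperature, K.
#' @param C_site binding-site concentration, mol/L.
#' @param C_std standard concentration, mol/L (1 M).
#' @return An object of class `thermo_context`.
#' @export
thermo_context <- function(temperature = 310,
                           C_site = 1 / (6.02214076e23 * 1e6 * 1e-27),
                           C_std = 1) {
  stopifnot(temperature > 0, C_site > 0, C_std > 0)
  structure(list(temperature = temperature, C_site = C_site, C_std = C_std,
                 R = phys_constants$R, kB = phys_constants$kB,
                 h = phys_constants$h),
            class = "thermo_context")
}

#' Bound / unbound integration masks over an FES grid
#'
#' Boolean fields over the grid defining the integration regions of the
#' standard binding free energy.  The masks must be disjoint and
#' non-empty; an optional exclusion mask (e.g. a nonstandard-contact
#' region at low X and low theta) is removed from both before
#' integration.
#'
#' @param bound,unbound,exclusion logical matrices over the grid
#'   (exclusion may be NULL).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(bound, unbound, exclusion = NULL) {
  stopifnot(is.logical(bound), is.logical(unbound),
            all(dim(bound) == dim(unbound)))
  if (!is.null(exclusion)) {
    stopifnot(is.logical(exclusion), all(dim(exclusion) == dim(bound)))
    bound <- bound & !exclusion
    unbound <- unbound & !exclusion
  }
  if (any(bound & unbound)) stop("bound and unbound masks overlap")
  if (!any(bound)) stop("bound mask is empty")
  if (!any(unbound)) stop("unbound mask is empty")
  structure(list(bound = bound, unbound = unbound,
                 exclusion = exclusion), class = "region_mask")
}

#' Default masks from the 1D profile of a surface
#'
#' The bound region collects cells with X below the barrier top of the 1D
#' PMF (the maximum between the global minimum and the unbound plateau);
#' the unbound region collects cells with X beyond the largest X at which
#' the 1D profile deviates from zero by more than `flat_tol` kJ/mol.
#'
#' @param fes an `fes_grid`.
#' @param temperature temperature, K, for the 1D reduction.
#' @param flat_tol flatness threshold, kJ/mol.
#' @param exclusion optional logical exclusion matrix (user-supplied, e.g.
#'   a low-X/low-theta nonstandard-contact region).
#' @return A `region_mask`.
#' @export
default_masks <- function(fes, temperature = 310, flat_tol = 0.5,
                          exclusion = NULL) {
  pmf <- pmf_1d(fes, temperature)
  i_min <- which.min(pmf$G)
  dev <- which(abs(pmf$G) > flat_tol)
  i_flat <- if (length(dev) == 0) i_min + 1 else
    min(length(pmf$G), max(dev) + 1)
  seg <- seq(i_min, i_flat)
  i_bar <- seg[which.max(pmf$G[seg])]
  bound_x <- fes$x < fes$x[i_bar]
  unbound_x <- fes$x >= fes$x[i_flat]
  nb <- length(fes$theta)
  out <- region_mask(matrix(rep(bound_x, nb), ncol = nb),
                     matrix(rep(unbound_x, nb), ncol = nb), exclusion)
  # sub-masks splitting the sub-barrier region at the inter-basin barrier:
  # intercalated below the barrier top, minor-groove between it and the
  # plateau onset
  mg_x <- fes$x >= fes$x[i_bar] & fes$x < fes$x[i_flat]
  attr(out, "intercalated") <- out$bound
  attr(out, "minor_groove") <- matrix(rep(mg_x, nb), ncol = nb)
  attr(out, "x_barrier") <- fes$x[i_bar]
  attr(out, "x_flat") <- fes$x[i_flat]
  out
}

# trapezoidal integral of exp(-G/RT) over a masked region: cells whose
# four corners are inside the mask contribute area * mean(corner values);
# the common max-subtraction factor is returned on log scale
masked_boltzmann_integral <- function(G, mask, dx, dtheta, rt, m0) {
  W <- exp(-(G / rt) - m0)
  W[!mask] <- 0
  inmask <- mask * 1
  nr <- nrow(G); nc <- ncol(G)
  c00 <- inmask[-nr, -nc]; c10 <- inmask[-1, -nc]
  c01 <- inmask[-nr, -1];  c11 <- inmask[-1, -1]
  full <- (c00 + c10 + c01 + c11) == 4
  cellmean <- (W[-nr, -nc] + W[-1, -nc] + W[-nr, -1] + W[-1, -1]) / 4
  sum(cellmean[full]) * dx * dtheta
}

#' Standard binding Gibbs energy from a 2D free-energy surface
#'
#' Implements the two-region Boltzmann-ratio estimator with standard-state
#' correction:
#' `dG_bind = -RT ln( I_b / I_ub ) - RT ln(C_std / C_site)`,
#' where `I_b` and `I_ub` are trapezoidal integrals of `exp(-G/RT)` over
#' the bound and unbound masks.  The result is invariant under any
#' constant shift of the surface.
#'
#' @param fes an `fes_grid`.
#' @param mask a `region_mask` (default: [default_masks()]).
#' @param ctx a `thermo_context`.
#' @return An object of class `binding_result` with elements `dG`
#'   (kJ/mol), `I_bound`, `I_unbound` (shift-dependent scale, internal),
#'   and `std_correction`.
#' @export
binding_free_energy <- function(fes, mask = NULL, ctx = thermo_context()) {
  if (is.null(mask)) mask <- default_masks(fes, ctx$temperature)
  stopifnot(inherits(mask, "region_mask"),
            all(dim(mask$bound) == dim(fes$G)))
  rt <- kBT_kJmol(ctx$temperature)
  dx <- fes$x[2] - fes$x[1]
  dtheta <- fes$theta[2] - fes$theta[1]
  m0 <- max(-fes$G / rt)
  ib <- masked_boltzmann_integral(fes$G, mask$bound, dx, dtheta, rt, m0)
  iub <- masked_boltzmann_integral(fes$G, mask$unbound, dx, dtheta, rt, m0)
  if (ib <= 0) stop("bound-region integral is empty or zero")
  if (iub <= 0) stop("unbound-region integral is empty or zero")
  corr <- -rt * log(ctx$C_std / ctx$C_site)
  structure(list(dG = -rt * log(ib / iub) + corr,
                 I_bound = ib, I_unbound = iub, std_correction = corr,
                 temperature = ctx$temperature),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("standard binding Gibbs energy: %.3f kJ/mol at %g K\n",
              x$dG, x$temperature))
  cat(sprintf("  (standard-state correction: %+.3f kJ/mol)\n",
              x$std_correction))
  invisible(x)
}

#' Aggregate per-run values into mean and standard error
#'
#' @param values numeric vector of per-run results.
#' @return List with `mean`, `sem` (sample SD / sqrt(n); `NA` with a flag
#'   for a single run), `sd`, `n`, `values`.
#' @export
aggregate_runs <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) stop("no values to aggregate")
  out <- list(mean = mean(values),
              sd = if (n > 1) stats::sd(values) else NA_real_,
              sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
              n = n, values = values,
              single_run = n == 1)
  class(out) <- "run_aggregate"
  out
}

#' @export
print.run_aggregate <- function(x, ...) {
  if (x$single_run)
    cat(sprintf("%.4g (single run; SEM undefined)\n", x$mean))
  else
    cat(sprintf("%.4g +/- %.2g (SEM over %d runs)\n", x$mean, x$sem, x$n))
  invisible(x)
}
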