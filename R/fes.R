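#' Metadynamics bias at arbitrary points
#'
#' Exact Gaussian summation over the deposited hills:
#' `V(s) = sum_h height_h * exp(-dX^2/(2 sigma_X^2) - dtheta^2/(2 sigma_theta^2))`
#' restricted to hills with deposition time `<= up_to_time`.
#'
#' @param hills a `hills` data frame (see [read_hills()]).
#' @param x,theta evaluation coordinates (recycled to common length).
#' @param up_to_time time cutoff, ps (default: all hills).
#' @return Bias values in kJ/mol.
#' @export
evaluate_bias <- function(hills, x, theta, up_to_time = Inf) {
  n <- max(length(x), length(theta))
  x <- rep_len(as.numeric(x), n); theta <- rep_len(as.numeric(theta), n)
  if (is.null(hills) || nrow(hills) == 0) return(numeric(n))
  hm <- as.matrix(hills[c("time", "X", "theta", "sigma_X", "sigma_theta",
                          "height")])
  .evaluate_bias_cpp(hm, x, theta, up_to_time)
}

#' Free-energy surface grid
#'
#' Discretised Gibbs energy over the (X, theta) plane with uniform axes.
#' The surface is shifted by a constant so that its mean over the unbound
#' mask is zero (the conventional zero of the unbound plateau).
#'
#' @param x,theta uniform axis vectors (angstrom, deg).
#' @param G matrix of Gibbs energies, `length(x)` by `length(theta)`,
#'   kJ/mol.
#' @param unbound_mask logical matrix of the same shape marking the
#'   unbound region used for the zero shift.
#' @return An object of class `fes_grid`.  The applied shift is stored in
#'   `$shift`.
#' @export
fes_grid <- function(x, theta, G, unbound_mask) {
  stopifnot(is.matrix(G), nrow(G) == length(x), ncol(G) == length(theta),
            all(is.finite(G)))
  if (length(x) > 1 && diff(range(diff(x))) > 1e-8 * mean(diff(x)))
    stop("x axis must be uniform")
  if (length(theta) > 1 &&
      diff(range(diff(theta))) > 1e-8 * mean(diff(theta)))
    stop("theta axis must be uniform")
  stopifnot(is.logical(unbound_mask), dim(unbound_mask) == dim(G),
            any(unbound_mask))
  shift <- mean(G[unbound_mask])
  G <- G - shift
  stopifnot(abs(mean(G[unbound_mask])) < 1e-9)
  structure(list(x = as.numeric(x), theta = as.numeric(theta), G = G,
                 unbound_mask = unbound_mask, shift = shift),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("fes_grid:", length(x$x), "x", length(x$theta), "points over X [",
      min(x$x), ",", max(x$x), "] A, theta [", min(x$theta), ",",
      max(x$theta), "] deg\n")
  cat("G range:", round(min(x$G), 3), "to", round(max(x$G), 3),
      "kJ/mol; unbound-mean shift applied:", round(x$shift, 4), "\n")
  invisible(x)
}

#' Reconstruct the well-tempered FES from deposited hills
#'
#' Uses the standard well-tempered estimator
#' `G(s) = -(T + deltaT)/deltaT * V(s, t_final)`, i.e. `-gamma/(gamma - 1)`
#' times the final bias, then shifts so the unbound-mask mean is zero.
#' All hills must share one bias factor.
#'
#' @param hills a `hills` data frame.
#' @param x,theta grid axes; defaults resolve the hill widths
#'   (0.1 angstrom by 1 deg over X in \[0, 14\], theta in \[0, 180\]).
#' @param unbound_mask logical matrix over the grid, or a predicate
#'   `function(X, theta)`; if missing, the unbound region is taken as all
#'   X beyond the largest X at which the surface deviates by more than
#'   0.5 kJ/mol from its large-X level.
#' @return An `fes_grid`.
#' @export
reconstruct_fes <- function(hills, x = seq(0, 14, by = 0.1),
                            theta = seq(0, 180, by = 1),
                            unbound_mask = NULL) {
  if (is.null(hills) || nrow(hills) == 0) stop("no hills to reconstruct from")
  gam <- unique(round(hills$biasf, 10))
  if (length(gam) != 1)
    stop("mixed bias factors in hills: ", paste(gam, collapse = ", "))
  gam <- gam[1]
  if (gam <= 1) stop("bias factor must exceed 1")
  pts <- expand.grid(X = x, theta = theta)
  V <- evaluate_bias(hills, pts$X, pts$theta)
  G <- matrix(-gam / (gam - 1) * V, nrow = length(x))
  if (is.function(unbound_mask)) {
    unbound_mask <- outer(x, theta, unbound_mask)
  } else if (is.null(unbound_mask)) {
    ref <- mean(G[length(x), ])
    dev_by_x <- apply(abs(G - ref), 1, max)
    beyond <- which(dev_by_x > 0.5)
    x_ub <- if (length(beyond) == 0) x[1] else
      x[min(length(x), max(beyond) + 1)]
    unbound_mask <- matrix(rep(x >= x_ub, length(theta)), nrow = length(x))
    if (!any(unbound_mask))
      unbound_mask <- matrix(rep(x >= stats::quantile(x, 0.9),
                                 length(theta)), nrow = length(x))
  }
  fes_grid(x, theta, G, unbound_mask)
}

#' Locate basins on a free-energy surface
#'
#' Strict local minima by 8-neighbourhood comparison, sorted by depth;
#' minima closer than the merge radius are merged into the deeper one.
#' A saddle estimate between the two deepest basins (the lowest level at
#' which they become connected) is attached as attribute `"saddle"`, and
#' cells within `plateau_band` of that saddle level are counted in
#' attribute `"plateau_cells"`.
#'
#' @param fes an `fes_grid`.
#' @param merge_radius c(X, theta) merge distances (angstrom, deg).
#' @param plateau_band half-width of the plateau band, kJ/mol.
#' @return data frame with columns X, theta, G (one row per basin).
#' @export
find_minima <- function(fes, merge_radius = c(0.5, 5), plateau_band = 2) {
  idx <- which_local_minima(fes$G)
  if (nrow(idx) == 0) {
    out <- data.frame(X = numeric(0), theta = numeric(0), G = numeric(0))
    attr(out, "saddle") <- NULL
    return(out)
  }
  out <- data.frame(X = fes$x[idx[, 1]], theta = fes$theta[idx[, 2]],
                    G = fes$G[idx])
  out$i <- idx[, 1]; out$j <- idx[, 2]
  out <- out[order(out$G), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (abs(out$X[i] - out$X[j]) <= merge_radius[1] &&
          abs(out$theta[i] - out$theta[j]) <= merge_radius[2])
        keep[j] <- FALSE  # j is shallower (sorted); merge into i
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) >= 2) {
    sad <- saddle_level(fes$G, c(out$i[1], out$j[1]), c(out$i[2], out$j[2]))
    attr(out, "saddle") <- sad
    attr(out, "plateau_cells") <- sum(abs(fes$G - sad) < plateau_band)
  }
  out$i <- NULL; out$j <- NULL
  out
}

# lowest level at which two grid cells are connected through cells with
# G <= level (4-connectivity); bisection over candidate levels
saddle_level <- function(G, a, b, tol = 1e-3) {
  lo <- max(G[a[1], a[2]], G[b[1], b[2]])
  hi <- max(G)
  nr <- nrow(G); nc <- ncol(G)
  a_lin <- a[1] + (a[2] - 1L) * nr
  b_lin <- b[1] + (b[2] - 1L) * nr
  connected <- function(level) {
    open <- G <= level
    if (!open[a_lin] || !open[b_lin]) return(FALSE)
    visited <- logical(nr * nc)
    stack <- integer(nr * nc)
    stack[1] <- a_lin; top <- 1L
    visited[a_lin] <- TRUE
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      if (cur == b_lin) return(TRUE)
      i <- (cur - 1L) %% nr + 1L
      nb <- c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
              if (cur > nr) cur - nr, if (cur <= nr * (nc - 1L)) cur + nr)
      for (v in nb) if (open[v] && !visited[v]) {
        visited[v] <- TRUE
        top <- top + 1L
        stack[top] <- v
      }
    }
    FALSE
  }
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (connected(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' One-dimensional potential of mean force over X
#'
#' Integrates out theta by Boltzmann weighting:
#' `G(X) = -RT ln \int exp(-G(X, theta)/RT) dtheta` (trapezoidal rule,
#' guarded against overflow by max subtraction), then shifts the profile
#' to zero over the unbound region of the surface.
#'
#' @param fes an `fes_grid`.
#' @param temperature temperature, K.
#' @return data frame (class `pmf_1d`) with columns X, G.
#' @export
pmf_1d <- function(fes, temperature = 310) {
  rt <- kBT_kJmol(temperature)
  dtheta <- fes$theta[2] - fes$theta[1]
  w <- rep(1, length(fes$theta)); w[c(1, length(w))] <- 0.5
  m <- -fes$G / rt
  mmax <- apply(m, 1, max)
  integral <- rowSums(exp(m - mmax) * rep(w, each = nrow(m))) * dtheta
  g <- -rt * (mmax + log(integral))
  ub_rows <- apply(fes$unbound_mask, 1, any)
  if (!any(ub_rows)) ub_rows <- seq_along(g) == length(g)
  g <- g - mean(g[ub_rows])
  out <- data.frame(X = fes$x, G = g)
  class(out) <- c("pmf_1d", "data.frame")
  out
}

#' Write / read an FES as plain text
#'
#' Three-column text grid (X, theta, G) with a JSON sidecar recording the
#' axes, applied shift and unbound mask (as run-length-encoded rows).
#'
#' @param fes an `fes_grid`.
#' @param path output path for the grid; the sidecar is `path` plus
#'   `.json`.
#' @export
write_fes <- function(fes, path) {
  pts <- expand.grid(X = fes$x, theta = fes$theta)
  df <- data.frame(X = pts$X, theta = pts$theta, G = as.vector(fes$G))
  utils::write.table(format(df, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, quote = FALSE, row.names = FALSE)
  side <- list(x = fes$x, theta = fes$theta, shift = fes$shift,
               unbound_x = fes$x[apply(fes$unbound_mask, 1, any)])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
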