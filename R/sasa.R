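# default van der Waals radii (angstrom); the source study prints none,
# so a standard set is used and everything is configurable
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                NA. = 2.27, CL = 1.75, MG = 1.73, K = 2.75, F = 1.47,
                FE = 1.63)

# deterministic golden-spiral point set on the unit sphere
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of their
#' covalent radii plus 0.4 angstrom.
#'
#' @param structure a `structure3d`.
#' @return Two-column matrix of bonded row-index pairs.
#' @export
infer_bonds <- function(structure) {
  a <- structure$atoms
  n <- nrow(a)
  if (n < 2) return(matrix(integer(0), 0, 2))
  r <- lookup_elem(.covalent_radii, a$elem, "covalent radius")
  xyz <- as.matrix(a[c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") + 0.4
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  unname(hit)
}

#' Partition atoms into nonpolar and polar classes
#'
#' All carbon and phosphorus atoms, plus hydrogens covalently bonded to a
#' carbon, are nonpolar; every other atom is polar.  The partition is
#' exhaustive and disjoint.
#'
#' @param structure a `structure3d`.
#' @param bonds optional two-column matrix of bonded row pairs; inferred
#'   by [infer_bonds()] when absent.
#' @return Character vector (`"nonpolar"`/`"polar"`), one entry per atom.
#' @export
classify_polarity <- function(structure, bonds = NULL) {
  a <- structure$atoms
  if (is.null(bonds)) bonds <- infer_bonds(structure)
  elem <- toupper(trimws(a$elem))
  cls <- ifelse(elem %in% c("C", "P"), "nonpolar", "polar")
  h_idx <- which(elem == "H")
  for (i in h_idx) {
    partners <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    partners <- partners[elem[partners] != "H"]
    if (length(partners) == 0)
      stop("hydrogen atom (serial ", a$serial[i],
           ") has no bonded heavy atom")
    # nearest bonded heavy atom decides the class
    d <- sqrt((a$x[partners] - a$x[i])^2 + (a$y[partners] - a$y[i])^2 +
              (a$z[partners] - a$z[i])^2)
    cls[i] <- if (elem[partners[which.min(d)]] == "C") "nonpolar" else
      "polar"
  }
  cls
}

#' Shrake--Rupley solvent-accessible surface area
#'
#' Per-atom accessible area by golden-spiral sphere-point sampling against
#' neighbour occlusion: each atom's sphere of radius `r_vdw + probe` is
#' sampled with `n_points` points and the fraction not buried inside any
#' neighbour sphere gives the accessible area.  Totals are split by the
#' nonpolar/polar atom classes of [classify_polarity()].
#'
#' @param structure a `structure3d`.
#' @param radii named vdW radius table (angstrom) indexed by element.
#' @param probe probe radius, angstrom.
#' @param n_points sample points per atom (>= 32).
#' @param polarity optional precomputed polarity classes.
#' @return An object of class `sasa_breakdown`: `total`, `polar`,
#'   `nonpolar` (angstrom^2), `per_atom`, `polarity`.
#' @export
shrake_rupley_sasa <- function(structure, radii = .vdw_radii, probe = 1.4,
                               n_points = 960, polarity = NULL) {
  stopifnot(n_points >= 32, probe >= 0)
  a <- structure$atoms
  n <- nrow(a)
  r <- lookup_elem(radii, a$elem, "vdW radius") + probe
  xyz <- as.matrix(a[c("x", "y", "z")])
  pts <- golden_spiral(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
             (sp[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 > r[j]^2
      if (!any(accessible)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(accessible)
  }
  if (is.null(polarity)) polarity <- classify_polarity(structure)
  nonpolar <- sum(per_atom[polarity == "nonpolar"])
  polar <- sum(per_atom[polarity == "polar"])
  structure(list(total = nonpolar + polar, polar = polar,
                 nonpolar = nonpolar, per_atom = per_atom,
                 polarity = polarity),
            class = "sasa_breakdown")
}

#' @export
print.sasa_breakdown <- function(x, ...) {
  cat(sprintf("SASA: total %.2f A^2 (nonpolar %.2f, polar %.2f)\n",
              x$total, x$nonpolar, x$polar))
  invisible(x)
}

#' Hydrophobic contribution to binding from buried surface area
#'
#' Heat-capacity model:
#' `dCp [cal/mol/K] = 0.382 * dSASA_np - 0.121 * dSASA_p` (areas in
#' angstrom^2), and `dG_hpb [cal/mol] = 80 * dCp`; also reported in
#' kJ/mol (x 4.184e-3).
#'
#' @param dSASA_np,dSASA_p changes in nonpolar and polar SASA upon
#'   binding, angstrom^2 (bound minus unbound; burial is negative).
#' @return An object of class `hydrophobic_result`: `dSASA_np`,
#'   `dSASA_p`, `dCp` (cal/mol/K), `dG_cal` (cal/mol), `dG_kJ` (kJ/mol).
#' @export
hydrophobic_free_energy <- function(dSASA_np, dSASA_p) {
  stopifnot(is.finite(dSASA_np), is.finite(dSASA_p))
  dCp <- 0.382 * dSASA_np - 0.121 * dSASA_p
  dG_cal <- 80 * dCp
  structure(list(dSASA_np = dSASA_np, dSASA_p = dSASA_p, dCp = dCp,
                 dG_cal = dG_cal, dG_kJ = dG_cal * 4.184e-3),
            class = "hydrophobic_result")
}

#' @export
print.hydrophobic_result <- function(x, ...) {
  cat(sprintf("dCp = %.2f cal/mol/K; dG_hpb = %.1f cal/mol = %.2f kJ/mol\n",
              x$dCp, x$dG_cal, x$dG_kJ))
  invisible(x)
}

#' Count entities within a cutoff of a reference centre of mass
#'
#' @param structure a `structure3d`.
#' @param reference_group serial vector or group name; its mass-weighted
#'   centre of mass is the reference point.
#' @param target_atoms serial vector of representative atoms (for waters,
#'   the oxygens).
#' @param cutoff distance cutoff, angstrom.
#' @return Integer count of targets within `cutoff` (inclusive).
#' @export
count_within_cutoff <- function(structure, reference_group, target_atoms,
                                cutoff = 5.0) {
  stopifnot(cutoff > 0)
  com <- center_of_mass(structure, reference_group)
  if (length(target_atoms) == 0) return(0L)
  t <- structure$atoms[group_rows(structure, target_atoms), ]
  d <- sqrt((t$x - com[1])^2 + (t$y - com[2])^2 + (t$z - com[3])^2)
  sum(d <= cutoff)
}

#' Count hydrogen bonds between donor and acceptor sets
#'
#' Counts (donor, hydrogen, acceptor) triples with donor--acceptor
#' distance at most `dist_cutoff` and H--D--A angle at most
#' `angle_cutoff`.  Donor hydrogens are located through the bond list.
#' The 3.5 angstrom / 30 degree default is the common MD-analysis
#' convention.
#'
#' @param structure a `structure3d`.
#' @param donors serial vector of donor heavy atoms (must carry bonded H).
#' @param acceptors serial vector of acceptor atoms.
#' @param dist_cutoff donor--acceptor distance cutoff, angstrom.
#' @param angle_cutoff H--D--A angle cutoff, degrees.
#' @param bonds optional bond matrix (row pairs); inferred when absent.
#' @return Integer hydrogen-bond count.
#' @export
hydrogen_bonds <- function(structure, donors, acceptors, dist_cutoff = 3.5,
                           angle_cutoff = 30, bonds = NULL) {
  a <- structure$atoms
  if (is.null(bonds)) bonds <- infer_bonds(structure)
  elem <- toupper(trimws(a$elem))
  don_rows <- group_rows(structure, donors)
  acc_rows <- group_rows(structure, acceptors)
  count <- 0L
  for (d in don_rows) {
    partners <- c(bonds[bonds[, 1] == d, 2], bonds[bonds[, 2] == d, 1])
    hs <- partners[elem[partners] == "H"]
    if (length(hs) == 0)
      stop("donor atom (serial ", a$serial[d], ") carries no bonded hydrogen")
    for (acc in acc_rows) {
      if (acc == d) next
      v_da <- c(a$x[acc] - a$x[d], a$y[acc] - a$y[d], a$z[acc] - a$z[d])
      dist_da <- sqrt(sum(v_da^2))
      if (dist_da > dist_cutoff) next
      for (h in hs) {
        v_dh <- c(a$x[h] - a$x[d], a$y[h] - a$y[d], a$z[h] - a$z[d])
        cosang <- sum(v_da * v_dh) / (dist_da * sqrt(sum(v_dh^2)))
        ang <- acos(min(1, max(-1, cosang))) * 180 / pi
        if (ang <= angle_cutoff) {
          count <- count + 1L
          break  # one bond per donor-acceptor pair
        }
      }
    }
  }
  count
}
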