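#' Atom-group specification for the collective variables
#'
#' Names the four selections the CVs are built from: the intercalation-site
#' base-pair atoms (IS), the minor-groove-side deoxyribose atoms (MG), the
#' ligand atoms, and the two ligand atoms defining the long axis of the
#' intercalating ring system (tail C14 -> head C6).
#'
#' @param is_group,mg_group,ligand_group integer serial vectors.
#' @param axis_pair length-2 integer vector: c(tail serial, head serial).
#' @return An object of class `atom_group_spec`.
#' @export
atom_group_spec <- function(is_group, mg_group, ligand_group, axis_pair) {
  stopifnot(length(is_group) > 0, length(mg_group) > 0,
            length(ligand_group) > 0, length(axis_pair) == 2)
  if (axis_pair[1] == axis_pair[2]) stop("axis atoms must be distinct")
  if (length(intersect(is_group, mg_group)) > 0)
    stop("IS and MG groups must be disjoint")
  structure(list(is_group = as.integer(is_group),
                 mg_group = as.integer(mg_group),
                 ligand_group = as.integer(ligand_group),
                 axis_pair = as.integer(axis_pair)),
            class = "atom_group_spec")
}

#' Default spec built from a structure's named groups
#'
#' @param structure a `structure3d` with groups `IS`, `MG`, `ligand`,
#'   `axis` (as produced by [synth_structure()] or a selection sidecar).
#' @return An `atom_group_spec`.
#' @export
spec_from_groups <- function(structure) {
  g <- structure$groups
  for (nm in c("IS", "MG", "ligand", "axis"))
    if (is.null(g[[nm]])) stop("structure has no group named '", nm, "'")
  atom_group_spec(g$IS, g$MG, g$ligand, g$axis)
}

#' Mass-weighted centre of mass of an atom group
#'
#' @param structure a `structure3d`.
#' @param group integer serial vector or a group name.
#' @return Length-3 numeric vector (angstrom).
#' @export
center_of_mass <- function(structure, group) {
  rows <- group_rows(structure, group)
  a <- structure$atoms[rows, ]
  m <- a$mass
  c(sum(m * a$x), sum(m * a$y), sum(m * a$z)) / sum(m)
}

#' Compute the two collective variables from coordinates
#'
#' The groove-directed unit vector is `m_hat = unit(MG - IS)` (MG the end
#' point), the ligand axis `n_hat = unit(C6 - C14)` (C6 the end point),
#' and `d = L - IS` with L the ligand centre of mass.  Then
#' `X = m_hat . d` (signed projection, angstrom) and
#' `theta = acos(m_hat . n_hat)` in degrees, with the dot product clamped
#' to \[-1, 1\] before the arccosine.
#'
#' @param structure a `structure3d`.
#' @param spec an `atom_group_spec`; defaults to the structure's named
#'   groups via [spec_from_groups()].
#' @return Named numeric vector c(X = ..., theta = ...).
#' @export
compute_cvs <- function(structure, spec = spec_from_groups(structure)) {
  is_com <- center_of_mass(structure, spec$is_group)
  mg_com <- center_of_mass(structure, spec$mg_group)
  l_com  <- center_of_mass(structure, spec$ligand_group)
  m_vec <- mg_com - is_com
  m_len <- sqrt(sum(m_vec^2))
  if (m_len < 1e-12)
    stop("degenerate groove vector: MG and IS centres of mass coincide")
  m_hat <- m_vec / m_len
  ax <- structure$atoms[group_rows(structure, spec$axis_pair), ]
  n_vec <- c(ax$x[2] - ax$x[1], ax$y[2] - ax$y[1], ax$z[2] - ax$z[1])
  n_len <- sqrt(sum(n_vec^2))
  if (n_len < 1e-12)
    stop("degenerate ligand axis: the two axis atoms coincide")
  n_hat <- n_vec / n_len
  d <- l_com - is_com
  cosang <- min(1, max(-1, sum(m_hat * n_hat)))
  c(X = sum(m_hat * d), theta = acos(cosang) * 180 / pi)
}
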