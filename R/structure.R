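#' @importFrom utils head tail
NULL

# standard atomic masses (u) and covalent radii (angstrom) by element symbol
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.973762, S = 32.06, NA. = 22.98977, CL = 35.45,
                    MG = 24.305, K = 39.0983, F = 18.998403, FE = 55.845)
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07,
                     S = 1.05, NA. = 1.66, CL = 1.02, MG = 1.41, K = 2.03,
                     F = 0.57, FE = 1.32)

lookup_elem <- function(table, elem, what) {
  key <- toupper(trimws(elem))
  key[key == "NA"] <- "NA."
  val <- table[key]
  if (any(is.na(val)))
    stop("unknown element(s): ",
         paste(unique(elem[is.na(val)]), collapse = ", "))
  unname(val)
}

#' Molecular structure container
#'
#' A light container for coordinates: a data frame of atoms (serial, name,
#' elem, x, y, z, mass, in angstrom) plus a named list of atom groups
#' given as serial-number vectors.  Masses default to standard atomic
#' masses by element; `unit_mass = TRUE` gives every atom mass 1 for
#' geometry-only fixtures.
#'
#' @param atoms data frame with columns serial, name, elem, x, y, z.
#' @param groups named list of integer serial vectors.
#' @param unit_mass logical; use unit masses instead of atomic masses.
#' @param box optional box edge length (angstrom); if given, a warning is
#'   issued when any coordinate extent exceeds half the edge (likely a
#'   periodic-boundary-wrapped input, which this package does not unwrap).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, groups = list(), unit_mass = FALSE,
                        box = NULL) {
  needed <- c("serial", "name", "elem", "x", "y", "z")
  if (!all(needed %in% names(atoms)))
    stop("atoms must have columns: ", paste(needed, collapse = ", "))
  atoms <- as.data.frame(atoms)[union(needed, names(atoms))]
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials")
  atoms$mass <- if (unit_mass) rep(1, nrow(atoms)) else
    lookup_elem(.atomic_masses, atoms$elem, "mass")
  for (g in names(groups)) {
    bad <- setdiff(groups[[g]], atoms$serial)
    if (length(bad) > 0)
      stop("group '", g, "' refers to unknown serial(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(box)) {
    ext <- c(diff(range(atoms$x)), diff(range(atoms$y)), diff(range(atoms$z)))
    if (any(ext > box / 2))
      warning("coordinate extent exceeds half the box edge (", box / 2,
              " A); input may be periodic-image wrapped")
  }
  structure(list(atoms = atoms, groups = groups), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms")
  if (length(x$groups))
    cat(";", length(x$groups), "group(s):",
        paste(names(x$groups), collapse = ", "))
  cat("\n")
  invisible(x)
}

group_rows <- function(structure, group) {
  if (is.character(group) && length(group) == 1) {
    if (!group %in% names(structure$groups))
      stop("no group named '", group, "'")
    group <- structure$groups[[group]]
  }
  if (length(group) == 0) stop("empty atom group")
  rows <- match(group, structure$atoms$serial)
  if (any(is.na(rows)))
    stop("serial(s) not in structure: ",
         paste(group[is.na(rows)], collapse = ", "))
  rows
}

#' Read a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()].  Coordinates in angstrom.
#'
#' @param path PDB file path.
#' @param selection_path optional sidecar selection file (see
#'   [read_selection()]); its groups are attached to the structure.
#' @param unit_mass see [structure3d()].
#' @return A `structure3d`.
#' @export
read_structure_pdb <- function(path, selection_path = NULL,
                               unit_mass = FALSE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- trimws(a$elesy)
  no_elem <- is.na(elem) | elem == ""
  if (any(no_elem)) elem[no_elem] <- substr(gsub("[0-9]", "", a$elety[no_elem]),
                                            1, 1)
  atoms <- data.frame(serial = a$eleno, name = trimws(a$elety), elem = elem,
                      x = a$x, y = a$y, z = a$z)
  groups <- if (is.null(selection_path)) list() else
    read_selection(selection_path)
  structure3d(atoms, groups, unit_mass = unit_mass)
}

#' Read a GRO file
#'
#' Minimal GROMACS GRO reader; coordinates are converted from nm to
#' angstrom on read.
#'
#' @inheritParams read_structure_pdb
#' @return A `structure3d`.
#' @export
read_structure_gro <- function(path, selection_path = NULL,
                               unit_mass = FALSE) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  name <- trimws(substr(rec, 11, 15))
  xyz <- matrix(as.numeric(c(substr(rec, 21, 28), substr(rec, 29, 36),
                             substr(rec, 37, 44))), ncol = 3) * 10
  elem <- substr(gsub("[0-9]", "", name), 1, 1)
  atoms <- data.frame(serial = seq_len(n), name = name, elem = elem,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  groups <- if (is.null(selection_path)) list() else
    read_selection(selection_path)
  structure3d(atoms, groups, unit_mass = unit_mass)
}

#' Write a minimal PDB file
#'
#' @param structure a `structure3d`.
#' @param path output path.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s LIG A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, substr(a$name, 1, 4), 1L, a$x, a$y, a$z, 1.0, 0.0,
    toupper(a$elem))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read / write a selection sidecar file
#'
#' Plain-text mapping of group names to 1-based atom serials (matching PDB
#' serial numbers), one group per line: `name: s1 s2 s3 ...`.
#'
#' @param path file path.
#' @return Named list of integer vectors.
#' @export
read_selection <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed selection line: ", ln)
    out[[trimws(parts[1])]] <-
      as.integer(strsplit(trimws(parts[2]), "\\s+")[[1]])
  }
  out
}

#' @rdname read_selection
#' @param groups named list of integer vectors.
#' @export
write_selection <- function(groups, path) {
  writeLines(vapply(names(groups), function(g)
    paste0(g, ": ", paste(groups[[g]], collapse = " ")), ""), path)
  invisible(path)
}

#' Synthetic coordinate fixture realising prescribed collective variables
#'
#' Builds a small labelled structure whose CVs evaluate exactly to the
#' requested values: an intercalation-site (IS) base-pair group with centre
#' of mass at the origin, a minor-groove (MG) deoxyribose group 6 angstrom
#' along +z (so the groove vector is the z axis), and a ligand whose centre
#' of mass sits at `X_target` along z with its C14->C6 axis tilted by
#' `theta_target` from z.  All groups are built from element-matched
#' symmetric atom pairs so centres of mass are exact for any mass table.
#'
#' @param X_target target X, angstrom (>= 0).
#' @param theta_target target theta, degrees in \[0, 180\].
#' @param unit_mass see [structure3d()].
#' @return A `structure3d` with groups `IS`, `MG`, `ligand`, `axis`
#'   (axis = c(C14 serial, C6 serial)).
#' @export
synth_structure <- function(X_target, theta_target, unit_mass = FALSE) {
  stopifnot(X_target >= 0, theta_target >= 0, theta_target <= 180)
  th <- theta_target * pi / 180
  pair <- function(elem, base, center, offset) {
    rbind(data.frame(name = paste0(elem, base), elem = elem,
                     x = center[1] + offset[1], y = center[2] + offset[2],
                     z = center[3] + offset[3]),
          data.frame(name = paste0(elem, base + 1), elem = elem,
                     x = center[1] - offset[1], y = center[2] - offset[2],
                     z = center[3] - offset[3]))
  }
  is_ctr <- c(0, 0, 0)
  mg_ctr <- c(0, 0, 6)
  lig_ctr <- c(0, 0, X_target)
  is_at <- rbind(pair("C", 1, is_ctr, c(1.4, 0, 0)),
                 pair("N", 1, is_ctr, c(0, 1.4, 0)),
                 pair("O", 1, is_ctr, c(1.0, 1.0, 0.6)))
  mg_at <- rbind(pair("C", 3, mg_ctr, c(1.2, 0, 0.5)),
                 pair("O", 3, mg_ctr, c(0, 1.2, 0)))
  n_hat <- c(sin(th), 0, cos(th))
  half <- 4.5
  lig_at <- rbind(
    data.frame(name = "C14", elem = "C",
               x = lig_ctr[1] - half * n_hat[1],
               y = lig_ctr[2] - half * n_hat[2],
               z = lig_ctr[3] - half * n_hat[3]),
    data.frame(name = "C6", elem = "C",
               x = lig_ctr[1] + half * n_hat[1],
               y = lig_ctr[2] + half * n_hat[2],
               z = lig_ctr[3] + half * n_hat[3]),
    pair("C", 20, lig_ctr, c(0, 1.3, 0)),
    pair("O", 20, lig_ctr, c(0.9, 0.7, 0.3)))
  atoms <- rbind(is_at, mg_at, lig_at)
  atoms$serial <- seq_len(nrow(atoms))
  n_is <- nrow(is_at); n_mg <- nrow(mg_at)
  groups <- list(
    IS = seq_len(n_is),
    MG = n_is + seq_len(n_mg),
    ligand = n_is + n_mg + seq_len(nrow(lig_at)),
    axis = n_is + n_mg + c(1L, 2L))
  structure3d(atoms[c("serial", "name", "elem", "x", "y", "z")], groups,
              unit_mass = unit_mass)
}
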