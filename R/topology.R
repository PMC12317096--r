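.element_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, S = 32.06, Cl = 35.45)

#' Molecular topology of a confined-water system
#'
#' A `wire_topology` records, per atom, the element label, the molecule it
#' belongs to and its mass, together with the list of intramolecular O-H
#' bonds, the indices of water oxygens and of any explicit wall atoms.
#' Topologies are normally inferred from the first frame of a trajectory by
#' [read_xyz_trajectory()] (every H is assigned to its nearest O within
#' 1.2 A) and kept fixed for the whole run, so transient proton excursions
#' never relabel an OH mode.
#'
#' @param atom_labels character vector of element symbols.
#' @param molecule_index integer vector, one molecule id per atom.
#' @param oh_bonds two-column integer matrix of (O index, H index) pairs.
#' @param masses atomic masses in amu; defaults to standard element masses.
#' @param wall_atoms indices of confining atoms (may be empty).
#' @return an object of class `wire_topology`.
#' @export
wire_topology <- function(atom_labels, molecule_index, oh_bonds,
                          masses = NULL, wall_atoms = integer()) {
  n <- length(atom_labels)
  if (length(molecule_index) != n)
    .stopf("molecule_index length (%d) != atom count (%d)", length(molecule_index), n)
  if (is.null(masses)) {
    masses <- unname(.element_masses[atom_labels])
    if (anyNA(masses)) .stopf("unknown element(s): %s",
                              paste(unique(atom_labels[is.na(masses)]), collapse = ", "))
  }
  if (any(masses <= 0)) .stopf("masses must be positive")
  oh_bonds <- matrix(as.integer(oh_bonds), ncol = 2,
                     dimnames = list(NULL, c("O", "H")))
  if (nrow(oh_bonds)) {
    same_mol <- molecule_index[oh_bonds[, 1]] == molecule_index[oh_bonds[, 2]]
    if (!all(same_mol)) .stopf("oh_bonds crossing molecules: rows %s",
                               paste(which(!same_mol), collapse = ", "))
  }
  water_oxygens <- sort(unique(oh_bonds[, 1]))
  per_o <- table(factor(oh_bonds[, 1], levels = water_oxygens))
  if (length(per_o) && any(per_o != 2L))
    .stopf("each water oxygen must carry exactly 2 OH bonds (oxygen %s has %d)",
           names(per_o)[per_o != 2][1], per_o[per_o != 2][1])
  structure(list(atom_labels = atom_labels,
                 molecule_index = as.integer(molecule_index),
                 oh_bonds = oh_bonds,
                 masses = as.numeric(masses),
                 water_oxygens = as.integer(water_oxygens),
                 wall_atoms = as.integer(wall_atoms)),
            class = "wire_topology")
}

#' @export
print.wire_topology <- function(x, ...) {
  cat(sprintf("wire_topology: %d atoms, %d molecules, %d OH bonds, %d wall atoms\n",
              length(x$atom_labels), length(unique(x$molecule_index)),
              nrow(x$oh_bonds), length(x$wall_atoms)))
  invisible(x)
}

n_atoms <- function(top) length(top$atom_labels)

# Infer water topology from one frame: every H joins its nearest O within
# `max_oh`; each O with its bonded H forms one molecule; remaining atoms are
# wall atoms (one molecule each).
.infer_topology <- function(labels, pos, box, periodic_axes, max_oh = 1.2) {
  n <- length(labels)
  is_H <- labels == "H"
  is_O <- labels == "O"
  o_idx <- which(is_O)
  mol <- integer(n)
  bonds <- NULL
  if (any(is_H)) {
    if (!any(is_O)) .stopf("H atoms present but no O atoms")
    for (h in which(is_H)) {
      d <- .pair_dist(pos[rep(h, length(o_idx)), , drop = FALSE],
                      pos[o_idx, , drop = FALSE], box, periodic_axes)
      j <- which.min(d)
      if (d[j] > max_oh)
        .stopf("H atom %d has no O within %.2f A (nearest %.2f A)", h, max_oh, d[j])
      bonds <- rbind(bonds, c(o_idx[j], h))
    }
  }
  next_mol <- 0L
  for (o in o_idx) {
    next_mol <- next_mol + 1L
    mol[o] <- next_mol
    if (!is.null(bonds)) mol[bonds[bonds[, 1] == o, 2]] <- next_mol
  }
  for (a in which(mol == 0L)) {
    next_mol <- next_mol + 1L
    mol[a] <- next_mol
  }
  wall <- which(!is_O & !is_H)
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2)
  wire_topology(labels, mol, bonds, wall_atoms = wall)
}

# minimum-image distance between matched rows of two coordinate matrices
.pair_dist <- function(a, b, box, periodic_axes) {
  d <- a - b
  for (ax in .axis_index(periodic_axes)) {
    L <- box[ax]
    d[, ax] <- d[, ax] - L * round(d[, ax] / L)
  }
  sqrt(rowSums(d * d))
}

.axis_index <- function(axes) {
  if (is.numeric(axes)) return(as.integer(axes))
  m <- match(axes, c("x", "y", "z"))
  if (anyNA(m)) .stopf("unknown axis: %s", paste(axes[is.na(m)], collapse = ", "))
  m
}
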