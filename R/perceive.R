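#' Bond perception parameters
#'
#' Distance-based bond perception declares atoms `i` and `j` bonded when
#' `dist(i, j) <= factor * (r_i + r_j)` with covalent radii `r`. The
#' default factor of 1.3 is the value used for chemically diverse organic
#' sets; the radius table defaults to the shipped consensus values.
#'
#' @param covalent_radius_factor Positive dimensionless scale.
#' @param radius_table Named numeric vector, element symbol to covalent
#'   radius in Angstrom. Defaults to the shipped table.
#' @return An object of class `"bond_perception_params"`.
#' @export
bond_perception_params <- function(covalent_radius_factor = 1.3,
                                   radius_table = NULL) {
  if (!is.numeric(covalent_radius_factor) || covalent_radius_factor <= 0) {
    stop("covalent_radius_factor must be > 0")
  }
  if (is.null(radius_table)) {
    radius_table <- stats::setNames(.element_table$radius,
                                    .element_table$symbol)
  }
  if (any(radius_table <= 0)) stop("all radii must be > 0")
  structure(list(covalent_radius_factor = covalent_radius_factor,
                 radius_table = radius_table),
            class = "bond_perception_params")
}

#' Perceive bonds from 3D coordinates
#'
#' Applies the covalent-radius distance rule to a molecule (or every
#' molecule of a set). All perceived bonds get order 1; bond-order and
#' aromaticity assignment is a separate step
#' ([assign_bond_orders_and_aromaticity()]).
#'
#' @param mol A `molecule` (with coordinates) or a `molecule_set`.
#' @param params A [bond_perception_params()] object.
#' @return The input with `bonds` filled in.
#' @export
#' @examples
#' h2 <- molecule(c("H", "H"), coords = rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' perceive_bonds(h2)$bonds
perceive_bonds <- function(mol, params = bond_perception_params()) {
  if (inherits(mol, "molecule_set")) {
    out <- lapply(mol, perceive_bonds, params = params)
    return(structure(out, class = "molecule_set",
                     removed = attr(mol, "removed")))
  }
  if (is.null(mol$coords)) stop("molecule ", mol$id, " has no coordinates")
  r <- params$radius_table[mol$elements]
  if (anyNA(r)) {
    bad <- unique(mol$elements[is.na(r)])
    stop("no covalent radius for element(s): ", paste(bad, collapse = ", "))
  }
  n <- length(mol$elements)
  if (n < 2L) {
    mol$bonds <- matrix(integer(0), ncol = 4,
                        dimnames = list(NULL,
                                        c("i", "j", "order", "aromatic")))
    return(mol)
  }
  d <- as.matrix(stats::dist(mol$coords))
  thresh <- params$covalent_radius_factor * outer(r, r, "+")
  hit <- which(d <= thresh & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- cbind(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                     order = rep(1L, nrow(hit)),
                     aromatic = rep(0L, nrow(hit)))
  mol
}

#' Assign bond orders, aromaticity and canonical SMILES
#'
#' Delegates chemical perception to Open Babel: each molecule's 3D
#' coordinates are interpreted once, bond orders (1/2/3) and aromatic
#' flags are read back, and a canonical SMILES string is attached.
#' Molecules whose perception is chemically inconsistent (an atom
#' exceeding its standard valence, a hydrogen with more than one bond, or
#' physically overlapping bonded atoms closer than 0.6 of the
#' covalent-radius sum) are flagged invalid rather than raising an error;
#' downstream analysis excludes them.
#'
#' @param mols A `molecule_set` whose molecules have coordinates, or a
#'   single `molecule`.
#' @return The input with orders, aromatic flags, `smiles` and `valid`
#'   updated.
#' @export
assign_bond_orders_and_aromaticity <- function(mols) {
  single <- inherits(mols, "molecule")
  if (single) mols <- molecule_set(list(mols))
  if (!length(mols)) return(mols)
  has_xyz <- vapply(mols, function(m) !is.null(m$coords), logical(1))
  if (!all(has_xyz)) stop("all molecules need coordinates for perception")
  xyz <- paste0(vapply(mols, .xyz_record, character(1)), collapse = "")
  mol2 <- paste0(.ob_convert_text(xyz, "xyz", "mol2"), collapse = "\n")
  parsed <- .parse_mol2_bonds(mol2)
  ids <- vapply(mols, function(m) m$id, character(1))
  pos <- if (!anyDuplicated(ids) && !is.null(names(parsed)))
    match(ids, names(parsed)) else seq_along(mols)
  out <- lapply(seq_along(mols), function(k) {
    m <- mols[[k]]
    b <- if (!is.na(pos[k]) && pos[k] <= length(parsed))
      parsed[[pos[k]]] else NULL
    if (is.null(b)) { m$valid <- FALSE; return(m) }
    n <- length(m$elements)
    if (nrow(b) && (max(b[, 1:2]) > n)) { m$valid <- FALSE; return(m) }
    m$bonds <- .as_bond_matrix(b, n)
    m$valid <- .chemically_consistent(m)
    m
  })
  out <- structure(out, class = "molecule_set", removed = attr(mols, "removed"))
  smi <- canonical_smiles(out)
  for (k in seq_along(out)) {
    out[[k]]$smiles <- smi[k]
    if (is.na(smi[k]) || !nzchar(smi[k])) out[[k]]$valid <- FALSE
  }
  if (single) out[[1]] else out
}

.parse_mol2_bonds <- function(mol2_text) {
  if (!nzchar(mol2_text)) return(list())
  recs <- strsplit(mol2_text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  recs <- recs[-1]
  nms <- vapply(recs, function(rec) {
    trimws(strsplit(rec, "\n", fixed = TRUE)[[1]][2])
  }, character(1), USE.NAMES = FALSE)
  out <- lapply(recs, function(rec) {
    bm <- regmatches(rec, regexpr("@<TRIPOS>BOND\n[^@]*", rec))
    if (!length(bm)) {
      return(matrix(integer(0), ncol = 4,
                    dimnames = list(NULL, c("i", "j", "order", "aromatic"))))
    }
    lines <- strsplit(sub("@<TRIPOS>BOND\n", "", bm), "\n")[[1]]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      return(matrix(integer(0), ncol = 4,
                    dimnames = list(NULL, c("i", "j", "order", "aromatic"))))
    }
    f <- strsplit(lines, "\\s+")
    i <- vapply(f, function(x) as.integer(x[2]), integer(1))
    j <- vapply(f, function(x) as.integer(x[3]), integer(1))
    ty <- vapply(f, function(x) x[4], character(1))
    arom <- as.integer(ty == "ar")
    ord <- suppressWarnings(as.integer(ty))
    ord[is.na(ord)] <- 1L        # ar / am / un fall back to single
    ord <- pmin(pmax(ord, 1L), 3L)
    cbind(i = i, j = j, order = ord, aromatic = arom)
  })
  names(out) <- nms
  out
}

.chemically_consistent <- function(m) {
  b <- m$bonds
  if (is.null(b)) return(FALSE)
  if (!nrow(b)) return(length(m$elements) == 1L)
  maxv <- standard_valences(m$elements)
  # bond-order units consumed at each atom; aromatic bonds count 1.5
  ord <- ifelse(b[, "aromatic"] == 1L, 1.5, b[, "order"])
  used <- numeric(length(m$elements))
  for (col in c("i", "j")) {
    t <- tapply(ord, b[, col], sum)
    used[as.integer(names(t))] <- used[as.integer(names(t))] + t
  }
  if (any(used > maxv + 0.51)) return(FALSE)
  if (!is.null(m$coords)) {
    r <- covalent_radii(m$elements)
    d <- sqrt(rowSums((m$coords[b[, "i"], , drop = FALSE] -
                       m$coords[b[, "j"], , drop = FALSE])^2))
    if (any(d < 0.6 * (r[b[, "i"]] + r[b[, "j"]]))) return(FALSE)
  }
  TRUE
}

.n_components <- function(m) {
  n <- length(m$elements)
  if (n == 0L) return(0L)
  b <- m$bonds
  comp <- seq_len(n)
  # union-find with path halving
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  if (!is.null(b) && nrow(b)) {
    for (k in seq_len(nrow(b))) {
      a <- find(b[k, 1]); c <- find(b[k, 2])
      if (a != c) comp[a] <- c
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Add aromatic flags to molecules with kekule bond tables
#'
#' Standard SDF and SMILES inputs carry kekule bond orders only; this
#' pass runs Open Babel's aromaticity perception over the connection
#' tables and sets the `aromatic` flag on the affected bonds without
#' touching the stored orders.
#'
#' @param mols A `molecule_set` with bond tables.
#' @return The set with aromatic flags updated.
#' @export
perceive_aromaticity <- function(mols) {
  if (!length(mols)) return(mols)
  txt <- molecules_to_sdf_text(mols)
  mol2 <- paste0(.ob_convert_text(txt, "sdf", "mol2"), collapse = "\n")
  parsed <- .parse_mol2_bonds(mol2)
  ids <- vapply(mols, function(m) m$id, character(1))
  pos <- if (!anyDuplicated(ids) && !is.null(names(parsed)))
    match(ids, names(parsed)) else seq_along(mols)
  for (k in seq_along(mols)) {
    if (is.na(pos[k]) || pos[k] > length(parsed)) next
    b2 <- parsed[[pos[k]]]
    b <- mols[[k]]$bonds
    if (is.null(b) || !nrow(b) || !nrow(b2)) next
    n <- length(mols[[k]]$elements)
    k1 <- b[, "i"] * (n + 1L) + b[, "j"]
    k2 <- pmin(b2[, "i"], b2[, "j"]) * (n + 1L) + pmax(b2[, "i"], b2[, "j"])
    arom <- k1 %in% k2[b2[, "aromatic"] == 1L]
    mols[[k]]$bonds[, "aromatic"] <- as.integer(arom)
  }
  mols
}

#' Filter a molecule set for validity, connectivity and uniqueness
#'
#' Removes, in order: (a) molecules flagged invalid by perception (these
#' cannot be deduplicated because they have no reliable canonical SMILES),
#' (b) molecules whose bond graph has more than one connected component,
#' and (c) duplicates by canonical-SMILES equality, keeping the first
#' occurrence. Survivors keep their input order. Removal counts are
#' attached as the `"removed"` attribute and shown by `print()`.
#'
#' @param mols A `molecule_set` with perceived bonds. Canonical SMILES are
#'   computed for molecules that lack them.
#' @return The filtered `molecule_set` (possibly empty), with attributes
#'   `removed` (named counts: invalid, disconnected, duplicate) and
#'   `removed_ids`.
#' @export
filter_set <- function(mols) {
  if (!length(mols)) {
    return(structure(mols, removed = c(invalid = 0L, disconnected = 0L,
                                       duplicate = 0L)))
  }
  no_bonds <- vapply(mols, function(m) is.null(m$bonds), logical(1))
  if (any(no_bonds)) stop("bonds must be perceived before filtering")
  need_smi <- vapply(mols, function(m) is.na(m$smiles), logical(1)) &
    vapply(mols, function(m) m$valid, logical(1))
  if (any(need_smi)) {
    smi <- canonical_smiles(mols[which(need_smi)])
    idx <- which(need_smi)
    for (k in seq_along(idx)) {
      mols[[idx[k]]]$smiles <- smi[k]
      if (is.na(smi[k])) mols[[idx[k]]]$valid <- FALSE
    }
  }
  valid <- vapply(mols, function(m) isTRUE(m$valid) && !is.na(m$smiles),
                  logical(1))
  connected <- rep(FALSE, length(mols))
  connected[valid] <- vapply(which(valid),
                             function(k) .n_components(mols[[k]]) == 1L,
                             logical(1))
  smi <- vapply(mols, function(m) m$smiles, character(1))
  keep <- valid & connected
  dup <- keep & duplicated(ifelse(keep, smi, NA_character_),
                           incomparables = NA)
  keep <- keep & !dup
  removed <- c(invalid = sum(!valid),
               disconnected = sum(valid & !connected),
               duplicate = sum(dup))
  ids <- vapply(mols, function(m) m$id, character(1))
  structure(unclass(mols)[keep], class = "molecule_set",
            removed = removed, removed_ids = ids[!keep])
}
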