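#' Construct a molecule
#'
#' The basic container consumed by every audit stage: explicit atoms with
#' optional 3D coordinates, an optional bond table, an optional canonical
#' SMILES string and a dataset label (`"train"` or `"generated"`).
#'
#' Bonds are stored once per atom pair (`i < j`) in a 4-column integer
#' matrix `(i, j, order, aromatic)`; `order` is the kekule bond order
#' (1, 2 or 3) and `aromatic` a 0/1 flag.
#'
#' @param elements Character vector of element symbols (hydrogens explicit).
#' @param coords Numeric matrix `n x 3` of Cartesian coordinates in
#'   Angstrom, or `NULL` when only the connection table is known.
#' @param bonds Integer matrix with columns `i`, `j`, `order`, `aromatic`,
#'   or `NULL` when bonds have not been perceived yet.
#' @param id Molecule identifier string.
#' @param smiles Canonical SMILES string or `NA`.
#' @param label Dataset label, `"train"` or `"generated"`.
#' @param valid Logical validity flag; set to `FALSE` by perception when a
#'   molecule cannot be interpreted chemically.
#' @return An object of class `"molecule"`.
#' @export
#' @examples
#' h2 <- molecule(c("H", "H"), coords = rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' h2
molecule <- function(elements, coords = NULL, bonds = NULL, id = "mol",
                     smiles = NA_character_, label = "train", valid = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3)
    if (nrow(coords) != n) stop("coords must have one row per atom")
  }
  if (!is.null(bonds)) bonds <- .as_bond_matrix(bonds, n)
  if (!label %in% c("train", "generated")) {
    stop("label must be 'train' or 'generated'")
  }
  structure(
    list(id = as.character(id), elements = elements, coords = coords,
         bonds = bonds, smiles = smiles, label = label, valid = valid),
    class = "molecule"
  )
}

.as_bond_matrix <- function(bonds, n_atoms) {
  if (is.data.frame(bonds)) bonds <- as.matrix(bonds)
  bonds <- matrix(as.integer(bonds), ncol = 4)
  colnames(bonds) <- c("i", "j", "order", "aromatic")
  if (nrow(bonds)) {
    if (any(bonds[, "i"] == bonds[, "j"])) stop("self-bonds are not allowed")
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n_atoms)) {
      stop("bond indices out of range")
    }
    # store each pair once, i < j
    swap <- bonds[, "i"] > bonds[, "j"]
    if (any(swap)) {
      tmp <- bonds[swap, "i"]
      bonds[swap, "i"] <- bonds[swap, "j"]
      bonds[swap, "j"] <- tmp
    }
    key <- bonds[, "i"] * (n_atoms + 1L) + bonds[, "j"]
    if (anyDuplicated(key)) stop("duplicate bonds in bond table")
  }
  bonds
}

#' @export
print.molecule <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat(sprintf("<molecule %s> %s, %d atoms, %s bonds%s%s\n",
              x$id, formula, length(x$elements),
              if (is.null(x$bonds)) "?" else nrow(x$bonds),
              if (!is.na(x$smiles)) paste0(", SMILES ", x$smiles) else "",
              if (!x$valid) " [invalid]" else ""))
  invisible(x)
}

#' Bundle molecules into a set
#'
#' @param mols List of `molecule` objects.
#' @param label Optional label applied to every molecule.
#' @return An object of class `"molecule_set"` (a list of molecules).
#' @export
molecule_set <- function(mols, label = NULL) {
  stopifnot(all(vapply(mols, inherits, logical(1), "molecule")))
  if (!is.null(label)) {
    mols <- lapply(mols, function(m) { m$label <- label; m })
  }
  structure(mols, class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<molecule_set> %d molecules", n))
  if (n) {
    na <- vapply(x, function(m) length(m$elements), integer(1))
    lab <- table(vapply(x, function(m) m$label, character(1)))
    cat(sprintf(", %.1f atoms on average (%s)", mean(na),
                paste(names(lab), lab, sep = ":", collapse = ", ")))
  }
  rem <- attr(x, "removed")
  if (!is.null(rem)) {
    cat(sprintf("\n  filtered: %s removed",
                paste(names(rem), rem, sep = "=", collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.molecule_set` <- function(x, i) {
  structure(unclass(x)[i], class = "molecule_set")
}

#' Per-molecule atom counts, masses and labels
#'
#' Convenience accessors used throughout the audit.
#'
#' @param mols A `molecule_set` or list of molecules.
#' @return `atom_counts`: integer total atom counts (hydrogens included);
#'   `heavy_atom_counts`: non-hydrogen atom counts; `molecular_weights`:
#'   numeric masses in g/mol; `set_labels`: character labels.
#' @export
atom_counts <- function(mols) {
  vapply(mols, function(m) length(m$elements), integer(1))
}

#' @rdname atom_counts
#' @export
heavy_atom_counts <- function(mols) {
  vapply(mols, function(m) sum(m$elements != "H"), integer(1))
}

#' @rdname atom_counts
#' @export
molecular_weights <- function(mols) {
  vapply(mols, function(m) sum(atomic_masses(m$elements)), numeric(1))
}

#' @rdname atom_counts
#' @export
set_labels <- function(mols) {
  vapply(mols, function(m) m$label, character(1))
}

#' Canonical SMILES of a set
#'
#' @param mols A `molecule_set`.
#' @return Character vector (NA where unset).
#' @export
set_smiles <- function(mols) {
  vapply(mols, function(m) m$smiles, character(1))
}
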