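# Functional-group prevalence (SMARTS) and the three-way ring
# classification (aromatic / unsaturated aliphatic / saturated).

#' Load a functional-group catalog
#'
#' A catalog is a two-column TSV (`name`, `smarts`); lines starting with
#' `#` are comments. Every pattern is validated against Open Babel's
#' SMARTS engine at load time. With no argument the shipped default
#' catalog of ~40 common organic groups is loaded (including hydroxyl,
#' C-C triple bond, aromatic C-C bond, thiol and gold-thiolate).
#'
#' @param path Path to a TSV file, or `NULL` for the default catalog.
#' @return An object of class `"group_catalog"` (data.frame with columns
#'   `name`, `smarts`).
#' @export
group_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_catalog.tsv",
                        package = "molaudit")
    if (!nzchar(path)) path <- "inst/extdata/group_catalog.tsv"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  raw <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           header = TRUE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(raw))) {
    stop("catalog needs columns 'name' and 'smarts'")
  }
  if (anyDuplicated(raw$name)) stop("catalog names must be unique")
  probe <- ChemmineOB::forEachMol("SMILES", "CCO probe", identity)
  for (k in seq_len(nrow(raw))) {
    ok <- tryCatch({
      ChemmineOB::smartsSearch_OB(probe, raw$smarts[k],
                                  uniqueMatches = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("SMARTS pattern does not compile: ", raw$name[k],
                  " = ", raw$smarts[k])
  }
  structure(raw[, c("name", "smarts")], class = c("group_catalog",
                                                  "data.frame"))
}

#' Count substructure matches per molecule
#'
#' Unique-match counts for every catalog pattern over the set, via Open
#' Babel SMARTS matching (molecules are parsed once and reused across
#' patterns).
#'
#' @param mols A `molecule_set` with bond orders assigned.
#' @param catalog A [group_catalog()].
#' @return Integer matrix, molecules x groups.
#' @export
group_counts <- function(mols, catalog) {
  stopifnot(inherits(catalog, "group_catalog"))
  out <- matrix(0L, nrow = length(mols), ncol = nrow(catalog),
                dimnames = list(vapply(mols, function(m) m$id,
                                       character(1)),
                                catalog$name))
  if (!length(mols)) return(out)
  refs <- .ob_refs(mols)
  for (k in seq_len(nrow(catalog))) {
    out[, k] <- as.integer(ChemmineOB::smartsSearch_OB(
      refs, catalog$smarts[k], uniqueMatches = TRUE))
  }
  out
}

#' Functional-group prevalence
#'
#' Fraction of molecules containing at least one match of each catalog
#' pattern. Only perception-valid molecules enter the denominator.
#'
#' @param mols A `molecule_set` with bond orders assigned.
#' @param catalog A [group_catalog()]; default: the shipped catalog.
#' @return data.frame with columns `name`, `smarts`, `n_match`,
#'   `fraction`; attribute `"n_molecules"` holds the denominator.
#' @export
#' @examples
#' \dontrun{
#' prev <- group_prevalence(mols, group_catalog())
#' }
group_prevalence <- function(mols, catalog = group_catalog()) {
  valid <- vapply(mols, function(m) isTRUE(m$valid), logical(1))
  vm <- mols[valid]
  counts <- group_counts(vm, catalog)
  n_match <- colSums(counts > 0L)
  out <- data.frame(name = catalog$name, smarts = catalog$smarts,
                    n_match = as.integer(n_match),
                    fraction = if (length(vm)) n_match / length(vm)
                               else rep(NA_real_, nrow(catalog)),
                    row.names = NULL)
  attr(out, "n_molecules") <- length(vm)
  out
}

# smallest-set-of-smallest-rings per molecule, as lists of atom indices
.sssr <- function(mols) {
  txt <- molecules_to_sdf_text(mols)
  tf <- tempfile(fileext = ".sdf"); on.exit(unlink(tf))
  cat(txt, file = tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  rr <- ChemmineR::rings(sdfset, upper = Inf, type = "all",
                         arom = FALSE, inner = TRUE)
  # rings() returns one flat list for a single-molecule set
  if (length(mols) == 1L && (!length(rr) || !is.list(rr[[1]]))) {
    rr <- list(rr)
  }
  lapply(rr, function(rings_of_mol) {
    lapply(rings_of_mol, function(ring) {
      as.integer(sub("^.*_", "", ring))
    })
  })
}

.classify_ring <- function(ring_atoms, bonds) {
  n <- length(ring_atoms)
  pairs <- cbind(ring_atoms, ring_atoms[c(2:n, 1L)])
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bkey <- key(bonds[, "i"], bonds[, "j"])
  hit <- match(key(pairs[, 1], pairs[, 2]), bkey)
  hit <- hit[!is.na(hit)]
  arom <- bonds[hit, "aromatic"] == 1L
  mult <- bonds[hit, "order"] > 1L
  if (length(hit) == n && all(arom)) return("aromatic")
  if (!any(arom) && !any(mult)) return("saturated")
  "unsaturated_aliphatic"
}

#' Ring profiles of a molecule set
#'
#' Counts smallest-set-of-smallest-rings per molecule and classifies
#' each ring: aromatic (all ring bonds aromatic), saturated (no multiple
#' or aromatic bond) or unsaturated aliphatic (anything else). The three
#' class counts always sum to the total SSSR ring count.
#'
#' @param mols A `molecule_set` with bond orders and aromaticity
#'   assigned.
#' @return List with `per_molecule` (data.frame: id, aromatic,
#'   unsaturated_aliphatic, saturated, total), `shares` (fraction of
#'   molecules having k = 0, 1, 2, 3+ rings of each class) and
#'   `by_size` (ring-class x ring-size count matrix over the set).
#' @export
ring_profiles <- function(mols) {
  classes <- c("aromatic", "unsaturated_aliphatic", "saturated")
  per <- data.frame(id = vapply(mols, function(m) m$id, character(1)),
                    aromatic = 0L, unsaturated_aliphatic = 0L,
                    saturated = 0L, total = 0L)
  sizes <- matrix(0L, nrow = 3, ncol = 10,
                  dimnames = list(classes, as.character(3:12)))
  if (length(mols)) {
    rr <- .sssr(mols)
    for (k in seq_along(mols)) {
      b <- mols[[k]]$bonds
      for (ring in rr[[k]]) {
        cl <- .classify_ring(ring, b)
        per[k, cl] <- per[k, cl] + 1L
        per[k, "total"] <- per[k, "total"] + 1L
        sz <- as.character(min(max(length(ring), 3L), 12L))
        sizes[cl, sz] <- sizes[cl, sz] + 1L
      }
    }
  }
  share_of <- function(counts) {
    k <- pmin(counts, 3L)
    vapply(0:3, function(v) mean(k == v), numeric(1))
  }
  shares <- t(vapply(classes, function(cl) share_of(per[[cl]]),
                     numeric(4)))
  colnames(shares) <- c("0", "1", "2", "3+")
  list(per_molecule = per, shares = shares, by_size = sizes)
}
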