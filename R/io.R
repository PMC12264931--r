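#' Read a molecule set from disk
#'
#' Supported formats: multi-record XYZ (two-line headers, coordinates in
#' Angstrom, no bonds), SDF (V2000; bond blocks carried through) and SMILES
#' line format (`smiles[ <id>]` per line; hydrogens are added, no
#' coordinates -- 3D embedding is only performed if geometry stages request
#' it).
#'
#' Malformed records are collected as warnings and skipped; the run
#' continues. An empty file is an error.
#'
#' @param path File path.
#' @param format One of `"xyz"`, `"sdf"`, `"smiles"`.
#' @param label Dataset label for every molecule, `"train"` or `"generated"`.
#' @return A [molecule_set()].
#' @export
read_molecules <- function(path, format = c("xyz", "sdf", "smiles"),
                           label = "train") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         xyz = .read_xyz(path, label),
         sdf = .read_sdf(path, label),
         smiles = .read_smiles(path, label))
}

#' Write a molecule set to disk
#'
#' @param mols A `molecule_set`.
#' @param path Output file path.
#' @param format One of `"xyz"`, `"sdf"`, `"smiles"`.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("xyz", "sdf", "smiles")) {
  format <- match.arg(format)
  txt <- switch(format,
                xyz = paste0(vapply(mols, .xyz_record, character(1)),
                             collapse = ""),
                sdf = molecules_to_sdf_text(mols),
                smiles = paste0(vapply(mols, function(m) {
                  s <- if (is.na(m$smiles)) "*" else m$smiles
                  paste0(s, "\t", m$id, "\n")
                }, character(1)), collapse = ""))
  cat(txt, file = path)
  invisible(path)
}

# ---- XYZ ------------------------------------------------------------------

.read_xyz <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  mols <- list(); errs <- character(0)
  pos <- 1L; k <- 0L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L || pos + 1L + n > length(lines) + 0L ||
        pos + 1L + n > length(lines)) {
      errs <- c(errs, sprintf("record at line %d: bad atom count", pos))
      # resync: skip to next line that parses as a count
      pos <- pos + 1L
      next
    }
    k <- k + 1L
    comment <- trimws(lines[pos + 1L])
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    ok <- all(lengths(fields) >= 4L)
    if (ok) {
      el <- vapply(fields, `[[`, character(1), 1L)
      xyz <- t(vapply(fields, function(f)
        suppressWarnings(as.numeric(f[2:4])), numeric(3)))
      ok <- !anyNA(xyz)
    }
    if (!ok) {
      errs <- c(errs, sprintf("record %d: malformed atom lines", k))
    } else {
      id <- if (nzchar(comment)) comment else sprintf("mol%04d", k)
      empty_bonds <- matrix(integer(0), ncol = 4,
                            dimnames = list(NULL, c("i", "j", "order",
                                                    "aromatic")))
      mols[[length(mols) + 1L]] <-
        molecule(el, coords = xyz, bonds = empty_bonds, id = id,
                 label = label)
    }
    pos <- pos + 2L + n
  }
  if (length(errs)) warning("skipped XYZ records: ",
                            paste(errs, collapse = "; "))
  if (!length(mols)) stop("no parseable XYZ records in ", path)
  molecule_set(mols)
}

.xyz_record <- function(m) {
  if (is.null(m$coords)) stop("molecule ", m$id, " has no coordinates")
  paste0(length(m$elements), "\n", m$id, "\n",
         paste(sprintf("%-2s %14.6f %14.6f %14.6f", m$elements,
                       m$coords[, 1], m$coords[, 2], m$coords[, 3]),
               collapse = "\n"), "\n")
}

# ---- SDF ------------------------------------------------------------------

.read_sdf <- function(path, label) {
  sdfset <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sdfset)
  if (any(!valid)) warning(sum(!valid), " malformed SDF record(s) skipped")
  sdfset <- sdfset[valid]
  if (!length(sdfset)) stop("no valid SDF records in ", path)
  mols <- sdfset_to_molecules(sdfset, label)
  perceive_aromaticity(molecule_set(mols))
}

#' Convert a ChemmineR SDFset to a molecule set
#'
#' @param sdfset A `ChemmineR::SDFset`.
#' @param label Dataset label.
#' @return List of `molecule` objects.
#' @export
sdfset_to_molecules <- function(sdfset, label = "train") {
  sdfs <- ChemmineR::SDFset2SDF(sdfset)
  lapply(seq_along(sdfs), function(k) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- NULL
    if (!is.null(bb) && nrow(bb)) {
      type <- as.integer(bb[, 3])
      arom <- as.integer(type == 4L)
      ord <- ifelse(type == 4L, 1L, pmin(type, 3L))
      bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                     order = ord, aromatic = arom)
    } else {
      bonds <- matrix(integer(0), ncol = 4,
                      dimnames = list(NULL, c("i", "j", "order", "aromatic")))
    }
    hdr <- ChemmineR::header(sdf)[["Molecule_Name"]]
    id <- if (!is.null(hdr) && nzchar(trimws(hdr))) trimws(hdr)
          else sprintf("mol%04d", k)
    molecule(el, coords = coords, bonds = bonds, id = id, label = label)
  })
}

#' Render a molecule set as SDF (V2000) text
#'
#' Aromatic bonds are written as bond type 4; coordinates default to zero
#' when absent.
#'
#' @param mols A `molecule_set`.
#' @return A single string of concatenated SDF records.
#' @export
molecules_to_sdf_text <- function(mols) {
  recs <- vapply(mols, function(m) {
    n <- length(m$elements)
    xyz <- if (is.null(m$coords)) matrix(0, n, 3) else m$coords
    b <- m$bonds
    if (is.null(b)) b <- matrix(integer(0), ncol = 4)
    paste0(
      m$id, "\n  molaudit\n\n",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", n, nrow(b)),
      paste(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                    xyz[, 1], xyz[, 2], xyz[, 3], m$elements),
            collapse = "\n"),
      if (n) "\n",
      if (nrow(b)) paste0(paste(sprintf("%3d%3d%3d  0  0  0  0",
                                        b[, 1], b[, 2],
                                        ifelse(b[, 4] == 1L, 4L, b[, 3])),
                                collapse = "\n"), "\n"),
      "M  END\n$$$$\n")
  }, character(1))
  paste0(recs, collapse = "")
}

# ---- SMILES ---------------------------------------------------------------

.read_smiles <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SMILES file: ", path)
  parts <- strsplit(lines, "\\s+")
  smi <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) > 1L) parts[[k]][[2L]] else sprintf("mol%04d", k)
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  inp <- paste0(paste(smi, ids, sep = "\t"), "\n", collapse = "")
  sdf_lines <- .ob_convert_text(inp, "smi", "sdf", args = "-h")
  got_ids <- function(lines) {
    if (!length(lines)) return(character(0))
    starts <- c(1L, which(lines == "$$$$") + 1L)
    trimws(lines[starts[starts <= length(lines)]])
  }
  # a malformed record aborts the remainder of an Open Babel batch;
  # retry anything missing one record at a time so the run continues
  missing <- setdiff(ids, got_ids(sdf_lines))
  for (id in missing) {
    one <- .ob_convert_text(
      paste0(smi[match(id, ids)], "\t", id, "\n"), "smi", "sdf",
      args = "-h")
    if (length(one)) sdf_lines <- c(sdf_lines, one)
  }
  still <- setdiff(ids, got_ids(sdf_lines))
  if (length(still)) {
    warning("skipped unparseable SMILES record(s): ",
            paste(still, collapse = ", "))
  }
  if (!length(sdf_lines)) stop("no parseable SMILES records in ", path)
  tf <- tempfile(fileext = ".sdf"); on.exit(unlink(tf))
  writeLines(sdf_lines, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  mols <- sdfset_to_molecules(sdfset, label)
  # restore input order
  mols <- mols[order(match(vapply(mols, function(m) m$id, character(1)),
                           ids))]
  mols <- lapply(mols, function(m) { m$coords <- NULL; m })
  out <- perceive_aromaticity(molecule_set(mols))
  csmi <- canonical_smiles(out)
  for (k in seq_along(out)) out[[k]]$smiles <- csmi[k]
  out
}

# ---- Open Babel bridge ----------------------------------------------------
# Batch conversions go through the obabel command-line tool (much faster on
# whole sets than per-molecule in-process calls); SMARTS matching uses
# ChemmineOB on molecule references parsed once per set.

.ob_convert_text <- function(text, informat, outformat,
                             args = character(0)) {
  fin <- tempfile(fileext = paste0(".", informat))
  fout <- tempfile(fileext = paste0(".", outformat))
  on.exit(unlink(c(fin, fout)))
  cat(text, file = fin)
  status <- suppressWarnings(
    system2("obabel", c(shQuote(fin), paste0("-o", outformat),
                        "-O", shQuote(fout), args),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

#' Open Babel molecule references for a set
#'
#' Parses the set once into Open Babel molecule objects, reusable across
#' SMARTS searches.
#'
#' @param mols A `molecule_set`.
#' @return List of OBMol references.
#' @keywords internal
.ob_refs <- function(mols) {
  txt <- molecules_to_sdf_text(mols)
  ChemmineOB::forEachMol("SDF", txt, identity)
}

canonical_smiles_of_text <- function(sdf_txt) {
  out <- .ob_convert_text(sdf_txt, "sdf", "can")
  if (!length(out)) return(NA_character_)
  strsplit(trimws(out[1]), "\t")[[1]][1]
}

#' Canonical SMILES for every molecule of a set
#'
#' Delegates canonicalization to Open Babel. Molecules whose conversion
#' fails get `NA`. Records are aligned with the input by molecule id, so
#' a record Open Babel cannot convert does not shift the others.
#'
#' @param mols A `molecule_set` with bond tables.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(mols) {
  if (!length(mols)) return(character(0))
  ids <- vapply(mols, function(m) m$id, character(1))
  uniq_ids <- !anyDuplicated(ids)
  txt <- molecules_to_sdf_text(mols)
  lines <- .ob_convert_text(txt, "sdf", "can")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1L)
  nm <- trimws(vapply(parts, function(p) if (length(p) > 1) p[[2]] else "",
                      character(1)))
  if (uniq_ids && all(nzchar(nm)) && !anyDuplicated(nm)) {
    return(unname(smi[match(ids, nm)]))
  }
  if (length(smi) == length(mols)) return(unname(smi))
  # fall back to per-molecule conversion so one bad record cannot shift
  # the alignment of the whole batch
  vapply(mols, function(m) {
    canonical_smiles_of_text(molecules_to_sdf_text(list(m)))
  }, character(1))
}
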