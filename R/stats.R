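# Composition, size, mass and geometry distributions, and the two-sample
# tests used to declare a distributional shift significant.

#' Histogram container
#'
#' A thin wrapper around fixed bin edges and counts used by every
#' distribution the audit exports. Density normalization divides by
#' `total count * bin width` so the result integrates to 1.
#'
#' @param values Numeric sample.
#' @param bin_edges Ordered numeric vector of bin edges; values outside
#'   the edges are clamped into the first/last bin.
#' @param normalization `"counts"` or `"density"`.
#' @return An object of class `"mol_histogram"` with fields `bin_edges`,
#'   `counts`, `density`, `normalization`, `n`.
#' @export
mol_histogram <- function(values, bin_edges, normalization = "counts") {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  values <- values[!is.na(values)]
  clamped <- pmin(pmax(values, bin_edges[1]),
                  bin_edges[length(bin_edges)])
  idx <- findInterval(clamped, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  widths <- diff(bin_edges)
  dens <- if (sum(counts) > 0) counts / (sum(counts) * widths)
          else counts * 0
  structure(list(bin_edges = bin_edges, counts = counts, density = dens,
                 normalization = normalization, n = length(values)),
            class = "mol_histogram")
}

#' @export
print.mol_histogram <- function(x, ...) {
  cat(sprintf("<mol_histogram> %d values in %d bins over [%g, %g]\n",
              x$n, length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Convert a histogram to a data frame
#'
#' @param x A `mol_histogram`.
#' @param ... Unused.
#' @return data.frame with columns `lower`, `upper`, `count`, `density`.
#' @export
as.data.frame.mol_histogram <- function(x, ...) {
  data.frame(lower = x$bin_edges[-length(x$bin_edges)],
             upper = x$bin_edges[-1],
             count = x$counts, density = x$density)
}

#' Elemental composition of a molecule set
#'
#' Fraction of all atoms (hydrogens included) per element, over the whole
#' set; fractions sum to 1.
#'
#' @param mols A non-empty `molecule_set`.
#' @return Named numeric vector of fractions, sorted by decreasing
#'   fraction.
#' @export
#' @examples
#' m <- molecule(c("C", "H", "H", "H", "H"))
#' elemental_composition(molecule_set(list(m)))
elemental_composition <- function(mols) {
  if (!length(mols)) stop("empty molecule set")
  tab <- table(unlist(lapply(mols, `[[`, "elements")))
  frac <- as.numeric(tab) / sum(tab)
  names(frac) <- names(tab)
  sort(frac, decreasing = TRUE)
}

#' Size and mass distributions of a molecule set
#'
#' Atom counts include hydrogens; heavy-atom counts exclude them.
#' Molecular weight uses the shipped standard atomic-mass table.
#'
#' @param mols A `molecule_set`.
#' @param atom_bin Bin width for atom-count histograms (default 1).
#' @param mw_bin Bin width for the molecular-weight histogram in g/mol
#'   (default 10).
#' @return List with `atom_count`, `heavy_atom_count`, `molecular_weight`
#'   (`mol_histogram`s), `H_vs_total` (data.frame of per-molecule `n_H`,
#'   `n_total`), and the raw per-molecule vectors `values`.
#' @export
size_and_mass_distributions <- function(mols, atom_bin = 1, mw_bin = 10) {
  na <- atom_counts(mols)
  nh <- heavy_atom_counts(mols)
  mw <- molecular_weights(mols)
  edges <- function(v, w) {
    lo <- floor(min(v) / w) * w
    hi <- ceiling((max(v) + 1e-9) / w) * w
    if (hi <= lo) hi <- lo + w
    seq(lo, hi, by = w)
  }
  list(atom_count = mol_histogram(na, edges(na, atom_bin)),
       heavy_atom_count = mol_histogram(nh, edges(nh, atom_bin)),
       molecular_weight = mol_histogram(mw, edges(mw, mw_bin)),
       H_vs_total = data.frame(n_H = na - nh, n_total = na),
       values = list(atom_count = na, heavy_atom_count = nh,
                     molecular_weight = mw))
}

#' Bonded distance distribution for an element pair
#'
#' Collects the lengths of perceived bonds between the two named elements
#' (pair unordered) across the set and bins them. The default bin width
#' of 0.02 Angstrom over [0.8, 2.2] resolves single, double and triple
#' carbon-carbon bond peaks.
#'
#' @param mols A `molecule_set` with coordinates and perceived bonds.
#' @param elem_a,elem_b Element symbols.
#' @param bin_edges Histogram bin edges in Angstrom.
#' @return A `mol_histogram`; its `"distances"` attribute holds the raw
#'   bond lengths. If the pair never occurs an empty histogram is
#'   returned with a warning.
#' @export
bonded_distance_distribution <- function(mols, elem_a, elem_b,
                                         bin_edges = seq(0.8, 2.2,
                                                         by = 0.02)) {
  d_all <- unlist(lapply(mols, function(m) {
    if (is.null(m$bonds) || !nrow(m$bonds) || is.null(m$coords))
      return(numeric(0))
    ei <- m$elements[m$bonds[, "i"]]
    ej <- m$elements[m$bonds[, "j"]]
    sel <- (ei == elem_a & ej == elem_b) | (ei == elem_b & ej == elem_a)
    if (!any(sel)) return(numeric(0))
    b <- m$bonds[sel, , drop = FALSE]
    sqrt(rowSums((m$coords[b[, "i"], , drop = FALSE] -
                  m$coords[b[, "j"], , drop = FALSE])^2))
  }))
  if (!length(d_all)) {
    warning("no ", elem_a, "-", elem_b, " bonds in set")
  }
  h <- mol_histogram(d_all, bin_edges)
  attr(h, "distances") <- d_all
  h
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, as used to compare molecular-weight
#' distributions between a training and a generated set.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return An object of class `"mol_test"` with fields `statistic`,
#'   `p_value`, `df`, `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_t needs at least 2 observations per sample")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("welch_t needs nonzero variance in at least one sample")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 n_x = length(x), n_y = length(y),
                 method = "welch_t"),
            class = "mol_test")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the
#' p-value is the asymptotic Kolmogorov form evaluated at
#' `sqrt(n_x * n_y / (n_x + n_y)) * D`.
#'
#' @param x,y Numeric samples (at least 1 observation each).
#' @return An object of class `"mol_test"`; `df` is `NA`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2), c(3, 4))
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 df = NA_real_,
                 n_x = length(x), n_y = length(y),
                 method = "ks_two_sample"),
            class = "mol_test")
}

#' @export
print.mol_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, p %.3g (n = %d, %d%s)\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y,
              if (!is.na(x$df)) sprintf(", df %.2f", x$df) else ""))
  invisible(x)
}
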