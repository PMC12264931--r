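# The three per-molecule vectorizations:
#  * an averaged SOAP-style power-spectrum descriptor of the atomic
#    neighbour density (rotation/translation/reindex invariant),
#  * an engineered bonding descriptor (counts of elements, bond kinds,
#    ring classes, functional groups plus global scalars),
#  * hashed circular (ECFP/Morgan-family) fingerprints for the
#    discriminator, via Open Babel.

#' Structural descriptor configuration
#'
#' Hyperparameters of the averaged power-spectrum descriptor: the atomic
#' neighbour density is a sum of Gaussians of width `sigma` expanded in
#' `n_radial` orthonormalized polynomial radial functions inside `cutoff`
#' and real spherical harmonics up to `l_max`; the rotationally invariant
#' power spectrum is averaged over all atoms.
#'
#' @param cutoff Environment cutoff radius in Angstrom.
#' @param n_radial Number of radial basis functions.
#' @param l_max Maximum angular momentum.
#' @param sigma Gaussian smearing width in Angstrom.
#' @param species Character vector of element symbols the descriptor
#'   distinguishes; must cover every element present in the input.
#' @param n_quad Radial quadrature nodes (Gauss-Legendre).
#' @return An object of class `"structural_config"`.
#' @export
structural_config <- function(cutoff = 5.0, n_radial = 8L, l_max = 6L,
                              sigma = 0.3,
                              species = c("H", "C", "N", "O", "F", "S",
                                          "Cl"),
                              n_quad = 64L) {
  stopifnot(cutoff > 0, n_radial >= 1L, l_max >= 0L, sigma > 0,
            length(species) >= 1L)
  structure(list(cutoff = cutoff, n_radial = as.integer(n_radial),
                 l_max = as.integer(l_max), sigma = sigma,
                 species = species, n_quad = as.integer(n_quad)),
            class = "structural_config")
}

# orthonormalized polynomial radial basis g_n(r) = sum_a W[n,a] (rc-r)^(a+2)
# evaluated at the quadrature nodes; returns the quadrature-weighted basis
# so that I_n = basis %*% f(nodes) approximates integral g_n(r) f(r) r^2 dr
.radial_basis <- function(cfg) {
  rc <- cfg$cutoff; nmax <- cfg$n_radial
  a <- seq_len(nmax)
  p <- outer(a, a, "+") + 4          # exponent of the overlap integrand
  S <- rc^(p + 3) * 2 / ((p + 1) * (p + 2) * (p + 3))
  es <- eigen(S, symmetric = TRUE)
  if (any(es$values <= 0)) stop("radial overlap matrix not positive definite")
  W <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  gq <- pracma::gaussLegendre(cfg$n_quad, 0, rc)
  phi <- t(outer(gq$x, a + 2, function(r, k) (rc - r)^k))   # nmax x nq
  list(nodes = gq$x,
       gw = (W %*% phi) * rep(gq$w * gq$x^2, each = nmax))
}

# real spherical harmonics Y_lm for unit vectors (rows of u), one matrix
# (2l+1) x npts per l; the fixed phase convention cancels in the power
# spectrum so rotational invariance is exact
.real_sph_harm <- function(u, l_max) {
  ct <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  lapply(0:l_max, function(l) {
    P <- pracma::legendre(l, ct)               # (l+1) x npts, m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    m <- 0:l
    lnN <- 0.5 * (log(2 * l + 1) - log(4 * pi) +
                    lgamma(l - m + 1) - lgamma(l + m + 1))
    Nn <- exp(lnN)
    Y <- matrix(0, 2 * l + 1, length(ct))
    Y[l + 1, ] <- Nn[1] * P[1, ]               # m = 0
    if (l > 0) {
      for (mm in 1:l) {
        base <- sqrt(2) * Nn[mm + 1] * P[mm + 1, ]
        Y[l + 1 + mm, ] <- base * cos(mm * phi)
        Y[l + 1 - mm, ] <- base * sin(mm * phi)
      }
    }
    Y
  })
}

.structural_feature_names <- function(cfg) {
  sp <- cfg$species; nmax <- cfg$n_radial
  out <- character(0)
  for (s1 in seq_along(sp)) for (s2 in s1:length(sp)) {
    for (l in 0:cfg$l_max) {
      nn <- if (s1 == s2) {
        which(upper.tri(diag(nmax), diag = TRUE), arr.ind = TRUE)
      } else as.matrix(expand.grid(row = 1:nmax, col = 1:nmax))
      out <- c(out, sprintf("%s-%s_n%d_n%d_l%d", sp[s1], sp[s2],
                            nn[, "row"], nn[, "col"], l))
    }
  }
  out
}

#' Averaged structural (SOAP-style) descriptor
#'
#' Expands each atom's Gaussian-smeared neighbour density (central atom
#' included) in radial functions and spherical harmonics, forms the
#' rotationally invariant power spectrum per species pair, and averages
#' over atoms. Identical under rigid rotation, translation and atom
#' reindexing; a dimer separated beyond twice the cutoff equals the
#' average of its monomer descriptors.
#'
#' @param mols A `molecule_set` with coordinates (or one `molecule`).
#' @param cfg A [structural_config()].
#' @return Numeric matrix, molecules x features, with feature names
#'   `"<sp1>-<sp2>_n<i>_n<j>_l<k>"`; attribute `"config"` holds `cfg`.
#' @export
structural_descriptors <- function(mols, cfg = structural_config()) {
  if (inherits(mols, "molecule")) mols <- molecule_set(list(mols))
  basis <- .radial_basis(cfg)
  nm <- .structural_feature_names(cfg)
  out <- t(vapply(mols, function(m) .structural_one(m, cfg, basis),
                  numeric(length(nm))))
  colnames(out) <- nm
  rownames(out) <- vapply(mols, function(m) m$id, character(1))
  attr(out, "config") <- cfg
  attr(out, "descriptor") <- "structural"
  out
}

# exponentially scaled modified spherical Bessel functions
# e^{-x} i_l(x) for l = 0..lmax, elementwise over x > 0: power series for
# small x, upward recurrence i_{l+1} = i_{l-1} - (2l+1)/x i_l otherwise
.sph_bessel_scaled <- function(x, lmax) {
  out <- vector("list", lmax + 1)
  small <- x < 1.5
  ex <- exp(-2 * x)
  s0 <- (1 - ex) / (2 * x)                 # e^{-x} sinh(x)/x
  s1 <- ((1 + ex) / 2 - s0) / x            # e^{-x} i_1(x)
  if (any(small)) {
    xs <- x[small]; exs <- exp(-xs); x2 <- xs^2
    ser <- function(l) {
      dfact <- prod(seq(1, 2 * l + 1, by = 2))
      t0 <- xs^l / dfact
      acc <- t0
      for (k in 1:10) {
        t0 <- t0 * x2 / (2 * k * (2 * (l + k) + 1))
        acc <- acc + t0
      }
      acc * exs
    }
    s0[small] <- ser(0)
    if (lmax >= 1) s1[small] <- ser(1)
  }
  out[[1]] <- s0
  if (lmax >= 1) out[[2]] <- s1
  if (lmax >= 2) {
    for (l in 1:(lmax - 1)) {
      nxt <- out[[l]] - (2 * l + 1) / x * out[[l + 1]]
      if (any(small)) nxt[small] <- ser(l + 1)
      out[[l + 2]] <- nxt
    }
  }
  out
}

# offsets of each (s1, s2, l) block in the feature vector
.structural_block_index <- function(cfg) {
  nmax <- cfg$n_radial; nsp <- length(cfg$species)
  n_same <- nmax * (nmax + 1) / 2
  idx <- list(); off <- 0L
  for (s1 in seq_len(nsp)) for (s2 in s1:nsp) {
    len <- if (s1 == s2) n_same else nmax * nmax
    for (l in 0:cfg$l_max) {
      idx[[paste(s1, s2, l)]] <- off + seq_len(len)
      off <- off + len
    }
  }
  attr(idx, "total") <- off
  idx
}

.structural_one <- function(m, cfg, basis) {
  if (is.null(m$coords)) stop("molecule ", m$id, " has no coordinates")
  sp_idx <- match(m$elements, cfg$species)
  if (anyNA(sp_idx)) {
    stop("element(s) outside species list: ",
         paste(unique(m$elements[is.na(sp_idx)]), collapse = ", "))
  }
  n_at <- length(m$elements)
  nmax <- cfg$n_radial; lmax <- cfg$l_max; nsp <- length(cfg$species)
  alpha <- 1 / (2 * cfg$sigma^2)
  xq <- basis$nodes; gw <- basis$gw
  # l = 0 radial integral of the central-atom (r -> 0) Gaussian
  I_center <- sqrt(4 * pi) * as.numeric(gw %*% exp(-alpha * xq^2))
  ut <- upper.tri(diag(nmax), diag = TRUE)
  blocks <- .structural_block_index(cfg)
  acc <- numeric(attr(blocks, "total"))
  for (at in seq_len(n_at)) {
    dx <- sweep(m$coords, 2, m$coords[at, ])
    r <- sqrt(rowSums(dx^2))
    nb <- which(r <= cfg$cutoff)
    near0 <- nb[r[nb] < 1e-10]
    far <- nb[r[nb] >= 1e-10]
    # coefficient arrays per species: list over l of (nmax x (2l+1))
    cs <- rep(list(NULL), nsp)
    zero_cs <- lapply(0:lmax, function(l) matrix(0, nmax, 2 * l + 1))
    if (length(far)) {
      rj <- r[far]
      u <- dx[far, , drop = FALSE] / rj
      X <- 2 * alpha * outer(xq, rj)                       # nq x J
      E <- exp(-alpha * (outer(xq, rj, "-"))^2)
      Ylist <- .real_sph_harm(u, lmax)
      SB <- .sph_bessel_scaled(X, lmax)
      for (l in 0:lmax) {
        Inl <- gw %*% (4 * pi * SB[[l + 1]] * E)           # nmax x J
        Y <- Ylist[[l + 1]]                                # (2l+1) x J
        for (s in unique(sp_idx[far])) {
          js <- which(sp_idx[far] == s)
          if (is.null(cs[[s]])) cs[[s]] <- zero_cs
          cs[[s]][[l + 1]] <- cs[[s]][[l + 1]] +
            Inl[, js, drop = FALSE] %*% t(Y[, js, drop = FALSE])
        }
      }
    }
    # an atom at the centre contributes only to l = 0 (its Gaussian is
    # spherically symmetric there): c_n00 += sqrt(4 pi) integral, and the
    # sqrt(4 pi) cancels against Y_00 = 1/sqrt(4 pi)
    for (j0 in near0) {
      s <- sp_idx[j0]
      if (is.null(cs[[s]])) cs[[s]] <- zero_cs
      cs[[s]][[1]][, 1] <- cs[[s]][[1]][, 1] + I_center
    }
    # power spectrum per species pair (pairs with an absent species
    # contribute nothing and are skipped)
    present <- which(!vapply(cs, is.null, logical(1)))
    for (s1 in present) for (s2 in present[present >= s1]) {
      for (l in 0:lmax) {
        M <- cs[[s1]][[l + 1]] %*% t(cs[[s2]][[l + 1]])    # nmax x nmax
        M <- M * pi * sqrt(8 / (2 * l + 1))
        pos <- blocks[[paste(s1, s2, l)]]
        acc[pos] <- acc[pos] + (if (s1 == s2) M[ut] else as.numeric(M))
      }
    }
  }
  acc / n_at
}

# ---- bonding descriptor ---------------------------------------------------

#' Default bonding descriptor schema
#'
#' An ordered, versioned feature list drawn from five families: element
#' counts, bond-kind x element-pair counts (single/double/triple/aromatic
#' over unordered element pairs), ring-class x ring-size counts,
#' functional-group match counts from a SMARTS catalog, and four global
#' scalars (molecular weight, heavy-atom count, hydrogen fraction,
#' rotatable-bond count). The schema object is the source of truth for
#' feature order and naming.
#'
#' @param elements Elements whose counts and pair combinations are
#'   featurized.
#' @param catalog A [group_catalog()] for the group-count family.
#' @param ring_sizes Ring sizes covered by the ring family.
#' @return An object of class `"bonding_schema"` (data.frame with columns
#'   `name`, `family`, `a1`, `a2`); the catalog is attached as an
#'   attribute.
#' @export
bonding_schema <- function(elements = c("C", "H", "N", "O", "F", "S",
                                        "Cl"),
                           catalog = group_catalog(),
                           ring_sizes = 3:8) {
  rows <- list()
  add <- function(name, family, a1 = NA, a2 = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, family = family, a1 = as.character(a1),
      a2 = as.character(a2), stringsAsFactors = FALSE)
  }
  for (e in elements) add(paste0("n_", e), "element_count", e)
  kinds <- c("single", "double", "triple", "aromatic")
  for (k in kinds) {
    for (i in seq_along(elements)) for (j in i:length(elements)) {
      add(sprintf("bond_%s_%s_%s", k, elements[i], elements[j]),
          "bond_pair_count", k, paste(elements[i], elements[j]))
    }
  }
  for (cl in c("aromatic", "unsaturated_aliphatic", "saturated")) {
    for (sz in ring_sizes) {
      add(sprintf("ring_%s_%d", cl, sz), "ring_count", cl, sz)
    }
  }
  for (g in catalog$name) add(paste0("group_", g), "group_count", g)
  add("molecular_weight", "scalar", "molecular_weight")
  add("heavy_atom_count", "scalar", "heavy_atom_count")
  add("h_fraction", "scalar", "h_fraction")
  add("rotatable_bonds", "scalar", "rotatable_bonds")
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name)) stop("schema feature names must be unique")
  structure(out, class = c("bonding_schema", "data.frame"),
            catalog = catalog)
}

#' Bonding descriptors of a molecule set
#'
#' Deterministic feature extraction in schema order. Requires assigned
#' bond orders (and aromatic flags for the aromatic families).
#'
#' @param mols A `molecule_set`.
#' @param schema A [bonding_schema()].
#' @return Numeric matrix, molecules x features, attribute
#'   `"descriptor" = "bonding"`.
#' @export
bonding_descriptors <- function(mols, schema = bonding_schema()) {
  stopifnot(inherits(schema, "bonding_schema"))
  no_bonds <- vapply(mols, function(m) is.null(m$bonds), logical(1))
  if (any(no_bonds)) {
    stop("bonding descriptor needs perceived bonds with orders")
  }
  n <- length(mols)
  out <- matrix(0, n, nrow(schema),
                dimnames = list(vapply(mols, function(m) m$id,
                                       character(1)), schema$name))
  fam <- schema$family

  # element counts
  ec <- which(fam == "element_count")
  for (k in ec) {
    e <- schema$a1[k]
    out[, k] <- vapply(mols, function(m) sum(m$elements == e), numeric(1))
  }

  # bond-kind x element-pair counts
  bp <- which(fam == "bond_pair_count")
  if (length(bp)) {
    keys <- paste(schema$a1[bp], schema$a2[bp])
    for (mi in seq_len(n)) {
      m <- mols[[mi]]; b <- m$bonds
      if (!nrow(b)) next
      kind <- ifelse(b[, "aromatic"] == 1L, "aromatic",
                     c("single", "double", "triple")[b[, "order"]])
      e1 <- m$elements[b[, "i"]]; e2 <- m$elements[b[, "j"]]
      pair <- paste(pmin(e1, e2), pmax(e1, e2))
      tb <- table(paste(kind, pair))
      hit <- match(names(tb), keys)
      ok <- !is.na(hit)
      out[mi, bp[hit[ok]]] <- as.numeric(tb[ok])
    }
  }

  # smallest set of smallest rings, computed once for the whole set and
  # shared by the ring-count family and the rotatable-bond scalar
  rr <- NULL
  need_rings <- any(fam == "ring_count") ||
    any(fam == "scalar" & schema$a1 == "rotatable_bonds")
  if (need_rings) rr <- .sssr(mols)

  # ring-class x size counts
  rc <- which(fam == "ring_count")
  if (length(rc)) {
    for (mi in seq_len(n)) {
      for (ring in rr[[mi]]) {
        cl <- .classify_ring(ring, mols[[mi]]$bonds)
        key <- sprintf("ring_%s_%d", cl,
                       min(max(length(ring), min(as.integer(schema$a2[rc]))),
                           max(as.integer(schema$a2[rc]))))
        hit <- match(key, schema$name)
        if (!is.na(hit)) out[mi, hit] <- out[mi, hit] + 1
      }
    }
  }

  # functional-group counts
  gc_idx <- which(fam == "group_count")
  if (length(gc_idx)) {
    catalog <- attr(schema, "catalog")
    want <- schema$a1[gc_idx]
    sub <- catalog[match(want, catalog$name), , drop = FALSE]
    class(sub) <- class(catalog)
    cnt <- group_counts(mols, sub)
    out[, gc_idx] <- cnt
  }

  # global scalars
  sc <- which(fam == "scalar")
  for (k in sc) {
    out[, k] <- switch(schema$a1[k],
      molecular_weight = molecular_weights(mols),
      heavy_atom_count = as.numeric(heavy_atom_counts(mols)),
      h_fraction = vapply(mols, function(m) mean(m$elements == "H"),
                          numeric(1)),
      rotatable_bonds = vapply(seq_len(n), function(mi) {
        .rotatable_bonds(mols[[mi]], rr[[mi]])
      }, numeric(1)),
      stop("unknown scalar: ", schema$a1[k]))
  }
  attr(out, "descriptor") <- "bonding"
  attr(out, "schema") <- schema
  out
}

# single, non-aromatic, non-ring bonds between heavy atoms that each have
# at least one further heavy neighbour; `rings` is the molecule's SSSR
.rotatable_bonds <- function(m, rings = NULL) {
  b <- m$bonds
  if (is.null(b) || !nrow(b)) return(0)
  heavy <- m$elements != "H"
  deg_h <- numeric(length(m$elements))
  hb <- heavy[b[, "i"]] & heavy[b[, "j"]]
  for (col in c("i", "j")) {
    t <- table(b[hb, col])
    deg_h[as.integer(names(t))] <- deg_h[as.integer(names(t))] + t
  }
  ring_edges <- character(0)
  if (is.null(rings)) rings <- .sssr(molecule_set(list(m)))[[1]]
  for (ring in rings) {
    nn <- length(ring)
    ring_edges <- c(ring_edges,
                    paste(pmin(ring, ring[c(2:nn, 1)]),
                          pmax(ring, ring[c(2:nn, 1)])))
  }
  cand <- b[, "order"] == 1L & b[, "aromatic"] == 0L & hb &
    deg_h[b[, "i"]] >= 2 & deg_h[b[, "j"]] >= 2 &
    !(paste(b[, "i"], b[, "j"]) %in% ring_edges)
  sum(cand)
}

# ---- circular fingerprints ------------------------------------------------

#' Hashed circular fingerprints
#'
#' ECFP-family fingerprints of the requested radius, hashed/folded to
#' `n_bits` bits by Open Babel, optionally augmented with the heavy-atom
#' total and per-element counts as integer features (the augmentation
#' appends exactly `length(elements) + 1` columns).
#'
#' @param mols A `molecule_set` of perception-valid molecules.
#' @param radius Circular radius (1, 2 or 3; ECFP2/4/6).
#' @param n_bits Fingerprint length; a power of two, at most 4096.
#' @param augment_counts Append count features (default `FALSE`).
#' @param elements Elements counted by the augmentation.
#' @return Numeric matrix, molecules x (`n_bits` [+ counts]).
#' @export
circular_fingerprints <- function(mols, radius = 2L, n_bits = 2048L,
                                  augment_counts = FALSE,
                                  elements = c("C", "H", "N", "O", "F",
                                               "S", "Cl")) {
  stopifnot(radius >= 1L, radius <= 3L, n_bits >= 32L, n_bits <= 4096L)
  if (bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("n_bits must be a power of two")
  }
  if (!length(mols)) stop("empty molecule set")
  bad <- !vapply(mols, function(m) isTRUE(m$valid), logical(1))
  if (any(bad)) {
    stop("invalid molecule(s) cannot be fingerprinted: ",
         paste(vapply(mols[which(bad)], function(m) m$id, character(1)),
               collapse = ", "))
  }
  txt <- molecules_to_sdf_text(mols)
  fpt <- .ob_convert_text(txt, "sdf", "fpt",
                          args = c(paste0("-xfECFP", 2L * radius),
                                   "-xN", n_bits, "-xh"))
  if (!length(fpt)) stop("fingerprint generation failed")
  parsed <- .parse_fpt(fpt, n_bits)
  ids <- vapply(mols, function(m) m$id, character(1))
  pos <- if (!anyDuplicated(ids) && all(ids %in% names(parsed)))
    match(ids, names(parsed)) else seq_along(mols)
  if (length(parsed) < length(mols) && anyNA(pos)) {
    stop("fingerprint output incomplete (",
         length(parsed), "/", length(mols), " molecules)")
  }
  out <- do.call(rbind, parsed[pos])
  colnames(out) <- paste0("bit_", seq_len(n_bits) - 1L)
  rownames(out) <- ids
  if (augment_counts) {
    counts <- t(vapply(mols, function(m) {
      c(sum(m$elements != "H"),
        vapply(elements, function(e) sum(m$elements == e), numeric(1)))
    }, numeric(length(elements) + 1L)))
    colnames(counts) <- c("heavy_atom_count", paste0("n_", elements))
    out <- cbind(out, counts)
  }
  attr(out, "descriptor") <- "fingerprint"
  attr(out, "config") <- list(radius = radius, n_bits = n_bits,
                              augment_counts = augment_counts)
  out
}

.parse_fpt <- function(lines, n_bits) {
  # drop diagnostic lines (e.g. "Possible superstructure of ..."):
  # fingerprint bodies are pure hex words
  keep <- grepl("^>", lines) | grepl("^[0-9a-fA-F ]+$", trimws(lines))
  lines <- lines[keep & nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  out <- vector("list", sum(hdr))
  names(out) <- ids
  body <- split(lines[!hdr], grp[!hdr])
  for (k in seq_along(out)) {
    words <- unlist(strsplit(trimws(body[[as.character(k)]]), "\\s+"))
    bits <- numeric(length(words) * 32L)
    for (w in seq_along(words)) {
      hi <- strtoi(substr(words[w], 1, 4), 16L)
      lo <- strtoi(substr(words[w], 5, 8), 16L)
      bits[(w - 1L) * 32L + 1:16] <- as.integer(intToBits(lo)[1:16])
      bits[(w - 1L) * 32L + 17:32] <- as.integer(intToBits(hi)[1:16])
    }
    out[[k]] <- bits[seq_len(n_bits)]
  }
  out
}
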