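# Seeded synthetic molecule generator. Molecules are grown as random trees
# over a carbon skeleton (optionally seeded with an aromatic six-ring
# template), closed into rings, promoted to double/triple bonds, substituted
# with heteroatoms under valence constraints, and completed with explicit
# hydrogens. Every step is vectorized across the whole set so large paired
# sets are cheap to simulate.

#' Synthetic generator configuration
#'
#' Defines the statistical conditions of a simulated molecule population:
#' the heavy-atom size distribution, the heteroatom alphabet and its
#' weights, and the probabilities steering unsaturation, ring closure,
#' aromatic seeding and heteroatom substitution. The defaults emulate a
#' mid-sized drug-like organic population (5-22 heavy atoms, ~25% of
#' substitutable positions carrying N/O/F/S/Cl).
#'
#' @param size_dist `data.frame` with columns `heavy` (heavy-atom counts)
#'   and `prob` (sampling weights). Default: Poisson(7) shifted to start
#'   at 5, truncated at 22.
#' @param hetero_elements Named numeric vector of heteroatom sampling
#'   weights (must sum to 1 after normalization).
#' @param p_hetero Probability that an eligible heavy atom is substituted
#'   by a heteroatom.
#' @param p_hetero_max Ceiling reached at bias shift 1 (see
#'   [bias_config()]).
#' @param p_unsat Probability that an eligible C-C bond is promoted to a
#'   double/triple bond.
#' @param p_unsat_max Ceiling reached at bias shift 1.
#' @param p_ring Ring-closure propensity in `[0, 1]`.
#' @param p_aromatic Probability that a molecule (with at least 8 heavy
#'   atoms) is grown from an aromatic six-ring template fragment.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(size_dist = NULL,
                             hetero_elements = c(N = 0.34, O = 0.34,
                                                 F = 0.10, S = 0.13,
                                                 Cl = 0.09),
                             p_hetero = 0.25, p_hetero_max = 1.00,
                             p_unsat = 0.15, p_unsat_max = 0.90,
                             p_ring = 0.40, p_aromatic = 0.25,
                             seed = 1L) {
  if (is.null(size_dist)) {
    heavy <- 5:22
    prob <- stats::dpois(heavy - 5L, lambda = 7)
    size_dist <- data.frame(heavy = heavy, prob = prob / sum(prob))
  }
  stopifnot(all(c("heavy", "prob") %in% names(size_dist)),
            all(size_dist$heavy >= 1L), all(size_dist$prob >= 0),
            sum(size_dist$prob) > 0)
  probs <- c(p_hetero, p_hetero_max, p_unsat, p_unsat_max, p_ring,
             p_aromatic)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_ring >= 1 && max(size_dist$heavy) < 3) {
    stop("ring propensity requires molecules with at least 3 heavy atoms")
  }
  hetero_elements <- hetero_elements / sum(hetero_elements)
  if (!all(names(hetero_elements) %in% .element_table$symbol)) {
    stop("unknown heteroatom symbol in alphabet")
  }
  structure(list(size_dist = size_dist, hetero_elements = hetero_elements,
                 p_hetero = p_hetero, p_hetero_max = p_hetero_max,
                 p_unsat = p_unsat, p_unsat_max = p_unsat_max,
                 p_ring = p_ring, p_aromatic = p_aromatic,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Shift a generator configuration along the bias axes
#'
#' Produces a biased copy of a configuration: the heteroatom and
#' unsaturation probabilities move linearly from their base values to
#' their configured ceilings, and the ring-closure propensity (the source
#' of saturated aliphatic rings) shrinks linearly, as the shift grows from
#' 0 (identity) to 1 (extreme bias).
#'
#' @param cfg A [generator_config()].
#' @param shift Bias magnitude in `[0, 1]`.
#' @return A new `generator_config`.
#' @export
bias_config <- function(cfg, shift) {
  stopifnot(inherits(cfg, "generator_config"))
  if (shift < 0 || shift > 1) stop("shift must lie in [0, 1]")
  out <- cfg
  out$p_hetero <- cfg$p_hetero + shift * (cfg$p_hetero_max - cfg$p_hetero)
  out$p_unsat <- cfg$p_unsat + shift * (cfg$p_unsat_max - cfg$p_unsat)
  out$p_ring <- cfg$p_ring * (1 - 0.9 * shift)
  clipped <- c(p_hetero = out$p_hetero, p_unsat = out$p_unsat)
  if (any(clipped > 1)) {
    warning("probabilities clipped at 1: ",
            paste(names(clipped)[clipped > 1], collapse = ", "))
    out$p_hetero <- min(out$p_hetero, 1)
    out$p_unsat <- min(out$p_unsat, 1)
  }
  out
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage seed from a global seed
#'
#' A fixed integer derivation so that pipeline stages can be re-run in
#' isolation while still fanning out from one global seed.
#'
#' @param seed Integer global seed.
#' @param stage Stage name string.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% 1000000007
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

# Gumbel-max trick: one uniform draw of a column index per row of the
# eligibility matrix `elig` (rows with no eligible column return NA)
.sample_col <- function(elig) {
  n <- nrow(elig); m <- ncol(elig)
  if (m == 1L) return(ifelse(elig[, 1], 1L, NA_integer_))
  g <- matrix(-log(-log(stats::runif(n * m))), n, m)
  g[!elig] <- -Inf
  idx <- max.col(g, ties.method = "first")
  idx[!elig[cbind(seq_len(n), idx)]] <- NA_integer_
  idx
}

#' Generate a synthetic molecule set
#'
#' Draws `n` valence-legal, connected molecules from the population
#' defined by `cfg`. Generation is deterministic given `(cfg, n, seed)`.
#' Canonical SMILES are attached via Open Babel unless `emit_smiles =
#' FALSE` (composition-level statistics do not need them and skipping the
#' conversion makes large simulation sweeps much cheaper). Coordinates are
#' not generated here; see [embed_3d()].
#'
#' @param cfg A [generator_config()].
#' @param n Number of molecules.
#' @param label Dataset label for the set.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param emit_smiles Attach canonical SMILES (default `TRUE`).
#' @return A [molecule_set()].
#' @export
generate_molecule_set <- function(cfg, n, label = "train",
                                  seed = cfg$seed, emit_smiles = TRUE) {
  stopifnot(inherits(cfg, "generator_config"), n >= 1)
  parts <- .with_seed(seed, .generate_raw(cfg, n))
  prefix <- if (label == "train") "tr" else "gen"
  mols <- lapply(seq_len(n), function(k) {
    molecule(parts$elements[[k]], bonds = parts$bonds[[k]],
             id = sprintf("%s%05d", prefix, k), label = label)
  })
  out <- molecule_set(mols)
  if (emit_smiles) {
    smi <- canonical_smiles(out)
    for (k in seq_len(n)) out[[k]]$smiles <- smi[k]
  }
  out
}

.generate_raw <- function(cfg, n) {
  h <- sample(cfg$size_dist$heavy, n, replace = TRUE,
              prob = cfg$size_dist$prob)
  maxh <- max(h)
  freeval <- matrix(0L, n, maxh)
  arom_seed <- stats::runif(n) < cfg$p_aromatic & h >= 8L
  start_t <- ifelse(arom_seed, 7L, 2L)

  # bond arrays (flat over the whole set)
  bm <- bi <- bj <- bord <- barom <- integer(0)

  # aromatic six-ring template: atoms 1..6, kekule orders 2,1,2,1,2,1
  if (any(arom_seed)) {
    idx <- which(arom_seed)
    ri <- rep(1:6, length(idx)); rj <- rep(c(2:6, 1L), length(idx))
    bm <- c(bm, rep(idx, each = 6L)); bi <- c(bi, pmin(ri, rj))
    bj <- c(bj, pmax(ri, rj))
    bord <- c(bord, rep(c(2L, 1L, 2L, 1L, 2L, 1L), length(idx)))
    barom <- c(barom, rep(1L, 6L * length(idx)))
    freeval[idx, 1:6] <- 1L
  }
  freeval[!arom_seed, 1] <- 4L

  # sequential tree growth, vectorized over molecules at each step
  for (t in 2:maxh) {
    alive <- which(h >= t & start_t <= t)
    if (!length(alive)) next
    elig <- freeval[alive, seq_len(t - 1L), drop = FALSE] > 0L
    parent <- .sample_col(elig)
    stopifnot(!anyNA(parent))     # a growing tree always has free valence
    bm <- c(bm, alive); bi <- c(bi, parent); bj <- c(bj, rep(t, length(alive)))
    bord <- c(bord, rep(1L, length(alive)))
    barom <- c(barom, rep(0L, length(alive)))
    freeval[cbind(alive, parent)] <- freeval[cbind(alive, parent)] - 1L
    freeval[alive, t] <- 3L
  }

  # ring closures: up to two attempts per molecule
  key <- function(m, a, b) (m - 1) * (maxh + 1)^2 + (a - 1) * (maxh + 1) + b
  edge_keys <- key(bm, bi, bj)
  for (attempt_p in c(cfg$p_ring, cfg$p_ring^2)) {
    try_mol <- which(stats::runif(n) < attempt_p & h >= 4L)
    if (!length(try_mol)) next
    eligm <- freeval[try_mol, , drop = FALSE] > 0L &
      outer(h[try_mol], seq_len(maxh), ">=")
    a <- .sample_col(eligm)
    eligm[cbind(seq_along(try_mol), ifelse(is.na(a), 1L, a))] <- FALSE
    b <- .sample_col(eligm)
    ok <- !is.na(a) & !is.na(b)
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- ok & !(key(try_mol, lo, hi) %in% edge_keys)
    if (!any(ok)) next
    m2 <- try_mol[ok]; lo <- lo[ok]; hi <- hi[ok]
    bm <- c(bm, m2); bi <- c(bi, lo); bj <- c(bj, hi)
    bord <- c(bord, rep(1L, length(m2)))
    barom <- c(barom, rep(0L, length(m2)))
    freeval[cbind(m2, lo)] <- freeval[cbind(m2, lo)] - 1L
    freeval[cbind(m2, hi)] <- freeval[cbind(m2, hi)] - 1L
    edge_keys <- c(edge_keys, key(m2, lo, hi))
  }

  # bond-order promotion: at most one promoted bond per atom (no cumulenes)
  cand <- which(barom == 0L & stats::runif(length(bm)) < cfg$p_unsat)
  if (length(cand)) {
    ki <- key(bm[cand], bi[cand], 0); kj <- key(bm[cand], bj[cand], 0)
    min_at <- tapply(rep(cand, 2L), c(ki, kj), min)
    # bond accepted iff it is the unique chosen candidate at both ends
    acc <- cand[cand == min_at[as.character(ki)] &
                cand == min_at[as.character(kj)]]
    fi <- freeval[cbind(bm[acc], bi[acc])]
    fj <- freeval[cbind(bm[acc], bj[acc])]
    acc <- acc[fi >= 1L & fj >= 1L]
    if (length(acc)) {
      fi <- freeval[cbind(bm[acc], bi[acc])]
      fj <- freeval[cbind(bm[acc], bj[acc])]
      triple <- stats::runif(length(acc)) < 1 / 3 & fi >= 2L & fj >= 2L
      dd <- ifelse(triple, 2L, 1L)
      bord[acc] <- bord[acc] + dd
      freeval[cbind(bm[acc], bi[acc])] <- fi - dd
      freeval[cbind(bm[acc], bj[acc])] <- fj - dd
    }
  }

  # heteroatom substitution under valence constraints
  elems <- matrix("C", n, maxh)
  present <- outer(h, seq_len(maxh), ">=")
  in_seed <- matrix(FALSE, n, maxh)
  in_seed[arom_seed, 1:6] <- TRUE
  used <- 4L - freeval
  sub_idx <- which(present & !in_seed & stats::runif(n * maxh) < cfg$p_hetero)
  if (length(sub_idx)) {
    # organic substitution valences (divalent sulfur, not hypervalent)
    organic <- c(N = 3L, O = 2L, F = 1L, S = 2L, Cl = 1L, Br = 1L,
                 I = 1L, P = 3L)
    het_val <- standard_valences(names(cfg$hetero_elements))
    known <- names(het_val) %in% names(organic)
    het_val[known] <- organic[names(het_val)[known]]
    for (u in sort(unique(used[sub_idx]))) {
      allowed <- het_val >= u
      if (!any(allowed)) next
      grp <- sub_idx[used[sub_idx] == u]
      pick <- sample(names(cfg$hetero_elements)[allowed], length(grp),
                     replace = TRUE, prob = cfg$hetero_elements[allowed])
      elems[grp] <- pick
      freeval[grp] <- het_val[pick] - used[grp]
    }
  }

  # explicit hydrogens fill the remaining valence
  nH <- freeval * present
  nH[nH < 0L] <- 0L
  ord <- order(bm, method = "radix")
  bm <- bm[ord]; bi <- bi[ord]; bj <- bj[ord]
  bord <- bord[ord]; barom <- barom[ord]
  bsplit <- split(seq_along(bm), factor(bm, levels = seq_len(n)))
  elements <- vector("list", n); bonds <- vector("list", n)
  for (k in seq_len(n)) {
    hk <- h[k]
    nh_at <- nH[k, seq_len(hk)]
    el <- c(elems[k, seq_len(hk)], rep("H", sum(nh_at)))
    rows <- bsplit[[k]]
    hb_i <- rep(seq_len(hk), nh_at)
    hb_j <- hk + seq_len(sum(nh_at))
    bonds[[k]] <- cbind(i = c(bi[rows], hb_i),
                        j = c(bj[rows], hb_j),
                        order = c(bord[rows], rep(1L, length(hb_i))),
                        aromatic = c(barom[rows], rep(0L, length(hb_i))))
    elements[[k]] <- el
  }
  list(elements = elements, bonds = bonds)
}

# ---- idealized 3D embedding ----------------------------------------------

.bond_length_target <- function(m, b) {
  r <- covalent_radii(m$elements)
  fac <- ifelse(b[, "aromatic"] == 1L, 0.92,
                c(1.0, 0.87, 0.78)[b[, "order"]])
  (r[b[, "i"]] + r[b[, "j"]]) * fac
}

#' Idealized 3D embedding of a connection table
#'
#' Produces plausible (not DFT-quality) coordinates: atoms are placed
#' breadth-first along their bonds at covalent-radius-sum distances
#' (scaled down for double/triple/aromatic bonds), choosing at each step
#' the direction that stays farthest from already-placed atoms, then the
#' whole structure is relaxed with harmonic bond springs plus a soft
#' repulsion that keeps non-bonded pairs outside the bond-perception
#' threshold. Bonded distances end up well within +/-15% of the
#' covalent-radius sums, so [perceive_bonds()] recovers the intended
#' graph. Deterministic given the seed. A single atom is placed at the
#' origin.
#'
#' @param mols A `molecule_set` (or single `molecule`) with bond tables.
#' @param seed Integer seed for the direction sampling.
#' @param n_steps Relaxation iterations.
#' @return The input with coordinates set; molecules whose embedding
#'   fails to reproduce their bond graph are flagged via the
#'   `"embed_failed"` field and skipped by geometry stages.
#' @export
embed_3d <- function(mols, seed = 1L, n_steps = 150L) {
  single <- inherits(mols, "molecule")
  if (single) mols <- molecule_set(list(mols))
  out <- .with_seed(seed, lapply(mols, .embed_one, n_steps = n_steps))
  out <- structure(out, class = "molecule_set",
                   removed = attr(mols, "removed"))
  if (single) out[[1]] else out
}

.embed_one <- function(m, n_steps = 150L) {
  n <- length(m$elements)
  if (is.null(m$bonds)) stop("molecule ", m$id, " has no bond table")
  if (n == 1L) { m$coords <- matrix(0, 1, 3); return(m) }
  b <- m$bonds
  L <- .bond_length_target(m, b)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbr[[b[k, 1]]] <- c(nbr[[b[k, 1]]], b[k, 2])
    nbr[[b[k, 2]]] <- c(nbr[[b[k, 2]]], b[k, 1])
  }
  # BFS placement order
  ordr <- integer(0); seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; ordr <- c(ordr, v)
    nxt <- nbr[[v]][!seen[nbr[[v]]]]
    seen[nxt] <- TRUE; queue <- c(queue, nxt)
  }
  pos <- matrix(NA_real_, n, 3)
  pos[ordr[1], ] <- 0
  blen <- function(i, j) {
    hit <- which((b[, 1] == min(i, j)) & (b[, 2] == max(i, j)))
    if (length(hit)) L[hit[1]] else 1.5
  }
  placed <- ordr[1]
  for (v in ordr[-1]) {
    par <- nbr[[v]][nbr[[v]] %in% placed][1]
    ln <- blen(par, v)
    cand <- matrix(stats::rnorm(3 * 16), ncol = 3)
    cand <- cand / sqrt(rowSums(cand^2))
    trial <- sweep(cand * ln, 2, pos[par, ], "+")
    others <- setdiff(placed, par)
    score <- if (length(others)) {
      apply(trial, 1, function(p) {
        min(sqrt(colSums((t(pos[others, , drop = FALSE]) - p)^2)))
      })
    } else stats::runif(nrow(trial))
    pos[v, ] <- trial[which.max(score), ]
    placed <- c(placed, v)
  }
  # relaxation: springs on bonds, soft repulsion on close non-bonded pairs
  rr <- covalent_radii(m$elements)
  bonded <- matrix(FALSE, n, n)
  bonded[b[, 1:2, drop = FALSE]] <- TRUE
  bonded <- bonded | t(bonded)
  repd <- 1.45 * outer(rr, rr, "+")          # non-bonded target floor
  scatter <- function(grad, idx, fd, sign) {
    rs <- rowsum(fd, idx)
    at <- as.integer(rownames(rs))
    grad[at, ] <- grad[at, ] + sign * rs
    grad
  }
  close <- NULL
  for (it in seq_len(n_steps)) {
    dif <- pos[b[, 1], , drop = FALSE] - pos[b[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dif^2)); d[d < 1e-9] <- 1e-9
    f <- (L - d) / d                          # spring toward target length
    grad <- matrix(0, n, 3)
    grad <- scatter(grad, b[, 1], dif * f, 1)
    grad <- scatter(grad, b[, 2], dif * f, -1)
    if (it %% 5L == 1L) {
      # refresh the candidate repulsion pair list with some slack
      D <- as.matrix(stats::dist(pos)); diag(D) <- Inf
      close <- which(!bonded & D < repd + 1 & upper.tri(D),
                     arr.ind = TRUE)
    }
    if (!is.null(close) && nrow(close)) {
      dif2 <- pos[close[, 1], , drop = FALSE] -
        pos[close[, 2], , drop = FALSE]
      d2 <- sqrt(rowSums(dif2^2)); d2[d2 < 1e-9] <- 1e-9
      f2 <- 0.5 * pmax(repd[close] - d2, 0) / d2
      act <- f2 > 0
      if (any(act)) {
        grad <- scatter(grad, close[act, 1], dif2[act, , drop = FALSE] *
                          f2[act], 1)
        grad <- scatter(grad, close[act, 2], dif2[act, , drop = FALSE] *
                          f2[act], -1)
      }
    }
    pos <- pos + 0.35 * grad
  }
  m$coords <- pos
  m
}
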