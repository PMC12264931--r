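# The two corrective samplers: atom-count-matched downsampling of a
# generated set against a reference histogram, and latent-space grid
# flattening of a training set with automatic grid-resolution selection.

#' Resample plan container
#'
#' @param indices Selected indices into the source set.
#' @param method `"histogram_match"` or `"grid_flatten"`.
#' @param parameters Method parameters (target histogram or `n_grid`).
#' @param seed Integer seed that produced the selection.
#' @return An object of class `"resample_plan"`.
#' @export
resample_plan <- function(indices, method, parameters, seed) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("plan indices must be unique")
  structure(list(indices = indices, method = method,
                 parameters = parameters, seed = as.integer(seed)),
            class = "resample_plan")
}

#' @export
print.resample_plan <- function(x, ...) {
  cat(sprintf("<resample_plan %s> %d molecules selected (seed %d)\n",
              x$method, length(x$indices), x$seed))
  invisible(x)
}

#' Serialize / replay a resample plan
#'
#' Plans are serialized as JSON (indices, method, parameters, seed) so a
#' resampling step can be replayed bit-exactly later.
#'
#' @param plan A `resample_plan`.
#' @param path JSON file path.
#' @return `write_resample_plan`: the path, invisibly;
#'   `read_resample_plan`: the plan.
#' @export
write_resample_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_resample_plan
#' @export
read_resample_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  resample_plan(x$indices, x$method, x$parameters, x$seed)
}

#' Apply a resample plan to a molecule set
#'
#' @param mols The source `molecule_set` the plan was computed on.
#' @param plan A `resample_plan`.
#' @return The selected subset, in source order.
#' @export
apply_resample_plan <- function(mols, plan) {
  if (length(plan$indices) &&
      (max(plan$indices) > length(mols) || min(plan$indices) < 1L)) {
    stop("plan indices out of bounds for this set")
  }
  mols[sort(plan$indices)]
}

#' Histogram-matched downsampling
#'
#' Selects a subset of `source` whose distribution of an integer key
#' (by default the total atom count) matches the `reference` set's
#' histogram: with reference bin probabilities `p_b` and source
#' availability `a_b`, the feasible scale is `s = min over bins with
#' p_b > 0 of a_b / p_b`; each bin contributes `floor(s * p_b)` molecules
#' sampled uniformly without replacement. This yields the reference's
#' histogram shape at the largest feasible sample size (per-bin deviation
#' at most 1 from rounding).
#'
#' @param source `molecule_set` to downsample (or an integer key vector).
#' @param reference `molecule_set` defining the target histogram (or an
#'   integer key vector).
#' @param key Function mapping a molecule set to integer keys; default
#'   [atom_counts()].
#' @param seed Integer seed.
#' @return A [resample_plan()] with method `"histogram_match"`. Reference
#'   bins with probability mass but no source availability trigger a
#'   coverage warning.
#' @export
downsample_to_histogram <- function(source, reference,
                                    key = atom_counts, seed = 1L) {
  ks <- if (is.numeric(source)) as.integer(source)
        else as.integer(key(source))
  kr <- if (is.numeric(reference)) as.integer(reference)
        else as.integer(key(reference))
  if (!length(ks) || !length(kr)) stop("both sets must be non-empty")
  ref_tab <- table(kr)
  p <- as.numeric(ref_tab) / sum(ref_tab)
  bins <- as.integer(names(ref_tab))
  avail <- vapply(bins, function(b) sum(ks == b), numeric(1))
  uncovered <- avail == 0 & p > 0
  if (any(uncovered)) {
    warning("no source molecules for reference key value(s): ",
            paste(bins[uncovered], collapse = ", "),
            " - those bins stay empty")
  }
  covered <- p > 0 & avail > 0
  if (!any(covered)) stop("source covers no reference histogram bin")
  s <- min(avail[covered] / p[covered])
  quota <- ifelse(covered, floor(s * p), 0)
  sel <- .with_seed(seed, {
    unlist(lapply(seq_along(bins), function(bi) {
      pool <- which(ks == bins[bi])
      if (quota[bi] <= 0L || !length(pool)) return(integer(0))
      if (length(pool) == 1L && quota[bi] >= 1L) return(pool)
      sample(pool, min(quota[bi], length(pool)))
    }))
  })
  resample_plan(sort(sel), "histogram_match",
                parameters = list(reference_bins = bins,
                                  reference_probs = p,
                                  scale = s, quota = as.integer(quota)),
                seed = seed)
}

#' Grid flattening of latent points
#'
#' Splits the bounding box of the latent plane into `n_grid x n_grid`
#' equal rectangles (each axis divided over its own range) and keeps
#' exactly one uniformly chosen molecule per occupied rectangle, which
#' balances the density of the set over chemical space.
#'
#' @param points Latent coordinates (data.frame with
#'   `structural_pc1`/`bonding_pc1`, or a 2-column matrix).
#' @param n_grid Number of grid divisions per axis (>= 1).
#' @param seed Integer seed for the within-cell choice.
#' @return A [resample_plan()] with method `"grid_flatten"`; the number
#'   of selected molecules equals the number of occupied cells.
#' @export
grid_flatten <- function(points, n_grid, seed = 1L) {
  xy <- .as_xy(points)
  if (!nrow(xy)) stop("no points to flatten")
  if (n_grid < 1L) stop("n_grid must be >= 1")
  cell <- .grid_cells(xy, n_grid)
  sel <- .with_seed(seed, {
    vapply(split(seq_len(nrow(xy)), cell), function(idx) {
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }, integer(1))
  })
  resample_plan(sort(unname(sel)), "grid_flatten",
                parameters = list(n_grid = as.integer(n_grid)),
                seed = seed)
}

.grid_cells <- function(xy, n_grid) {
  bin1 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(1L, length(v)))
    idx <- findInterval(v, seq(rng[1], rng[2], length.out = n_grid + 1),
                        rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(idx, 1L), n_grid)
  }
  (bin1(xy[, 1]) - 1L) * n_grid + bin1(xy[, 2])
}

#' Select the grid resolution for flattening
#'
#' For each candidate `n_grid`, flattens the points, fits a KDE to the
#' survivors and scores the remaining spatial localization as the
#' coefficient of variation of the survivors' self-density (a perfectly
#' de-localized sample scores 0). Returns the candidate minimizing the
#' score; ties go to the smallest candidate. Candidates keeping fewer
#' than 10 survivors are excluded with a warning.
#'
#' @param points Latent coordinates.
#' @param candidates Integer vector of grid resolutions to try.
#' @param seed Integer seed (each candidate uses a seed derived from it).
#' @return List: `n_grid` (chosen), `curve` (data.frame: n_grid,
#'   survivors, score), `plan` (the winning [resample_plan()]).
#' @export
select_n_grid <- function(points, candidates = c(5L, 10L, 20L, 35L, 50L),
                          seed = 1L) {
  if (!length(candidates)) stop("no candidates")
  xy <- .as_xy(points)
  rows <- lapply(sort(unique(as.integer(candidates))), function(g) {
    plan <- grid_flatten(xy, g, seed = derive_seed(seed, paste0("g", g)))
    surv <- xy[plan$indices, , drop = FALSE]
    if (nrow(surv) < 10L) {
      warning("n_grid = ", g, " keeps fewer than 10 molecules; excluded")
      return(NULL)
    }
    bw <- pmax(apply(surv, 2, stats::sd), 1e-9) * nrow(surv)^(-1 / 6)
    dens <- kde2d_at(surv, surv, bw)
    list(n_grid = g, survivors = nrow(surv),
         score = stats::sd(dens) / mean(dens), plan = plan)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no feasible grid resolution among candidates")
  curve <- data.frame(n_grid = vapply(rows, `[[`, numeric(1), "n_grid"),
                      survivors = vapply(rows, `[[`, numeric(1),
                                         "survivors"),
                      score = vapply(rows, `[[`, numeric(1), "score"))
  best <- which.min(curve$score)     # ties: first = smallest candidate
  list(n_grid = as.integer(curve$n_grid[best]), curve = curve,
       plan = rows[[best]]$plan)
}
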