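# The 2D latent chemical space: independent PCAs on the structural and
# bonding descriptor matrices (fit on the concatenation of all datasets
# being compared), a kernel density map of the resulting plane, and a
# two-stage clustering that works across concatenated datasets.

#' Fit the latent chemical-space map
#'
#' Fits one PCA per descriptor on the concatenated population and maps
#' every molecule to (structural PC1 score, bonding PC1 score). Centering
#' only, no scaling; all principal components are stored but only PC1 of
#' each descriptor spans the latent plane.
#'
#' @param structural Numeric matrix (molecules x structural features) for
#'   the whole concatenated population.
#' @param bonding Numeric matrix (molecules x bonding features), same
#'   rows.
#' @param labels Optional per-molecule dataset labels carried through to
#'   the scores.
#' @return An object of class `"latent_map"` with fields `scores`
#'   (data.frame: id, label, structural_pc1, bonding_pc1),
#'   `explained_variance` (fraction of variance in PC1 per descriptor),
#'   and the fitted centers/loadings.
#' @export
fit_latent_map <- function(structural, bonding, labels = NULL) {
  stopifnot(is.matrix(structural), is.matrix(bonding),
            nrow(structural) == nrow(bonding))
  if (nrow(structural) < 3L) stop("need at least 3 molecules to fit")
  fit_one <- function(x, what) {
    keep <- which(apply(x, 2, stats::var) > 0)
    if (!length(keep)) {
      stop("degenerate fit: all ", what, " descriptor columns constant")
    }
    p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                       scale. = FALSE)
    list(keep = keep, center = p$center, rotation = p$rotation,
         ev1 = p$sdev[1]^2 / sum(p$sdev^2), scores1 = p$x[, 1])
  }
  fs <- fit_one(structural, "structural")
  fb <- fit_one(bonding, "bonding")
  ids <- rownames(structural)
  if (is.null(ids)) ids <- sprintf("mol%05d", seq_len(nrow(structural)))
  scores <- data.frame(id = ids,
                       label = if (is.null(labels)) NA_character_
                               else labels,
                       structural_pc1 = unname(fs$scores1),
                       bonding_pc1 = unname(fb$scores1),
                       stringsAsFactors = FALSE)
  structure(list(scores = scores,
                 explained_variance = c(structural = fs$ev1,
                                        bonding = fb$ev1),
                 structural_fit = fs[c("keep", "center", "rotation")],
                 bonding_fit = fb[c("keep", "center", "rotation")],
                 n_fit = nrow(structural)),
            class = "latent_map")
}

#' @export
print.latent_map <- function(x, ...) {
  cat(sprintf(paste0("<latent_map> %d molecules; PC1 variance fraction: ",
                     "structural %.1f%%, bonding %.1f%%\n"),
              x$n_fit, 100 * x$explained_variance["structural"],
              100 * x$explained_variance["bonding"]))
  invisible(x)
}

#' Project new descriptor matrices through a fitted latent map
#'
#' Affine projection with the stored centers and loadings; no refit.
#' Projecting the fit population reproduces the fit scores exactly.
#'
#' @param map A [fit_latent_map()] result.
#' @param structural,bonding Descriptor matrices with the same feature
#'   registries (column sets) as the fit.
#' @param labels Optional labels.
#' @return data.frame like `map$scores`.
#' @export
project_latent <- function(map, structural, bonding, labels = NULL) {
  stopifnot(inherits(map, "latent_map"))
  proj <- function(x, fit, what) {
    if (ncol(x) < max(fit$keep)) {
      stop(what, " feature registry does not match the fitted map")
    }
    xs <- x[, fit$keep, drop = FALSE]
    if (!identical(colnames(xs), names(fit$center))) {
      stop(what, " feature registry does not match the fitted map")
    }
    sweep(xs, 2, fit$center) %*% fit$rotation[, 1]
  }
  s1 <- proj(structural, map$structural_fit, "structural")
  b1 <- proj(bonding, map$bonding_fit, "bonding")
  ids <- rownames(structural)
  if (is.null(ids)) ids <- sprintf("new%05d", seq_len(nrow(structural)))
  data.frame(id = ids,
             label = if (is.null(labels)) NA_character_ else labels,
             structural_pc1 = as.numeric(s1),
             bonding_pc1 = as.numeric(b1), stringsAsFactors = FALSE)
}

#' 2D kernel density estimate over latent points
#'
#' Gaussian-kernel density on a regular grid covering the data bounding
#' box (padded by 3.5 bandwidths so the grid captures essentially all
#' kernel mass; the grid sum times the cell area is 1 within ~2%).
#' Bandwidth is the per-axis Gaussian kernel standard deviation,
#' defaulting to Scott's rule `sd * n^(-1/6)`.
#'
#' @param points data.frame or matrix whose first two numeric columns
#'   (or `structural_pc1`/`bonding_pc1`) are the coordinates.
#' @param bandwidth Numeric length-2 (or 1, recycled) kernel sd; `NULL`
#'   for Scott's rule.
#' @param grid_size Grid nodes per axis.
#' @return List of class `"latent_kde"`: `x`, `y` (grid node vectors),
#'   `z` (density matrix), `bandwidth`.
#' @export
latent_kde2d <- function(points, bandwidth = NULL, grid_size = 100L) {
  xy <- .as_xy(points)
  if (nrow(xy) < 2L) stop("need at least 2 points for a KDE")
  sx <- stats::sd(xy[, 1]); sy <- stats::sd(xy[, 2])
  if (sx == 0 && sy == 0) stop("zero-variance point cloud")
  if (is.null(bandwidth)) {
    n <- nrow(xy)
    bandwidth <- c(sx, sy) * n^(-1 / 6)
    bandwidth[bandwidth == 0] <- max(bandwidth) * 1e-3
  }
  bandwidth <- rep(bandwidth, length.out = 2)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  pad <- 3.5 * bandwidth
  lims <- c(min(xy[, 1]) - pad[1], max(xy[, 1]) + pad[1],
            min(xy[, 2]) - pad[2], max(xy[, 2]) + pad[2])
  # MASS::kde2d uses h/4 as the Gaussian kernel sd
  k <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * bandwidth, n = grid_size,
                   lims = lims)
  structure(list(x = k$x, y = k$y, z = k$z, bandwidth = bandwidth),
            class = "latent_kde")
}

.as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("structural_pc1", "bonding_pc1") %in% names(points))) {
      return(cbind(points$structural_pc1, points$bonding_pc1))
    }
    num <- points[vapply(points, is.numeric, logical(1))]
    return(as.matrix(num[, 1:2]))
  }
  as.matrix(points)[, 1:2, drop = FALSE]
}

#' Evaluate a Gaussian KDE exactly at arbitrary points
#'
#' Direct kernel sum (no grid interpolation); used by the grid-resolution
#' selector's uniformity score.
#'
#' @param xy Data matrix (n x 2) defining the density.
#' @param at Matrix of evaluation points (m x 2).
#' @param bandwidth Per-axis kernel sd (length 2).
#' @return Numeric vector of densities at `at`.
#' @export
kde2d_at <- function(xy, at, bandwidth) {
  bandwidth <- rep(bandwidth, length.out = 2)
  dx <- outer(at[, 1], xy[, 1], "-") / bandwidth[1]
  dy <- outer(at[, 2], xy[, 2], "-") / bandwidth[2]
  rowMeans(exp(-0.5 * (dx^2 + dy^2))) /
    (2 * pi * bandwidth[1] * bandwidth[2])
}

#' Cluster latent points (two-stage: subclusters, then merging)
#'
#' Stage one builds fine-grained subclusters with an incremental
#' clustering-feature (leader) pass: each point joins the nearest
#' subcluster centroid within `threshold`, otherwise starts a new
#' subcluster. The threshold is auto-tuned downward until at least
#' `4 * n_clusters` subclusters exist. Stage two merges subcluster
#' centroids by Ward agglomeration to the requested cluster count, which
#' lets clusters take very different sizes. Clustering the concatenation
#' of several datasets assigns co-located molecules from different sets
#' to the same cluster.
#'
#' @param points Latent coordinates (see [latent_kde2d()] for accepted
#'   forms).
#' @param n_clusters Final number of clusters.
#' @param threshold Initial subcluster radius; `NULL` for auto.
#' @return An object of class `"cluster_assignment"`: `cluster`
#'   (integer vector), `n_clusters`, `sizes`, `centroids`,
#'   `subclusters`, `threshold`.
#' @export
cluster_latent <- function(points, n_clusters = 25L, threshold = NULL) {
  xy <- .as_xy(points)
  n <- nrow(xy)
  if (n < n_clusters) stop("fewer points than clusters")
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  span <- max(apply(xy, 2, function(v) diff(range(v))))
  if (is.null(threshold)) threshold <- span / 10
  if (threshold <= 0 || span == 0) threshold <- 1e-8
  repeat {
    sub <- .leader_pass(xy, threshold)
    if (max(sub$id) >= min(4L * n_clusters, n) || threshold < 1e-10)
      break
    threshold <- threshold / 2
  }
  cent <- sub$centroids
  if (n_clusters == 1L) {
    cl <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::dist(cent), method = "ward.D2")
    merge_id <- stats::cutree(hc, k = n_clusters)
    cl <- merge_id[sub$id]
  }
  sizes <- tabulate(cl, n_clusters)
  centroids <- t(vapply(seq_len(n_clusters), function(k) {
    colMeans(xy[cl == k, , drop = FALSE])
  }, numeric(2)))
  structure(list(cluster = cl, n_clusters = n_clusters, sizes = sizes,
                 centroids = centroids, subclusters = max(sub$id),
                 threshold = threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(paste0("<cluster_assignment> %d points in %d clusters ",
                     "(sizes %s; %d subclusters, threshold %.3g)\n"),
              length(x$cluster), x$n_clusters,
              paste(range(x$sizes), collapse = "-"), x$subclusters,
              x$threshold))
  invisible(x)
}

# incremental leader pass: assign each point to the nearest existing
# subcluster centroid if closer than `threshold`, else open a new one;
# centroids are running means (clustering features n, linear sum)
.leader_pass <- function(xy, threshold) {
  n <- nrow(xy)
  cap <- min(n, 4096L)
  cent <- matrix(NA_real_, cap, 2)
  cnt <- integer(cap)
  id <- integer(n)
  k <- 0L
  th2 <- threshold^2
  for (i in seq_len(n)) {
    if (k > 0L) {
      d2 <- (cent[1:k, 1] - xy[i, 1])^2 + (cent[1:k, 2] - xy[i, 2])^2
      j <- which.min(d2)
    }
    if (k > 0L && d2[j] <= th2) {
      id[i] <- j
      cnt[j] <- cnt[j] + 1L
      cent[j, ] <- cent[j, ] + (xy[i, ] - cent[j, ]) / cnt[j]
    } else {
      k <- k + 1L
      if (k > nrow(cent)) {
        cent <- rbind(cent, matrix(NA_real_, nrow(cent), 2))
        cnt <- c(cnt, integer(length(cnt)))
      }
      cent[k, ] <- xy[i, ]
      cnt[k] <- 1L
      id[i] <- k
    }
  }
  list(id = id, centroids = cent[1:k, , drop = FALSE], counts = cnt[1:k])
}
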