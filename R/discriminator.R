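# Decision-tree train-vs-generated discriminator: stratified splitting,
# balanced class weights, depth selection on a validation set, balanced
# accuracy on a held-out test set, and impurity-based feature importances.

#' Balanced accuracy
#'
#' Mean of per-class recalls; robust to class imbalance.
#'
#' @param truth Factor or character vector of true labels.
#' @param pred Predicted labels.
#' @return Numeric in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

#' Stratified train/validation/test split
#'
#' Per class: 20% of molecules go to the test set; the remainder is
#' split 90:10 into train and validation. Partitions are disjoint and
#' exhaustive, and identical for identical seeds.
#'
#' @param labels Class labels (two classes, >= 10 molecules each).
#' @param seed Integer seed.
#' @param test_frac,val_frac Held-out fractions (of the whole set and of
#'   the non-test remainder respectively).
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(labels, seed = 1L, test_frac = 0.2,
                       val_frac = 0.1) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need both classes present")
  if (any(table(labels) < 10L)) stop("need >= 10 molecules per class")
  parts <- .with_seed(seed, {
    out <- list(train = integer(0), validation = integer(0),
                test = integer(0))
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_test <- round(test_frac * n)
      n_val <- round(val_frac * (n - n_test))
      out$test <- c(out$test, idx[seq_len(n_test)])
      out$validation <- c(out$validation,
                          idx[n_test + seq_len(n_val)])
      out$train <- c(out$train, idx[-seq_len(n_test + n_val)])
    }
    out
  })
  lapply(parts, sort)
}

# depth of an rpart node, root = 0
.rpart_depths <- function(fit) {
  floor(log2(as.integer(rownames(fit$frame))))
}

# impurity-based feature importances of an rpart tree: the improvement
# of each primary split, summed per feature and normalized to 1
.tree_importances <- function(fit) {
  fr <- fit$frame
  sp <- fit$splits
  if (is.null(sp) || !nrow(sp) || all(fr$var == "<leaf>")) {
    return(numeric(0))
  }
  internal <- which(fr$var != "<leaf>")
  imp <- numeric(0)
  row <- 1L
  for (k in seq_len(nrow(fr))) {
    if (fr$var[k] == "<leaf>") next
    nblock <- 1L + fr$ncompete[k] + fr$nsurrogate[k]
    v <- rownames(sp)[row]
    gain <- sp[row, "improve"]
    imp[v] <- (if (is.na(imp[v])) 0 else imp[v]) + gain
    row <- row + nblock
  }
  imp <- imp[imp > 0]
  if (!length(imp)) return(numeric(0))
  sort(imp / sum(imp), decreasing = TRUE)
}

# truncate a grown tree to the given depth: internal nodes at depth d
# become leaves, giving a nested family of trees indexed by depth
.truncate_tree <- function(fit, d) {
  dep <- .rpart_depths(fit)
  cut_at <- as.integer(rownames(fit$frame))[dep == d &
                                              fit$frame$var != "<leaf>"]
  if (!length(cut_at)) return(fit)
  rpart::snip.rpart(fit, toss = cut_at)
}

#' Train the train-vs-generated decision-tree discriminator
#'
#' Trees use class weights inversely proportional to class frequency.
#' One tree is grown greedily to the deepest depth in `depth_range` and
#' truncated to each candidate depth, giving a nested one-tree-per-depth
#' family; the depth maximizing validation balanced accuracy is selected
#' (ties: shallowest), then test balanced accuracy and impurity-based
#' feature importances (split improvements of the selected tree, summed
#' per feature and normalized) are reported. A discriminator stuck at balanced accuracy ~0.5 on separable
#' features (e.g. all-constant inputs) is flagged, not an error.
#'
#' @param features Numeric matrix, molecules x features (finite values).
#' @param labels Two-class labels aligned with the rows.
#' @param depth_range Integer depths to sweep (default 3:17).
#' @param seed Integer seed (controls the split).
#' @param split Optional precomputed [split_data()] partition.
#' @param top_k Number of top features reported (default 5).
#' @return An object of class `"mol_discriminator"`.
#' @export
fit_discriminator <- function(features, labels, depth_range = 3:17,
                              seed = 1L, split = NULL, top_k = 5L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (!all(is.finite(features))) stop("features must be finite")
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("need exactly two classes")
  if (is.null(split)) split <- split_data(labels, seed = seed)
  depth_range <- sort(unique(as.integer(depth_range)))

  df <- as.data.frame(features)
  names(df) <- make.names(colnames(features), unique = TRUE)
  df$.y <- labels
  w <- as.numeric(length(labels) /
                    (nlevels(labels) * table(labels)[labels]))

  tr <- split$train
  fit_full <- .with_seed(derive_seed(seed, "tree"), {
    rpart::rpart(.y ~ ., data = df[tr, , drop = FALSE],
                 weights = w[tr], method = "class",
                 control = rpart::rpart.control(
                   # rpart counts the root as depth 1; "+ 1" makes depth
                   # mean the number of split levels along a path
                   maxdepth = min(max(depth_range) + 1L, 30L), cp = 0,
                   xval = 0, minsplit = 4, minbucket = 2))
  })
  val_acc <- vapply(depth_range, function(d) {
    td <- .truncate_tree(fit_full, d)
    pred <- predict(td, df[split$validation, , drop = FALSE],
                    type = "class")
    balanced_accuracy(labels[split$validation], pred)
  }, numeric(1))
  chosen <- depth_range[which.max(val_acc)]   # ties: shallowest

  tree <- .truncate_tree(fit_full, chosen)
  test_pred <- predict(tree, df[split$test, , drop = FALSE],
                       type = "class")
  test_ba <- balanced_accuracy(labels[split$test], test_pred)

  importances <- .tree_importances(tree)
  degenerate <- !length(importances)
  structure(list(chosen_depth = chosen,
                 validation = data.frame(depth = depth_range,
                                         balanced_accuracy = val_acc),
                 test_balanced_accuracy = test_ba,
                 importances = importances,
                 top_features = utils::head(
                   sort(importances, decreasing = TRUE), top_k),
                 seed = seed, split = split,
                 class_sizes = as.integer(table(labels)),
                 classes = levels(labels),
                 degenerate = degenerate,
                 tree = tree),
            class = "mol_discriminator")
}

#' @export
print.mol_discriminator <- function(x, ...) {
  cat(sprintf(paste0("<mol_discriminator> depth %d, test balanced ",
                     "accuracy %.3f%s\n"),
              x$chosen_depth, x$test_balanced_accuracy,
              if (x$degenerate) " [degenerate: no splits]" else ""))
  if (length(x$top_features)) {
    cat("  top features:",
        paste(sprintf("%s (%.2f)", names(x$top_features),
                      x$top_features), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
predict.mol_discriminator <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  names(df) <- make.names(colnames(newdata), unique = TRUE)
  predict(object$tree, df, type = "class")
}

#' Discriminator sensitivity to injected generation bias
#'
#' Turns the discriminator into a sensitivity instrument: for each bias
#' shift level, paired synthetic sets are generated (reference at shift
#' 0, candidate at the given shift), featurized with circular
#' fingerprints, split, and a discriminator is trained; the mean test
#' balanced accuracy per shift traces the power curve. At shift 0 the
#' sets are exchangeable and accuracy stays near 0.5; it rises towards 1
#' as the shift grows.
#'
#' @param cfg Base [generator_config()].
#' @param shift_levels Numeric shifts in `[0, 1]`.
#' @param n_per_set Molecules per set and side.
#' @param seeds Integer vector; each seed is one full replicate.
#' @param n_bits Fingerprint length used for featurization.
#' @param augment_counts Append element-count features.
#' @return data.frame with columns `shift`, `seed`,
#'   `balanced_accuracy`; attribute `"summary"` has per-shift means.
#' @export
bias_power_curve <- function(cfg, shift_levels = c(0, 0.25, 0.5, 0.75, 1),
                             n_per_set = 500L, seeds = 1:3,
                             n_bits = 256L, augment_counts = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  rows <- list()
  for (s in shift_levels) {
    cfg_s <- bias_config(cfg, s)
    for (sd in seeds) {
      ref <- generate_molecule_set(cfg, n_per_set, label = "train",
                                   seed = derive_seed(sd, "ref"),
                                   emit_smiles = FALSE)
      gen <- generate_molecule_set(cfg_s, n_per_set, label = "generated",
                                   seed = derive_seed(sd, paste0("gen", s)),
                                   emit_smiles = FALSE)
      both <- molecule_set(c(unclass(ref), unclass(gen)))
      feats <- circular_fingerprints(both, n_bits = n_bits,
                                     augment_counts = augment_counts)
      lab <- set_labels(both)
      disc <- fit_discriminator(feats, lab, seed = derive_seed(sd, "split"))
      rows[[length(rows) + 1L]] <-
        data.frame(shift = s, seed = sd,
                   balanced_accuracy = disc$test_balanced_accuracy)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(balanced_accuracy ~ shift, out, mean)
  attr(out, "summary") <- agg
  out
}
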