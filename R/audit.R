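# End-to-end audit: filter -> (optional) atom-count downsampling ->
# composition/size/geometry statistics with two-sample tests ->
# substructure prevalence and ring classes -> descriptors, latent map,
# KDE and clusters -> decision-tree discriminator. The fitted object is
# the package's central result container.

#' Audit a generated molecule set against its training set
#'
#' Runs the full distribution-fidelity audit between a reference
#' ("train") set and a candidate ("generated") set and returns a fitted
#' audit object with `print()`, `summary()` and `plot()` methods. Stages
#' can be toggled; a stage that fails is recorded in `$errors` and its
#' dependents are skipped while the rest of the audit continues.
#'
#' Molecules must carry bond tables (from SDF input, [perceive_bonds()] +
#' [assign_bond_orders_and_aromaticity()] for raw XYZ, or the synthetic
#' generator). Geometry stages (bond-distance distributions, structural
#' descriptor) run only when coordinates are present or `embed = TRUE`.
#'
#' @param train Reference `molecule_set`.
#' @param generated Candidate `molecule_set`.
#' @param downsample Match the generated set's atom-count histogram to
#'   the training set before analysis (default `TRUE`).
#' @param latent Build descriptors, latent map, KDE and clusters.
#' @param discriminator Train the decision-tree discriminator.
#' @param embed Embed idealized 3D coordinates when absent (needed by
#'   geometry stages for connection-table-only input).
#' @param catalog A [group_catalog()] for prevalence analysis.
#' @param structural_cfg A [structural_config()].
#' @param schema A [bonding_schema()].
#' @param n_clusters Latent cluster count.
#' @param fp_bits,fp_augment Fingerprint settings for the discriminator.
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @return An object of class `"mol_audit"`.
#' @export
mol_audit <- function(train, generated, downsample = TRUE, latent = TRUE,
                      discriminator = TRUE, embed = FALSE,
                      catalog = group_catalog(),
                      structural_cfg = structural_config(),
                      schema = bonding_schema(catalog = catalog),
                      n_clusters = 10L, fp_bits = 1024L,
                      fp_augment = TRUE, seed = 0L) {
  stopifnot(inherits(train, "molecule_set"),
            inherits(generated, "molecule_set"))
  audit <- list(seed = seed, errors = list(),
                provenance = list(package = "molaudit",
                                  version = as.character(
                                    utils::packageVersion("molaudit")),
                                  seed = seed,
                                  timestamp = format(Sys.time(),
                                                     tz = "UTC")))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      audit$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  train <- molecule_set(train, label = "train")
  generated <- molecule_set(generated, label = "generated")

  # filtering (duplicates, disconnected, perception-invalid)
  ftr <- filter_set(train)
  fge <- filter_set(generated)
  audit$filter <- list(
    train = list(kept = length(ftr), removed = attr(ftr, "removed")),
    generated = list(kept = length(fge), removed = attr(fge, "removed")))
  if (!length(ftr) || !length(fge)) {
    stop("no molecules survive filtering")
  }

  # optional atom-count-matched downsampling of the generated set
  if (downsample) {
    plan <- run_stage("downsample", {
      downsample_to_histogram(fge, ftr, seed = derive_seed(seed,
                                                           "downsample"))
    })
    if (!is.null(plan)) {
      audit$downsample_plan <- plan
      fge <- apply_resample_plan(fge, plan)
    }
  }
  audit$n_train <- length(ftr)
  audit$n_generated <- length(fge)

  has_xyz <- function(ms) all(vapply(ms, function(m) !is.null(m$coords),
                                     logical(1)))
  if (embed && !has_xyz(ftr)) {
    ftr <- embed_3d(ftr, seed = derive_seed(seed, "embed_train"))
  }
  if (embed && !has_xyz(fge)) {
    fge <- embed_3d(fge, seed = derive_seed(seed, "embed_gen"))
  }
  audit$train_set <- ftr
  audit$generated_set <- fge

  # composition / size / mass + two-sample tests
  audit$composition <- run_stage("composition", {
    list(train = elemental_composition(ftr),
         generated = elemental_composition(fge))
  })
  audit$size_mass <- run_stage("size_mass", {
    st <- size_and_mass_distributions(ftr)
    sg <- size_and_mass_distributions(fge)
    list(train = st, generated = sg,
         tests = list(
           mw_welch = welch_t(st$values$molecular_weight,
                              sg$values$molecular_weight),
           mw_ks = ks_two_sample(st$values$molecular_weight,
                                 sg$values$molecular_weight),
           atoms_ks = ks_two_sample(st$values$atom_count,
                                    sg$values$atom_count)))
  })

  # bonded C-C distances (geometry)
  if (has_xyz(ftr) && has_xyz(fge)) {
    audit$cc_distances <- run_stage("cc_distances", {
      ht <- bonded_distance_distribution(ftr, "C", "C")
      hg <- bonded_distance_distribution(fge, "C", "C")
      dt <- attr(ht, "distances"); dg <- attr(hg, "distances")
      list(train = ht, generated = hg,
           ks = if (length(dt) && length(dg)) ks_two_sample(dt, dg))
    })
  }

  # substructure prevalence and ring classes
  audit$groups <- run_stage("groups", {
    list(train = group_prevalence(ftr, catalog),
         generated = group_prevalence(fge, catalog))
  })
  audit$rings <- run_stage("rings", {
    list(train = ring_profiles(ftr), generated = ring_profiles(fge))
  })

  # latent chemical space (fit on the concatenation)
  if (latent) {
    audit$latent <- run_stage("latent", {
      both <- molecule_set(c(unclass(ftr), unclass(fge)))
      bd <- bonding_descriptors(both, schema)
      sd_ <- if (has_xyz(ftr) && has_xyz(fge)) {
        structural_descriptors(both, structural_cfg)
      } else {
        # connection-table-only audit: the bonding descriptor spans
        # both axes (recorded in the report)
        bd
      }
      map <- fit_latent_map(sd_, bd, labels = set_labels(both))
      kde <- latent_kde2d(map$scores)
      cl <- cluster_latent(map$scores, n_clusters = n_clusters)
      tab <- table(map$scores$label, cl$cluster)
      list(map = map, kde = kde, clusters = cl,
           cluster_table = tab,
           structural_is_bonding = !(has_xyz(ftr) && has_xyz(fge)))
    })
  }

  # decision-tree discriminator
  if (discriminator) {
    audit$discriminator <- run_stage("discriminator", {
      both <- molecule_set(c(unclass(ftr), unclass(fge)))
      fp <- circular_fingerprints(both, n_bits = fp_bits,
                                  augment_counts = fp_augment)
      fit_discriminator(fp, set_labels(both),
                        seed = derive_seed(seed, "discriminator"))
    })
  }

  structure(audit, class = "mol_audit")
}

#' @export
print.mol_audit <- function(x, ...) {
  cat("<mol_audit>\n")
  cat(sprintf("  train: %d molecules (removed: %s)\n", x$n_train,
              paste(names(x$filter$train$removed),
                    x$filter$train$removed, sep = "=", collapse = ", ")))
  cat(sprintf("  generated: %d molecules (removed: %s%s)\n",
              x$n_generated,
              paste(names(x$filter$generated$removed),
                    x$filter$generated$removed, sep = "=",
                    collapse = ", "),
              if (!is.null(x$downsample_plan)) "; atom-count downsampled"
              else ""))
  if (!is.null(x$size_mass)) {
    ks <- x$size_mass$tests$mw_ks
    wt <- x$size_mass$tests$mw_welch
    cat(sprintf("  molecular weight: KS D = %.3f (p = %.3g), Welch t = %.2f (p = %.3g)\n",
                ks$statistic, ks$p_value, wt$statistic, wt$p_value))
  }
  if (!is.null(x$latent)) {
    ev <- x$latent$map$explained_variance
    cat(sprintf("  latent map: PC1 variance %.0f%% (structural), %.0f%% (bonding); %d clusters\n",
                100 * ev[1], 100 * ev[2], x$latent$clusters$n_clusters))
  }
  if (!is.null(x$discriminator)) {
    cat(sprintf("  discriminator: depth %d, test balanced accuracy %.3f\n",
                x$discriminator$chosen_depth,
                x$discriminator$test_balanced_accuracy))
  }
  if (length(x$errors)) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.mol_audit <- function(object, ...) {
  x <- object
  comp <- NULL
  if (!is.null(x$composition)) {
    els <- union(names(x$composition$train), names(x$composition$generated))
    comp <- data.frame(
      element = els,
      train = as.numeric(x$composition$train[els]),
      generated = as.numeric(x$composition$generated[els]))
    comp[is.na(comp)] <- 0
    comp$difference <- comp$generated - comp$train
    comp <- comp[order(-abs(comp$difference)), ]
  }
  shifted_groups <- NULL
  if (!is.null(x$groups)) {
    g <- merge(x$groups$train[, c("name", "fraction")],
               x$groups$generated[, c("name", "fraction")],
               by = "name", suffixes = c("_train", "_generated"))
    g$difference <- g$fraction_generated - g$fraction_train
    shifted_groups <- g[order(-abs(g$difference)), ]
  }
  out <- list(composition = comp, groups = shifted_groups,
              tests = if (!is.null(x$size_mass)) x$size_mass$tests,
              discriminator = x$discriminator,
              errors = x$errors)
  class(out) <- "summary.mol_audit"
  out
}

#' @export
print.summary.mol_audit <- function(x, ...) {
  cat("Audit summary\n=============\n")
  if (!is.null(x$composition)) {
    cat("\nElemental composition (largest shifts first):\n")
    print(utils::head(x$composition, 8), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$groups)) {
    cat("\nFunctional-group prevalence (largest shifts first):\n")
    print(utils::head(x$groups, 8), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$tests)) {
    cat("\nMolecular weight tests:\n")
    print(x$tests$mw_welch); print(x$tests$mw_ks)
  }
  if (!is.null(x$discriminator)) print(x$discriminator)
  invisible(x)
}

#' @export
plot.mol_audit <- function(x, which = c("mw", "latent", "composition"),
                           ...) {
  which <- match.arg(which)
  if (which == "mw" && !is.null(x$size_mass)) {
    ht <- x$size_mass$train$molecular_weight
    hg <- x$size_mass$generated$molecular_weight
    xl <- range(ht$bin_edges, hg$bin_edges)
    plot(ht$bin_edges[-1], ht$density, type = "s", col = "grey30",
         xlab = "molecular weight [g/mol]", ylab = "density",
         xlim = xl, main = "Molecular weight")
    graphics::lines(hg$bin_edges[-1], hg$density, type = "s",
                    col = "firebrick")
    graphics::legend("topright", c("train", "generated"),
                     col = c("grey30", "firebrick"), lty = 1, bty = "n")
  } else if (which == "latent" && !is.null(x$latent)) {
    sc <- x$latent$map$scores
    cols <- ifelse(sc$label == "train", "grey40", "firebrick")
    plot(sc$structural_pc1, sc$bonding_pc1, col = cols, pch = 16,
         cex = 0.5, xlab = "structural PC1", ylab = "bonding PC1",
         main = "Latent chemical space")
    graphics::legend("topright", c("train", "generated"),
                     col = c("grey40", "firebrick"), pch = 16, bty = "n")
  } else if (which == "composition" && !is.null(x$composition)) {
    s <- summary(x)$composition
    graphics::barplot(t(as.matrix(s[, c("train", "generated")])),
                      beside = TRUE, names.arg = s$element,
                      legend.text = c("train", "generated"),
                      ylab = "fraction of atoms",
                      main = "Elemental composition")
  }
  invisible(x)
}

#' Write an audit report to disk
#'
#' Serializes the audit as a JSON report plus CSV tables (composition,
#' group prevalence, ring shares, latent coordinates, discriminator
#' depth sweep) under the given directory. The JSON is byte-stable for a
#' fixed config and inputs apart from the provenance timestamp field.
#'
#' @param audit A `mol_audit` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_audit_report <- function(audit, dir) {
  stopifnot(inherits(audit, "mol_audit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(audit)
  if (!is.null(s$composition)) {
    utils::write.csv(s$composition, file.path(dir, "composition.csv"),
                     row.names = FALSE)
  }
  if (!is.null(s$groups)) {
    utils::write.csv(s$groups, file.path(dir, "group_prevalence.csv"),
                     row.names = FALSE)
  }
  if (!is.null(audit$rings)) {
    utils::write.csv(cbind(set = "train",
                           as.data.frame(audit$rings$train$shares)),
                     file.path(dir, "ring_shares_train.csv"))
    utils::write.csv(cbind(set = "generated",
                           as.data.frame(audit$rings$generated$shares)),
                     file.path(dir, "ring_shares_generated.csv"))
  }
  if (!is.null(audit$latent)) {
    sc <- audit$latent$map$scores
    sc$cluster <- audit$latent$clusters$cluster
    utils::write.csv(sc, file.path(dir, "latent_coordinates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(audit$discriminator)) {
    utils::write.csv(audit$discriminator$validation,
                     file.path(dir, "discriminator_depths.csv"),
                     row.names = FALSE)
  }
  report <- list(
    provenance = audit$provenance,
    filter = audit$filter,
    n_train = audit$n_train,
    n_generated = audit$n_generated,
    downsample = if (!is.null(audit$downsample_plan))
      unclass(audit$downsample_plan),
    composition = audit$composition,
    tests = if (!is.null(audit$size_mass))
      lapply(audit$size_mass$tests, unclass),
    cc_distance_ks = if (!is.null(audit$cc_distances$ks))
      unclass(audit$cc_distances$ks),
    latent = if (!is.null(audit$latent)) list(
      explained_variance = audit$latent$map$explained_variance,
      n_clusters = audit$latent$clusters$n_clusters,
      cluster_sizes = audit$latent$clusters$sizes,
      structural_is_bonding = audit$latent$structural_is_bonding),
    discriminator = if (!is.null(audit$discriminator)) list(
      chosen_depth = audit$discriminator$chosen_depth,
      test_balanced_accuracy =
        audit$discriminator$test_balanced_accuracy,
      top_features = as.list(audit$discriminator$top_features),
      class_sizes = audit$discriminator$class_sizes),
    errors = audit$errors)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
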