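# Histogram-matched downsampling and latent-grid flattening.

test_that("downsampling follows the floor(s * p) quota rule", {
  # reference {5: 1, 10: 1}; source has 4 at key 5 and 2 at key 10
  src <- c(5, 5, 5, 5, 10, 10)
  ref <- c(5, 10)
  plan <- downsample_to_histogram(src, ref, seed = 2)
  ks <- src[plan$indices]
  expect_equal(sum(ks == 5), 2)
  expect_equal(sum(ks == 10), 2)

  # a source already proportional to the reference is kept whole
  src2 <- c(5, 5, 10, 10)
  plan2 <- downsample_to_histogram(src2, ref, seed = 2)
  expect_equal(sort(plan2$indices), 1:4)

  # uncovered reference bin: quota 0 plus a coverage warning
  expect_warning(p3 <- downsample_to_histogram(c(5, 5), c(5, 10),
                                               seed = 1),
                 "no source molecules")
  expect_true(all(c(5, 5)[p3$indices] == 5))
})

test_that("downsampling reproduces the reference histogram shape", {
  cfg <- generator_config(seed = 31)
  ref <- generate_molecule_set(cfg, 300, "train", seed = 1,
                               emit_smiles = FALSE)
  src <- generate_molecule_set(bias_config(cfg, 0.4), 900, "generated",
                               seed = 2, emit_smiles = FALSE)
  plan <- suppressWarnings(downsample_to_histogram(src, ref, seed = 3))
  ks_before <- ks_two_sample(atom_counts(ref), atom_counts(src))$statistic
  ks_after <- ks_two_sample(atom_counts(ref),
                            atom_counts(src)[plan$indices])$statistic
  expect_lte(ks_after, ks_before)

  # per-bin deviation from the scaled reference is rounding only (<= 1)
  p <- plan$parameters
  sel_keys <- atom_counts(src)[plan$indices]
  got <- vapply(p$reference_bins, function(b) sum(sel_keys == b),
                numeric(1))
  expect_true(all(abs(got - p$scale * p$reference_probs) <= 1 + 1e-9))
})

test_that("plans are deterministic and replay bit-exactly", {
  cfg <- generator_config(seed = 41)
  ref <- generate_molecule_set(cfg, 150, "train", seed = 4,
                               emit_smiles = FALSE)
  src <- generate_molecule_set(cfg, 300, "generated", seed = 5,
                               emit_smiles = FALSE)
  p1 <- suppressWarnings(downsample_to_histogram(src, ref, seed = 9))
  p2 <- suppressWarnings(downsample_to_histogram(src, ref, seed = 9))
  expect_identical(p1$indices, p2$indices)

  tf <- tempfile(fileext = ".json")
  write_resample_plan(p1, tf)
  p3 <- read_resample_plan(tf)
  expect_identical(p3$indices, p1$indices)
  expect_identical(set_smiles(apply_resample_plan(src, p3)),
                   set_smiles(apply_resample_plan(src, p1)))
})

test_that("grid flattening keeps one molecule per occupied cell", {
  # every point in its own cell -> all kept
  pts <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))
  plan <- grid_flatten(pts, n_grid = 4, seed = 1)
  expect_equal(sort(plan$indices), 1:4)

  # ten identical points -> exactly one kept
  one <- matrix(rep(c(0.5, 0.5), each = 10), ncol = 2)
  one <- one + 0   # all in one cell
  p1 <- grid_flatten(rbind(one, c(5, 5)), n_grid = 2, seed = 3)
  expect_equal(length(p1$indices), 2)

  # occupied-cell count equals a brute-force cell assignment
  set.seed(21)
  pts <- cbind(runif(400, 0, 10), runif(400, -5, 5))
  for (g in c(3, 7, 15)) {
    plan <- grid_flatten(pts, g, seed = 7)
    ex <- function(v) {
      br <- seq(min(v), max(v), length.out = g + 1)
      pmin(pmax(findInterval(v, br, rightmost.closed = TRUE,
                             all.inside = TRUE), 1), g)
    }
    occupied <- length(unique(paste(ex(pts[, 1]), ex(pts[, 2]))))
    expect_equal(length(plan$indices), occupied)
    expect_lte(length(plan$indices), g^2)
    # replay determinism
    expect_identical(plan$indices, grid_flatten(pts, g, seed = 7)$indices)
  }
})

test_that("grid-resolution selection optimizes de-localization", {
  # uniform cloud: scores are flat, tie rule returns a small candidate
  set.seed(31)
  unif <- cbind(runif(600), runif(600))
  sel <- select_n_grid(unif, candidates = c(5, 10, 15), seed = 2)
  expect_true(sel$n_grid %in% c(5, 10, 15))
  expect_equal(nrow(sel$curve), 3)

  # strongly bimodal cloud: flattening reduces localization vs raw data
  bim <- rbind(cbind(rnorm(500, 0, 0.2), rnorm(500, 0, 0.2)),
               cbind(rnorm(100, 4, 0.8), rnorm(100, 4, 0.8)))
  sel2 <- select_n_grid(bim, candidates = c(8, 16, 24), seed = 3)
  raw_bw <- apply(bim, 2, stats::sd) * nrow(bim)^(-1 / 6)
  raw_score <- stats::sd(kde2d_at(bim, bim, raw_bw)) /
    mean(kde2d_at(bim, bim, raw_bw))
  expect_lt(min(sel2$curve$score), raw_score)

  # candidates keeping < 10 survivors are excluded with a warning
  few <- cbind(runif(30), runif(30))
  expect_warning(s3 <- select_n_grid(few, candidates = c(1, 6), seed = 1),
                 "fewer than 10")
  expect_equal(s3$n_grid, 6)
})
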