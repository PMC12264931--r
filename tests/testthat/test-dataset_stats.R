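# Composition, size/mass and bonded-distance distributions, and the two
# two-sample tests.

test_that("elemental composition matches direct atom tallies", {
  ch4 <- molecule_set(list(fix_methane()))
  expect_equal(elemental_composition(ch4),
               sort(c(C = 0.2, H = 0.8), decreasing = TRUE))
  two <- molecule_set(list(fix_water(), fix_methane()))
  comp <- elemental_composition(two)
  expect_equal(comp[["H"]], 6 / 8)
  expect_equal(comp[["O"]], 1 / 8)
  expect_equal(comp[["C"]], 1 / 8)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
  expect_error(elemental_composition(molecule_set(list())), "empty")

  # brute-force tally oracle on a 500-molecule synthetic set
  ms <- generate_molecule_set(generator_config(seed = 2), 500,
                              emit_smiles = FALSE)
  comp <- elemental_composition(ms)
  all_atoms <- unlist(lapply(ms, function(m) m$elements))
  for (e in names(comp)) {
    expect_equal(comp[[e]], sum(all_atoms == e) / length(all_atoms))
  }
})

test_that("size and mass distributions use the standard mass table", {
  ch4 <- molecule_set(list(fix_methane()))
  sm <- size_and_mass_distributions(ch4)
  expect_equal(sm$values$atom_count, 5)
  expect_equal(sm$H_vs_total$n_H, 4)
  expect_equal(sm$values$molecular_weight, 16.04, tolerance = 0.01)

  ms <- generate_molecule_set(generator_config(seed = 4), 200,
                              emit_smiles = FALSE)
  sm <- size_and_mass_distributions(ms)
  expect_equal(mean(sm$values$atom_count),
               mean(vapply(ms, function(m) length(m$elements),
                           numeric(1))))
  # histograms conserve the total count
  expect_equal(sum(sm$atom_count$counts), length(ms))
  expect_equal(sum(sm$molecular_weight$counts), length(ms))
  # density normalization integrates to 1
  h <- mol_histogram(sm$values$molecular_weight,
                     seq(0, 600, by = 10), "density")
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)
})

test_that("bonded distance distributions pick out the named pair", {
  ms <- molecule_set(lapply(list(fix_ethane(), fix_ethene(),
                                 fix_ethyne()),
                            function(m) perceive_bonds(m)))
  h <- bonded_distance_distribution(ms, "C", "C")
  d <- attr(h, "distances")
  expect_equal(sort(d), c(1.20, 1.33, 1.54), tolerance = 1e-6)
  expect_equal(sum(h$counts), 3)

  # brute-force loop over every bond table
  brute <- c()
  for (m in ms) {
    for (k in seq_len(nrow(m$bonds))) {
      i <- m$bonds[k, "i"]; j <- m$bonds[k, "j"]
      if (m$elements[i] == "C" && m$elements[j] == "C") {
        brute <- c(brute, sqrt(sum((m$coords[i, ] - m$coords[j, ])^2)))
      }
    }
  }
  expect_equal(sort(d), sort(brute))
  expect_warning(bonded_distance_distribution(ms, "C", "Au"), "no C-Au")
})

test_that("welch_t reproduces the closed form and a permutation oracle", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  r <- welch_t(x, y)
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-6)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_error(welch_t(1, y), "at least 2")
  expect_error(welch_t(c(1, 1), c(1, 1)), "variance")

  # two-sided p close to a permutation distribution of |t|
  set.seed(7)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  obs <- abs(welch_t(x, y)$statistic)
  pool <- c(x, y)
  perm <- replicate(20000, {
    s <- sample(16, 8)
    abs(welch_t(pool[s], pool[-s])$statistic)
  })
  p_perm <- mean(perm >= obs)
  expect_equal(welch_t(x, y)$p_value, p_perm, tolerance = 0.02)
})

test_that("ks_two_sample equals the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(c(1, 2), c(1, 2))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$statistic, 1)
  set.seed(11)
  x <- rnorm(60); y <- rnorm(45, 0.3)
  r <- ks_two_sample(x, y)
  pooled <- sort(c(x, y))
  d_brute <- max(abs(vapply(pooled, function(t) {
    mean(x <= t) - mean(y <= t)
  }, numeric(1))))
  expect_equal(r$statistic, d_brute, tolerance = 1e-12)
  expect_gte(r$statistic, 0); expect_lte(r$statistic, 1)

  # invariance under a common strictly monotone transform
  r2 <- ks_two_sample(exp(x), exp(y))
  expect_equal(r2$statistic, r$statistic)
})

test_that("KS test is calibrated under the null", {
  set.seed(13)
  rej <- replicate(1000, {
    x <- rgamma(100, 2); y <- rgamma(100, 2)
    ks_two_sample(x, y)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
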