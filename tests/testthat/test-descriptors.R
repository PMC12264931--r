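# The structural power-spectrum descriptor, the bonding descriptor and
# circular fingerprints.

cfg3 <- structural_config(species = c("H", "C", "O"))

test_that("structural descriptor is invariant to rigid motion and order", {
  w <- fix_water()
  d1 <- structural_descriptors(w, cfg3)
  Q <- fix_rotation(3)
  w2 <- w
  w2$coords <- w$coords %*% Q + matrix(c(5, -3, 2), 3, 3, byrow = TRUE)
  d2 <- structural_descriptors(w2, cfg3)
  expect_lt(max(abs(d1 - d2)), 1e-8)

  perm <- c(2, 1, 3)
  w3 <- molecule(w$elements[perm], coords = w$coords[perm, ], id = "p")
  d3 <- structural_descriptors(w3, cfg3)
  expect_lt(max(abs(d1 - d3)), 1e-8)
})

test_that("single isolated atom matches the analytic l = 0 closed form", {
  a <- molecule("O", coords = matrix(0, 1, 3), id = "a")
  da <- structural_descriptors(a, cfg3)
  nz <- which(abs(da[1, ]) > 1e-12)
  expect_true(all(grepl("^O-O_.*_l0$", colnames(da)[nz])))

  # independent evaluation: orthonormalize the radial basis by hand and
  # integrate against the central Gaussian with stats::integrate
  rc <- cfg3$cutoff; nmax <- cfg3$n_radial
  alpha <- 1 / (2 * cfg3$sigma^2)
  a_ <- seq_len(nmax)
  p <- outer(a_, a_, "+") + 4
  S <- rc^(p + 3) * 2 / ((p + 1) * (p + 2) * (p + 3))
  es <- eigen(S, symmetric = TRUE)
  W <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  I <- vapply(seq_len(nmax), function(n) {
    stats::integrate(function(r) {
      vapply(r, function(rr) sum(W[n, ] * (rc - rr)^(a_ + 2)),
             numeric(1)) * exp(-alpha * r^2) * r^2
    }, 0, rc, rel.tol = 1e-12)$value
  }, numeric(1))
  cn <- sqrt(4 * pi) * I
  ut <- which(upper.tri(diag(nmax), diag = TRUE), arr.ind = TRUE)
  expected <- pi * sqrt(8) * cn[ut[, 1]] * cn[ut[, 2]]
  got <- da[1, grep("^O-O_.*_l0$", colnames(da))]
  expect_lt(max(abs(got - expected)), 1e-8)
})

test_that("well-separated dimer averages the monomer descriptors", {
  m1 <- fix_water()
  off <- 2 * cfg3$cutoff + 3
  m2 <- m1; m2$coords <- m1$coords + matrix(c(off, 0, 0), 3, 3,
                                            byrow = TRUE)
  dim_ <- molecule(c(m1$elements, m2$elements),
                   coords = rbind(m1$coords, m2$coords), id = "dimer")
  dd <- structural_descriptors(molecule_set(list(m1, m2, dim_)), cfg3)
  expect_lt(max(abs(dd[3, ] - (dd[1, ] + dd[2, ]) / 2)), 1e-10)
})

test_that("structural descriptor rejects unknown species", {
  au <- molecule("Au", coords = matrix(0, 1, 3))
  expect_error(structural_descriptors(au, cfg3), "Au")
})

test_that("bonding descriptor extracts schema features in order", {
  schema <- bonding_schema()
  ms <- fix_smiles_set(c("C methane", "c1ccccc1 benzene"))
  bd <- bonding_descriptors(ms, schema)
  expect_identical(colnames(bd), schema$name)
  expect_equal(unname(bd["methane", c("n_C", "n_H")]), c(1, 4))
  expect_equal(unname(bd["methane", "ring_saturated_3"]), 0)
  expect_equal(unname(bd["benzene", "ring_aromatic_6"]), 1)
  expect_equal(unname(bd["benzene", "bond_aromatic_C_C"]), 6)
  expect_equal(unname(bd["methane", "molecular_weight"]), 16.04,
               tolerance = 0.01)
  # non-negative except declared scalars (all families are counts or
  # non-negative scalars here)
  expect_true(all(bd >= 0))
})

test_that("bonding descriptor group family equals substructure counts", {
  ms <- generate_molecule_set(generator_config(seed = 6), 40, "train")
  ms <- filter_set(ms)
  schema <- bonding_schema()
  bd <- bonding_descriptors(ms, schema)
  cat <- attr(schema, "catalog")
  cnt <- group_counts(ms, cat)
  gcols <- paste0("group_", colnames(cnt))
  expect_equal(unname(bd[, gcols]), unname(cnt))
  # ring family equals ring_profiles per-molecule classes
  rp <- ring_profiles(ms)$per_molecule
  ring_cols <- grep("^ring_aromatic_", colnames(bd), value = TRUE)
  expect_equal(unname(rowSums(bd[, ring_cols, drop = FALSE])),
               as.numeric(rp$aromatic))
})

test_that("descriptors are invariant to atom reindexing", {
  ms <- fix_smiles_set("CCO ethanol")
  m <- ms[[1]]
  perm <- sample(length(m$elements))
  inv <- order(perm)
  b <- m$bonds
  b[, "i"] <- inv[b[, "i"]]; b[, "j"] <- inv[b[, "j"]]
  m2 <- molecule(m$elements[perm], bonds = b, id = m$id)
  m2$valid <- TRUE
  schema <- bonding_schema()
  expect_equal(bonding_descriptors(molecule_set(list(m)), schema)[1, ],
               bonding_descriptors(molecule_set(list(m2)), schema)[1, ])
  fp1 <- circular_fingerprints(molecule_set(list(m)), n_bits = 512)
  fp2 <- circular_fingerprints(molecule_set(list(m2)), n_bits = 512)
  expect_equal(unname(fp1[1, ]), unname(fp2[1, ]))
})

test_that("circular fingerprints distinguish and augment correctly", {
  ms <- fix_smiles_set(c("C methane", "CC ethane", "C methane2"))
  fp <- circular_fingerprints(ms, radius = 1, n_bits = 512)
  expect_equal(unname(fp[1, ]), unname(fp[3, ]))   # identical molecules
  expect_false(all(fp[1, ] == fp[2, ]))            # distinct environments
  expect_equal(ncol(fp), 512)

  els <- c("C", "H", "N", "O", "F", "S", "Cl")
  fpa <- circular_fingerprints(ms, radius = 2, n_bits = 512,
                               augment_counts = TRUE, elements = els)
  expect_equal(ncol(fpa), 512 + length(els) + 1)
  expect_equal(unname(fpa["methane", "heavy_atom_count"]), 1)
  expect_equal(unname(fpa["ethane", "n_H"]), 6)
  expect_error(circular_fingerprints(ms, n_bits = 1000), "power of two")

  bad <- ms; bad[[2]]$valid <- FALSE
  expect_error(circular_fingerprints(bad, n_bits = 512), "invalid")
})
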