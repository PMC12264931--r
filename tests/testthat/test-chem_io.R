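# Reading/writing molecule sets, distance-based bond perception, order
# and aromaticity assignment, and the validity/connectivity/duplicate
# filter.

test_that("XYZ round trip preserves elements and coordinates", {
  cfg <- generator_config(seed = 3)
  ms <- embed_3d(generate_molecule_set(cfg, 12, emit_smiles = FALSE),
                 seed = 4)
  tf <- tempfile(fileext = ".xyz")
  write_molecules(ms, tf, "xyz")
  back <- read_molecules(tf, "xyz")
  expect_length(back, length(ms))
  for (k in seq_along(ms)) {
    expect_identical(back[[k]]$elements, ms[[k]]$elements)
    expect_lt(max(abs(back[[k]]$coords - ms[[k]]$coords)), 1e-4)
    expect_equal(nrow(back[[k]]$bonds), 0)   # XYZ carries no bonds
  }
})

test_that("SDF round trip preserves geometry and bond tables", {
  cfg <- generator_config(seed = 8)
  ms <- embed_3d(generate_molecule_set(cfg, 10, emit_smiles = FALSE),
                 seed = 2)
  tf <- tempfile(fileext = ".sdf")
  write_molecules(ms, tf, "sdf")
  back <- read_molecules(tf, "sdf")
  expect_length(back, length(ms))
  for (k in seq_along(ms)) {
    expect_identical(back[[k]]$elements, ms[[k]]$elements)
    expect_lt(max(abs(back[[k]]$coords - ms[[k]]$coords)), 1e-4)
    a <- ms[[k]]$bonds; b <- back[[k]]$bonds
    o <- order(a[, 1], a[, 2]); o2 <- order(b[, 1], b[, 2])
    expect_identical(unname(a[o, c("i", "j")]),
                     unname(b[o2, c("i", "j")]))
  }
})

test_that("minimal records parse: H2 XYZ and SDF with bonds", {
  tf <- tempfile(fileext = ".xyz")
  writeLines(c("2", "hh", "H 0 0 0", "H 0.74 0 0"), tf)
  ms <- read_molecules(tf, "xyz")
  expect_identical(ms[[1]]$elements, c("H", "H"))
  expect_equal(nrow(ms[[1]]$bonds), 0)

  eth <- fix_smiles_set("CCO ethanol")
  expect_length(eth[[1]]$elements, 9)      # explicit hydrogens added
  expect_equal(nrow(eth[[1]]$bonds), 8)
  expect_true(all(eth[[1]]$bonds[, "order"] == 1))
})

test_that("malformed records are skipped with a warning, empty errors", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("CCO a", "zz((bad b", "CC c"), tf)
  expect_warning(ms <- read_molecules(tf, "smiles"), "skipped")
  expect_length(ms, 2)
  tf2 <- tempfile(); file.create(tf2)
  expect_error(read_molecules(tf2, "smiles"), "empty")
  expect_error(read_molecules(tempfile(), "xyz"), "not found")
})

test_that("bond perception applies the covalent-radius rule", {
  # r_H = 0.31: threshold 1.3 * 0.62 = 0.806
  expect_equal(nrow(perceive_bonds(fix_h2(0.74))$bonds), 1)
  expect_equal(nrow(perceive_bonds(fix_h2(1.00))$bonds), 0)
  expect_equal(formals(bond_perception_params)$covalent_radius_factor,
               1.3)
  # exactly at the threshold counts as bonded (<=)
  expect_equal(nrow(perceive_bonds(fix_h2(0.806))$bonds), 1)
  expect_error(perceive_bonds(molecule("Xx", coords = matrix(0, 1, 3))),
               "Xx")
})

test_that("perception is invariant to rotation, translation and order", {
  m <- fix_methane()
  b0 <- perceive_bonds(m)$bonds
  Q <- fix_rotation(5)
  m2 <- m; m2$coords <- m$coords %*% Q + matrix(c(3, -1, 7), 5, 3,
                                                byrow = TRUE)
  expect_identical(perceive_bonds(m2)$bonds, b0)
  perm <- c(2, 1, 4, 3, 5)
  m3 <- molecule(m$elements[perm], coords = m$coords[perm, ], id = "p")
  b3 <- perceive_bonds(m3)$bonds
  expect_equal(nrow(b3), nrow(b0))          # same bond count, new labels
})

test_that("order/aromaticity assignment covers canonical cases", {
  bz <- assign_bond_orders_and_aromaticity(perceive_bonds(fix_benzene()))
  cc <- bz$bonds[bz$elements[bz$bonds[, "i"]] == "C" &
                 bz$elements[bz$bonds[, "j"]] == "C", ]
  expect_equal(sum(cc[, "aromatic"]), 6)
  expect_match(bz$smiles, "c1ccccc1")

  ey <- assign_bond_orders_and_aromaticity(perceive_bonds(fix_ethyne()))
  expect_equal(sort(ey$bonds[, "order"]), c(1L, 1L, 3L))
  expect_true(ey$valid)

  # physically impossible geometry is flagged invalid, not an error
  cc2 <- perceive_bonds(molecule(c("C", "C"),
                                 coords = rbind(c(0, 0, 0), c(0.3, 0, 0)),
                                 id = "clash"))
  expect_false(assign_bond_orders_and_aromaticity(cc2)$valid)
})

test_that("filter_set removes duplicates, fragments and invalids", {
  ms <- fix_smiles_set(c("CCO a", "CCO b", "C c"))
  out <- filter_set(ms)
  expect_length(out, 2)
  expect_equal(unname(attr(out, "removed")["duplicate"]), 1L)

  # a disconnected record (two methane fragments)
  frag <- fix_smiles_set("C.C frag")
  expect_length(filter_set(frag), 0)
  expect_equal(unname(attr(filter_set(frag), "removed")["disconnected"]),
               1L)
})

test_that("filter_set is idempotent and output SMILES are unique", {
  cfg <- generator_config(seed = 21)
  ms <- generate_molecule_set(cfg, 100, "train")
  f1 <- filter_set(ms)
  f2 <- filter_set(f1)
  expect_identical(set_smiles(f1), set_smiles(f2))
  expect_false(anyDuplicated(set_smiles(f1)) > 0)
  expect_identical(unname(attr(f2, "removed")),
                   c(0L, 0L, 0L))
})

test_that("filter survivors match an independent brute-force filter", {
  cfg <- generator_config(seed = 33)
  ms <- generate_molecule_set(cfg, 100, "train")
  out <- filter_set(ms)
  # independent re-implementation of the three rules
  n_comp <- function(m) {
    n <- length(m$elements)
    adj <- matrix(FALSE, n, n)
    adj[m$bonds[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    seen <- logical(n); ncomp <- 0
    for (s in seq_len(n)) {
      if (seen[s]) next
      ncomp <- ncomp + 1
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (seen[v]) next
        seen[v] <- TRUE
        stack <- c(stack, which(adj[v, ] & !seen))
      }
    }
    ncomp
  }
  keep <- logical(length(ms)); seen_smi <- character(0)
  for (k in seq_along(ms)) {
    m <- ms[[k]]
    if (!isTRUE(m$valid) || is.na(m$smiles)) next
    if (n_comp(m) != 1) next
    if (m$smiles %in% seen_smi) next
    seen_smi <- c(seen_smi, m$smiles)
    keep[k] <- TRUE
  }
  expect_equal(length(out), sum(keep))
  expect_identical(set_smiles(out), set_smiles(ms)[keep])
})
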