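test_that("signature counts match hand-enumerable molecules", {
  # benzene: all atoms equivalent -> one height-1 signature with count 6
  fv <- featurize(parse_smiles("c1ccccc1"), signature_config(1))
  expect_length(fv$counts, 1)
  expect_equal(unname(fv$counts), 6L)

  # single heavy atom: one signature per height, count 1 each
  fv <- featurize(parse_smiles("C"), signature_config(1:3))
  expect_length(fv$counts, 3)
  expect_true(all(fv$counts == 1L))

  # ethanol at height 1: no two atoms are equivalent
  fv <- featurize(parse_smiles("CCO"), signature_config(1))
  expect_length(fv$counts, 3)
  expect_true(all(fv$counts == 1L))
})

test_that("symmetry-equivalent roots share a signature; height 0 is the label", {
  p <- parse_smiles("CCC")
  expect_identical(atom_signature(p, 1, 1), atom_signature(p, 3, 1))
  expect_identical(atom_signature(p, 2, 0), "[C]")
})

test_that("canonical string equals the brute-force DFS minimum", {
  # spec-level example: ethanol, central carbon, height 1
  m <- parse_smiles("CCO")
  central <- which(vapply(seq_len(3), function(a)
    sum(m$bonds$from == a | m$bonds$to == a), integer(1)) == 2)
  expect_identical(atom_signature(m, central, 1),
                   oracle_signature(m, central, 1))
  # ring-containing molecule, every atom and height
  m <- parse_smiles("Cc1ccccc1")
  for (a in seq_len(m$n)) for (h in 1:3) {
    expect_identical(atom_signature(m, a, h), oracle_signature(m, a, h))
  }
})

test_that("oracle equivalence holds on random graphs up to 8 atoms", {
  for (s in 1:30) {
    mol <- random_molgraph(sample(2:8, 1), seed = 1000 + s)
    for (a in seq_len(mol$n)) for (h in 1:3) {
      expect_identical(atom_signature(mol, a, h), oracle_signature(mol, a, h))
    }
  }
})

test_that("featurization is permutation invariant and conserves counts", {
  cfg <- signature_config(1:3)
  for (s in 1:40) {
    mol <- random_molgraph(sample(2:12, 1), seed = 2000 + s)
    fv <- featurize(mol, cfg)
    # per-height counts sum to the number of heavy atoms
    h_of <- as.integer(sub("\\|.*$", "", names(fv$counts)))
    for (h in cfg$heights) {
      expect_equal(sum(fv$counts[h_of == h]), mol$n)
    }
    # random relabelling of atom indices leaves the count vector unchanged
    set.seed(3000 + s)
    perm <- sample(mol$n)
    fv2 <- featurize(permute_molgraph(mol, perm), cfg)
    expect_identical(fv$counts[order(names(fv$counts))],
                     fv2$counts[order(names(fv2$counts))])
  }
})

test_that("repeated featurization of one SMILES is identical", {
  a <- featurize("CC(Cl)c1ccccc1C(=O)O")
  b <- featurize("CC(Cl)c1ccccc1C(=O)O")
  expect_identical(a$counts, b$counts)
})

test_that("dictionary building and vectorization follow the frozen contract", {
  v1 <- featurize("CCO", signature_config(1))
  v2 <- featurize("CCN", signature_config(1))
  d1 <- build_dictionary(list(v1))
  expect_length(d1$signatures, 3)
  expect_true(d1$frozen)
  # idempotent on identical vectors; union on disjoint ones
  expect_identical(build_dictionary(list(v1, v1)), d1)
  d12 <- build_dictionary(list(v1, v2))
  expect_length(d12$signatures,
                length(union(names(v1$counts), names(v2$counts))))
  expect_error(build_dictionary(list()))

  # all-seen, all-unseen, half-seen
  r <- vectorize(v1, d1)
  expect_equal(sum(r), sum(v1$counts))
  expect_equal(attr(r, "n_dropped"), 0)
  r <- vectorize(featurize("NCl", signature_config(1)), d1)  # no shared signature
  expect_equal(sum(r), 0)
  expect_equal(attr(r, "n_dropped"), 2)
  r <- vectorize(v2, d1)          # shares some carbon signatures with CCO
  expect_true(attr(r, "n_dropped") > 0)
  expect_true(sum(r) > 0)
})

test_that("sparse dataset and dictionary files round-trip", {
  smiles <- c("CCO", "CCN", "c1ccccc1", "CC(=O)O")
  vecs <- featurize_all(smiles, signature_config(1:2))
  dict <- build_dictionary(vecs)
  tmp <- withr::local_tempdir()
  f_data <- file.path(tmp, "ds.libsvm")
  f_dict <- file.path(tmp, "ds.dict.tsv")
  write_sparse_dataset(vecs, c("A", "A", "N", "N"), dict, f_data)
  write_dictionary(dict, f_dict)

  expect_equal(length(readLines(f_dict)), length(dict$signatures))
  dict2 <- read_dictionary(f_dict)
  expect_identical(dict2$signatures, dict$signatures)
  back <- read_sparse_dataset(f_data, dict2)
  expect_equal(back$labels, c("A", "A", "N", "N"))
  expect_equal(as.matrix(back$x),
               as.matrix(cpligand:::.sig_matrix(vecs, dict)),
               ignore_attr = TRUE)
})
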