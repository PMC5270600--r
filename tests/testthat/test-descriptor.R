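test_that("atom-type features count heavy-atom bonds by order", {
  eth <- parse_smiles("CC", "ethane")
  f <- atom_type_features(eth, 1)
  expect_equal(unname(f), c(2, 4, 1, 0, 0, 0, 0, 0))

  pyr <- parse_smiles("c1ccncc1", "pyridine")
  fn <- atom_type_features(pyr, 4)               # the nitrogen
  expect_equal(fn[["period"]], 2)
  expect_equal(fn[["family"]], 5)
  expect_equal(fn[["aromatic_bonds"]], 2)
  expect_equal(fn[["ring_atom"]], 1)
  expect_equal(fn[["pka"]], 0)                    # no provider attached

  # bond-count consistency with heavy-atom degree on all toys
  for (g in toy_molecules()) {
    for (a in seq_len(nrow(g$atoms))) {
      f <- atom_type_features(g, a)
      deg <- sum(g$bonds$i == a | g$bonds$j == a)
      expect_equal(sum(f[3:6]), deg)
    }
  }
})

test_that("isomerism feature follows the single-double-single window rules", {
  z2p <- parse_smiles("C/C=C\\CC", "z2pentene")    # (Z)-2-pentene
  e2p <- parse_smiles("C/C=C/CC", "e2pentene")
  p15 <- shortest_path(z2p, 1, 5)
  expect_equal(isomerism_feature(z2p, p15), -1)
  expect_equal(isomerism_feature(e2p, shortest_path(e2p, 1, 5)), 1)
  expect_equal(isomerism_feature(z2p, shortest_path(z2p, 1, 4)), -1)

  benzene <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(isomerism_feature(benzene, shortest_path(benzene, 1, 4)), 0)
  expect_equal(isomerism_feature(z2p, shortest_path(z2p, 1, 3)), 0)  # 2 bonds
  # wrong bond-order window: all-single butane
  but <- parse_smiles("CCCC", "butane")
  expect_equal(isomerism_feature(but, shortest_path(but, 1, 4)), 0)
})

test_that("descriptors group ordered pairs with frequencies", {
  c20 <- parse_smiles(strrep("C", 20), "c20")
  d20 <- build_descriptor(c20)
  expect_equal(d20$n_pairs, 380)
  expect_equal(sum(d20$freq), 380)
  expect_equal(ncol(d20$features), 19)

  pyr <- build_descriptor(parse_smiles("c1ccncc1", "pyridine"))
  expect_equal(sum(pyr$freq), 30)

  eth <- build_descriptor(parse_smiles("CC", "ethane"))
  expect_equal(nrow(eth$features), 1)
  expect_equal(eth$freq, 2L)

  single <- build_descriptor(parse_smiles("C", "methane"))
  expect_equal(nrow(single$features), 0)
  expect_equal(single$n_pairs, 0L)
})

test_that("descriptor invariants hold on all toys", {
  for (d in toy_descriptors()) {
    n <- (1 + sqrt(1 + 4 * d$n_pairs)) / 2        # invert n(n-1)
    expect_equal(sum(d$freq), n * (n - 1))
    expect_equal(ncol(d$features), 19)
    # grouping is exhaustive: no duplicate feature rows
    expect_false(anyDuplicated(apply(d$features, 1, paste, collapse = ",")) > 0)
    # canonical lexicographic order
    ord <- do.call(order, as.data.frame(d$features))
    expect_equal(ord, seq_along(ord))
  }
})

test_that("descriptor is invariant under atom renumbering", {
  set.seed(42)
  for (g in toy_molecules()[c("pyridine", "acetic_acid",
                              "chloro_fluorobenzene_meta", "butene_cis")]) {
    d0 <- build_descriptor(g)
    for (rep in 1:3) {
      perm <- sample(nrow(g$atoms))
      dp <- build_descriptor(permute_graph(g, perm))
      expect_equal(dp$features, d0$features, ignore_attr = TRUE)
      expect_equal(dp$freq, d0$freq)
    }
  }
})

test_that("grouped descriptor expands to the raw ordered-pair multiset", {
  for (g in toy_molecules()[c("pyridine", "methanesulfonic_acid")]) {
    d <- build_descriptor(g)
    # raw enumeration oracle: every ordered pair, ungrouped
    n <- nrow(g$atoms)
    atom_feats <- t(vapply(seq_len(n),
                           function(a) atom_type_features(g, a), numeric(8)))
    rf <- ring_flags(g)
    raw <- do.call(rbind, lapply(seq_len(n), function(i)
      do.call(rbind, lapply(setdiff(seq_len(n), i), function(j) {
        p <- shortest_path(g, i, j)
        c(atom_feats[i, ], atom_feats[j, ], rf$pair(i, j), length(p) - 1,
          isomerism_feature(g, p))
      }))))
    expanded <- expand_descriptor(d)
    key <- function(m) sort(apply(m, 1, paste, collapse = ","))
    expect_equal(key(expanded$features), key(raw))
  }
})

test_that("descriptor TSV serialization round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  descs <- toy_descriptors()
  write_descriptors(descs, path)
  back <- read_descriptors(path)
  expect_length(back, length(descs))
  for (k in seq_along(descs)) {
    expect_equal(back[[k]]$id, descs[[k]]$id)
    expect_equal(back[[k]]$n_pairs, descs[[k]]$n_pairs)
    expect_equal(back[[k]]$freq, descs[[k]]$freq)
    expect_equal(back[[k]]$features, descs[[k]]$features, tolerance = 1e-9)
  }
})
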