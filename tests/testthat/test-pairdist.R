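test_that("weight expansion ties the two atoms' feature weights", {
  ones <- weight_vector(rep(1, 11))
  expect_equal(unname(expand_weights(ones)), rep(1, 19))

  w <- weight_vector(c(0.927, rep(0, 10)))
  w19 <- expand_weights(w)
  expect_equal(unname(w19[c(1, 9)]), c(0.927, 0.927))
  expect_equal(unname(w19[-c(1, 9)]), rep(0, 17))

  expect_equal(unname(expand_weights(rep(0, 11))), rep(0, 19))
  expect_error(weight_vector(c(-0.1, rep(1, 10))), "non-negative")
  expect_error(weight_vector(rep(1, 10)), "11 components")
})

test_that("feature distance is the weighted Euclidean norm without frequency", {
  w19 <- expand_weights(rep(1, 11))
  a <- feat_row(path_bonds = 3)[1, ]
  expect_equal(feature_distance(a, a, w19), 0)

  b <- feat_row(path_bonds = 5)[1, ]
  w19_half <- expand_weights(c(rep(1, 9), 0.5, 1))   # path-bonds weight 0.5
  expect_equal(feature_distance(a, b, w19_half), 1.0)
  expect_equal(feature_distance(a, b, expand_weights(rep(0, 11))), 0)
})

test_that("frequency matching reproduces the hand-worked micro-cases", {
  w19 <- expand_weights(rep(1, 11))
  a <- feat_row(path_bonds = 1)

  # identical row with enough frequency -> 0
  B0 <- make_descriptor("B0", feat_row(path_bonds = 1), 5)
  expect_equal(frequency_matched_distance(a[1, ], 3, B0, w19), 0)

  # freq(a)=3; b1 at distance 1 freq 2, b2 at distance 2 freq 5 -> 2*1+1*2=4
  B1 <- make_descriptor("B1", rbind(feat_row(path_bonds = 2),
                                    feat_row(path_bonds = 3)), c(2, 5))
  expect_equal(frequency_matched_distance(a[1, ], 3, B1, w19), 4)
  expect_equal(freq_match_oracle(a[1, ], 3, B1$features, B1$freq, w19), 4)

  # freq(a)=5; B one row at distance 1 freq 3 -> d=3 scaled by 5/3 = 5
  B2 <- make_descriptor("B2", feat_row(path_bonds = 2), 3)
  expect_equal(frequency_matched_distance(a[1, ], 5, B2, w19), 5)
  expect_equal(freq_match_oracle(a[1, ], 5, B2$features, B2$freq, w19), 5)

  expect_error(frequency_matched_distance(a[1, ], 1,
                                          make_descriptor("E", feat_row()[0, , drop = FALSE],
                                                          integer()), w19),
               "empty")
})

test_that("frequency matching agrees with the step-through oracle on random cases", {
  set.seed(11)
  w19 <- expand_weights(runif(11, 0, 1.2))
  for (case in 1:25) {
    a <- feat_row(path_bonds = sample(1:6, 1), period_i = sample(2:4, 1))[1, ]
    a <- a + round(runif(19), 2) * (runif(19) < 0.3)
    nb <- sample(1:6, 1)
    B_rows <- do.call(rbind, lapply(seq_len(nb), function(k)
      round(feat_row() + runif(19, 0, 4) * (runif(19) < 0.4), 2)))
    B_freq <- sample(1:5, nb, replace = TRUE)
    B <- make_descriptor("rand", B_rows, B_freq)
    af <- sample(1:12, 1)
    expect_equal(frequency_matched_distance(a, af, B, w19),
                 freq_match_oracle(a, af, B_rows, B_freq, w19),
                 tolerance = 1e-12)
  }
})

test_that("directed distance is the RMS over A's pair count", {
  w19 <- expand_weights(rep(1, 11))
  A <- make_descriptor("A", feat_row(path_bonds = 1), 2)
  B <- make_descriptor("B", feat_row(path_bonds = 2), 2)
  expect_equal(directed_distance(A, A, w19), 0)
  expect_equal(directed_distance(A, B, w19), sqrt(4 / 2))  # f=2, n_A=2
  # homogeneity in the weights
  expect_equal(directed_distance(A, B, 3 * w19),
               3 * directed_distance(A, B, w19))
})

test_that("pseudo-distance is symmetric, zero on identity, as-printed", {
  A <- make_descriptor("A", feat_row(path_bonds = 1), 2)
  B <- make_descriptor("B", feat_row(path_bonds = 2), 2)
  ones <- rep(1, 11)
  expect_equal(pseudo_distance(A, A, ones), 0)
  expect_equal(pseudo_distance(A, B, ones), 2)          # sqrt(2 + 2)
  expect_equal(pseudo_distance(A, B, ones, rms = TRUE), sqrt(2))
  for (pair in list(c(1, 3), c(2, 5), c(4, 8), c(6, 7))) {
    d <- toy_descriptors()
    expect_identical(pseudo_distance(d[[pair[1]]], d[[pair[2]]]),
                     pseudo_distance(d[[pair[2]]], d[[pair[1]]]))
  }
})

test_that("pairwise matrix mirrors element-wise recomputation", {
  descs <- toy_descriptors()[1:5]
  w <- default_weights()
  D <- pairwise_matrix(descs, w)
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  expect_true(all(D >= 0))
  expect_identical(D, t(D))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], pseudo_distance(descs[[i]], descs[[j]], w))
  # homogeneity under weight scaling
  expect_equal(pairwise_matrix(descs, 2.5 * w), 2.5 * D)
  # identical molecules give zero entries; duplicate ids are rejected
  copies <- descs[c(1, 1, 1)]
  expect_error(pairwise_matrix(copies), "duplicate")
  copies <- lapply(1:3, function(k) { d <- descs[[1]]; d$id <- paste0("m", k); d })
  expect_equal(unname(pairwise_matrix(copies)), matrix(0, 3, 3))
})

test_that("grouping granularity of the consumed side is irrelevant (1e-9)", {
  # Expanding the target descriptor B to frequency-1 rows must not change
  # any distance: the greedy matching consumes B one unit at a time either
  # way. (Expanding the source side A is a different quantity by design:
  # a row's frequency multiplies into its matched sum before squaring.)
  descs <- toy_descriptors()
  expanded <- lapply(descs, expand_descriptor)
  w19 <- expand_weights(default_weights())
  for (i in c(1, 4, 6)) for (j in c(2, 5, 7)) {
    A <- descs[[i]]
    expect_equal(directed_distance(A, descs[[j]], w19),
                 directed_distance(A, expanded[[j]], w19),
                 tolerance = 1e-9)
    for (r in seq_len(nrow(A$features)))
      expect_equal(
        frequency_matched_distance(A$features[r, ], A$freq[r], descs[[j]], w19),
        frequency_matched_distance(A$features[r, ], A$freq[r], expanded[[j]], w19),
        tolerance = 1e-9)
  }
})

test_that("weight JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  w <- default_weights()
  write_weights(w, path)
  expect_equal(read_weights(path), w)
})
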