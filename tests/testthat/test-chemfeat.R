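test_that("canonicalization desalts and is idempotent", {
  res <- canonicalize_desalt(c("CCO.[Na+].[Cl-]", "OCC", "CCO"))
  expect_true(all(res$parse_ok))
  expect_equal(res$smiles[1], res$smiles[2])  # salt stripped, same ethanol
  expect_equal(res$smiles[2], res$smiles[3])
  again <- canonicalize_desalt(res$smiles)
  expect_equal(again$smiles, res$smiles)      # canon(canon(s)) == canon(s)
})

test_that("unparsable SMILES are flagged, not raised", {
  res <- suppressWarnings(
    canonicalize_desalt(c("C1CC", "CCO", "", "not a molecule")))
  expect_equal(res$parse_ok, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(res$smiles[1]))
  expect_equal(canonicalize_desalt("CCO")$smiles, res$smiles[2])
})

test_that("desalting keeps the largest covalent fragment", {
  res <- canonicalize_desalt("CC(=O)O.CCCCCCCC")
  expect_equal(res$smiles, canonicalize_desalt("CCCCCCCC")$smiles)
  # an invalid-in-batch record does not corrupt its neighbors
  res2 <- suppressWarnings(canonicalize_desalt(c("CCO", "C1CC", "CCN")))
  expect_equal(res2$parse_ok, c(TRUE, FALSE, TRUE))
  expect_equal(res2$smiles[3], canonicalize_desalt("CCN")$smiles)
})

test_that("molecular graphs carry the declared shapes", {
  g <- smiles_to_graph("C")
  expect_equal(nrow(g$node_features), 1)
  expect_equal(nrow(g$edges), 0)
  g <- smiles_to_graph("CC")
  expect_equal(nrow(g$node_features), 2)
  expect_equal(nrow(g$edges), 2)       # both directed edges per bond
  expect_equal(sort(g$degrees), c(1, 1))
  g <- smiles_to_graph("c1ccccc1")
  expect_equal(nrow(g$node_features), 6)
  expect_equal(nrow(g$edges), 12)
  expect_true(all(g$degrees == 2))
  expect_equal(ncol(g$node_features), 30)
  expect_equal(ncol(g$edge_features), 75)
})

test_that("graph degrees equal adjacency row sums (property)", {
  smis <- c("CCO", "c1ccccc1CN", "CC(C)(C)c1ccc2ncnc(N)c2c1",
            "O=C(Nc1ccccc1)Nc1ccc(Cl)cc1", "C#N", "CC(=O)[O-]")
  for (s in smis) {
    g <- smiles_to_graph(s)
    n <- nrow(g$node_features)
    deg <- tabulate(g$edges[, "to"], nbins = n)
    expect_equal(unname(g$degrees), deg, info = s)
    expect_true(all(g$edges <= n))
  }
})

test_that("fingerprint block is deterministic with correct offsets", {
  fams <- c("ecfp2", "elemcount", "ringprofile")
  fb1 <- fingerprint_block(c("CCO", "c1ccccc1"), families = fams)
  fb2 <- fingerprint_block(c("CCO", "c1ccccc1"), families = fams)
  expect_identical(fb1$bits, fb2$bits)
  reg <- fingerprint_families()
  expect_equal(ncol(fb1$bits), sum(vapply(reg[fams], `[[`, 1, "length")))
  offs <- fb1$family_offsets
  expect_equal(offs$ecfp2[["start"]], 1)
  expect_equal(offs$elemcount[["start"]], 1 + reg$ecfp2$length)
  # kekulized and aromatic notations collapse to the same canonical bits
  benz <- canonicalize_desalt(c("C1=CC=CC=C1", "c1ccccc1"))$smiles
  fb <- fingerprint_block(benz, families = fams)
  expect_identical(fb$bits[1, ], fb$bits[2, ])
})

test_that("unknown fingerprint family is a configuration error", {
  expect_error(fingerprint_block("CCO", families = c("ecfp2", "nope")),
               "unknown fingerprint families")
})

test_that("ecfp4 keys are deterministic and discriminate", {
  k <- ecfp4(c("CCO", "CCN", "CCO"))
  expect_identical(k[1, ], k[3, ])
  expect_true(any(k[1, ] != k[2, ]))
  expect_equal(ncol(k), 2048)
})

test_that("tanimoto matches hand values and its properties hold", {
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE)), 1 / 3)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_warning(z <- tanimoto(c(FALSE, FALSE), c(FALSE, FALSE)))
  expect_equal(z, 0)
  keys <- random_keys(520, bits = 48, seed = 7)
  keys <- keys[rowSums(keys) > 0, ]
  # symmetry and unit self-similarity, >= 1000 random trials in total
  for (i in seq_len(nrow(keys))) {
    j <- (i %% nrow(keys)) + 1
    expect_equal(tanimoto(keys[i, ], keys[j, ]),
                 tanimoto(keys[j, ], keys[i, ]))
    expect_equal(tanimoto(keys[i, ], keys[i, ]), 1)
  }
  # the matrix form agrees with the scalar form
  tm <- pnaqsar:::tanimoto_matrix(keys[1:5, ], keys[1:7, ])
  for (i in 1:5) for (j in 1:7)
    expect_equal(tm[i, j], tanimoto(keys[i, ], keys[j, ]))
})

test_that("nearest neighbor similarity returns max and argmax", {
  train <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                 c(TRUE, TRUE, TRUE, FALSE))
  q <- c(TRUE, TRUE, TRUE, FALSE)
  nn <- nearest_neighbor_similarity(q, train)
  expect_equal(nn$similarity, 1)
  expect_equal(nn$index, 2)
  nn2 <- nearest_neighbor_similarity(c(FALSE, FALSE, FALSE, TRUE), train)
  expect_equal(nn2$similarity, 0)
  expect_error(nearest_neighbor_similarity(q, train[0, , drop = FALSE]),
               "empty")
})

test_that("feature reducer retains the targeted variance minimally", {
  set.seed(3)
  # 3 points on a line in 10-D: one component suffices
  L <- outer(c(0, 1, 2), rnorm(10))
  r <- fit_feature_reducer(L, 0.95)
  expect_equal(r$k, 1)
  # full retention on full-rank data keeps rank components
  X <- matrix(rnorm(80), 8, 10)
  rf <- fit_feature_reducer(X, 1.0)
  expect_equal(rf$k, 7)  # rank of an 8-row centered matrix
  # the training mean projects to zero
  expect_equal(max(abs(predict(rf, matrix(colMeans(X), 1)))), 0,
               tolerance = 1e-10)
  # minimality: k components reach the target, k-1 do not
  Y <- matrix(rnorm(200), 20, 10) %*% diag(c(5, 3, 2, rep(0.5, 7)))
  rr <- fit_feature_reducer(Y, 0.9)
  ev <- stats::prcomp(Y)$sdev^2
  cum <- cumsum(ev) / sum(ev)
  expect_gte(cum[rr$k], 0.9)
  if (rr$k > 1) expect_lt(cum[rr$k - 1], 0.9)
  expect_error(fit_feature_reducer(matrix(1, 5, 4), 0.95), "degenerate")
})
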