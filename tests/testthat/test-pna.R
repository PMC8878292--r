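ns <- asNamespace("pnaqsar")

test_that("delta is the mean log(degree + 1) over training nodes", {
  g1 <- smiles_to_graph("CC")          # degrees 1, 1
  sc <- compute_delta(list(g1))
  expect_equal(sc$delta, log(2))
  # degrees {1, 3} in equal numbers
  g2 <- smiles_to_graph("CC(C)C")      # degrees 1, 3, 1, 1
  sc2 <- compute_delta(list(g1, g2, g1, g2))  # degrees: ten 1s, two 3s
  manual <- mean(log(c(rep(1, 10), rep(3, 2)) + 1))
  expect_equal(sc2$delta, manual)
  sc3 <- structure(list(delta = (log(2) + log(4)) / 2, alphas = c(0, 1, -1)),
                   class = "scaler_params")
  expect_equal(sc3$delta, 1.0397, tolerance = 1e-4)
  # adding graphs with the same degree distribution leaves delta unchanged
  expect_equal(compute_delta(list(g1, g1, g1))$delta, sc$delta)
})

test_that("degree scaler satisfies its algebraic identities", {
  sc <- compute_delta(list(smiles_to_graph("CC(C)Cc1ccccc1")))
  d <- c(1, 2, 3, 4, 5, 7)
  expect_equal(degree_scaler(d, 0, sc), rep(1, length(d)))
  expect_equal(degree_scaler(d, 1, sc) * degree_scaler(d, -1, sc),
               rep(1, length(d)))
  dfix <- exp(sc$delta) - 1   # log(d+1) = delta -> S = 1 for all alpha
  for (a in c(0, 1, -1)) expect_equal(degree_scaler(dfix, a, sc), 1)
  # d = 0 policy: scaler 1 for every alpha
  for (a in c(0, 1, -1)) expect_equal(degree_scaler(0, a, sc), 1)
})

test_that("reference aggregation collapses correctly on small cases", {
  sc <- structure(list(delta = log(2), alphas = c(0, 1, -1)),
                  class = "scaler_params")
  m <- matrix(c(1.5, -2, 0.5), 1)
  out <- pna_aggregate(NULL, m, degree = 1, scaler = sc)
  expect_equal(length(out), 36)
  # single neighbor: mean = max = min = message, std = 0
  expect_equal(out[1:3], as.numeric(m))
  expect_equal(out[4:6], rep(0, 3))
  expect_equal(out[7:9], as.numeric(m))
  expect_equal(out[10:12], as.numeric(m))
  # two messages m and -m: mean 0, std |m| (population), max m, min -m
  two <- rbind(c(2, -1), c(-2, 1))
  o2 <- pna_aggregate(NULL, two, degree = 2, scaler = sc)
  expect_equal(o2[1:2], c(0, 0))
  expect_equal(o2[3:4], c(2, 1))
  expect_equal(o2[5:6], c(2, 1))
  expect_equal(o2[7:8], c(-2, -1))
  # zero neighbors aggregate to zeros
  expect_equal(pna_aggregate(numeric(3), NULL, 0, sc), rep(0, 36))
  # permutation invariance in neighbor order
  m3 <- matrix(rnorm(12), 4, 3)
  expect_equal(pna_aggregate(NULL, m3, 4, sc),
               pna_aggregate(NULL, m3[c(3, 1, 4, 2), ], 4, sc))
})

test_that("batched aggregation agrees with the per-node reference", {
  set.seed(4)
  g <- smiles_to_graph("CC(C)c1ccc(O)cc1")
  pk <- pack_graphs(list(g))
  sc <- compute_delta(pk)
  h <- 3
  M <- matrix(rnorm(pk$n_edges * h), pk$n_edges, h)
  N <- pk$n_nodes
  nin <- tabulate(pk$eto, nbins = N)
  mu <- ns$index_add(matrix(0, N, h), pk$eto, M) / pmax(nin, 1)
  v <- ns$index_add(matrix(0, N, h), pk$eto, M^2) / pmax(nin, 1) - mu^2
  v[v < 0] <- 0
  ex <- ns$segment_extrema(M, pk$eto, N)
  S1 <- degree_scaler(pk$deg, 1, sc)
  A0 <- cbind(mu, sqrt(v), ex$max, ex$min)
  AGG <- cbind(A0, S1 * A0, (1 / S1) * A0)
  for (i in seq_len(N)) {
    msgs <- M[pk$eto == i, , drop = FALSE]
    ref <- pna_aggregate(NULL, if (nrow(msgs)) msgs else NULL,
                         degree = pk$deg[i], scaler = sc, std_eps = 0)
    expect_equal(unname(AGG[i, ]), unname(ref), tolerance = 1e-12)
  }
})

test_that("masked loss reduces to plain MSE and handles missing labels", {
  pred <- matrix(c(1, 2, 3), 3, 1)
  obs <- matrix(c(1.5, 2, 2), 3, 1)
  mask <- matrix(TRUE, 3, 1)
  expect_equal(masked_multitask_loss(pred, obs, mask),
               mean((pred - obs)^2))
  expect_equal(masked_multitask_loss(obs, obs, mask), 0)
  # two tasks, errors {1,1} on A (n=2), {2} on B (n=1) -> 1 + 4 = 5
  p <- matrix(c(1, 1, 2, 99), 2, 2)
  l <- matrix(0, 2, 2)
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(masked_multitask_loss(p, l, m), 5)
  expect_error(masked_multitask_loss(p, l, m & FALSE), "no training signal")
})

test_that("forward output is invariant to atom relabelling", {
  set.seed(11)
  ent <- tiny_entries()
  graphs <- tiny_features()$graphs
  cfg <- tiny_net_config(seed = 2)
  params <- ns$init_params(cfg, node_dim = 30, n_features = 4, n_tasks = 7)
  feat <- matrix(rnorm(4), 1, 4)
  sc <- compute_delta(pack_graphs(graphs))
  for (g in graphs[sample(length(graphs), 25)]) {
    n <- nrow(g$node_features)
    perm <- sample(n)
    p1 <- ns$net_forward(params, list(pack = pack_graphs(list(g)),
                                      features = feat), cfg, sc)$pred
    gp <- permute_graph(g, perm)
    p2 <- ns$net_forward(params, list(pack = pack_graphs(list(gp)),
                                      features = feat), cfg, sc)$pred
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("forward is deterministic and free of cross-example coupling", {
  graphs <- tiny_features()$graphs[1:6]
  cfg <- tiny_net_config(seed = 5)
  params <- ns$init_params(cfg, node_dim = 30, n_features = 3, n_tasks = 7)
  sc <- compute_delta(pack_graphs(graphs))
  set.seed(8)
  feat <- matrix(rnorm(18), 6, 3)
  batch <- list(pack = pack_graphs(graphs), features = feat)
  p1 <- ns$net_forward(params, batch, cfg, sc)$pred
  p2 <- ns$net_forward(params, batch, cfg, sc)$pred
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(6, 7))
  # batch of one equals the corresponding row of the big batch
  single <- list(pack = pack_graphs(graphs[3]),
                 features = feat[3, , drop = FALSE])
  expect_equal(ns$net_forward(params, single, cfg, sc)$pred,
               p1[3, , drop = FALSE], tolerance = 1e-12)
  # duplicated molecule rows predict identically
  dup <- list(pack = pack_graphs(graphs[c(2, 2)]),
              features = feat[c(2, 2), , drop = FALSE])
  pd <- ns$net_forward(params, dup, cfg, sc)$pred
  expect_equal(pd[1, ], pd[2, ])
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(21)
  graphs <- lapply(c("CCO", "c1ccncc1C", "CC(=O)NC"), smiles_to_graph)
  pk <- pack_graphs(graphs)
  cfg <- default_net_config(n_pna_layers = 2, msg_hidden = 4, hidden = 5,
                            pool_width = 4, dnn_widths = c(4L),
                            fc_widths = c(5L), dropout = 0, seed = 1)
  sc <- compute_delta(pk)
  params <- ns$init_params(cfg, node_dim = 30, n_features = 3, n_tasks = 7)
  feat <- matrix(rnorm(9), 3, 3)
  labels <- matrix(rnorm(21), 3, 7)
  mask <- matrix(TRUE, 3, 7)
  batch <- list(pack = pk, features = feat)
  fw <- ns$net_forward(params, batch, cfg, sc, need_grad = TRUE)
  gr <- ns$net_backward(params, batch, cfg, sc, fw$cache,
                        ns$masked_loss_grad(fw$pred, labels, mask))
  lossfn <- function(p) {
    masked_multitask_loss(ns$net_forward(p, batch, cfg, sc)$pred,
                          labels, mask)
  }
  eps <- 1e-6
  for (nm in c("msg_W1", "upd_W2", "pool_W", "dnn_W1", "fc_W1", "head_W")) {
    idx <- sample(length(params[[nm]]), 4)
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})

test_that("early stopping follows the moving-average rule", {
  # strictly decreasing: never stops, best = last
  dec <- seq(1, 0.1, length.out = 30)
  tr <- early_stop_trace(dec, patience = 10)
  expect_false(tr$stopped)
  expect_equal(tr$best_epoch, 30)
  # constant loss: stops exactly patience epochs after the first
  con <- rep(0.5, 40)
  tr2 <- early_stop_trace(con, patience = 10)
  expect_true(tr2$stopped)
  expect_equal(tr2$stop_epoch, 11)
  expect_equal(tr2$best_epoch, 1)
  # moving-average improvements defer stopping long after the best loss:
  # hand trace gives improvements at epochs 6..11 and 13, so with patience
  # 5 training stops at epoch 18 while the best loss sits at epoch 2
  seqv <- c(1.0, 0.6, 1.0, rep(0.7, 20))
  tr3 <- early_stop_trace(seqv, patience = 5, ma_window = 10)
  expect_equal(tr3$stop_epoch, 18)
  expect_equal(tr3$best_epoch, 2)
  # hand-traced mixed case
  v <- c(1.0, 0.8, 0.9, 0.9, 0.9, 0.9, 0.9)
  tr4 <- early_stop_trace(v, patience = 3, ma_window = 3)
  # epoch 2 improves loss; ma improves through epoch 4 (0.867);
  # epochs 5..7 improve nothing -> stop at 7
  expect_equal(tr4$stop_epoch, 7)
  expect_equal(tr4$best_epoch, 2)
})

test_that("training is reproducible and returns the best-epoch weights", {
  ent <- tiny_entries()
  feats <- tiny_features()
  cfg <- tiny_net_config(seed = 77, max_epochs = 8L)
  m1 <- qsar_fit(ent, cfg, features = feats)
  m2 <- qsar_fit(ent, cfg, features = feats)
  expect_equal(m1$net$training_log, m2$net$training_log)
  p1 <- predict_pic50(m1, ent$smiles[1:4], features = feats)
  p2 <- predict_pic50(m2, ent$smiles[1:4], features = feats)
  expect_equal(p1, p2)
  expect_equal(dim(p1), c(4, 7))
  # prediction of a training compound matches the forward pass bit-for-bit
  expect_identical(p1, predict_pic50(m1, ent$smiles[1:4], features = feats))
})

test_that("unparsable SMILES yield flagged rows without derailing others", {
  ent <- tiny_entries()
  m <- qsar_fit(ent, tiny_net_config(seed = 3, max_epochs = 5L),
                features = tiny_features())
  sm <- c(ent$smiles[1], "C1CC", ent$smiles[2])
  pred <- suppressWarnings(predict_pic50(m, sm))
  expect_true(all(is.na(pred[2, ])))
  expect_false(anyNA(pred[c(1, 3), ]))
  expect_equal(attr(pred, "parse_ok"), c(TRUE, FALSE, TRUE))
  # permuting the input permutes the output
  pred2 <- suppressWarnings(predict_pic50(m, rev(sm)))
  expect_equal(unname(pred2[3, ]), unname(pred[1, ]))
})
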