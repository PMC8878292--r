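## The multitask regressor: a principal-neighborhood-aggregation (PNA)
## message-passing branch on molecular graphs fused with a deep-network
## branch on PCA-reduced fingerprints, ending in seven hard-shared task
## heads. Forward and reverse passes are written directly against the
## packed-batch representation; training uses Adam with L2 weight decay,
## a masked multitask loss and moving-average early stopping.

#' Network configuration
#'
#' Hyperparameters of the multitask PNA+DNN regressor. `default_net_config()`
#' is the general-purpose default; `study_net_config()` is the compact
#' configuration used by the bundled synthetic-data studies (one PNA layer,
#' narrower widths, large batches) where wall-clock cost matters.
#'
#' @param ... Named overrides of any config field.
#' @return A named list of hyperparameters.
#' @export
default_net_config <- function(...) {
  cfg <- list(
    n_pna_layers = 2L,     # PNA message-passing rounds
    msg_hidden = 32L,      # width of the edge-message MLP output
    hidden = 32L,          # node embedding width after each update
    pool_width = 32L,      # graph-embedding MLP width after pooling
    dnn_widths = c(64L, 32L),  # descriptor branch layer widths
    fc_widths = c(64L, 32L),   # fused trunk layer widths
    dropout = 0.1,         # dropout probability on DNN/trunk layers
    learning_rate = 3e-3,
    weight_decay = 1e-5,   # L2 regularization strength
    batch_size = 64L,
    max_epochs = 200L,
    patience = 10L,        # early-stopping patience (epochs)
    ma_window = 10L,       # moving-average window for early stopping
    std_eps = 1e-3,        # epsilon of the smoothed std aggregator
    pooling = "sum",       # "sum" or "mean" global pooling
    seed = 1L
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' @rdname default_net_config
#' @export
study_net_config <- function(...) {
  default_net_config(n_pna_layers = 1L, msg_hidden = 16L, hidden = 16L,
                     pool_width = 16L, dnn_widths = c(48L, 24L),
                     fc_widths = c(48L, 24L), dropout = 0,
                     learning_rate = 4e-3, batch_size = 256L,
                     max_epochs = 60L, ...)
}

#' Degree-scaler normalization constant
#'
#' Computes the degree-scaler normalization `delta` as the mean of
#' `log(d + 1)` over all nodes of the training graphs (natural log).
#'
#' @param train_graphs List of `mol_graph` objects, or a `graph_pack`.
#' @return Object of class `scaler_params` with fields `delta` and
#'   `alphas`.
#' @export
compute_delta <- function(train_graphs) {
  deg <- if (inherits(train_graphs, "graph_pack")) train_graphs$deg
         else unlist(lapply(train_graphs, `[[`, "degrees"))
  if (length(deg) == 0) stop("no nodes in training graphs")
  delta <- mean(log(deg + 1))
  if (delta <= 0)
    stop("all training nodes are isolated; degree scaler undefined")
  structure(list(delta = delta, alphas = c(0, 1, -1)),
            class = "scaler_params")
}

#' Degree scaler
#'
#' `S(d, alpha) = (log(d + 1) / delta)^alpha`, with alpha 0 (identity),
#' +1 (amplification) or -1 (attenuation). Isolated nodes (d = 0) receive
#' scaler 1 for every alpha, extending the definition continuously.
#'
#' @param d Node degree(s), non-negative integers.
#' @param alpha Scaler exponent: 0, +1 or -1.
#' @param scaler A `scaler_params` object from [compute_delta()].
#' @return Numeric vector of scale factors.
#' @export
degree_scaler <- function(d, alpha, scaler) {
  stopifnot(alpha %in% c(0, 1, -1))
  s <- (log(d + 1) / scaler$delta)^alpha
  s[d == 0] <- 1
  s
}

#' Reference PNA aggregation for a single node
#'
#' Aggregates already-transformed neighbor messages with the four PNA
#' aggregators (mean, std, max, min), each combined with the three degree
#' scalers (identity, amplification, attenuation), and returns the 12
#' concatenated blocks. Permutation-invariant in neighbor order; the empty
#' neighborhood aggregates to zeros and the std of a single message is 0.
#' This direct implementation is the oracle against which the vectorized
#' batched aggregation is checked.
#'
#' @param node Node feature vector (unused by the aggregation itself; kept
#'   for interface clarity).
#' @param messages Matrix of transformed neighbor messages (one row each),
#'   or NULL/0-row for no neighbors.
#' @param degree The node degree used by the scalers.
#' @param scaler `scaler_params` from [compute_delta()].
#' @param std_eps Epsilon of the smoothed population std
#'   (`sqrt(var + eps^2) - eps`); 0 gives the exact population std.
#' @return Numeric vector of length `12 * ncol(messages)`.
#' @export
pna_aggregate <- function(node, messages, degree, scaler, std_eps = 0) {
  h <- if (is.null(messages)) length(node) else ncol(messages)
  k <- if (is.null(messages)) 0L else nrow(messages)
  if (k == 0) {
    agg <- matrix(0, 4, h)
  } else {
    mu <- colMeans(messages)
    v <- colMeans(messages^2) - mu^2
    v[v < 0] <- 0
    sdv <- sqrt(v + std_eps^2) - std_eps
    agg <- rbind(mu, sdv, apply(messages, 2, max), apply(messages, 2, min))
  }
  out <- numeric(0)
  for (alpha in c(0, 1, -1)) {
    s <- degree_scaler(degree, alpha, scaler)
    for (r in 1:4) out <- c(out, s * agg[r, ])
  }
  out
}

#' Masked multitask loss
#'
#' `sum_t (1/n_t) sum_i (pred - obs)^2` over observed labels only, where
#' `n_t` is the number of labelled compounds of task `t` in the batch.
#' Tasks with no labels contribute zero.
#'
#' @param pred,labels Numeric matrices (n x T).
#' @param mask Logical matrix, `TRUE` where a label exists.
#' @return Scalar loss.
#' @export
masked_multitask_loss <- function(pred, labels, mask) {
  stopifnot(all(dim(pred) == dim(labels)), all(dim(pred) == dim(mask)))
  if (!any(mask)) stop("mask is all FALSE: no training signal in batch")
  se <- (pred - labels)^2
  se[!mask] <- 0
  nt <- colSums(mask)
  contrib <- colSums(se)
  sum(ifelse(nt > 0, contrib / nt, 0))
}

# gradient of the masked loss with respect to predictions
masked_loss_grad <- function(pred, labels, mask) {
  nt <- colSums(mask)
  g <- 2 * (pred - labels)
  g[!mask] <- 0
  sweep(g, 2, pmax(nt, 1), "/")
}

# ---------------------------------------------------------------------------
# parameters

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

init_params <- function(config, node_dim = 30L, edge_dim = 75L, n_features,
                        n_tasks = 7L) {
  p <- list()
  d <- node_dim
  for (l in seq_len(config$n_pna_layers)) {
    hm <- config$msg_hidden
    p[[paste0("msg_W", l)]] <- glorot(2 * d + edge_dim, hm)
    p[[paste0("msg_b", l)]] <- matrix(0, 1, hm)
    p[[paste0("upd_W", l)]] <- glorot(d + 12 * hm, config$hidden)
    p[[paste0("upd_b", l)]] <- matrix(0, 1, config$hidden)
    d <- config$hidden
  }
  p$pool_W <- glorot(d, config$pool_width)
  p$pool_b <- matrix(0, 1, config$pool_width)
  din <- n_features
  for (i in seq_along(config$dnn_widths)) {
    p[[paste0("dnn_W", i)]] <- glorot(din, config$dnn_widths[i])
    p[[paste0("dnn_b", i)]] <- matrix(0, 1, config$dnn_widths[i])
    din <- config$dnn_widths[i]
  }
  fin <- config$pool_width + din
  for (i in seq_along(config$fc_widths)) {
    p[[paste0("fc_W", i)]] <- glorot(fin, config$fc_widths[i])
    p[[paste0("fc_b", i)]] <- matrix(0, 1, config$fc_widths[i])
    fin <- config$fc_widths[i]
  }
  p$head_W <- glorot(fin, n_tasks)
  p$head_b <- matrix(0, 1, n_tasks)
  p
}

relu <- function(x) { x[x < 0] <- 0; x }

addb <- function(x, b) sweep(x, 2, as.numeric(b), "+")

# ---------------------------------------------------------------------------
# forward

# batch: list(pack = graph_pack, features = matrix n_graphs x n_features)
# Returns list(pred, cache) — cache only when need_grad.
net_forward <- function(params, batch, config, scaler, need_grad = FALSE,
                        dropout_masks = NULL) {
  pk <- batch$pack
  N <- pk$n_nodes
  eps <- config$std_eps
  S1 <- degree_scaler(pk$deg, 1, scaler)
  Sm1 <- degree_scaler(pk$deg, -1, scaler)
  n_in <- tabulate(pk$eto, nbins = N)
  H <- pk$X
  cache <- if (need_grad) list(layers = vector("list", config$n_pna_layers))
           else NULL
  for (l in seq_len(config$n_pna_layers)) {
    Wm <- params[[paste0("msg_W", l)]]; bm <- params[[paste0("msg_b", l)]]
    Wu <- params[[paste0("upd_W", l)]]; bu <- params[[paste0("upd_b", l)]]
    if (pk$n_edges > 0) {
      msg_in <- cbind(H[pk$eto, , drop = FALSE], pk$edge_attr,
                      H[pk$efrom, , drop = FALSE])
      M <- relu(addb(msg_in %*% Wm, bm))
      nsafe <- pmax(n_in, 1)
      sumM <- matrix(0, N, ncol(M))
      sumM <- index_add(sumM, pk$eto, M)
      mu <- sumM / nsafe
      sumSq <- matrix(0, N, ncol(M))
      sumSq <- index_add(sumSq, pk$eto, M^2)
      v <- sumSq / nsafe - mu^2
      v[v < 0] <- 0
      sdv <- sqrt(v + eps^2) - eps
      ex <- segment_extrema(M, pk$eto, N)
      A0 <- cbind(mu, sdv, ex$max, ex$min)
      AGG <- cbind(A0, S1 * A0, Sm1 * A0)
    } else {
      M <- matrix(0, 0, config$msg_hidden)
      mu <- v <- sdv <- matrix(0, N, config$msg_hidden)
      ex <- NULL
      AGG <- matrix(0, N, 12 * config$msg_hidden)
    }
    U_in <- cbind(H, AGG)
    H_new <- relu(addb(U_in %*% Wu, bu))
    if (need_grad) {
      cache$layers[[l]] <- list(H_in = H, M = M, mu = mu, v = v, sdv = sdv,
                                ex = ex, AGG = AGG, H_out = H_new)
    }
    H <- H_new
  }
  # global pooling over nodes, then graph MLP
  P <- matrix(0, pk$n_graphs, ncol(H))
  P <- index_add(P, pk$gid, H)
  if (config$pooling == "mean") {
    gsize <- tabulate(pk$gid, nbins = pk$n_graphs)
    P <- P / pmax(gsize, 1)
  }
  G <- relu(addb(P %*% params$pool_W, params$pool_b))
  # descriptor branch
  D <- batch$features
  dnn_cache <- list()
  for (i in seq_along(config$dnn_widths)) {
    Zin <- D
    D <- relu(addb(D %*% params[[paste0("dnn_W", i)]],
                   params[[paste0("dnn_b", i)]]))
    if (!is.null(dropout_masks)) D <- D * dropout_masks[[paste0("dnn", i)]]
    if (need_grad) dnn_cache[[i]] <- list(Zin = Zin, Zout = D)
  }
  FZ <- cbind(G, D)
  fc_cache <- list()
  for (i in seq_along(config$fc_widths)) {
    Zin <- FZ
    FZ <- relu(addb(FZ %*% params[[paste0("fc_W", i)]],
                    params[[paste0("fc_b", i)]]))
    if (!is.null(dropout_masks)) FZ <- FZ * dropout_masks[[paste0("fc", i)]]
    if (need_grad) fc_cache[[i]] <- list(Zin = Zin, Zout = FZ)
  }
  pred <- addb(FZ %*% params$head_W, params$head_b)
  if (need_grad) {
    cache$P <- P; cache$G <- G; cache$H_final <- H
    cache$dnn <- dnn_cache; cache$fc <- fc_cache; cache$FZ_final <- FZ
    cache$S1 <- S1; cache$Sm1 <- Sm1; cache$n_in <- n_in
  }
  list(pred = pred, cache = cache)
}

# ---------------------------------------------------------------------------
# backward

net_backward <- function(params, batch, config, scaler, cache, dpred,
                         dropout_masks = NULL) {
  pk <- batch$pack
  N <- pk$n_nodes
  eps <- config$std_eps
  g <- list()
  # heads
  FZ <- cache$FZ_final
  g$head_W <- t(FZ) %*% dpred
  g$head_b <- matrix(colSums(dpred), 1)
  dFZ <- dpred %*% t(params$head_W)
  # fused trunk
  for (i in rev(seq_along(config$fc_widths))) {
    cc <- cache$fc[[i]]
    if (!is.null(dropout_masks)) dFZ <- dFZ * dropout_masks[[paste0("fc", i)]]
    dpre <- dFZ * (cc$Zout > 0)
    g[[paste0("fc_W", i)]] <- t(cc$Zin) %*% dpre
    g[[paste0("fc_b", i)]] <- matrix(colSums(dpre), 1)
    dFZ <- dpre %*% t(params[[paste0("fc_W", i)]])
  }
  pw <- config$pool_width
  dG <- dFZ[, seq_len(pw), drop = FALSE]
  dD <- dFZ[, -seq_len(pw), drop = FALSE]
  # descriptor branch
  for (i in rev(seq_along(config$dnn_widths))) {
    cc <- cache$dnn[[i]]
    if (!is.null(dropout_masks)) dD <- dD * dropout_masks[[paste0("dnn", i)]]
    dpre <- dD * (cc$Zout > 0)
    g[[paste0("dnn_W", i)]] <- t(cc$Zin) %*% dpre
    g[[paste0("dnn_b", i)]] <- matrix(colSums(dpre), 1)
    dD <- dpre %*% t(params[[paste0("dnn_W", i)]])
  }
  # pooling MLP
  dpreG <- dG * (cache$G > 0)
  g$pool_W <- t(cache$P) %*% dpreG
  g$pool_b <- matrix(colSums(dpreG), 1)
  dP <- dpreG %*% t(params$pool_W)
  dH <- dP[pk$gid, , drop = FALSE]
  if (config$pooling == "mean") {
    gsize <- tabulate(pk$gid, nbins = pk$n_graphs)
    dH <- dH / pmax(gsize, 1)[pk$gid]
  }
  # PNA layers, top down
  for (l in rev(seq_len(config$n_pna_layers))) {
    cc <- cache$layers[[l]]
    Wm <- params[[paste0("msg_W", l)]]
    Wu <- params[[paste0("upd_W", l)]]
    dpreU <- dH * (cc$H_out > 0)
    U_in <- cbind(cc$H_in, cc$AGG)
    g[[paste0("upd_W", l)]] <- t(U_in) %*% dpreU
    g[[paste0("upd_b", l)]] <- matrix(colSums(dpreU), 1)
    dU_in <- dpreU %*% t(Wu)
    d_in <- ncol(cc$H_in)
    dH_in <- dU_in[, seq_len(d_in), drop = FALSE]
    dAGG <- dU_in[, -seq_len(d_in), drop = FALSE]
    hm <- config$msg_hidden
    if (pk$n_edges > 0) {
      # undo scalers: blocks are [A0, S1*A0, Sm1*A0]
      dA0 <- dAGG[, 1:(4 * hm), drop = FALSE] +
        cache$S1 * dAGG[, (4 * hm + 1):(8 * hm), drop = FALSE] +
        cache$Sm1 * dAGG[, (8 * hm + 1):(12 * hm), drop = FALSE]
      dmu <- dA0[, 1:hm, drop = FALSE]
      dsd <- dA0[, (hm + 1):(2 * hm), drop = FALSE]
      dmx <- dA0[, (2 * hm + 1):(3 * hm), drop = FALSE]
      dmn <- dA0[, (3 * hm + 1):(4 * hm), drop = FALSE]
      nsafe <- pmax(cache$n_in, 1)
      dM <- matrix(0, nrow(cc$M), hm)
      # mean
      dM <- dM + (dmu / nsafe)[pk$eto, , drop = FALSE]
      # std: d std/d var = 0.5 / sqrt(var + eps^2); d var/d m = 2(m - mu)/n
      dvar <- dsd * 0.5 / sqrt(cc$v + eps^2)
      dM <- dM + (dvar / nsafe)[pk$eto, , drop = FALSE] *
        2 * (cc$M - cc$mu[pk$eto, , drop = FALSE])
      # max / min: route to the arg-extreme edge
      am <- cc$ex$amax
      sel <- am > 0
      if (any(sel)) {
        idx <- cbind(am[sel], col(am)[sel])
        dM[idx] <- dM[idx] + dmx[sel]
      }
      am <- cc$ex$amin
      sel <- am > 0
      if (any(sel)) {
        idx <- cbind(am[sel], col(am)[sel])
        dM[idx] <- dM[idx] + dmn[sel]
      }
      # message MLP
      dpreM <- dM * (cc$M > 0)
      msg_in <- cbind(cc$H_in[pk$eto, , drop = FALSE], pk$edge_attr,
                      cc$H_in[pk$efrom, , drop = FALSE])
      g[[paste0("msg_W", l)]] <- t(msg_in) %*% dpreM
      g[[paste0("msg_b", l)]] <- matrix(colSums(dpreM), 1)
      dmsg_in <- dpreM %*% t(Wm)
      dH_in <- index_add(dH_in, pk$eto,
                         dmsg_in[, seq_len(d_in), drop = FALSE])
      dH_in <- index_add(dH_in, pk$efrom,
                         dmsg_in[, (d_in + 75 + 1):(2 * d_in + 75),
                                 drop = FALSE])
    } else {
      g[[paste0("msg_W", l)]] <- matrix(0, 2 * d_in + 75, hm)
      g[[paste0("msg_b", l)]] <- matrix(0, 1, hm)
    }
    dH <- dH_in
  }
  g
}

# ---------------------------------------------------------------------------
# optimizer and early stopping

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    gr <- gr + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  list(params = params, state = state)
}

#' Trace the early-stopping rule over a validation-loss sequence
#'
#' Training halts when, for `patience` consecutive epochs, neither the
#' validation loss nor its moving average (over the last up-to-`ma_window`
#' epochs) has improved on its respective best. Returns the epoch training
#' stops after, and the best-loss epoch whose weights would be restored.
#'
#' @param losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param ma_window Moving-average window length.
#' @return List with `stop_epoch` (`length(losses)` if never triggered),
#'   `best_epoch`, and `stopped` (logical).
#' @export
early_stop_trace <- function(losses, patience = 10, ma_window = 10) {
  best <- Inf; best_ma <- Inf; best_epoch <- 0L; wait <- 0L
  for (t in seq_along(losses)) {
    ma <- mean(losses[max(1, t - ma_window + 1):t])
    improved <- FALSE
    if (losses[t] < best) {
      best <- losses[t]; best_epoch <- t; improved <- TRUE
    }
    if (ma < best_ma) {
      best_ma <- ma; improved <- TRUE
    }
    wait <- if (improved) 0L else wait + 1L
    if (wait >= patience)
      return(list(stop_epoch = t, best_epoch = best_epoch, stopped = TRUE))
  }
  list(stop_epoch = length(losses), best_epoch = best_epoch, stopped = FALSE)
}

# ---------------------------------------------------------------------------
# training

# train/val: list(pack, features, labels, mask). Returns a pna_net object.
train_pna <- function(train, val, config) {
  set.seed(config$seed)
  n_tasks <- ncol(train$labels)
  params <- init_params(config, node_dim = ncol(train$pack$X),
                        n_features = ncol(train$features),
                        n_tasks = n_tasks)
  scaler <- compute_delta(train$pack)
  state <- adam_init(params)
  nG <- train$pack$n_graphs
  best <- Inf; best_ma <- Inf; wait <- 0L; best_params <- params
  best_epoch <- 0L
  log_tr <- numeric(0); log_val <- numeric(0)
  val_batch <- list(pack = val$pack, features = val$features)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nG)
    nb <- ceiling(nG / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      gs <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                      nG)]
      bpack <- subset_pack(train$pack, gs)
      bmask <- train$mask[gs, , drop = FALSE]
      if (!any(bmask)) next
      batch <- list(pack = bpack,
                    features = train$features[gs, , drop = FALSE])
      dmask <- NULL
      if (config$dropout > 0) {
        dmask <- list()
        for (i in seq_along(config$dnn_widths))
          dmask[[paste0("dnn", i)]] <-
            matrix(stats::rbinom(length(gs) * config$dnn_widths[i], 1,
                                 1 - config$dropout) / (1 - config$dropout),
                   length(gs), config$dnn_widths[i])
        for (i in seq_along(config$fc_widths))
          dmask[[paste0("fc", i)]] <-
            matrix(stats::rbinom(length(gs) * config$fc_widths[i], 1,
                                 1 - config$dropout) / (1 - config$dropout),
                   length(gs), config$fc_widths[i])
      }
      fw <- net_forward(params, batch, config, scaler, need_grad = TRUE,
                        dropout_masks = dmask)
      loss <- masked_multitask_loss(fw$pred, train$labels[gs, , drop = FALSE],
                                    bmask)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch))
      ep_loss <- ep_loss + loss
      dpred <- masked_loss_grad(fw$pred, train$labels[gs, , drop = FALSE],
                                bmask)
      grads <- net_backward(params, batch, config, scaler, fw$cache, dpred,
                            dropout_masks = dmask)
      st <- adam_step(params, grads, state, config$learning_rate,
                      config$weight_decay)
      params <- st$params; state <- st$state
    }
    vp <- net_forward(params, val_batch, config, scaler)$pred
    vloss <- masked_multitask_loss(vp, val$labels, val$mask)
    log_tr <- c(log_tr, ep_loss / nb); log_val <- c(log_val, vloss)
    ma <- mean(log_val[max(1, epoch - config$ma_window + 1):epoch])
    improved <- FALSE
    if (vloss < best) {
      best <- vloss; best_params <- params; best_epoch <- epoch
      improved <- TRUE
    }
    if (ma < best_ma) { best_ma <- ma; improved <- TRUE }
    wait <- if (improved) 0L else wait + 1L
    if (wait >= config$patience) break
  }
  structure(list(params = best_params, scaler = scaler, config = config,
                 training_log = data.frame(epoch = seq_along(log_val),
                                           train_loss = log_tr,
                                           val_loss = log_val),
                 best_epoch = best_epoch, n_tasks = n_tasks),
            class = "pna_net")
}

# predictions from a trained core net on pre-featurized inputs
predict_pna <- function(net, pack, features) {
  batch <- list(pack = pack, features = features)
  net_forward(net$params, batch, net$config, net$scaler)$pred
}
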