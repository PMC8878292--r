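## High-level model interface: featurization store, fitting, prediction,
## checkpoints.

#' Featurize a set of compounds
#'
#' Computes, once, everything the model consumes: molecular graphs for the
#' PNA branch, the concatenated fingerprint block for the descriptor
#' branch, and ECFP4 keys for similarity. SMILES are expected to be
#' canonical and desalted already (see [canonicalize_desalt()]); rows that
#' fail to parse get empty graphs/all-zero bits and are flagged.
#'
#' @param smiles Character vector of canonical SMILES.
#' @param roster Fingerprint families for the block.
#' @return Object of class `feature_store`.
#' @export
featurize_compounds <- function(smiles,
                                roster = default_fingerprint_roster()) {
  mols <- parse_mol_batch(smiles)
  graphs <- lapply(mols, function(m) {
    if (is.null(m)) return(NULL)
    tryCatch(graph_from_mol(m), error = function(e) NULL)
  })
  ok <- !vapply(graphs, is.null, logical(1))
  # unparsable rows become single-atom placeholders so packs stay aligned;
  # they are masked out of training and flagged at prediction time
  if (any(!ok)) graphs[!ok] <- list(smiles_to_graph("C"))
  block <- fingerprint_block(smiles, families = roster, mols = mols)
  keys <- ecfp4(smiles, mols = mols)
  structure(list(smiles = smiles, graphs = graphs, block = block,
                 keys = keys, parse_ok = ok & block$parse_ok,
                 roster = roster),
            class = "feature_store")
}

#' @export
print.feature_store <- function(x, ...) {
  cat(sprintf("<feature_store> %d compounds, %d fingerprint bits, %s\n",
              length(x$smiles), ncol(x$block$bits),
              paste0(length(x$roster), " families")))
  invisible(x)
}

store_rows <- function(features, smiles) {
  idx <- match(smiles, features$smiles)
  if (anyNA(idx)) stop("feature store is missing ",
                       sum(is.na(idx)), " compounds")
  idx
}

#' Fit the multitask PNA+DNN model
#'
#' End-to-end fit on a curated entry table: featurizes (graphs +
#' fingerprint block), fits the PCA reducer on the training rows only,
#' computes the degree-scaler normalization on training graphs only, and
#' trains the network with the masked multitask loss, Adam with L2
#' regularization, and moving-average early stopping on the validation
#' split.
#'
#' @param entries Curated entries with `split` assigned (`train` /
#'   `validation`; `external_test` rows are ignored here). If no split
#'   column is present a 90:10 train/validation split is made per task
#'   label with the config seed.
#' @param config Configuration from [default_net_config()].
#' @param features Optional [featurize_compounds()] store covering all
#'   entries.
#' @return Object of class `qsar_model`.
#' @export
qsar_fit <- function(entries, config = default_net_config(),
                     features = NULL) {
  targets <- kinase_targets()
  if (is.null(entries$split)) {
    if (is.null(entries$task_label)) entries <- assign_task_labels(entries)
    entries$split <- "train"
    fold <- stratified_kfold(entries, k = 10, seed = config$seed)
    entries$split[fold == 1] <- "validation"
  }
  roster <- config$roster %||% default_fingerprint_roster()
  if (is.null(features)) features <- featurize_compounds(entries$smiles,
                                                         roster = roster)
  tr <- entries[entries$split == "train", , drop = FALSE]
  va <- entries[entries$split == "validation", , drop = FALSE]
  if (nrow(va) == 0) {  # degenerate: borrow a slice of train
    take <- seq_len(max(1, nrow(tr) %/% 10))
    va <- tr[take, , drop = FALSE]
    tr <- tr[-take, , drop = FALSE]
  }
  it <- store_rows(features, tr$smiles)
  iv <- store_rows(features, va$smiles)
  reducer <- fit_feature_reducer(features$block$bits[it, , drop = FALSE],
                                 variance_target = config$pca_variance %||%
                                   0.95)
  red_tr <- predict(reducer, features$block$bits[it, , drop = FALSE])
  red_va <- predict(reducer, features$block$bits[iv, , drop = FALSE])
  lab_tr <- activity_matrix(tr); lab_va <- activity_matrix(va)
  train_data <- list(pack = pack_graphs(features$graphs[it]),
                     features = red_tr, labels = lab_tr,
                     mask = !is.na(lab_tr))
  val_data <- list(pack = pack_graphs(features$graphs[iv]),
                   features = red_va, labels = lab_va,
                   mask = !is.na(lab_va))
  net <- train_pna(train_data, val_data, config)
  train_ranges <- apply(lab_tr, 2, function(v)
    if (all(is.na(v))) c(NA, NA) else range(v, na.rm = TRUE))
  structure(list(net = net, reducer = reducer, roster = roster,
                 targets = targets, config = config,
                 train_smiles = tr$smiles,
                 train_ranges = train_ranges,
                 ad = NULL,
                 versions = list(
                   pnaqsar = as.character(utils::packageVersion("pnaqsar")),
                   R = R.version.string)),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf(paste0("<qsar_model> %d targets, %d training compounds, ",
                     "%d fingerprint families -> %d PCA components%s\n"),
              length(x$targets), length(x$train_smiles), length(x$roster),
              x$reducer$k,
              if (is.null(x$ad)) "" else ", AD fitted"))
  invisible(x)
}

#' Predict pIC50 for a list of SMILES
#'
#' End-to-end prediction: canonicalize/desalt, featurize with the model's
#' own fingerprint roster and reducer, and run the network. Unparsable
#' SMILES yield an all-`NA` row (flagged in the `parse_ok` attribute)
#' without affecting other rows.
#'
#' @param model A `qsar_model`.
#' @param smiles Character vector of SMILES (raw; canonicalized
#'   internally unless a feature store row is supplied).
#' @param features Optional feature store containing the (already
#'   canonical) SMILES; skips canonicalization.
#' @return Numeric matrix (n x 7) of predicted pIC50, columns named by
#'   target; attribute `parse_ok`.
#' @export
predict_pic50 <- function(model, smiles, features = NULL) {
  if (is.null(features)) {
    can <- canonicalize_desalt(smiles)
    okm <- can$parse_ok
    use <- ifelse(okm, can$smiles, "C")
    features <- featurize_compounds(use, roster = model$roster)
    idx <- seq_along(smiles)
    ok <- okm & features$parse_ok
  } else {
    idx <- store_rows(features, smiles)
    ok <- features$parse_ok[idx]
  }
  pack <- pack_graphs(features$graphs[idx])
  red <- predict(model$reducer,
                 features$block$bits[idx, , drop = FALSE])
  pred <- predict_pna(model$net, pack, red)
  colnames(pred) <- model$targets
  pred[!ok, ] <- NA_real_
  attr(pred, "parse_ok") <- ok
  pred
}

#' Attach applicability-domain parameters to a model
#'
#' @param model A `qsar_model`.
#' @param ad An `ad_params` object from [fit_ad_params()].
#' @return The model with the AD attached.
#' @export
set_model_ad <- function(model, ad) {
  stopifnot(inherits(model, "qsar_model"), inherits(ad, "ad_params"))
  model$ad <- ad
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the network weights, degree
#' scaler, PCA reducer, fingerprint roster, target order, configuration,
#' AD parameters (if fitted) and version stamps. Loading refuses a
#' checkpoint whose roster or target order does not match the current
#' package constants.
#'
#' @param model A `qsar_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the `qsar_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "qsar_model")) stop("not a qsar_model checkpoint")
  if (!identical(model$targets, kinase_targets()))
    stop("checkpoint target order does not match this package")
  reg <- names(fingerprint_families())
  if (!all(model$roster %in% reg))
    stop("checkpoint fingerprint roster contains unknown families: ",
         paste(setdiff(model$roster, reg), collapse = ", "))
  model
}

#' Entries table from a synthetic library truth
#'
#' Builds the curated-style wide entry table directly from a generated
#' library's observed labels (bypassing curation), canonicalizing the
#' SMILES and dropping canonical duplicates. Useful for model-quality
#' studies where the generating truth must stay aligned with the entries.
#'
#' @param lib Result of [generate_library()].
#' @return Entries data frame with `pIC50_<target>` columns, `task_label`
#'   and the aligned `truth` matrix as an attribute.
#' @export
library_entries <- function(lib) {
  tr <- lib$truth
  can <- canonicalize_desalt(tr$smiles)
  keep <- which(can$parse_ok & !duplicated(can$smiles))
  ent <- data.frame(smiles = can$smiles[keep], stringsAsFactors = FALSE)
  targets <- kinase_targets()
  obs <- matrix(NA_real_, length(keep), length(targets))
  colnames(obs) <- targets
  present <- match(colnames(tr$pic50), targets)
  om <- tr$observed; om[!tr$mask] <- NA
  obs[, present] <- om[keep, , drop = FALSE]
  for (t in targets) ent[[paste0("pIC50_", t)]] <- obs[, t]
  ent <- assign_task_labels(ent)
  attr(ent, "scaffold") <- tr$combos$scaffold[keep]
  truth_full <- matrix(NA_real_, length(keep), length(targets),
                       dimnames = list(NULL, targets))
  truth_full[, present] <- tr$pic50[keep, , drop = FALSE]
  attr(ent, "truth") <- truth_full
  ent
}
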