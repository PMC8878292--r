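## Activity-cliff analysis: identification and iterative removal of
## activity-cliff (AC) generators from the train-validation pool, per
## target, scored by the mean activity-similarity difference.

#' Activity-cliff pairs for one target
#'
#' An AC pair is two compounds labelled for the same target with ECFP4
#' Tanimoto similarity at or above `sim_threshold` and an absolute pIC50
#' difference at or above `delta_threshold`.
#'
#' @param entries Compound entries with `pIC50_<target>` columns.
#' @param target Target name.
#' @param sim_threshold Tanimoto threshold (default 0.9).
#' @param delta_threshold pIC50 difference threshold (default 1.0).
#' @param keys Optional precomputed ECFP4 key matrix aligned with
#'   `entries` rows.
#' @return Data frame of pairs `(i, j, similarity, delta)` with row
#'   indices into `entries`.
#' @export
activity_cliff_pairs <- function(entries, target, sim_threshold = 0.9,
                                 delta_threshold = 1.0, keys = NULL) {
  col <- paste0("pIC50_", target)
  lab <- which(!is.na(entries[[col]]))
  if (length(lab) < 2)
    return(data.frame(i = integer(0), j = integer(0),
                      similarity = numeric(0), delta = numeric(0)))
  if (is.null(keys)) keys <- ecfp4(entries$smiles)
  sim <- tanimoto_matrix(keys[lab, , drop = FALSE],
                         keys[lab, , drop = FALSE])
  act <- entries[[col]][lab]
  dd <- abs(outer(act, act, "-"))
  hit <- which(sim >= sim_threshold & dd >= delta_threshold &
                 upper.tri(sim), arr.ind = TRUE)
  data.frame(i = lab[hit[, 1]], j = lab[hit[, 2]],
             similarity = sim[hit], delta = dd[hit])
}

#' Remove activity-cliff generators for one target
#'
#' An AC generator is a compound participating in at least one AC pair
#' whose mean activity-similarity difference — the mean over its pairs of
#' `|delta pIC50| - (1 - Tanimoto)` — is positive. Generators are removed
#' iteratively (highest mean difference first; ties broken by pair count,
#' then SMILES) until no AC pair remains. Removal blanks the compound's
#' label for that target only; the full removal log is returned so
#' alternative cliff definitions can be audited.
#'
#' Never apply this to external-test compounds: restrict `entries` to the
#' train-validation pool.
#'
#' @inheritParams activity_cliff_pairs
#' @return List with `entries` (labels blanked), `removed` (log data
#'   frame) and `n_pairs_initial`.
#' @export
remove_activity_cliff_generators <- function(entries, target,
                                             sim_threshold = 0.9,
                                             delta_threshold = 1.0,
                                             keys = NULL) {
  col <- paste0("pIC50_", target)
  if (sum(!is.na(entries[[col]])) < 2)
    return(list(entries = entries, removed = data.frame(),
                n_pairs_initial = 0L))
  if (is.null(keys)) keys <- ecfp4(entries$smiles)
  log_rows <- list()
  iter <- 0L
  pairs0 <- NULL
  repeat {
    pairs <- activity_cliff_pairs(entries, target, sim_threshold,
                                  delta_threshold, keys = keys)
    if (is.null(pairs0)) pairs0 <- nrow(pairs)
    if (nrow(pairs) == 0) break
    iter <- iter + 1L
    members <- c(pairs$i, pairs$j)
    score_term <- rep(pairs$delta - (1 - pairs$similarity), 2)
    agg <- tapply(score_term, members, mean)
    npair <- table(members)
    cand <- as.integer(names(agg))
    ord <- order(-as.numeric(agg), -as.numeric(npair),
                 entries$smiles[cand])
    worst <- cand[ord[1]]
    if (agg[as.character(worst)] <= 0) break  # no generator by definition
    log_rows[[iter]] <- data.frame(
      smiles = entries$smiles[worst], target = target, iteration = iter,
      mean_act_sim_diff = unname(agg[as.character(worst)]),
      n_pairs = unname(as.integer(npair[as.character(worst)])))
    entries[[col]][worst] <- NA_real_
  }
  list(entries = entries,
       removed = if (length(log_rows)) do.call(rbind, log_rows)
                 else data.frame(),
       n_pairs_initial = pairs0)
}

#' Remove activity-cliff generators for every target
#'
#' Applies [remove_activity_cliff_generators()] per target over the
#' train-validation pool (external-test rows are passed through
#' untouched), drops compounds left with no activity at all, and refreshes
#' task labels for compounds whose labelled target was blanked.
#'
#' @param entries Entries with `split` assigned.
#' @inheritParams activity_cliff_pairs
#' @return List with `entries` and the combined removal log.
#' @export
remove_cliffs_all_targets <- function(entries, sim_threshold = 0.9,
                                      delta_threshold = 1.0, keys = NULL) {
  pool <- entries$split != "external_test"
  sub <- entries[pool, , drop = FALSE]
  if (is.null(keys)) keys <- ecfp4(sub$smiles)
  logs <- list()
  for (tg in kinase_targets()) {
    res <- remove_activity_cliff_generators(sub, tg, sim_threshold,
                                            delta_threshold, keys = keys)
    sub <- res$entries
    if (nrow(res$removed)) logs[[tg]] <- res$removed
  }
  am <- activity_matrix(sub)
  empty <- rowSums(!is.na(am)) == 0
  # refresh labels where the labelled target was blanked
  counts <- colSums(!is.na(activity_matrix(entries)))
  sub <- assign_task_labels(sub, target_counts = counts)
  sub <- sub[!empty, , drop = FALSE]
  out <- rbind(sub, entries[!pool, , drop = FALSE])
  rownames(out) <- NULL
  list(entries = out,
       removed = if (length(logs)) do.call(rbind, c(logs,
                                                    make.row.names = FALSE))
                 else data.frame())
}
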