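## Two-stage applicability domain (AD): a cross-validation-optimized global
## nearest-neighbor Tanimoto threshold, plus a per-target neighborhood
## reliability check based on the cross-validation residuals of training
## neighbors.

#' Optimize the global similarity threshold from CV residuals
#'
#' Per fold: compounds whose (mean, across labelled targets) squared
#' out-of-fold error is at or below the fold's third quartile are kept;
#' their nearest-neighbor similarities are z-scored, and the fold
#' threshold is the minimum similarity among compounds with `|z|` within
#' `confidence_z`. The global threshold is the mean over fold thresholds.
#'
#' @param cv A `cv_result` from [cross_validate()] (or its `residuals`
#'   data frame with columns `smiles`, `fold`, `sq_error`, `similarity`).
#' @param confidence_z Critical z-value (default 1.96, two-sided 95%).
#' @param min_fold_size Folds with fewer compounds are skipped with a
#'   warning (default 4).
#' @return The optimized Tanimoto threshold (scalar).
#' @export
optimize_global_threshold <- function(cv, confidence_z = 1.96,
                                      min_fold_size = 4) {
  res <- if (inherits(cv, "cv_result")) cv$residuals else cv
  key <- paste(res$smiles, res$fold, sep = "\r")
  agg <- stats::aggregate(res$sq_error, by = list(key = key), FUN = mean)
  first <- !duplicated(key)
  meta <- data.frame(key = key[first], fold = res$fold[first],
                     similarity = res$similarity[first])
  agg <- merge(agg, meta, by = "key")
  thresholds <- c()
  for (f in sort(unique(agg$fold))) {
    sub <- agg[agg$fold == f, , drop = FALSE]
    if (nrow(sub) < min_fold_size) {
      warning("fold ", f, " has fewer than ", min_fold_size,
              " compounds; skipped for threshold optimization")
      next
    }
    q3 <- stats::quantile(sub$x, 0.75, type = 7, names = FALSE)
    kept <- sub[sub$x <= q3, , drop = FALSE]
    s <- kept$similarity
    sdv <- stats::sd(s)
    z <- if (is.na(sdv) || sdv == 0) rep(0, length(s)) else
      (s - mean(s)) / sdv
    within <- abs(z) <= confidence_z
    if (!any(within)) next
    thresholds <- c(thresholds, min(s[within]))
  }
  if (length(thresholds) == 0)
    stop("no fold produced a similarity threshold")
  mean(thresholds)
}

#' Fit applicability-domain parameters
#'
#' Combines the CV-optimized global similarity threshold with per-target
#' reliability data: for each target, the ECFP4 keys and out-of-fold
#' squared residuals of its labelled training compounds, and a cutoff set
#' at `cutoff_fraction` (default 10%) of the target's training pIC50
#' range. By default the cutoff is compared against the root mean squared
#' residual of the neighbors (`scale = "rmsr"`, dimensionally consistent);
#' `scale = "literal"` compares the mean squared residual itself.
#'
#' @param cv A `cv_result` from [cross_validate()].
#' @param entries The train-validation entries the CV ran on.
#' @param keys ECFP4 key matrix aligned with `entries` rows (computed when
#'   omitted).
#' @param neighbor_similarity Tanimoto radius for target neighbors (0.35).
#' @param confidence_z Critical z-value for threshold optimization (1.96).
#' @param cutoff_fraction Fraction of the training property range (0.10).
#' @param scale `"rmsr"` or `"literal"` (see above).
#' @return Object of class `ad_params`.
#' @export
fit_ad_params <- function(cv, entries, keys = NULL,
                          neighbor_similarity = 0.35, confidence_z = 1.96,
                          cutoff_fraction = 0.10, scale = c("rmsr",
                                                            "literal")) {
  scale <- match.arg(scale)
  if (is.null(keys)) keys <- ecfp4(entries$smiles)
  global_threshold <- optimize_global_threshold(cv, confidence_z)
  targets <- kinase_targets()
  per_target <- list()
  for (tg in targets) {
    col <- paste0("pIC50_", tg)
    lab <- which(!is.na(entries[[col]]))
    if (length(lab) == 0) { per_target[[tg]] <- NULL; next }
    rng <- diff(range(entries[[col]][lab]))
    res <- cv$residuals[cv$residuals$target == tg, , drop = FALSE]
    sq <- res$sq_error[match(entries$smiles[lab], res$smiles)]
    per_target[[tg]] <- list(
      rows = lab, range = rng, cutoff = cutoff_fraction * rng,
      keys = keys[lab, , drop = FALSE], sq_residuals = sq)
  }
  structure(list(global_threshold = global_threshold,
                 neighbor_similarity = neighbor_similarity,
                 confidence_z = confidence_z,
                 cutoff_fraction = cutoff_fraction, scale = scale,
                 train_keys = keys, per_target = per_target),
            class = "ad_params")
}

#' @export
print.ad_params <- function(x, ...) {
  cat(sprintf(paste0("<ad_params> global Tanimoto threshold %.3f, ",
                     "neighbor similarity %.2f, cutoff %.0f%% of training ",
                     "range (%s scale)\n"),
              x$global_threshold, x$neighbor_similarity,
              100 * x$cutoff_fraction, x$scale))
  invisible(x)
}

#' Per-target neighborhood reliability
#'
#' Target neighbors of a query are the training compounds labelled for the
#' target with Tanimoto similarity at or above `neighbor_similarity`. The
#' check passes when neighbors exist and their mean CV squared residual is
#' below the target cutoff (compared on the scale configured in
#' `ad_params`). Zero neighbors fail: no evidence of reliability.
#'
#' @param query ECFP4 key (logical vector) or matrix of keys.
#' @param target Target name.
#' @param params An `ad_params` object.
#' @return Data frame with `neighbor_count`, `neighbor_msr`, `pass`.
#' @export
target_reliability <- function(query, target, params) {
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  pt <- params$per_target[[target]]
  n <- nrow(query)
  if (is.null(pt))
    return(data.frame(neighbor_count = rep(0L, n),
                      neighbor_msr = rep(NA_real_, n),
                      pass = rep(FALSE, n)))
  sim <- tanimoto_matrix(query, pt$keys)
  out <- lapply(seq_len(n), function(i) {
    nb <- which(sim[i, ] >= params$neighbor_similarity &
                  !is.na(pt$sq_residuals))
    if (length(nb) == 0)
      return(data.frame(neighbor_count = 0L, neighbor_msr = NA_real_,
                        pass = FALSE))
    msr <- mean(pt$sq_residuals[nb])
    ok <- if (params$scale == "rmsr") sqrt(msr) < pt$cutoff
          else msr < pt$cutoff
    data.frame(neighbor_count = length(nb), neighbor_msr = msr, pass = ok)
  })
  do.call(rbind, out)
}

#' Assign applicability-domain verdicts
#'
#' A query is "inside" the domain for a target iff (i) its nearest-neighbor
#' Tanimoto similarity to the training compounds reaches the global
#' threshold and (ii) the per-target reliability check passes.
#'
#' @param query_keys ECFP4 key matrix (one row per query).
#' @param params An `ad_params` object.
#' @return Data frame with `nearest_similarity` plus, per target,
#'   `AD_<target>` columns holding `"inside"`/`"outside"`.
#' @export
assign_ad <- function(query_keys, params) {
  if (is.vector(query_keys)) query_keys <- matrix(query_keys, nrow = 1)
  nn <- nearest_neighbor_similarity(query_keys, params$train_keys)
  out <- data.frame(nearest_similarity = nn$similarity)
  global_ok <- nn$similarity >= params$global_threshold
  for (tg in kinase_targets()) {
    rel <- target_reliability(query_keys, tg, params)
    out[[paste0("AD_", tg)]] <- ifelse(global_ok & rel$pass,
                                       "inside", "outside")
  }
  out
}
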