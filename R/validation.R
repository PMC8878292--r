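## Regression metrics, the Golbraikh-Tropsha acceptability multicriterion,
## and stratified 10-fold cross-validation with pooled out-of-fold metrics.

#' Root-mean-square error
#'
#' @param pred,obs Numeric vectors of equal, non-zero length.
#' @return `sqrt(mean((pred - obs)^2))`, in pIC50 units.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1)
  sqrt(mean((pred - obs)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the observed mean as reference.
#'
#' @param pred,obs Numeric vectors of equal length (n >= 2).
#' @return R-squared; `NA` with a warning when the observations have zero
#'   variance.
#' @export
r_squared <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) {
    warning("observed values have zero variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((pred - obs)^2) / sst
}

#' Regression through the origin
#'
#' Least-squares slope through the origin of `y` on `x`
#' (`k = sum(xy)/sum(x^2)`) and the associated correlation coefficient
#' `r0^2 = 1 - sum((y - kx)^2) / sum((y - mean(y))^2)`. For the
#' Golbraikh-Tropsha checks this is evaluated in both orientations:
#' predicted on the X axis (giving `R0^2` and the slope `k`) and
#' experimental on the X axis (giving `R0'^2`).
#'
#' @param x,y Numeric vectors; `sum(x^2)` must be positive.
#' @return List with `slope` and `r0_squared`.
#' @export
through_origin_stats <- function(x, y) {
  stopifnot(length(x) == length(y))
  sxx <- sum(x^2)
  if (sxx <= 0) stop("degenerate x: sum of squares is zero")
  k <- sum(x * y) / sxx
  sst <- sum((y - mean(y))^2)
  r0 <- if (sst == 0) NA_real_ else 1 - sum((y - k * x)^2) / sst
  list(slope = k, r0_squared = r0)
}

#' Full external-validation statistics for one target
#'
#' @param pred Predicted pIC50 (X axis for `k` and `R0^2`).
#' @param obs Experimental pIC50.
#' @return List with `rmse`, `r2`, `r0sq_pred_x` (predicted on X),
#'   `r0sq_obs_x` (experimental on X), `k_slope` and `n`.
#' @export
regression_metrics <- function(pred, obs) {
  to1 <- through_origin_stats(pred, obs)  # predicted on X
  to2 <- through_origin_stats(obs, pred)  # experimental on X
  list(rmse = rmse(pred, obs), r2 = r_squared(pred, obs),
       r0sq_pred_x = to1$r0_squared, r0sq_obs_x = to2$r0_squared,
       k_slope = to1$slope, n = length(obs))
}

#' Golbraikh-Tropsha acceptability verdict
#'
#' Applies the five-condition multicriterion for an acceptable QSAR model:
#' `Q^2 > 0.5`, `R^2 > 0.6`, `(R^2 - R0^2)/R^2 < 0.1`, `0.9 <= k <= 1.1`
#' and `|R0^2 - R0'^2| < 0.3`, where `R0^2`/`R0'^2` are the
#' through-origin correlation coefficients of predicted-versus-experimental
#' in the two orientations and `k` the through-origin slope with predicted
#' values on the X axis.
#'
#' @param q2 Cross-validated determination coefficient.
#' @param metrics External-test metrics from [regression_metrics()].
#' @return List of five booleans plus `overall` (their conjunction).
#' @export
golbraikh_tropsha <- function(q2, metrics) {
  q2_pass <- is.finite(q2) && q2 > 0.5
  r2_pass <- is.finite(metrics$r2) && metrics$r2 > 0.6
  rel_r0_pass <- is.finite(metrics$r2) && metrics$r2 != 0 &&
    is.finite(metrics$r0sq_pred_x) &&
    (metrics$r2 - metrics$r0sq_pred_x) / metrics$r2 < 0.1
  k_pass <- is.finite(metrics$k_slope) &&
    metrics$k_slope >= 0.9 && metrics$k_slope <= 1.1
  r0_diff_pass <- is.finite(metrics$r0sq_pred_x) &&
    is.finite(metrics$r0sq_obs_x) &&
    abs(metrics$r0sq_pred_x - metrics$r0sq_obs_x) < 0.3
  list(q2_pass = q2_pass, r2_pass = r2_pass, rel_r0_pass = rel_r0_pass,
       k_pass = k_pass, r0_diff_pass = r0_diff_pass,
       overall = q2_pass && r2_pass && rel_r0_pass && k_pass && r0_diff_pass)
}

#' Stratified k-fold cross-validation
#'
#' Splits the train-validation pool into `k` folds preserving task-label
#' proportions, trains a fresh model on each fold complement and predicts
#' the holdout. RMSECV and Q^2 per target are pooled over all out-of-fold
#' predictions. The per-compound out-of-fold squared residuals and the
#' nearest-neighbor Tanimoto similarity of each holdout compound to its
#' fold's training compounds are retained for the applicability domain.
#'
#' @param entries Curated compound data frame (see [curate_records()]) with
#'   `split` other than `"external_test"`.
#' @param config Net configuration ([default_net_config()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and training.
#' @param features Optional pre-computed [featurize_compounds()] store.
#' @param fit_fun Model fitting function `(entries, config, features)`;
#'   defaults to [qsar_fit()]. Injectable so an oracle predictor can
#'   exercise the bookkeeping exactly.
#' @param predict_fun Matching prediction function
#'   `(model, smiles, features)`; defaults to [predict_pic50()].
#' @return Object of class `cv_result`: per-target `rmsecv`/`q2` table and
#'   a per-compound residual table with fold ids and similarities.
#' @export
cross_validate <- function(entries, config = default_net_config(), k = 10,
                           seed = 1, features = NULL, fit_fun = qsar_fit,
                           predict_fun = predict_pic50) {
  stopifnot(k >= 2)
  pool <- if (is.null(entries$split)) entries else
    entries[is.na(entries$split) | entries$split != "external_test", ,
            drop = FALSE]
  folds <- stratified_kfold(pool, k = k, seed = seed)
  targets <- kinase_targets()
  if (is.null(features))
    features <- featurize_compounds(pool$smiles,
                                    roster = config$roster %||%
                                      default_fingerprint_roster())
  res_rows <- list()
  for (f in seq_len(k)) {
    hold <- folds == f
    tr <- pool[!hold, , drop = FALSE]
    te <- pool[hold, , drop = FALSE]
    if (nrow(te) == 0) next
    cfg <- config
    cfg$seed <- seed + f
    model <- fit_fun(tr, cfg, features = features)
    pred <- predict_fun(model, te$smiles, features = features)
    sim <- nearest_neighbor_similarity(
      features$keys[match(te$smiles, features$smiles), , drop = FALSE],
      features$keys[match(tr$smiles, features$smiles), , drop = FALSE]
    )$similarity
    for (t in seq_along(targets)) {
      col <- paste0("pIC50_", targets[t])
      ok <- !is.na(te[[col]])
      if (!any(ok)) next
      res_rows[[length(res_rows) + 1]] <- data.frame(
        smiles = te$smiles[ok], target = targets[t], fold = f,
        obs = te[[col]][ok], pred = pred[ok, t],
        sq_error = (pred[ok, t] - te[[col]][ok])^2,
        similarity = sim[ok], stringsAsFactors = FALSE)
    }
  }
  residuals <- do.call(rbind, res_rows)
  per_target <- do.call(rbind, lapply(targets, function(tg) {
    r <- residuals[residuals$target == tg, , drop = FALSE]
    if (nrow(r) < 2)
      return(data.frame(target = tg, n = nrow(r), rmsecv = NA_real_,
                        q2 = NA_real_))
    data.frame(target = tg, n = nrow(r), rmsecv = rmse(r$pred, r$obs),
               q2 = r_squared(r$pred, r$obs))
  }))
  all_rmse <- rmse(residuals$pred, residuals$obs)
  structure(list(per_target = per_target, residuals = residuals,
                 rmsecv_all = all_rmse, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold, all-target RMSECV %.4f\n", x$k,
              x$rmsecv_all))
  print(x$per_target, row.names = FALSE)
  invisible(x)
}

#' Assemble the per-target validation report
#'
#' Combines calibration (training-set) fit, cross-validation and
#' external-test statistics with the Golbraikh-Tropsha verdict per target,
#' mirroring the usual calibration / internal validation / external
#' validation report layout.
#'
#' @param model A fitted `qsar_model`.
#' @param entries Curated compound data frame with split assignments.
#' @param cv A `cv_result` from [cross_validate()].
#' @param features Optional featurization store.
#' @return Object of class `validation_report` (data frame plus verdicts).
#' @export
validation_report <- function(model, entries, cv, features = NULL) {
  targets <- kinase_targets()
  train <- entries[entries$split == "train", , drop = FALSE]
  ext <- entries[entries$split == "external_test", , drop = FALSE]
  pred_tr <- predict_pic50(model, train$smiles, features = features)
  pred_ex <- if (nrow(ext)) predict_pic50(model, ext$smiles,
                                          features = features) else NULL
  rows <- list(); verdicts <- list()
  for (t in seq_along(targets)) {
    col <- paste0("pIC50_", targets[t])
    ok_tr <- !is.na(train[[col]])
    rmse_tr <- r2_tr <- NA_real_
    if (sum(ok_tr) >= 2) {
      rmse_tr <- rmse(pred_tr[ok_tr, t], train[[col]][ok_tr])
      r2_tr <- r_squared(pred_tr[ok_tr, t], train[[col]][ok_tr])
    }
    pt <- cv$per_target[cv$per_target$target == targets[t], ]
    rmsep <- r2_ext <- NA_real_; met <- NULL
    if (!is.null(pred_ex)) {
      ok_ex <- !is.na(ext[[col]])
      if (sum(ok_ex) >= 3) {
        met <- regression_metrics(pred_ex[ok_ex, t], ext[[col]][ok_ex])
        rmsep <- met$rmse; r2_ext <- met$r2
      }
    }
    verdict <- if (!is.null(met)) golbraikh_tropsha(pt$q2, met) else NULL
    verdicts[[targets[t]]] <- verdict
    rows[[t]] <- data.frame(
      target = targets[t], rmse_train = rmse_tr, r2_train = r2_tr,
      rmsecv = pt$rmsecv, q2 = pt$q2, rmsep = rmsep, r2_ext = r2_ext,
      gt_overall = if (is.null(verdict)) NA else verdict$overall)
  }
  structure(list(table = do.call(rbind, rows), verdicts = verdicts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (calibration / internal / external):\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) if (is.numeric(v)) round(v, 4)
                    else v)
  print(tab, row.names = FALSE)
  invisible(x)
}
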