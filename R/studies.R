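## Bundled synthetic-data studies: multi-seed model-quality experiments on
## generated libraries with known truth. These back the package's
## behavioural guarantees (learning beats a trivial baseline, multitask
## transfer helps data-poor tasks, the applicability domain separates
## reliable from unreliable predictions) and are what the acceptance
## script reruns. Problem sizes are chosen so a full study runs in minutes
## on one CPU; see the methods vignette.

study_config <- function(seed) {
  study_net_config(seed = seed, roster = compact_fingerprint_roster())
}

pooled_external_stats <- function(model, entries, features, targets) {
  ext <- entries[entries$split == "external_test", , drop = FALSE]
  tr <- entries[entries$split != "external_test", , drop = FALSE]
  pred <- predict_pic50(model, ext$smiles, features = features)
  obs_all <- pred_all <- base_all <- numeric(0)
  for (tg in targets) {
    col <- paste0("pIC50_", tg)
    ok <- !is.na(ext[[col]])
    if (!any(ok)) next
    obs_all <- c(obs_all, ext[[col]][ok])
    pred_all <- c(pred_all, pred[ok, tg])
    base_all <- c(base_all, rep(mean(tr[[col]], na.rm = TRUE), sum(ok)))
  }
  list(rmse = rmse(pred_all, obs_all),
       baseline_rmse = rmse(base_all, obs_all),
       r2 = r_squared(pred_all, obs_all), n = length(obs_all))
}

#' Learning-sanity study
#'
#' Generates one 500-compound, two-task library (descriptor-linear truth,
#' noise sd 0.3 pIC50, task correlation 0.7, 90% label coverage) and
#' trains the multitask model under `n_seeds` different split/training
#' seeds. Per seed it reports the pooled external-test RMSE, the RMSE of
#' the predict-the-training-mean baseline, and the pooled external R^2.
#'
#' @param n_seeds Number of training seeds (default 20).
#' @param seed Base seed for the library and the seed sequence.
#' @param config Net configuration; defaults to the compact study config.
#' @return Data frame with one row per seed.
#' @export
study_learning_sanity <- function(n_seeds = 20, seed = 1,
                                  config = NULL) {
  spec <- synthetic_spec(n_compounds = 500, targets = c("EGFR", "MET"),
                         coverage = 0.9,
                         activity_model = "descriptor_linear",
                         noise_sd = 0.3, task_correlation = 0.7,
                         seed = seed)
  lib <- generate_library(spec)
  ent0 <- library_entries(lib)
  cfg0 <- config %||% study_config(seed)
  features <- featurize_compounds(ent0$smiles, roster = cfg0$roster)
  out <- list()
  for (s in seq_len(n_seeds)) {
    sd_s <- seed * 1000 + s
    ent <- stratified_split(ent0, seed = sd_s)
    cfg <- cfg0; cfg$seed <- sd_s
    model <- qsar_fit(ent, cfg, features = features)
    st <- pooled_external_stats(model, ent, features, c("EGFR", "MET"))
    out[[s]] <- data.frame(seed = sd_s, rmse = st$rmse,
                           baseline_rmse = st$baseline_rmse, r2 = st$r2,
                           n_external = st$n,
                           beats_baseline = st$rmse < st$baseline_rmse)
  }
  do.call(rbind, out)
}

#' Multitask-transfer study
#'
#' Generates a 440-compound library in which a data-poor task (ERBB4,
#' roughly 40 labels) shares structure-activity signal with a data-rich
#' task (EGFR, roughly 400 labels; task correlation 0.7). Per seed, the
#' data-poor task is evaluated on held-out compounds against the
#' generating truth twice: once for the multitask model trained on both
#' tasks, once for a single-task model trained on the data-poor labels
#' alone.
#'
#' @inheritParams study_learning_sanity
#' @param n_seeds Number of seeds (default 10).
#' @return Data frame with per-seed multitask and single-task RMSE on the
#'   data-poor task.
#' @export
study_multitask_transfer <- function(n_seeds = 10, seed = 1,
                                     config = NULL) {
  spec <- synthetic_spec(n_compounds = 440, targets = c("EGFR", "ERBB4"),
                         coverage = c(EGFR = 0.91, ERBB4 = 0.10),
                         activity_model = "substructure_additive",
                         noise_sd = 0.3, task_correlation = 0.7,
                         seed = seed)
  lib <- generate_library(spec)
  ent0 <- library_entries(lib)
  truth <- attr(ent0, "truth")
  cfg0 <- config %||% study_config(seed)
  features <- featurize_compounds(ent0$smiles, roster = cfg0$roster)
  single <- ent0
  single$pIC50_EGFR <- NA_real_
  keep_single <- !is.na(single$pIC50_ERBB4)
  out <- list()
  for (s in seq_len(n_seeds)) {
    sd_s <- seed * 1000 + s
    ent <- stratified_split(ent0, seed = sd_s)
    cfg <- cfg0; cfg$seed <- sd_s
    m_mt <- qsar_fit(ent, cfg, features = features)
    ssub <- single[keep_single, , drop = FALSE]
    ssub <- suppressWarnings(
      assign_task_labels(ssub))
    ssub <- suppressWarnings(stratified_split(ssub, seed = sd_s))
    m_st <- qsar_fit(ssub, cfg, features = features)
    # evaluate on compounds unseen by both models, against the truth
    seen <- union(ent$smiles[ent$split != "external_test"],
                  ssub$smiles[ssub$split != "external_test"])
    hold <- which(!(ent0$smiles %in% seen))
    p_mt <- predict_pic50(m_mt, ent0$smiles[hold], features = features)
    p_st <- predict_pic50(m_st, ent0$smiles[hold], features = features)
    tv <- truth[hold, "ERBB4"]
    out[[s]] <- data.frame(seed = sd_s, n_eval = length(hold),
                           rmse_multitask = rmse(p_mt[, "ERBB4"], tv),
                           rmse_singletask = rmse(p_st[, "ERBB4"], tv))
  }
  do.call(rbind, out)
}

#' Applicability-domain study
#'
#' Generates a 400-compound, three-task library and holds out every
#' compound built on four of the fourteen scaffolds as a structurally
#' alien subset. Per seed, the model and its two-stage applicability
#' domain are fitted on the remaining scaffolds (3-fold cross-validation
#' supplies the residuals and the global similarity threshold), and the
#' mixed test set (in-domain external split plus the alien subset) is
#' screened. Reported per seed: RMSE of predictions flagged inside versus
#' outside the domain.
#'
#' @inheritParams study_multitask_transfer
#' @param cv_folds Folds for the AD residual cross-validation (default 3).
#' @return Data frame with per-seed inside/outside RMSE and counts.
#' @export
study_applicability_domain <- function(n_seeds = 10, seed = 1,
                                       config = NULL, cv_folds = 3) {
  targets <- c("EGFR", "MET", "ALK")
  spec <- synthetic_spec(n_compounds = 400, targets = targets,
                         coverage = 0.8,
                         activity_model = "substructure_additive",
                         noise_sd = 0.3, task_correlation = 0.7,
                         seed = seed)
  lib <- generate_library(spec)
  ent0 <- library_entries(lib)
  scaff <- attr(ent0, "scaffold")
  alien_scaffolds <- c("diarylurea", "diarylalkyne", "benzamide",
                       "anilinopyrimidine")
  alien <- ent0[scaff %in% alien_scaffolds, , drop = FALSE]
  alien$split <- "external_alien"
  pool0 <- ent0[!(scaff %in% alien_scaffolds), , drop = FALSE]
  cfg0 <- config %||% study_config(seed)
  cfg0$max_epochs <- min(cfg0$max_epochs, 40L)
  features <- featurize_compounds(ent0$smiles, roster = cfg0$roster)
  out <- list()
  for (s in seq_len(n_seeds)) {
    sd_s <- seed * 1000 + s
    ent <- stratified_split(pool0, seed = sd_s)
    cfg <- cfg0; cfg$seed <- sd_s
    trainval <- ent[ent$split != "external_test", , drop = FALSE]
    model <- qsar_fit(ent, cfg, features = features)
    cv <- cross_validate(trainval, cfg, k = cv_folds, seed = sd_s,
                         features = features)
    keys_tv <- features$keys[match(trainval$smiles, features$smiles), ,
                             drop = FALSE]
    ad <- fit_ad_params(cv, trainval, keys = keys_tv)
    test <- rbind(ent[ent$split == "external_test", , drop = FALSE],
                  alien)
    pred <- predict_pic50(model, test$smiles, features = features)
    verdict <- assign_ad(features$keys[match(test$smiles,
                                             features$smiles), ,
                                       drop = FALSE], ad)
    res_in <- res_out <- numeric(0)
    for (tg in targets) {
      col <- paste0("pIC50_", tg)
      ok <- !is.na(test[[col]])
      err <- pred[ok, tg] - test[[col]][ok]
      inside <- verdict[[paste0("AD_", tg)]][ok] == "inside"
      res_in <- c(res_in, err[inside])
      res_out <- c(res_out, err[!inside])
    }
    out[[s]] <- data.frame(
      seed = sd_s, global_threshold = ad$global_threshold,
      n_inside = length(res_in), n_outside = length(res_out),
      rmse_inside = if (length(res_in)) sqrt(mean(res_in^2)) else NA_real_,
      rmse_outside = if (length(res_out)) sqrt(mean(res_out^2))
                     else NA_real_)
  }
  do.call(rbind, out)
}
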