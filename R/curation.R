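## Activity-record curation: unit conversion, per-source deduplication,
## IQR-based property outlier removal, cross-source merging, task
## labelling and stratified splitting.

#' Convert molar IC50 to pIC50
#'
#' @param ic50_molar Positive IC50 in molar units.
#' @return `-log10(ic50_molar)`.
#' @export
#' @examples
#' to_pic50(1e-6)  # 6
to_pic50 <- function(ic50_molar) {
  if (any(!is.na(ic50_molar) & ic50_molar <= 0))
    stop("IC50 must be positive")
  -log10(ic50_molar)
}

#' Read an activity-record table
#'
#' Reads a delimited text export with required columns `smiles`, `target`
#' and exactly one activity column among `pic50`, `ic50_M` (molar) or
#' `ic50_nM` per row. Optional columns: `source`, `assay`, `mw`, `logp`,
#' `ro5_violations`. IC50 values are converted to pIC50; rows with
#' non-positive IC50 are rejected with a reason code.
#'
#' @param path CSV/TSV file path (delimiter sniffed from the header line).
#' @return List with `records` (data frame incl. `pic50`) and `rejected`.
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_activity_records.csv",
#'                  package = "pnaqsar")
#' rd <- read_activity_csv(f)
#' head(rd$records)
read_activity_csv <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("smiles", "target")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  bad_target <- !(df$target %in% kinase_targets())
  pic50 <- rep(NA_real_, nrow(df))
  reason <- rep(NA_character_, nrow(df))
  if ("pic50" %in% names(df)) {
    has <- !is.na(df$pic50)
    pic50[has] <- df$pic50[has]
  }
  for (cc in c("ic50_M", "ic50_nM")) {
    if (!cc %in% names(df)) next
    fac <- if (cc == "ic50_nM") 1e-9 else 1
    has <- is.na(pic50) & !is.na(df[[cc]])
    bad <- has & df[[cc]] <= 0
    reason[bad] <- "nonpositive_ic50"
    ok <- has & df[[cc]] > 0
    pic50[ok] <- to_pic50(df[[cc]][ok] * fac)
  }
  reason[is.na(pic50) & is.na(reason)] <- "no_activity_value"
  reason[bad_target] <- "unknown_target"
  df$pic50 <- pic50
  keep <- is.na(reason)
  for (cc in c("source", "assay")) if (!cc %in% names(df)) df[[cc]] <- ""
  list(records = df[keep, , drop = FALSE],
       rejected = cbind(df[!keep, , drop = FALSE],
                        reason = reason[!keep]))
}

#' Deduplicate records within one source
#'
#' Collapses exact duplicates (same compound, target, assay text and
#' value) and resolves conflicting values for the same compound/target by
#' retaining the lowest IC50 (highest pIC50). Records must carry canonical
#' SMILES and populated `pic50`.
#'
#' @param records Data frame with `smiles`, `target`, `pic50`, `assay`.
#' @return Data frame with one record per (smiles, target); attributes
#'   `n_exact_dups` and `n_conflicts` report what was collapsed.
#' @export
dedupe_within_source <- function(records) {
  if (nrow(records) == 0) return(records)
  exact_key <- paste(records$smiles, records$target, records$assay,
                     records$pic50, sep = "\r")
  n0 <- nrow(records)
  records <- records[!duplicated(exact_key), , drop = FALSE]
  n_exact <- n0 - nrow(records)
  key <- paste(records$smiles, records$target, sep = "\r")
  ord <- order(key, -records$pic50)
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  out <- records[!duplicated(key), , drop = FALSE]
  attr(out, "n_exact_dups") <- n_exact
  attr(out, "n_conflicts") <- nrow(records) - nrow(out)
  rownames(out) <- NULL
  out
}

#' IQR property-outlier filter
#'
#' Removes a record when any listed property falls outside
#' `[Q1 - 3 IQR, Q3 + 3 IQR]`, with quartiles computed per target over the
#' records being filtered (linear interpolation between order statistics,
#' R quantile type 7). Records with a missing property value pass that
#' property with a warning.
#'
#' @param records Data frame with `target` and the property columns.
#' @param property_names Character vector, e.g.
#'   `c("mw", "logp", "ro5_violations")`. Empty vector is the identity.
#' @param iqr_mult Multiplier of the IQR (default 3).
#' @return List with `kept` and `removed` data frames; `removed` carries a
#'   `reason` column naming the offending property.
#' @export
iqr_outlier_filter <- function(records, property_names,
                               iqr_mult = 3) {
  if (length(property_names) == 0 || nrow(records) == 0)
    return(list(kept = records, removed = records[0, , drop = FALSE]))
  bad <- rep(FALSE, nrow(records))
  why <- rep(NA_character_, nrow(records))
  warned <- FALSE
  for (tg in unique(records$target)) {
    sel <- which(records$target == tg)
    for (pn in property_names) {
      v <- records[[pn]][sel]
      if (is.null(v)) stop("unknown property column: ", pn)
      if (anyNA(v) && !warned) {
        warning("missing ", pn, " values pass the IQR filter unexamined")
        warned <- TRUE
      }
      vv <- v[!is.na(v)]
      if (length(vv) < 2) next
      q <- stats::quantile(vv, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - iqr_mult * iqr
      hi <- q[2] + iqr_mult * iqr
      out <- !is.na(v) & (v < lo | v > hi)
      newly <- sel[out] [!bad[sel[out]]]
      why[newly] <- pn
      bad[sel[out]] <- TRUE
    }
  }
  removed <- records[bad, , drop = FALSE]
  if (nrow(removed)) removed$reason <- why[bad]
  list(kept = records[!bad, , drop = FALSE], removed = removed)
}

#' Merge per-source record sets into compound entries
#'
#' Keys compounds by canonical SMILES; for each (compound, target) the
#' maximum pIC50 across sources is retained ("better-reported value").
#' Returns the wide compound-entry table used by the rest of the pipeline:
#' one row per compound with a `pIC50_<target>` column per target
#' (`NA` = not measured).
#'
#' @param per_source List of deduplicated record data frames.
#' @return Data frame with columns `smiles` and `pIC50_<target>`.
#' @export
merge_sources <- function(per_source) {
  all <- do.call(rbind, lapply(per_source, function(df)
    df[, c("smiles", "target", "pic50")]))
  targets <- kinase_targets()
  key <- paste(all$smiles, all$target, sep = "\r")
  ord <- order(key, -all$pic50)
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(key[ord]), , drop = FALSE]
  smiles <- sort(unique(all$smiles))
  out <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
  for (tg in targets) {
    col <- rep(NA_real_, length(smiles))
    sub <- all[all$target == tg, , drop = FALSE]
    col[match(sub$smiles, smiles)] <- sub$pic50
    out[[paste0("pIC50_", tg)]] <- col
  }
  out
}

activity_matrix <- function(entries) {
  as.matrix(entries[, paste0("pIC50_", kinase_targets()), drop = FALSE])
}

#' Assign multitask labels
#'
#' Each compound's task label is the reported target with the fewest
#' labelled compounds overall (so data-poor tasks keep their compounds in
#' their own stratum); ties are broken by the fixed target order.
#'
#' @param entries Compound-entry data frame from [merge_sources()].
#' @param target_counts Optional named count vector; computed from
#'   `entries` when omitted.
#' @return `entries` with a `task_label` column.
#' @export
assign_task_labels <- function(entries, target_counts = NULL) {
  targets <- kinase_targets()
  am <- activity_matrix(entries)
  if (is.null(target_counts)) target_counts <- colSums(!is.na(am))
  names(target_counts) <- targets
  rank_order <- order(target_counts, seq_along(targets))
  pref <- match(seq_along(targets), rank_order)  # smaller = rarer target
  entries$task_label <- apply(!is.na(am), 1, function(has) {
    if (!any(has)) return(NA_character_)
    targets[which(has)[which.min(pref[has])]]
  })
  entries
}

#' Stratified train/validation/external-test split
#'
#' Per task label, assigns approximately `external_fraction` of compounds
#' to the external test set first, then `validation_fraction` of the
#' remainder to the validation (internal test) set; the rest train.
#' Deterministic for a fixed seed and invariant to input row order.
#' Labels with fewer than 3 compounds go entirely to train with a warning.
#'
#' @param entries Entries with `task_label`.
#' @param external_fraction Fraction held out as external test (0.10).
#' @param validation_fraction Fraction of the remainder used for early
#'   stopping (0.10).
#' @param seed Integer seed.
#' @return `entries` with a `split` column
#'   (`train`/`validation`/`external_test`).
#' @export
stratified_split <- function(entries, external_fraction = 0.10,
                             validation_fraction = 0.10, seed = 1) {
  stopifnot(external_fraction > 0, external_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  split <- rep("train", nrow(entries))
  set.seed(seed)
  for (tg in sort(unique(entries$task_label))) {
    idx <- which(entries$task_label == tg)
    idx <- idx[order(entries$smiles[idx])]   # row-order invariance
    n <- length(idx)
    if (n < 3) {
      warning("task label ", tg, " has fewer than 3 compounds; all to train")
      next
    }
    perm <- sample(idx)
    n_ext <- round(external_fraction * n)
    ext <- perm[seq_len(n_ext)]
    rem <- setdiff(perm, ext)
    n_val <- round(validation_fraction * length(rem))
    val <- rem[seq_len(n_val)]
    split[ext] <- "external_test"
    split[val] <- "validation"
  }
  entries$split <- split
  entries
}

#' Stratified k-fold assignment
#'
#' Partitions entries into `k` folds preserving per-label proportions
#' (fold sizes differ by at most one compound per label). Deterministic
#' under a fixed seed; labels with fewer than `k` compounds degrade
#' gracefully with a warning.
#'
#' @param entries Entries with `task_label`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
stratified_kfold <- function(entries, k = 10, seed = 1) {
  stopifnot(k >= 2)
  fold <- integer(nrow(entries))
  set.seed(seed)
  for (tg in sort(unique(entries$task_label))) {
    idx <- which(entries$task_label == tg)
    idx <- idx[order(entries$smiles[idx])]
    if (length(idx) < k)
      warning("task label ", tg, " has fewer than k compounds; some folds ",
              "will not contain it")
    perm <- sample(idx)
    fold[perm] <- rep_len(seq_len(k), length(perm))
  }
  fold
}
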