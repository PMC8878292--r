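test_that("pIC50 conversion matches hand values", {
  expect_equal(to_pic50(1e-6), 6)
  expect_equal(to_pic50(1e-9), 9)
  expect_equal(to_pic50(5e-8), 7.301, tolerance = 1e-3)
  expect_error(to_pic50(0), "positive")
  expect_error(to_pic50(-1e-9), "positive")
})

test_that("within-source deduplication keeps the lowest IC50", {
  rec <- data.frame(
    smiles = c("CCO", "CCO", "CCO", "CCO", "CCN"),
    target = c("EGFR", "EGFR", "EGFR", "MET", "EGFR"),
    pic50 = c(7, 7, 8, 6, 5),   # 100 nM, 100 nM dup, 10 nM, ...
    assay = c("a", "a", "b", "a", "a"),
    stringsAsFactors = FALSE)
  out <- dedupe_within_source(rec)
  expect_equal(nrow(out), 3)
  expect_equal(out$pic50[out$smiles == "CCO" & out$target == "EGFR"], 8)
  expect_equal(attr(out, "n_exact_dups"), 1)
  expect_equal(attr(out, "n_conflicts"), 1)
  # distinct targets never merge
  expect_setequal(out$target[out$smiles == "CCO"], c("EGFR", "MET"))
})

test_that("IQR filter removes gross outliers and nothing else", {
  rec <- data.frame(smiles = paste0("m", 1:11), target = "EGFR",
                    mw = c(1:10, 1000), stringsAsFactors = FALSE)
  flt <- iqr_outlier_filter(rec, "mw")
  expect_equal(flt$removed$mw, 1000)
  expect_equal(nrow(flt$kept), 10)
  # identical values: IQR = 0, bounds collapse, nothing removed
  rec2 <- data.frame(smiles = paste0("m", 1:5), target = "MET", mw = 7)
  expect_equal(nrow(iqr_outlier_filter(rec2, "mw")$removed), 0)
  # empty property list is the identity
  flt3 <- iqr_outlier_filter(rec, character(0))
  expect_identical(flt3$kept, rec)
  # missing values pass with a warning
  rec$mw[2] <- NA
  expect_warning(flt4 <- iqr_outlier_filter(rec, "mw"), "missing")
  expect_true("m2" %in% flt4$kept$smiles)
})

test_that("IQR filter is applied per target", {
  rec <- data.frame(smiles = paste0("m", 1:12),
                    target = rep(c("EGFR", "MET"), each = 6),
                    mw = c(100, 110, 120, 105, 115, 400,
                           400, 410, 395, 405, 415, 402))
  flt <- iqr_outlier_filter(rec, "mw")
  # 400 is an outlier among the EGFR group but normal for MET
  expect_equal(flt$removed$smiles, "m6")
})

test_that("cross-source merge keeps the higher pIC50", {
  a <- data.frame(smiles = c("CCO", "CCN"), target = c("EGFR", "EGFR"),
                  pic50 = c(6.2, 7.0), stringsAsFactors = FALSE)
  b <- data.frame(smiles = c("CCO", "CCO"), target = c("EGFR", "MET"),
                  pic50 = c(6.8, 5.5), stringsAsFactors = FALSE)
  ent <- merge_sources(list(a, b))
  expect_equal(nrow(ent), 2)
  expect_equal(ent$pIC50_EGFR[ent$smiles == "CCO"], 6.8)
  expect_equal(ent$pIC50_MET[ent$smiles == "CCO"], 5.5)   # keyed merge
  expect_equal(ent$pIC50_EGFR[ent$smiles == "CCN"], 7.0)  # passthrough
  # one row per compound: exactly one value per (compound, target)
  expect_false(any(duplicated(ent$smiles)))
})

test_that("task labels go to the rarest reported target", {
  ent <- data.frame(smiles = c("a", "b", "c"))
  for (tg in kinase_targets()) ent[[paste0("pIC50_", tg)]] <- NA_real_
  ent$pIC50_EGFR <- c(7, 7, 7)
  ent$pIC50_ROS1 <- c(6, NA, NA)
  out <- assign_task_labels(ent)
  expect_equal(out$task_label, c("ROS1", "EGFR", "EGFR"))
  # tie in counts breaks by fixed target order
  ent2 <- data.frame(smiles = "x", stringsAsFactors = FALSE)
  for (tg in kinase_targets()) ent2[[paste0("pIC50_", tg)]] <- NA_real_
  ent2$pIC50_MET <- 6; ent2$pIC50_ALK <- 6
  expect_equal(assign_task_labels(ent2)$task_label, "ALK")
})

test_that("stratified split honours the stated fractions", {
  ent <- data.frame(smiles = sprintf("s%04d", 1:1000),
                    task_label = "EGFR", stringsAsFactors = FALSE)
  for (tg in kinase_targets()) ent[[paste0("pIC50_", tg)]] <- NA_real_
  ent$pIC50_EGFR <- 6
  out <- stratified_split(ent, seed = 5)
  expect_equal(sum(out$split == "external_test"), 100)
  expect_equal(sum(out$split == "validation"), 90)
  expect_equal(sum(out$split == "train"), 810)
  # determinism and row-order invariance
  out2 <- stratified_split(ent[sample(1000), ], seed = 5)
  expect_equal(out2$split[order(out2$smiles)],
               out$split[order(out$smiles)])
  # per-label proportions for a 3-label set stay within one compound
  ent3 <- data.frame(smiles = sprintf("t%04d", 1:600),
                     task_label = rep(c("ALK", "MET", "ROS1"),
                                      c(300, 200, 100)))
  for (tg in kinase_targets()) ent3[[paste0("pIC50_", tg)]] <- 6
  out3 <- stratified_split(ent3, seed = 2)
  for (tg in c("ALK", "MET", "ROS1")) {
    n <- sum(ent3$task_label == tg)
    next_sel <- out3$task_label == tg
    expect_lte(abs(sum(out3$split[next_sel] == "external_test") -
                     round(0.1 * n)), 1)
  }
  # tiny label degrades gracefully
  ent4 <- ent3[1:2, ]; ent4$task_label <- "ERBB4"
  expect_warning(out4 <- stratified_split(ent4, seed = 1), "fewer than 3")
  expect_true(all(out4$split == "train"))
})

test_that("stratified k-fold partitions the data evenly per label", {
  ent <- tiny_entries()
  fold <- stratified_kfold(ent, k = 5, seed = 9)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), nrow(ent))
  for (tg in unique(ent$task_label)) {
    sizes <- table(fold[ent$task_label == tg])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(fold, stratified_kfold(ent, k = 5, seed = 9))
  expect_false(identical(fold, stratified_kfold(ent, k = 5, seed = 10)))
})

test_that("curation is insensitive to record order", {
  spec <- synthetic_spec(n_compounds = 40, targets = c("EGFR", "MET"),
                         coverage = 0.8, duplicate_fraction = 0.2,
                         salt_fraction = 0.2, seed = 33)
  rec <- generate_library(spec)$records
  rec$pic50 <- to_pic50(rec$ic50_nM * 1e-9)
  c1 <- curate_records(rec)
  set.seed(1)
  c2 <- curate_records(rec[sample(nrow(rec)), ])
  o1 <- c1$entries[order(c1$entries$smiles), ]
  o2 <- c2$entries[order(c2$entries$smiles), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
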