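## Deterministic synthetic molecular libraries with known
## structure-activity relationships, so curation, training, validation and
## the applicability domain are all testable offline. Molecules are
## assembled from a fixed grammar of kinase-inhibitor-like scaffolds and
## substituents; the true activity is additive in scaffold/substituent
## contributions (or linear in whole-molecule descriptors), shared across
## targets with tunable correlation.

# Scaffold templates with two substitution slots. All slots sit on carbon
# (or pyrrole-type nitrogen) so any substituent fragment yields valid
# SMILES; "{R}" slots are replaced by "(<fragment>)" or dropped for H.
QSAR_SCAFFOLDS <- c(
  benzene        = "c1cc({R1})cc({R2})c1",
  pyridine       = "c1nc({R1})cc({R2})c1",
  pyrimidine     = "c1nc({R1})nc({R2})c1",
  quinazoline    = "c1ccc2nc({R1})nc({R2})c2c1",
  quinoline      = "c1ccc2nc({R1})cc({R2})c2c1",
  indole         = "c1ccc2c(c1)cc({R1})n2{R2}",
  thiophene      = "c1sc({R1})cc1{R2}",
  furan          = "c1oc({R1})cc1{R2}",
  pyrazole       = "c1cc({R1})nn1{R2}",
  biphenyl       = "c1ccc(-c2ccc({R1})cc2)cc1{R2}",
  anilinopyrimidine = "c1cc({R1})ccc1Nc1ncnc({R2})c1",
  diarylurea     = "O=C(Nc1ccc({R1})cc1)Nc1ccc({R2})cc1",
  diarylalkyne   = "C(#Cc1ccc({R1})cc1)c1ccc({R2})cc1",
  benzamide      = "O=C(c1ccc({R1})cc1)Nc1ccc({R2})cc1"
)

# substituent fragments; ring closures use digit 9 so they can never
# collide with a scaffold ring that is still open at the insertion point
QSAR_SUBSTITUENTS <- c(
  "H", "C", "CC", "CCC", "C(C)C", "CO", "CN", "O", "OC", "OCC",
  "N", "NC", "N(C)C", "F", "Cl", "Br", "I", "C(F)(F)F", "C#N",
  "[N+](=O)[O-]", "C(=O)O", "C(=O)N", "C(=O)C", "S", "SC",
  "OC(F)(F)F", "CCl", "CCO", "CCN", "C9CC9"
)

assemble_smiles <- function(scaffold, r1, r2) {
  s <- QSAR_SCAFFOLDS[[scaffold]]
  s <- sub("({R1})", if (r1 == "H") "" else paste0("(", r1, ")"),
           s, fixed = TRUE)
  s <- sub("{R1}", if (r1 == "H") "" else r1, s, fixed = TRUE)
  s <- sub("({R2})", if (r2 == "H") "" else paste0("(", r2, ")"),
           s, fixed = TRUE)
  if (r2 == "H") {
    # unsubstituted pyrrole-type nitrogen must carry its explicit H
    s <- sub("n([12])\\{R2\\}", "[nH]\\1", s)
    s <- sub("{R2}", "", s, fixed = TRUE)
  } else {
    s <- sub("{R2}", r2, s, fixed = TRUE)
  }
  s
}

#' Specification of a synthetic library
#'
#' @param n_compounds Number of unique compounds.
#' @param targets Targets carrying labels (subset of [kinase_targets()]).
#' @param coverage Named fractions: probability each target is labelled
#'   per compound (recycled if a single number).
#' @param activity_model `"substructure_additive"` (activity additive in
#'   scaffold and substituent contributions) or `"descriptor_linear"`
#'   (linear in standardized whole-molecule descriptors).
#' @param noise_sd Gaussian noise (pIC50 units) on observed labels.
#' @param task_correlation Designed Pearson correlation between the true
#'   activities of any two targets (default 0.7).
#' @param cliff_fraction Fraction of compounds given an engineered
#'   activity-cliff partner.
#' @param salt_fraction Fraction of records emitted with a salt fragment.
#' @param duplicate_fraction Fraction of records duplicated (half exact,
#'   half conflicting by a higher IC50).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 500,
                           targets = kinase_targets(),
                           coverage = 0.6,
                           activity_model = c("substructure_additive",
                                              "descriptor_linear"),
                           noise_sd = 0.3, task_correlation = 0.7,
                           cliff_fraction = 0, salt_fraction = 0,
                           duplicate_fraction = 0, seed = 1) {
  activity_model <- match.arg(activity_model)
  stopifnot(n_compounds >= 1, noise_sd >= 0,
            all(targets %in% kinase_targets()),
            cliff_fraction >= 0, cliff_fraction <= 1,
            salt_fraction >= 0, salt_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            task_correlation >= 0, task_correlation <= 1)
  if (length(coverage) == 1) coverage <- stats::setNames(
    rep(coverage, length(targets)), targets)
  stopifnot(all(coverage > 0), all(coverage <= 1))
  structure(list(n_compounds = n_compounds, targets = targets,
                 coverage = coverage, activity_model = activity_model,
                 noise_sd = noise_sd, task_correlation = task_correlation,
                 cliff_fraction = cliff_fraction,
                 salt_fraction = salt_fraction,
                 duplicate_fraction = duplicate_fraction, seed = seed),
            class = "synthetic_spec")
}

# whole-molecule descriptors for the descriptor_linear truth model;
# string-derived, so the truth is a transparent function of structure
truth_descriptors <- function(scaffold, r1, r2) {
  cnt <- function(x, pat) lengths(regmatches(x, gregexpr(pat, x)))
  frag_atoms <- function(x) if (x == "H") 0 else count_heavy_atoms(x)
  sc <- QSAR_SCAFFOLDS[[scaffold]]
  c(size = frag_atoms(r1) + frag_atoms(r2) +
      count_heavy_atoms(gsub("\\{R[12]\\}|\\(\\{R[12]\\}\\)", "", sc)),
    halo = cnt(r1, "F|Cl|Br|I") + cnt(r2, "F|Cl|Br|I"),
    polar = cnt(r1, "[NO]") + cnt(r2, "[NO]") + cnt(sc, "[NOno]"),
    sulfur = cnt(r1, "S|s") + cnt(r2, "S|s") + cnt(sc, "S|s"),
    chains = cnt(r1, "C") + cnt(r2, "C"),
    nitro = as.numeric(r1 == "[N+](=O)[O-]" || r2 == "[N+](=O)[O-]"),
    cf3 = as.numeric(grepl("C(F)(F)F", paste(r1, r2), fixed = TRUE)),
    r1size = frag_atoms(r1),
    fused = as.numeric(scaffold %in% c("quinazoline", "quinoline",
                                       "indole")),
    linked = as.numeric(scaffold %in% c("biphenyl", "anilinopyrimidine",
                                        "diarylurea", "diarylalkyne",
                                        "benzamide")))
}

standardize_vec <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-10) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# residualize v against the columns of basis, then standardize; returns
# NULL when nothing of v survives (degenerate direction)
orthogonalize <- function(v, basis) {
  for (j in seq_len(ncol(basis))) {
    b <- basis[, j]
    nb <- sum(b^2)
    if (nb > 0) v <- v - b * sum(v * b) / nb
  }
  if (stats::sd(v) < 1e-8) return(NULL)
  standardize_vec(v)
}

#' Generate a synthetic activity library
#'
#' Produces raw activity records (long format, one row per measurement) in
#' the same schema [read_activity_csv()] consumes, together with the
#' generating truth. True activity is shared across targets through a
#' common component mixed with per-target components so that any two
#' targets' true activities correlate at `task_correlation`; observed
#' labels add Gaussian noise. Requested fractions of salt forms, exact and
#' conflicting duplicates, and engineered activity cliffs are injected.
#' Cliff partners are isotopologues of the base compound (a methyl swapped
#' for [13C]-methyl): structurally indistinguishable to the fingerprints
#' (Tanimoto 1) yet distinct compounds, with the label of the cliff target
#' shifted by at least 2 pIC50 units.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (data frame: `smiles`, `target`, `ic50_nM`,
#'   `source`, `assay`, `mw`, `logp`, `ro5_violations`), `truth` (per
#'   compound per target true pIC50 and generating coefficients) and
#'   `cliffs` (the engineered pair log).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  scaffs <- names(QSAR_SCAFFOLDS)
  subs <- QSAR_SUBSTITUENTS
  n <- spec$n_compounds
  if (n > length(scaffs) * length(subs)^2 * 0.8)
    stop("n_compounds infeasible for the scaffold/substituent grammar")
  # sample unique (scaffold, r1, r2) combos
  combos <- data.frame(scaffold = character(0), r1 = character(0),
                       r2 = character(0))
  while (nrow(combos) < n) {
    need <- n - nrow(combos)
    new <- data.frame(
      scaffold = sample(scaffs, need, replace = TRUE),
      r1 = sample(subs, need, replace = TRUE),
      r2 = sample(subs, need, replace = TRUE))
    combos <- unique(rbind(combos, new))
  }
  combos <- combos[seq_len(n), , drop = FALSE]
  smiles <- mapply(assemble_smiles, combos$scaffold, combos$r1, combos$r2)
  names(smiles) <- NULL

  tg <- spec$targets
  ntg <- length(tg)
  rho <- sqrt(spec$task_correlation)
  amplitude <- 1.2   # sd of true activity around the target baseline
  base <- stats::runif(ntg, 5.5, 7)
  # one shared structure-activity component plus one per-target component;
  # per-target components are orthogonalized against the shared one (and
  # each other) in realized compound space, so any two targets' truths
  # correlate at rho^2 = task_correlation up to sampling noise
  if (spec$activity_model == "substructure_additive") {
    score <- function() {
      sc <- stats::rnorm(length(scaffs)); names(sc) <- scaffs
      su <- stats::rnorm(length(subs)); names(su) <- subs
      list(raw = sc[combos$scaffold] + su[combos$r1] + su[combos$r2],
           scaffold = sc, substituent = su)
    }
  } else {
    D <- t(mapply(truth_descriptors, combos$scaffold, combos$r1, combos$r2))
    D <- scale(D)
    D[is.nan(D)] <- 0
    score <- function() {
      w <- stats::rnorm(ncol(D))
      list(raw = as.numeric(D %*% w), weights = w)
    }
  }
  shared <- score()
  s <- standardize_vec(shared$raw)
  basis <- matrix(s, ncol = 1)
  comp <- matrix(0, n, ntg)
  draws <- vector("list", ntg)
  for (t in seq_len(ntg)) {
    repeat {
      cand <- score()
      e <- orthogonalize(cand$raw, basis)
      if (!is.null(e)) break
    }
    draws[[t]] <- cand
    basis <- cbind(basis, e)
    comp[, t] <- amplitude * (rho * s + sqrt(1 - rho^2) * e)
  }
  truth <- sweep(comp, 2, base, "+")
  coefs <- list(base = base, amplitude = amplitude, rho = rho,
                shared = shared, per_target = draws)
  truth <- pmin(pmax(truth, 3), 11)
  colnames(truth) <- tg

  # label coverage: each compound keeps at least one label
  mask <- sapply(tg, function(t) stats::runif(n) < spec$coverage[[t]])
  mask <- matrix(mask, nrow = n)
  none <- rowSums(mask) == 0
  if (any(none)) mask[cbind(which(none),
                            max.col(matrix(spec$coverage, sum(none), ntg,
                                           byrow = TRUE)))] <- TRUE
  observed <- truth + matrix(stats::rnorm(n * ntg, 0, spec$noise_sd), n)

  rows <- list()
  for (t in seq_len(ntg)) {
    has <- which(mask[, t])
    if (length(has) == 0) next
    rows[[t]] <- data.frame(compound = has, smiles = smiles[has],
                            target = tg[t], pic50 = observed[has, t],
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)

  # engineered activity cliffs: isotopologue partner with shifted label
  cliffs <- data.frame()
  n_cliff <- round(spec$cliff_fraction * n)
  if (n_cliff > 0) {
    cand <- which(combos$r1 == "C" | combos$r2 == "C")
    if (length(cand) < n_cliff) {
      # force methyl at R1 on additional compounds so a partner exists
      extra <- setdiff(seq_len(n), cand)[seq_len(n_cliff - length(cand))]
      combos$r1[extra] <- "C"
      smiles[extra] <- mapply(assemble_smiles, combos$scaffold[extra],
                              combos$r1[extra], combos$r2[extra])
      rec$smiles <- smiles[rec$compound]
      cand <- c(cand, extra)
    }
    picked <- sample(cand, n_cliff)
    cl_rows <- list()
    for (i in picked) {
      use_r1 <- combos$r1[i] == "C"
      iso <- assemble_smiles(combos$scaffold[i],
                             if (use_r1) "[13CH3]" else combos$r1[i],
                             if (use_r1) combos$r2[i] else "[13CH3]")
      tsel <- which(mask[i, ])[1]
      delta <- 2 + stats::runif(1, 0, 1)
      shifted <- observed[i, tsel] +
        if (observed[i, tsel] < 7) delta else -delta
      cl_rows[[length(cl_rows) + 1]] <- data.frame(
        compound = NA, smiles = iso, target = tg[tsel], pic50 = shifted,
        stringsAsFactors = FALSE)
      cliffs <- rbind(cliffs, data.frame(
        base_smiles = smiles[i], partner_smiles = iso, target = tg[tsel],
        delta = shifted - observed[i, tsel]))
    }
    rec <- rbind(rec, do.call(rbind, cl_rows))
  }

  # duplicates: half exact, half conflicting (higher IC50 = lower pIC50)
  n_dup <- round(spec$duplicate_fraction * nrow(rec))
  if (n_dup > 0) {
    di <- sample(nrow(rec), n_dup)
    dup <- rec[di, , drop = FALSE]
    conflict <- seq_len(n_dup) > n_dup / 2
    dup$pic50[conflict] <- dup$pic50[conflict] -
      stats::runif(sum(conflict), 0.2, 1)
    rec <- rbind(rec, dup)
  }

  # salts appended to a fraction of record SMILES (desalting must strip)
  n_salt <- round(spec$salt_fraction * nrow(rec))
  if (n_salt > 0) {
    si <- sample(nrow(rec), n_salt)
    salts <- sample(c("Cl", "[Na+]", "O", "OC(=O)C"), n_salt,
                    replace = TRUE)
    rec$smiles[si] <- paste0(rec$smiles[si], ".", salts)
  }

  # simple computed properties for the IQR filter
  props <- t(vapply(rec$smiles, function(s) {
    halo <- lengths(regmatches(s, gregexpr("F|Cl|Br|I", s)))
    nat <- count_heavy_atoms(s)
    mw <- 13.5 * nat + 20 * halo
    logp <- 0.25 * nat - 0.9 * lengths(regmatches(s, gregexpr("[NOno]", s)))
    c(mw = mw, logp = logp)
  }, numeric(2)))
  rec$ic50_nM <- 10^(-rec$pic50) * 1e9
  rec$pic50 <- NULL
  rec$source <- "SYNTH"
  rec$assay <- paste0("biochemical single-protein assay ", rec$target)
  rec$mw <- unname(props[, "mw"])
  rec$logp <- unname(props[, "logp"])
  rec$ro5_violations <- as.integer(props[, "mw"] > 500) +
    as.integer(props[, "logp"] > 5)
  rec$compound <- NULL
  rownames(rec) <- NULL

  list(records = rec,
       truth = list(smiles = smiles, combos = combos, pic50 = truth,
                    observed = observed, mask = mask, coefficients = coefs),
       cliffs = cliffs)
}

#' Corrupt a record table for curation tests
#'
#' Injects known faults at recorded indices: non-positive IC50 values,
#' gross property outliers and unparsable SMILES. The tamper log allows
#' tests to check that curation removes exactly the corrupted records.
#'
#' @param records Record data frame from [generate_library()].
#' @param n_bad_ic50,n_outliers,n_bad_smiles Number of faults of each kind.
#' @param seed Integer seed.
#' @return List with `records` and `tamper_log` (data frame `row`, `kind`).
#' @export
corrupt_for_curation_tests <- function(records, n_bad_ic50 = 0,
                                       n_outliers = 0, n_bad_smiles = 0,
                                       seed = 1) {
  set.seed(seed)
  total <- n_bad_ic50 + n_outliers + n_bad_smiles
  if (total == 0) return(list(records = records,
                              tamper_log = data.frame(row = integer(0),
                                                      kind = character(0))))
  stopifnot(total <= nrow(records))
  rows <- sample(nrow(records), total)
  log <- data.frame(row = rows,
                    kind = rep(c("nonpositive_ic50", "property_outlier",
                                 "bad_smiles"),
                               c(n_bad_ic50, n_outliers, n_bad_smiles)))
  take <- function(k) log$row[log$kind == k]
  records$ic50_nM[take("nonpositive_ic50")] <- -1
  out_rows <- take("property_outlier")
  if (length(out_rows)) {
    records$mw[out_rows] <- 1e5
    records$logp[out_rows] <- 99
  }
  bad <- take("bad_smiles")
  if (length(bad))
    records$smiles[bad] <- sprintf("C%dCC", seq_along(bad))  # unclosed ring
  list(records = records, tamper_log = log)
}
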