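---
title: "Multitask kinase QSAR with principal neighborhood aggregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask kinase QSAR with principal neighborhood aggregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

`pnaqsar` builds multitask QSAR regression models that predict pIC50
(−log10 of the molar IC50) of small molecules against seven receptor
tyrosine kinases relevant to non-small-cell lung cancer therapy: ALK,
EGFR, ERBB2, ERBB4, MET, RET and ROS1. A single model serves all seven
tasks, so structure–activity signal learned on data-rich kinases (EGFR has
thousands of public measurements) can support predictions on data-poor
ones (ERBB4 and ROS1 have a few hundred at best). The package implements
the complete workflow: curation of raw assay records, activity-cliff
filtering, dual featurization (molecular graphs and fingerprints), the
fused PNA+DNN network, stratified validation with the Golbraikh–Tropsha
acceptability criteria, and a two-stage applicability domain for
screening.

# The model

## Dual featurization

Every compound is represented twice.

**Molecular graph.** Atoms become nodes with a 30-dimensional feature
vector: element one-hot over {C, N, O, S, F, Cl, Br, I, P, other}
(columns 1–10), degree one-hot 0–≥5 (11–16), formal-charge sign one-hot
(17–19), ring membership (20), smallest-ring-size one-hot 3–≥8 (21–26),
attached double bond (27), attached triple bond (28), heteroatom neighbor
(29) and terminal-atom flag (30). Every bond contributes both directed
edges; each edge carries a 75-dimensional feature vector composed of the
source-node features (30), target-node features (30) and 15 bond-specific
features (bond-order one-hot, ring membership, ring-size one-hot, plus
three reserved zero slots). Ring annotation comes from bridge analysis of
the bond graph: an edge is in a ring iff it is not a bridge, and its ring
size is one plus the shortest alternative path between its endpoints.

**Fingerprint block.** A configurable registry of bit-vector families is
concatenated into one boolean block with recorded per-family offsets. The
default roster spans 16 families: MACCS-type substructure keys and the
OpenBabel FP2/FP3/FP4 keys, circular (Morgan-type) fingerprints of the
element-typed atom environment at radii 0–3, circular fingerprints of a
pharmacophore-typed environment (donor/acceptor/halogen/ring/charge
classes) at radii 1–2, hashed linear paths of length ≤3/5/7, hashed
topological atom pairs, and element-count and ring-profile descriptor
bits (~9.8k bits in total). The block is reduced by PCA fitted **on
training compounds only**, keeping the smallest number of components
whose cumulative explained variance reaches 95% (`pca_variance`,
tunable). The roster in force is stored inside every model checkpoint so
predictions are reproducible; whether to reduce per family or after
concatenation was an open choice — we concatenate first and run a single
PCA, which lets the reduction exploit redundancy *between* families.

## The network

Two branches are fused. The graph branch applies `n_pna_layers` rounds of
principal neighborhood aggregation. For node $i$ with incoming edges
$(j, i)$, messages are $m_{j\to i} =
\mathrm{MLP}([x_i, E_{j\to i}, x_j])$; they are pooled by four
aggregators — mean, population standard deviation, maximum, minimum —
each modulated by three degree scalers

$$ S(d, \alpha) = \left(\frac{\log(d+1)}{\delta}\right)^{\alpha},
\qquad \alpha \in \{0, +1, -1\}, \qquad
\delta = \frac{1}{|\mathrm{train}|}\sum_{i \in \mathrm{train}}
\log(d_i + 1), $$

giving 12 concatenated blocks, and the node is updated as
$x_i' = \mathrm{MLP}([x_i, \oplus])$. $\delta$ averages over all *nodes*
of the training graphs (the alternative — averaging per graph — changes
little for molecules of similar size, but the node-level mean is the
natural reading of the normalization) and uses the natural logarithm.
Isolated heavy atoms ($d = 0$) receive $S = 1$ for every $\alpha$,
extending the definition continuously instead of dividing by zero. After
message passing, node embeddings are sum-pooled per molecule
(mean-pooling selectable via `pooling = "mean"`) and passed through a
dense layer. The descriptor branch is a plain deep network on the
PCA-reduced fingerprint block. The two embeddings are concatenated and
passed through fully connected layers into **seven task heads that share
every layer except the final linear map per task** (hard parameter
sharing, implemented as a single hidden-to-7 matrix).

Two compositions of the update MLP are defensible from the architecture's
usual presentation; we use
`update = MLP([x_i, aggregation(MLP([x_i, E_ji, x_j]))])`, i.e. the inner
MLP transforms messages before aggregation and the outer MLP sees the raw
node features next to the aggregate. Likewise the scaler-aggregator
combination is realized as 12 concatenated blocks rather than a
structured tensor product, matching the reference design of the PNA
layer.

## Loss, optimization, early stopping

Labels are sparse: most compounds are measured against one or two
kinases. The training loss is the masked multitask MSE

$$ \mathcal{L} = \sum_{t=1}^{T} \frac{1}{n_t}
   \sum_{i:\,\mathrm{labelled}} (\hat Y_{it} - Y_{it})^2 $$

with $n_t$ the number of labelled compounds of task $t$ inside the
mini-batch; tasks absent from a batch contribute zero. Batches are drawn
by seeded shuffling each epoch and may contain unequal task counts.
Optimization is Adam with L2 regularization (`weight_decay` added to the
gradient). Training stops early when, for `patience = 10` consecutive
epochs, neither the validation loss nor its moving average over the last
(up to) 10 epochs improves on its respective best; the weights of the
best-validation epoch are restored. `early_stop_trace()` exposes the rule
as a pure function so it can be audited on scripted loss sequences.

All forward and reverse computations are written against a packed
block-diagonal batch representation (one node matrix, edge lists with
offsets), and the analytic gradients are tested against central
differences. Two numerical choices matter: the std aggregator uses the
smoothed form $\sqrt{\mathrm{var} + \varepsilon^2} - \varepsilon$
(`std_eps = 1e-3`) which is exactly zero for a single message and keeps
the gradient bounded near zero variance; and the max/min aggregators
route gradients to the first arg-extreme edge on exact ties.

## Hyperparameters

`default_net_config()` holds the general defaults (2 PNA layers, widths
32/64, dropout 0.1 on the dense branches, learning rate 3e-3, weight
decay 1e-5, batch 64, ≤200 epochs, patience 10). These approximate, at a
desk-computation scale, the shape of a Bayesian-optimized configuration:
we do not re-run hyperparameter search, and every value is exposed.
`study_net_config()` is the compact variant used by the bundled studies
(1 PNA layer, widths 16–48, full-precision batches of 256, ≤60 epochs, a
4-family fingerprint roster) chosen so that a complete multi-seed study
runs in minutes on one CPU core.

# Curation protocol

`curate_records()` applies, in order: optional assay-text filtering
(regex, since raw source schemas differ); canonicalization and desalting
(largest covalent fragment by heavy-atom count, ties by molecular weight
then lexicographic SMILES; unparsable records are counted and logged,
never raised); per-source deduplication (exact (assay, value) duplicates
collapsed, then conflicting values for the same compound/target resolved
to the **lowest IC50**, i.e. highest pIC50); a per-target IQR outlier
filter on molecular properties (removed iff any property lies outside
[Q1 − 3·IQR, Q3 + 3·IQR]; quartiles by linear interpolation between
order statistics, R type 7 — the convention is stated because it is not
implied by the rule); and a cross-source merge keeping the **higher
pIC50** per (compound, target). Task labels then go to each compound's
rarest reported target (ties by the fixed target order), the stratified
split takes 10% per label as the external test set and 10% of the
remainder for validation, and activity-cliff generators are removed from
the train–validation pool only.

An activity-cliff pair is two same-target compounds with ECFP4 Tanimoto
≥ 0.9 and |ΔpIC50| ≥ 1.0; a generator's score is the mean over its pairs
of |ΔpIC50| − (1 − T). Generators are removed one at a time (highest
score first, ties by pair count then SMILES), recomputing pairs after
each removal until none remain; only the offending target's label is
blanked, and the full removal log is emitted so alternative cliff
definitions can be audited. All three thresholds are arguments.

# Validation

`cross_validate()` runs stratified k-fold (default 10) cross-validation,
training a fresh model per fold; RMSECV and Q² are computed on the pooled
out-of-fold predictions per target (not as a mean of per-fold statistics
— pooling treats the 10 rounds as one validation experiment and is
well-defined even for targets with few compounds per fold). External
validation reports RMSEP, R², the through-origin statistics in both
orientations and the Golbraikh–Tropsha verdict: Q² > 0.5, R² > 0.6,
(R² − R0²)/R² < 0.1 with R0² from the predicted-on-X orientation,
0.9 ≤ k ≤ 1.1 (the slope bound is routinely misprinted with inverted
inequalities; this is the standard reading), and |R0² − R0′²| < 0.3. Both
orientations are reported so the reader can audit the asymmetric
criteria.

# Applicability domain

Stage one is a global structural gate: a query must reach a
nearest-neighbor ECFP4 Tanimoto similarity to the training compounds at
or above a threshold optimized from cross-validation — per fold, the
best-predicted 75% of compounds (squared error ≤ Q3; read as "≤ Q3"
rather than the strict third-quartile band, configurable) have their
similarities z-scored, the fold threshold is the minimum similarity among
compounds with |z| ≤ 1.96 (two-sided 95%; a one-sided option exists), and
the global threshold is the fold mean. Stage two is per-target
reliability: target neighbors are training compounds with that target's
label and Tanimoto ≥ 0.35; the check passes iff neighbors exist and their
mean cross-validated squared residual is small enough. The cutoff is set
at 10% of the target's training pIC50 range; because a squared residual
and a pIC50 range are dimensionally incommensurable, the default compares
the **root** mean squared residual against the cutoff
(`scale = "rmsr"`) — the literal squared-scale comparison is available as
`scale = "literal"`. A compound is "inside" for a target iff both stages
pass; zero neighbors mean no evidence of reliability, hence "outside".
Raising the global threshold can only shrink the inside set (tested as an
exact monotonicity property).

# The synthetic-data generator

`generate_library()` assembles molecules from 14 kinase-inhibitor-like
scaffolds (benzene through quinazoline, anilinopyrimidine, diaryl urea
and relatives) with two substitution slots filled from 30 fragments —
fully enumerated in code, no downloads, 12,600 valid combinations. True
activity is built from one shared structure–activity component plus one
per-target component (additive scaffold/substituent contributions, or a
linear map of whole-molecule descriptors), Gram–Schmidt orthogonalized in
realized compound space so that any two targets' truths correlate at
`task_correlation` (default 0.7) up to sampling noise; observed labels
add Gaussian noise (`noise_sd`, default 0.3 pIC50 — a realistic
inter-assay spread for public IC50 data). Requested fractions of salts,
exact and conflicting duplicates, and engineered activity cliffs are
injected with a tamper-style log.

Cliff partners are *isotopologues* (a methyl swapped for [13C]-methyl):
distinct canonical SMILES, hence distinct compounds to curation, but
Tanimoto 1.0 to the fingerprints — the idealized activity cliff. A
genuine one-substituent swap on molecules of this size (15–35 heavy
atoms) lands at ECFP4 Tanimoto ≈ 0.65–0.88 and would be invisible at the
0.9 detection default; the isotopologue construction makes the engineered
cliffs recoverable by the detector at its defaults, at the cost of being
chemically idealized.

What the generator does **not** emulate: medicinal-chemistry
plausibility, assay heterogeneity beyond i.i.d. Gaussian noise,
target-family structure beyond a single correlation parameter, tautomers
or stereochemistry. Green tests on these libraries show the pipeline's
mechanics and learning behavior are sound; they say nothing about
predictive accuracy on real ChEMBL/BindingDB chemistry.

# Bundled studies and their problem sizes

Three multi-seed studies (also rerun by `scripts/acceptance.R`) back the
package's behavioral claims:

- `study_learning_sanity()` — one 500-compound, two-task library
  (descriptor-linear truth, noise 0.3); 20 split/training seeds; the
  trained model must beat the predict-the-training-mean baseline on
  held-out RMSE and reach pooled external R² > 0.6 on most seeds.
- `study_multitask_transfer()` — 440 compounds with ~400 labels on a
  data-rich task and ~40 on a data-poor one (correlation 0.7); per seed,
  the data-poor task is evaluated against the generating truth for the
  multitask model and a single-task model trained on the 40 labels alone.
  The multitask median RMSE should not exceed the single-task median —
  the transfer direction expected for data-poor tasks.
- `study_applicability_domain()` — 400 compounds over three tasks;
  compounds on four scaffolds are held out as a structurally alien
  subset; the AD is fitted from 3-fold CV residuals per seed, and the
  inside-domain RMSE is compared with the outside-domain RMSE on the
  mixed test set.

Sizes (500/440/400 compounds, 3-fold CV in the AD study, the compact
config) were chosen once as the smallest designs on which the effects
under study are reliably visible across seeds; they are package
constants, not tuned quantities.

# Known limitations

- Atom/bond features are the package's own 30/75-dimensional layout;
  other toolkits' featurizers differ in detail (e.g. no explicit
  aromaticity perception — ring membership and ring size stand in).
- The hand-written network is CPU-only and sized for datasets of
  10^3–10^4 compounds; it is not a GPU training framework.
- Canonicalization follows OpenBabel; no tautomer enumeration or
  stereochemistry standardization beyond what canonical SMILES provides.
- ERBB4-style failure modes (narrow test-set activity range deflating
  R² despite competitive RMSE) are reported, not corrected: the
  Golbraikh–Tropsha verdict is emitted per target and a failing target
  simply fails its gate.
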