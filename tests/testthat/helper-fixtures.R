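# Shared test helpers: small cached libraries and featurizations so slow
# chemistry setup is paid once per test run.

test_roster <- function() compact_fingerprint_roster()

# small curated-style entry table with known labels, cached per session
tiny_entries <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_compounds = 80, targets = c("EGFR", "MET"),
                             coverage = 0.9, noise_sd = 0.2, seed = 101)
      lib <- generate_library(spec)
      ent <- library_entries(lib)
      ent <- stratified_split(ent, seed = 101)
      cache <<- ent
    }
    cache
  }
})

tiny_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- featurize_compounds(tiny_entries()$smiles,
                                    roster = test_roster())
    cache
  }
})

# fast net config for unit tests (not for quality studies)
tiny_net_config <- function(...) {
  study_net_config(msg_hidden = 8L, hidden = 8L, pool_width = 8L,
                   dnn_widths = c(16L, 8L), fc_widths = c(16L, 8L),
                   max_epochs = 15L, roster = test_roster(), ...)
}

# random fingerprint keys for similarity property tests
random_keys <- function(n, bits = 64, density = 0.3, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n * bits) < density, n, bits)
}

# apply a node permutation to a mol_graph (tests of permutation invariance)
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$node_features <- g$node_features[perm, , drop = FALSE]
  g2$degrees <- g$degrees[perm]
  if (nrow(g$edges) > 0) {
    g2$edges <- cbind(from = inv[g$edges[, "from"]],
                      to = inv[g$edges[, "to"]])
  }
  g2
}
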