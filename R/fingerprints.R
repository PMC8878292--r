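## Fingerprint families, the concatenated fingerprint block, ECFP-style
## circular keys and Tanimoto similarity.
##
## The block is assembled from a configurable registry of bit-vector
## families. Four families are delegated to OpenBabel (MACCS-type keys and
## the FP2/FP3/FP4 path & substructure keys); the circular, path, atom-pair
## and profile families are computed from the parsed atom/bond tables.

ecfp_atom_code <- function(mol) {
  ei <- match(mol$elements, ELEMENT_SLOTS)
  ei[is.na(ei)] <- 10L
  ei
}

pharm_atom_code <- function(mol) {
  nh <- implicit_h(mol)
  donor <- mol$elements %in% c("N", "O") & nh > 0
  acceptor <- mol$elements %in% c("N", "O")
  halogen <- mol$elements %in% c("F", "Cl", "Br", "I")
  code <- 1L + donor * 2L + acceptor * 4L + halogen * 8L +
    mol$ring_atom * 16L + (mol$charges > 0) * 32L + (mol$charges < 0) * 64L
  as.integer(code)
}

# neighbor adjacency list: for each atom, matrix of (bond order, neighbor)
neighbor_list <- function(mol) {
  n <- mol$n
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- matrix(integer(0), 0, 2)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
      out[[a]] <- rbind(out[[a]], c(o, b))
      out[[b]] <- rbind(out[[b]], c(o, a))
    }
  }
  out
}

# circular (Morgan/ECFP-style) identifiers for all atoms at radii 0..radius
circular_ids <- function(mol, radius, pharm = FALSE) {
  nh <- implicit_h(mol)
  base <- if (pharm) pharm_atom_code(mol) else ecfp_atom_code(mol)
  ids <- vapply(seq_len(mol$n), function(a) {
    hash31(c(base[a], mol$degree[a], mol$charges[a] + 3L, nh[a],
             as.integer(mol$ring_atom[a])))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0 && mol$n > 1) {
    nbl <- neighbor_list(mol)
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(mol$n), function(a) {
        nb <- nbl[[a]]
        if (nrow(nb) == 0) return(hash31(c(r, ids[a])))
        pairs <- cbind(nb[, 1], ids[nb[, 2]])
        ord <- order(pairs[, 1], pairs[, 2])
        hash31(c(r, ids[a], as.numeric(t(pairs[ord, , drop = FALSE]))))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  all_ids
}

fp_circular <- function(mol, radius, nbits, pharm = FALSE) {
  bits <- logical(nbits)
  bits[(circular_ids(mol, radius, pharm) %% nbits) + 1] <- TRUE
  bits
}

# linear path identifiers up to `maxlen` bonds, canonical direction
path_ids <- function(mol, maxlen) {
  if (mol$n == 0) return(numeric(0))
  ecode <- ecfp_atom_code(mol)
  nbl <- neighbor_list(mol)
  acc <- new.env()
  acc$ids <- vector("list", 256); acc$k <- 0L
  push <- function(code) {
    # canonical orientation: lexicographically smaller of code / reverse
    rev_code <- rev(code)
    for (i in seq_along(code)) {
      if (code[i] < rev_code[i]) break
      if (code[i] > rev_code[i]) { code <- rev_code; break }
    }
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$ids)) acc$ids <- c(acc$ids, vector("list", acc$k))
    acc$ids[[acc$k]] <- hash31(code)
  }
  walk <- function(atom, code, visited) {
    push(code)
    if ((length(code) - 1) / 2 >= maxlen) return()
    nb <- nbl[[atom]]
    if (nrow(nb) == 0) return()
    for (j in seq_len(nrow(nb))) {
      nxt <- nb[j, 2]
      if (visited[nxt]) next
      v2 <- visited; v2[nxt] <- TRUE
      walk(nxt, c(code, nb[j, 1], ecode[nxt]), v2)
    }
  }
  for (a in seq_len(mol$n)) {
    v <- logical(mol$n); v[a] <- TRUE
    walk(a, ecode[a], v)
  }
  unlist(acc$ids[seq_len(acc$k)])
}

fp_paths <- function(mol, maxlen, nbits) {
  bits <- logical(nbits)
  bits[(path_ids(mol, maxlen) %% nbits) + 1] <- TRUE
  bits
}

fp_atompair <- function(mol, nbits, maxdist = 8) {
  bits <- logical(nbits)
  if (mol$n < 2) return(bits)
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$a, mol$bonds$b),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n)
    g <- igraph::add_vertices(g, mol$n - igraph::vcount(g))
  d <- igraph::distances(g)
  ecode <- ecfp_atom_code(mol)
  for (i in seq_len(mol$n - 1)) {
    for (j in (i + 1):mol$n) {
      dij <- d[i, j]
      if (!is.finite(dij) || dij > maxdist) next
      pair <- sort(c(ecode[i], ecode[j]))
      bits[(hash31(c(pair, dij)) %% nbits) + 1] <- TRUE
    }
  }
  bits
}

fp_elemcount <- function(mol) {
  bits <- logical(64)
  ecode <- ecfp_atom_code(mol)
  th <- c(1, 2, 4, 8)
  for (e in 1:10) {
    cnt <- sum(ecode == e)
    bits[(e - 1) * 4 + which(th <= cnt)] <- TRUE
  }
  bits[40 + which(c(5, 10, 15, 20, 25, 30) <= mol$n)] <- TRUE
  ncycle <- nrow(mol$bonds) - mol$n +
    if (mol$n > 0) length(unique(comp_membership(mol))) else 0
  bits[46 + which(c(1, 2, 3, 4) <= ncycle)] <- TRUE
  bits[51] <- any(mol$charges > 0)
  bits[52] <- any(mol$charges < 0)
  nh <- implicit_h(mol)
  ndon <- sum(mol$elements %in% c("N", "O") & nh > 0)
  bits[52 + which(c(1, 2, 4) <= ndon)] <- TRUE
  nacc <- sum(mol$elements %in% c("N", "O"))
  bits[55 + which(c(1, 2, 4, 6) <= nacc)] <- TRUE
  bits
}

comp_membership <- function(mol) {
  if (mol$n == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$a, mol$bonds$b),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n)
    g <- igraph::add_vertices(g, mol$n - igraph::vcount(g))
  igraph::components(g)$membership
}

fp_ringprofile <- function(mol) {
  bits <- logical(32)
  sizes <- mol$ring_size_bond[!is.na(mol$ring_size_bond)]
  bits[which(3:8 %in% pmin(sizes, 8))] <- TRUE
  ncycle <- nrow(mol$bonds) - mol$n + length(unique(comp_membership(mol)))
  bits[6 + which(c(1, 2, 3, 4) <= ncycle)] <- TRUE
  ring_deg <- tabulate(c(mol$bonds$a[mol$ring_bond], mol$bonds$b[mol$ring_bond]),
                       nbins = mol$n)
  bits[11] <- any(ring_deg >= 3)                       # fused / bridgehead
  bits[12] <- any(mol$ring_atom & mol$elements != "C") # heteroatom in ring
  bits[13] <- mol$n > 0 && all(mol$ring_atom)
  bits[14] <- !any(mol$ring_atom)
  bits[15] <- any(sizes == 6) && any(mol$ring_atom & mol$elements == "C")
  bits
}

OB_FP_LENGTHS <- c(MACCS = 256, FP2 = 1024, FP3 = 64, FP4 = 512)

#' Registry of fingerprint families
#'
#' Returns the full registry of available fingerprint families. Each entry
#' records the bit length and how the family is computed. The default
#' roster ([default_fingerprint_roster()]) spans 16 families: MACCS-type
#' substructure keys, OpenBabel path/substructure keys (FP2/FP3/FP4),
#' circular element-typed fingerprints at four radii, circular
#' pharmacophore-typed fingerprints at two radii, hashed linear paths at
#' three lengths, hashed atom pairs, and element-count and ring-profile
#' descriptors.
#'
#' @return Named list; each element has `length` (bits) and `kind`.
#' @export
fingerprint_families <- function() {
  list(
    maccs       = list(length = 256,  kind = "openbabel", ob = "MACCS"),
    ob_fp2      = list(length = 1024, kind = "openbabel", ob = "FP2"),
    ob_fp3      = list(length = 64,   kind = "openbabel", ob = "FP3"),
    ob_fp4      = list(length = 512,  kind = "openbabel", ob = "FP4"),
    ecfp0       = list(length = 128,  kind = "circular", radius = 0),
    ecfp2       = list(length = 1024, kind = "circular", radius = 1),
    ecfp4       = list(length = 1024, kind = "circular", radius = 2),
    ecfp6       = list(length = 1024, kind = "circular", radius = 3),
    fcfp2       = list(length = 512,  kind = "circular", radius = 1,
                       pharm = TRUE),
    fcfp4       = list(length = 512,  kind = "circular", radius = 2,
                       pharm = TRUE),
    path3       = list(length = 512,  kind = "path", maxlen = 3),
    path5       = list(length = 1024, kind = "path", maxlen = 5),
    path7       = list(length = 1024, kind = "path", maxlen = 7),
    atompair    = list(length = 1024, kind = "atompair"),
    elemcount   = list(length = 64,   kind = "elemcount"),
    ringprofile = list(length = 32,   kind = "ringprofile")
  )
}

#' @rdname fingerprint_families
#' @export
default_fingerprint_roster <- function() names(fingerprint_families())

#' Compact fingerprint roster
#'
#' A four-family roster (circular radius 1 and 2, atom pairs, element
#' counts) used by the bundled synthetic-data studies where featurization
#' throughput matters more than descriptor breadth.
#' @export
compact_fingerprint_roster <- function() {
  c("ecfp2", "ecfp4", "atompair", "elemcount")
}

compute_family <- function(fam, spec, mols, sdf, ob_rows = NULL) {
  n <- length(mols)
  if (spec$kind == "openbabel") {
    m <- matrix(FALSE, n, spec$length)
    if (any(ob_rows)) {
      fps <- ChemmineR::fingerprintOB(sdf[which(ob_rows)], spec$ob)
      fm <- methods::slot(fps, "fpma") > 0
      m[which(ob_rows), ] <- fm[, seq_len(spec$length), drop = FALSE]
    }
    return(m)
  }
  rows <- lapply(mols, function(mol) {
    if (is.null(mol)) return(logical(spec$length))
    switch(spec$kind,
      circular = fp_circular(mol, spec$radius, spec$length,
                             pharm = isTRUE(spec$pharm)),
      path = fp_paths(mol, spec$maxlen, spec$length),
      atompair = fp_atompair(mol, spec$length),
      elemcount = fp_elemcount(mol),
      ringprofile = fp_ringprofile(mol),
      stop("unknown fingerprint kind: ", spec$kind)
    )
  })
  do.call(rbind, rows)
}

#' Concatenated fingerprint block
#'
#' Computes the boolean fingerprint block for a set of molecules by
#' concatenating the requested fingerprint families, recording the bit
#' offset of every family. Identical SMILES always yield identical bits.
#'
#' @param smiles Character vector of canonical desalted SMILES.
#' @param families Character vector of family names from
#'   [fingerprint_families()]. Unknown names are a configuration error.
#' @param mols Optional pre-parsed molecule list aligned with `smiles`
#'   (avoids re-parsing when the caller already holds one).
#' @return Object of class `feature_block`: list with `bits` (logical
#'   matrix, one row per molecule), `family_offsets` (named list of
#'   `c(start, length)`) and `smiles`.
#' @export
fingerprint_block <- function(smiles, families = default_fingerprint_roster(),
                              mols = NULL) {
  stopifnot(length(families) > 0)
  reg <- fingerprint_families()
  unknown <- setdiff(families, names(reg))
  if (length(unknown) > 0)
    stop("unknown fingerprint families: ", paste(unknown, collapse = ", "))
  if (is.null(mols)) mols <- parse_mol_batch(smiles)
  ok <- !vapply(mols, is.null, logical(1))
  # the SDF round trip cannot carry single-atom molecules; those rows get
  # all-zero bits for the OpenBabel families
  ob_rows <- ok & vapply(mols, function(m) !is.null(m) && m$n >= 2,
                         logical(1))
  sdf <- NULL
  if (any(vapply(reg[families], function(x) x$kind == "openbabel",
                 logical(1)))) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(ifelse(ob_rows, smiles, "CC"),
                      paste0("m", seq_along(smiles)))))
  }
  mats <- list()
  offsets <- list()
  pos <- 1L
  for (fam in families) {
    spec <- reg[[fam]]
    mats[[fam]] <- compute_family(fam, spec, mols, sdf, ob_rows = ob_rows)
    offsets[[fam]] <- c(start = pos, length = spec$length)
    pos <- pos + spec$length
  }
  bits <- do.call(cbind, mats)
  rownames(bits) <- NULL
  structure(list(bits = bits, family_offsets = offsets, smiles = smiles,
                 parse_ok = ok),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %d molecules x %d bits (%d families)\n",
              nrow(x$bits), ncol(x$bits), length(x$family_offsets)))
  invisible(x)
}

#' ECFP4 keys for applicability-domain similarity
#'
#' Circular fingerprint of radius 2 (diameter 4) hashed to a fixed-length
#' bit vector, used for Tanimoto similarity in activity-cliff detection
#' and the applicability domain.
#'
#' @param smiles Character vector of canonical SMILES.
#' @param nbits Key length in bits (default 2048).
#' @param mols Optional pre-parsed molecule list aligned with `smiles`.
#' @return Logical matrix with one row per molecule (all-`FALSE` row for
#'   unparsable input).
#' @export
ecfp4 <- function(smiles, nbits = 2048, mols = NULL) {
  if (is.null(mols)) mols <- parse_mol_batch(smiles)
  rows <- lapply(mols, function(mol) {
    if (is.null(mol)) return(logical(nbits))
    fp_circular(mol, radius = 2, nbits = nbits)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  m
}

#' Tanimoto similarity between two fingerprint keys
#'
#' @param a,b Logical vectors of equal length.
#' @return `|a AND b| / |a OR b|`; defined as 0 (with a warning) when both
#'   vectors are all-zero.
#' @export
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))  # 1/3
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / u
}

# Tanimoto similarity matrix between rows of two 0/1 matrices
tanimoto_matrix <- function(qkeys, tkeys) {
  qm <- matrix(as.numeric(qkeys), nrow = nrow(qkeys))
  tm <- matrix(as.numeric(tkeys), nrow = nrow(tkeys))
  inter <- qm %*% t(tm)
  qa <- rowSums(qm); tb <- rowSums(tm)
  uni <- outer(qa, tb, "+") - inter
  s <- ifelse(uni > 0, inter / uni, 0)
  s
}

#' Nearest-neighbor Tanimoto similarity
#'
#' Maximum Tanimoto similarity of each query key against a set of training
#' keys, with the argmax index (lowest index on ties).
#'
#' @param query Logical matrix (or vector) of query keys.
#' @param train_keys Logical matrix of training keys (one row each).
#' @return Data frame with columns `similarity` and `index`.
#' @export
nearest_neighbor_similarity <- function(query, train_keys) {
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  if (nrow(train_keys) == 0) stop("empty training key set")
  s <- tanimoto_matrix(query, train_keys)
  idx <- apply(s, 1, which.max)
  data.frame(similarity = s[cbind(seq_len(nrow(s)), idx)], index = idx)
}

#' Fit a PCA feature reducer on training fingerprint blocks
#'
#' Centers the training bits and retains the smallest number of principal
#' components whose cumulative explained variance reaches
#' `variance_target`. Fit strictly on training data; apply with
#' [predict.feature_reducer()].
#'
#' @param x A `feature_block` or logical/numeric matrix (rows = training
#'   molecules).
#' @param variance_target Fraction of variance to retain (default 0.95).
#' @return Object of class `feature_reducer` with `center`, `rotation`,
#'   `k` and `explained_variance`.
#' @export
fit_feature_reducer <- function(x, variance_target = 0.95) {
  if (inherits(x, "feature_block")) x <- x$bits
  stopifnot(nrow(x) >= 2, variance_target > 0, variance_target <= 1)
  xm <- matrix(as.numeric(x), nrow = nrow(x))
  vars <- apply(xm, 2, stats::var)
  if (all(vars == 0))
    stop("degenerate feature set: all fingerprint bits are constant ",
         "across the training data")
  pc <- stats::prcomp(xm, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  cum <- cumsum(ev)
  k <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k, explained_variance = cum[k],
                 variance_target = variance_target,
                 n_input = ncol(xm)),
            class = "feature_reducer")
}

#' Apply a fitted feature reducer
#'
#' @param object A `feature_reducer` from [fit_feature_reducer()].
#' @param newdata A `feature_block` or matrix with the same bit layout the
#'   reducer was fitted on.
#' @param ... Unused.
#' @return Numeric matrix with `object$k` columns.
#' @export
predict.feature_reducer <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_block")) newdata <- newdata$bits
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_input)
    stop(sprintf("feature_reducer expects %d bits, got %d",
                 object$n_input, ncol(newdata)))
  xm <- matrix(as.numeric(newdata), nrow = nrow(newdata))
  sweep(xm, 2, object$center) %*% object$rotation
}

#' @export
print.feature_reducer <- function(x, ...) {
  cat(sprintf(
    "<feature_reducer> %d bits -> %d components (%.1f%% variance)\n",
    x$n_input, x$k, 100 * x$explained_variance))
  invisible(x)
}
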