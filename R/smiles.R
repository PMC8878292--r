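## SMILES handling: canonicalization, desalting, molecular graph extraction.
## Parsing is delegated to OpenBabel (ChemmineOB) and ChemmineR; everything
## downstream works on the parsed atom/bond tables.

# Canonicalize a batch of SMILES through OpenBabel. Returns a character
# vector aligned with `smiles`; NA where parsing failed. OpenBabel stops
# converting a multi-molecule stream at the first bad record, so output is
# realigned by injected titles and stragglers are retried one by one.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) &
    !grepl("[[:space:]]", trimws(smiles))
  idx <- which(ok)
  if (length(idx) == 0L) return(out)
  one <- function(s, tag) {
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "CAN", paste0(trimws(s), " ", tag, collapse = "\n"))),
      error = function(e) ""
    )
    res
  }
  tags <- paste0("q", seq_along(idx))
  raw <- one(smiles[idx], tags)
  got <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  got <- got[nzchar(got)]
  parts <- strsplit(got, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2) {
      j <- match(p[2], tags)
      if (!is.na(j)) out[idx[j]] <- p[1]
    }
  }
  # anything still missing: retry individually (isolates the bad records)
  for (j in which(ok & is.na(out))) {
    raw <- one(smiles[j], "q1")
    got <- strsplit(raw, "[\t\n]")[[1]]
    if (length(got) >= 1 && nzchar(got[1])) out[j] <- got[1]
  }
  out
}

# heavy (non-hydrogen) atom count of a single canonical SMILES fragment
count_heavy_atoms <- function(frag) {
  toks <- gregexpr("\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnosp]", frag)[[1]]
  if (toks[1] == -1L) return(0L)
  strs <- regmatches(frag, gregexpr("\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnosp]",
                                    frag))[[1]]
  sum(vapply(strs, function(s) {
    if (startsWith(s, "[")) {
      # bracket atom: exclude isotopic/explicit hydrogen e.g. [H], [2H]
      !grepl("^\\[[0-9]*H[^a-z]", s) && s != "[H]"
    } else TRUE
  }, logical(1)))
}

#' Canonicalize and desalt SMILES strings
#'
#' Converts each SMILES to its canonical form and strips salts/solvates by
#' keeping only the largest covalently connected fragment (heavy-atom
#' count; ties broken by exact molecular weight, then lexicographically).
#' Unparsable input never raises an error mid-pipeline: it is returned with
#' `parse_ok = FALSE` so callers can count and log failures.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data frame with columns `input` (the original string),
#'   `smiles` (canonical desalted SMILES, `NA` on failure) and `parse_ok`.
#' @export
#' @examples
#' canonicalize_desalt(c("CCO.[Na+].[Cl-]", "OCC", "C1CC"))
canonicalize_desalt <- function(smiles) {
  stopifnot(is.character(smiles))
  can <- ob_canonical(smiles)
  res <- vapply(can, function(s) {
    if (is.na(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    counts <- vapply(frags, count_heavy_atoms, integer(1))
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      mw <- vapply(frags[best], fragment_mw, numeric(1))
      best <- best[mw == max(mw)]
      if (length(best) > 1L) best <- best[order(frags[best])][1]
    }
    frags[best[1]]
  }, character(1), USE.NAMES = FALSE)
  # re-canonicalize chosen fragments so the result is idempotent
  redo <- which(!is.na(res) & res != can)
  if (length(redo)) res[redo] <- ob_canonical(res[redo])
  data.frame(input = smiles, smiles = res, parse_ok = !is.na(res),
             stringsAsFactors = FALSE)
}

# exact molecular weight of one fragment via OpenBabel (rare tie-break path)
fragment_mw <- function(frag) {
  p <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(frag, "x")))
    ChemmineOB::propOB(sdf)$MW
  }, error = function(e) NA_real_)
  if (is.na(p)) 0 else p
}

# ---------------------------------------------------------------------------
# parsed molecule tables

SDF_CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                     `5` = -1L, `6` = -2L, `7` = -3L)

STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3)

# Parse one canonical SMILES into atom/bond tables plus ring annotation.
# Returns list(elements, charges, bonds = data.frame(a, b, order),
# degree, ring_atom, ring_size_atom, ring_bond, ring_size_bond, n).
parse_mol <- function(smiles) {
  if (count_heavy_atoms(smiles) <= 1L) return(parse_single_atom(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
  mol_from_sdf(sdf[[1]], smiles)
}

# Parse many SMILES in one SDF round trip (the per-call overhead of the
# converter dominates otherwise). Returns a list aligned with `smiles`;
# NULL where parsing failed.
parse_mol_batch <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  single <- !is.na(smiles) & vapply(smiles, count_heavy_atoms,
                                    integer(1)) <= 1L
  for (i in which(single)) {
    out[[i]] <- tryCatch(parse_single_atom(smiles[i]),
                         error = function(e) NULL)
  }
  todo <- which(!single & !is.na(smiles))
  if (length(todo) > 0) {
    tags <- paste0("m", todo)
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles[todo], tags))), error = function(e) NULL)
    got <- if (is.null(sdf)) character(0) else ChemmineR::cid(sdf)
    for (j in seq_along(todo)) {
      i <- todo[j]
      k <- match(tags[j], got)
      out[[i]] <- if (!is.na(k)) {
        tryCatch(mol_from_sdf(sdf[[k]], smiles[i]), error = function(e) NULL)
      } else {
        tryCatch(parse_mol(smiles[i]), error = function(e) NULL)
      }
    }
  }
  out
}

mol_from_sdf <- function(sdfcmp, smiles) {
  ab <- ChemmineR::atomblock(sdfcmp)
  bb <- ChemmineR::bondblock(sdfcmp)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charges <- integer(n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charges <- unname(SDF_CHARGE_CODE[code])
    charges[is.na(charges)] <- 0L
  }
  if (length(bb) == 0L) {
    bb <- matrix(integer(0), nrow = 0, ncol = 3,
                 dimnames = list(NULL, c("C1", "C2", "C3")))
  } else if (is.null(dim(bb))) {
    bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  }
  keep <- elements != "H"
  if (!all(keep)) {
    # remap bonds onto heavy atoms only (OpenBabel rarely emits explicit H)
    map <- cumsum(keep)
    map[!keep] <- NA_integer_
    if (nrow(bb) > 0) {
      a <- map[bb[, "C1"]]; b <- map[bb[, "C2"]]
      ok <- !is.na(a) & !is.na(b)
      bb <- bb[ok, , drop = FALSE]
      bb[, "C1"] <- a[ok]; bb[, "C2"] <- b[ok]
    }
    elements <- elements[keep]
    charges <- charges[keep]
    n <- length(elements)
  }
  nb <- nrow(bb)
  bonds <- if (nb > 0) {
    data.frame(a = as.integer(bb[, "C1"]), b = as.integer(bb[, "C2"]),
               order = as.integer(bb[, "C3"]))
  } else {
    data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  degree <- tabulate(c(bonds$a, bonds$b), nbins = n)
  ring_bond <- logical(nrow(bonds))
  ring_size_bond <- rep(NA_integer_, nrow(bonds))
  if (nrow(bonds) > 0 && n > 1) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a, bonds$b), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    for (e in which(ring_bond)) {
      g2 <- igraph::delete_edges(g, e)
      d <- igraph::distances(g2, v = bonds$a[e], to = bonds$b[e])[1, 1]
      ring_size_bond[e] <- as.integer(d + 1)
    }
  }
  ring_atom <- logical(n)
  ring_size_atom <- rep(NA_integer_, n)
  for (e in which(ring_bond)) {
    for (v in c(bonds$a[e], bonds$b[e])) {
      ring_atom[v] <- TRUE
      rs <- ring_size_bond[e]
      if (is.na(ring_size_atom[v]) || rs < ring_size_atom[v])
        ring_size_atom[v] <- rs
    }
  }
  list(smiles = smiles, elements = elements, charges = charges,
       bonds = bonds, degree = degree, ring_atom = ring_atom,
       ring_size_atom = ring_size_atom, ring_bond = ring_bond,
       ring_size_bond = ring_size_bond, n = n)
}

# single heavy atoms (and bare ions) sidestep the SDF round trip, which
# cannot represent a zero-bond molecule
parse_single_atom <- function(smiles) {
  tok <- regmatches(smiles, regexpr("\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnosp]",
                                    smiles))
  if (length(tok) == 0) stop("no atom found in SMILES: ", smiles)
  charge <- 0L
  if (startsWith(tok, "[")) {
    body <- gsub("\\[|\\]|[0-9]|H", "", tok)
    charge <- sum(gregexpr("\\+", tok)[[1]] > 0) -
      sum(gregexpr("-", tok)[[1]] > 0)
    elem <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
  } else elem <- tok
  elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  n <- 1L
  list(smiles = smiles, elements = elem, charges = as.integer(charge),
       bonds = data.frame(a = integer(0), b = integer(0),
                          order = integer(0)),
       degree = 0L, ring_atom = FALSE, ring_size_atom = NA_integer_,
       ring_bond = logical(0), ring_size_bond = integer(0), n = n)
}

ELEMENT_SLOTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

# implicit hydrogen count from standard valences (floored at zero)
implicit_h <- function(mol) {
  val <- STD_VALENCE[mol$elements]
  val[is.na(val)] <- 4
  bonded <- numeric(mol$n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      bonded[mol$bonds$a[k]] <- bonded[mol$bonds$a[k]] + o
      bonded[mol$bonds$b[k]] <- bonded[mol$bonds$b[k]] + o
    }
  }
  pmax(0, val + mol$charges - bonded)
}

# 30-dimensional node feature matrix; see the methods vignette for layout
node_feature_matrix <- function(mol) {
  n <- mol$n
  f <- matrix(0, n, 30)
  ei <- match(mol$elements, ELEMENT_SLOTS)
  ei[is.na(ei)] <- 10L                     # "other" slot
  f[cbind(seq_len(n), ei)] <- 1
  dbin <- pmin(mol$degree, 5L) + 1L        # degree 0..>=5 -> cols 11..16
  f[cbind(seq_len(n), 10L + dbin)] <- 1
  cbin <- sign(mol$charges) + 2L           # -,0,+ -> cols 17..19
  f[cbind(seq_len(n), 16L + cbin)] <- 1
  f[, 20] <- as.numeric(mol$ring_atom)
  rs <- mol$ring_size_atom
  rbin <- ifelse(is.na(rs), NA, pmin(pmax(rs, 3L), 8L) - 2L)  # 3..>=8 -> 1..6
  has <- !is.na(rbin)
  f[cbind(which(has), 20L + rbin[has])] <- 1
  if (nrow(mol$bonds) > 0) {
    dbl <- unique(c(mol$bonds$a[mol$bonds$order == 2],
                    mol$bonds$b[mol$bonds$order == 2]))
    trp <- unique(c(mol$bonds$a[mol$bonds$order == 3],
                    mol$bonds$b[mol$bonds$order == 3]))
    f[dbl, 27] <- 1
    f[trp, 28] <- 1
    het <- mol$elements != "C"
    hn <- unique(c(mol$bonds$a[het[mol$bonds$b]], mol$bonds$b[het[mol$bonds$a]]))
    f[hn, 29] <- 1
  }
  f[, 30] <- as.numeric(mol$degree == 1L)
  f
}

# 15 bond-specific features: order one-hot(3), in-ring, ring-size one-hot(6),
# both-ends-in-ring, same-element, 3 reserved zero slots
bond_feature_rows <- function(mol) {
  nb <- nrow(mol$bonds)
  f <- matrix(0, nb, 15)
  if (nb == 0) return(f)
  o <- pmin(mol$bonds$order, 3L)
  f[cbind(seq_len(nb), o)] <- 1
  f[, 4] <- as.numeric(mol$ring_bond)
  rs <- mol$ring_size_bond
  rbin <- ifelse(is.na(rs), NA, pmin(pmax(rs, 3L), 8L) - 2L)
  has <- !is.na(rbin)
  f[cbind(which(has), 4L + rbin[has])] <- 1
  f[, 11] <- as.numeric(mol$ring_atom[mol$bonds$a] & mol$ring_atom[mol$bonds$b])
  f[, 12] <- as.numeric(mol$elements[mol$bonds$a] == mol$elements[mol$bonds$b])
  f
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Builds the graph representation consumed by the PNA branch: a 30-column
#' node (atom) feature matrix, both directed edges per bond, and a
#' 75-column edge (bond) feature matrix composed of the source-node
#' features, target-node features and 15 bond-specific features.
#'
#' @param smiles A single canonical (desalted) SMILES string.
#' @return An object of class `mol_graph`: list with `node_features`
#'   (n x 30), `edges` (E x 2 integer matrix, columns `from`/`to`, both
#'   directions per bond), `edge_features` (E x 75), `degrees` and
#'   `smiles`.
#' @export
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' dim(g$node_features)  # 6 x 30
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  graph_from_mol(parse_mol(smiles))
}

graph_from_mol <- function(mol) {
  smiles <- mol$smiles
  nf <- node_feature_matrix(mol)
  bf <- bond_feature_rows(mol)
  nb <- nrow(mol$bonds)
  if (nb > 0) {
    from <- c(mol$bonds$a, mol$bonds$b)
    to <- c(mol$bonds$b, mol$bonds$a)
    ef <- rbind(cbind(nf[mol$bonds$a, , drop = FALSE],
                      nf[mol$bonds$b, , drop = FALSE], bf),
                cbind(nf[mol$bonds$b, , drop = FALSE],
                      nf[mol$bonds$a, , drop = FALSE], bf))
  } else {
    from <- integer(0); to <- integer(0)
    ef <- matrix(0, 0, 75)
  }
  edges <- cbind(from = from, to = to)
  structure(list(node_features = nf, edges = edges, edge_features = ef,
                 degrees = mol$degree, smiles = smiles),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d directed edges\n",
              x$smiles, nrow(x$node_features), nrow(x$edges)))
  invisible(x)
}
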