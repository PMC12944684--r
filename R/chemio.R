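# Structure I/O: SMILES standardization, canonical graphs, random
# serializations, Murcko scaffolds. Parsing and canonicalization are
# delegated to ChemmineR/ChemmineOB (OpenBabel); ring perception, implicit
# hydrogens, hybridization and scaffold pruning are computed here from the
# parsed graph.

STANDARD_VALENCE <- c(H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
                      Si = 4L, P = 3L, S = 2L, Cl = 1L, Br = 1L, I = 1L,
                      Se = 2L)

# canonical SMILES of one string via OpenBabel; NA_character_ if unparseable
ob_canonical <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- gsub("[\t\n ]+.*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

ob_parse_sdf <- function(smiles) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdfset) || length(sdfset) == 0) return(NULL)
  ab <- ChemmineR::atomblock(sdfset[[1]])
  # a malformed parse (e.g. single-heavy-atom input) yields a stub block
  # without element_index rownames
  if (is.null(dim(ab)) || nrow(ab) == 0 || ncol(ab) < 3 ||
      !all(grepl("^[A-Za-z]+_[0-9]+$", rownames(ab)))) {
    return(NULL)
  }
  sdfset
}

#' Smallest set of smallest rings of a molecular graph
#'
#' Pure-graph SSSR: the cyclomatic number fixes the ring count; candidate
#' rings are, for every edge, the shortest cycle through it; rings are then
#' selected greedily by size until every cycle-space dimension is covered.
#' Operates on plain edge lists so it also serves graphs that no longer
#' correspond to a molecule (e.g. augmented views with deleted bonds).
#'
#' @param edges Two-column integer matrix of undirected edges (1-based).
#' @param n_atoms Number of vertices.
#' @return List of integer vectors, each an ordered atom cycle.
#' @export
perceive_rings <- function(edges, n_atoms) {
  edges <- matrix(as.integer(edges), ncol = 2)
  m <- nrow(edges)
  if (m == 0 || n_atoms == 0) return(list())
  adj <- vector("list", n_atoms)
  for (k in seq_len(m)) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  n_comp <- local({
    seen <- logical(n_atoms); comp <- 0L
    for (s in seq_len(n_atoms)) {
      if (seen[s]) next
      comp <- comp + 1L
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (k in adj[[v]]) {
          w <- edges[k, 1] + edges[k, 2] - v
          if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
        }
      }
    }
    comp
  })
  target <- m - n_atoms + n_comp
  if (target <= 0) return(list())

  # shortest path a..b avoiding edge `skip`, by BFS; NULL if disconnected
  bfs_path <- function(a, b, skip) {
    prev <- integer(n_atoms); prev[] <- -1L
    prev[a] <- 0L
    queue <- a
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (k in adj[[v]]) {
        if (k == skip) next
        w <- edges[k, 1] + edges[k, 2] - v
        if (prev[w] == -1L) {
          prev[w] <- v
          if (w == b) {
            path <- w
            while (path[[1]] != a) path <- c(prev[path[[1]]], path)
            return(path)
          }
          queue <- c(queue, w)
        }
      }
    }
    NULL
  }

  cand <- list(); seen_keys <- character()
  for (k in seq_len(m)) {
    p <- bfs_path(edges[k, 1], edges[k, 2], k)
    if (is.null(p)) next
    key <- paste(sort(p), collapse = ",")
    if (!(key %in% seen_keys)) { seen_keys <- c(seen_keys, key); cand[[length(cand) + 1L]] <- p }
  }
  if (!length(cand)) return(list())
  cand <- cand[order(lengths(cand))]

  edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  ring_edges <- function(r) edge_id(r, c(r[-1], r[[1]]))
  covered <- character(); chosen <- list()
  for (r in cand) {
    if (length(chosen) >= target) break
    re <- ring_edges(r)
    if (any(!(re %in% covered))) {
      chosen[[length(chosen) + 1L]] <- as.integer(r)
      covered <- union(covered, re)
    }
  }
  chosen
}

# derive atom/bond tables (features) from a parsed single-molecule SDFset
build_mol_tables <- function(sdfset) {
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    # bondless molecule: decode the ctab charge codes directly
    code <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, n)
    as.integer(c(0, 3, 2, 1, 0, -1, -2, -3)[code + 1L])
  } else {
    as.integer(ChemmineR::bonds(sdf, type = "bonds")$charge)
  }

  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical(), conjugated = logical(),
                        in_ring = logical())
  } else {
    order_raw <- as.integer(bb[, 3])
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = ifelse(order_raw == 4L, 1L, order_raw),
                        aromatic = FALSE, conjugated = FALSE, in_ring = FALSE)
  }

  rings <- perceive_rings(cbind(bonds$a1, bonds$a2), n)

  # aromatic ring detection from the toolkit's ring perception
  arom_atom <- logical(n)
  if (length(rings)) {
    ri <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(ri) && length(ri$RINGS)) {
      for (i in seq_along(ri$RINGS)) {
        if (isTRUE(ri$AROMATIC[[i]])) {
          ids <- as.integer(sub("^.*_", "", ri$RINGS[[i]]))
          arom_atom[ids] <- TRUE
        }
      }
    }
  }

  in_ring_atom <- logical(n)
  for (r in rings) in_ring_atom[r] <- TRUE
  if (nrow(bonds)) {
    ring_edge_keys <- unlist(lapply(rings, function(r) {
      nxt <- c(r[-1], r[[1]])
      paste(pmin(r, nxt), pmax(r, nxt), sep = "-")
    }))
    bkey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2), sep = "-")
    bonds$in_ring <- bkey %in% ring_edge_keys
    bonds$aromatic <- bonds$in_ring & arom_atom[bonds$a1] & arom_atom[bonds$a2]
  }

  degree <- integer(n); order_sum <- numeric(n)
  n_double <- integer(n); n_triple <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      for (a in c(bonds$a1[k], bonds$a2[k])) {
        degree[a] <- degree[a] + 1L
        order_sum[a] <- order_sum[a] + bonds$order[k]
        if (bonds$order[k] == 2L) n_double[a] <- n_double[a] + 1L
        if (bonds$order[k] == 3L) n_triple[a] <- n_triple[a] + 1L
      }
    }
  }

  # implicit hydrogens from standard valences, adjusted for formal charge
  val <- unname(STANDARD_VALENCE[element])
  adj <- ifelse(element %in% c("N", "P", "O", "S"), charge, -abs(charge))
  val_eff <- ifelse(is.na(val), order_sum, val + adj)
  n_h <- pmax(0L, as.integer(round(val_eff - order_sum)))

  hybrid <- ifelse(degree == 0L, "s",
            ifelse(arom_atom | n_double == 1L & n_triple == 0L, "sp2",
            ifelse(n_triple >= 1L | n_double >= 2L, "sp", "sp3")))
  sp2ish <- hybrid %in% c("sp", "sp2")
  if (nrow(bonds)) bonds$conjugated <- sp2ish[bonds$a1] & sp2ish[bonds$a2]

  z_tab <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Si = 14,
             P = 15, S = 16, Cl = 17, K = 19, Br = 35, I = 53, Se = 34)
  z <- unname(z_tab[element]); z[is.na(z)] <- 0

  atoms <- data.frame(element = element, z = as.integer(z), charge = charge,
                      aromatic = arom_atom, in_ring = in_ring_atom,
                      n_h = n_h, degree = degree, hybrid = hybrid,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds, rings = rings)
}

#' Standardize a raw SMILES string
#'
#' Keeps the largest organic fragment (most heavy atoms; carbon-containing
#' fragments preferred; ties broken by canonical-string order), then
#' canonicalizes with the toolkit's default perception rules. The result is
#' idempotent: re-standardizing the canonical string returns it unchanged.
#'
#' @param raw A non-empty SMILES string, possibly multi-fragment
#'   (salt/solvent separated by `.`).
#' @return A `standard_molecule`: canonical SMILES plus atom/bond/ring
#'   tables of the parent structure.
#' @examples
#' m <- standardize_structure("CCO.Cl")
#' m$canonical
#' @export
standardize_structure <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw))) {
    abort2("structure must be a single non-empty SMILES string", "cyp3a4hybrid_parse_error")
  }
  raw <- trimws(raw)
  frags <- strsplit(raw, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) abort2("empty structure", "cyp3a4hybrid_parse_error")

  stripped <- length(frags) > 1L
  if (stripped) {
    info <- lapply(frags, function(f) {
      can <- ob_canonical(f)
      if (is.na(can)) return(NULL)
      sdfset <- ob_parse_sdf(can)
      if (is.null(sdfset)) return(NULL)
      el <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdfset[[1]])))
      heavy <- sum(el != "H")
      list(can = can, heavy = heavy, has_c = any(el == "C"))
    })
    info <- Filter(Negate(is.null), info)
    if (!length(info)) {
      abort2(sprintf("unparseable structure: %s", raw), "cyp3a4hybrid_parse_error")
    }
    has_c <- vapply(info, `[[`, logical(1), "has_c")
    if (any(has_c)) info <- info[has_c]
    heavy <- vapply(info, `[[`, numeric(1), "heavy")
    cans <- vapply(info, `[[`, character(1), "can")
    best <- which(heavy == max(heavy))
    parent <- sort(cans[best])[[1]]
  } else {
    parent <- raw
  }

  canonical <- ob_canonical(parent)
  if (is.na(canonical)) {
    abort2(sprintf("unparseable structure: %s", raw), "cyp3a4hybrid_parse_error")
  }
  sdfset <- ob_parse_sdf(canonical)
  if (is.null(sdfset)) {
    abort2(sprintf("unparseable structure: %s", raw), "cyp3a4hybrid_parse_error")
  }
  tabs <- build_mol_tables(sdfset)
  structure(list(canonical = canonical, parent_only = stripped,
                 sdfset = sdfset, atoms = tabs$atoms, bonds = tabs$bonds,
                 rings = tabs$rings),
            class = "standard_molecule")
}

#' @export
print.standard_molecule <- function(x, ...) {
  cat("<standard_molecule>", x$canonical, "\n")
  cat(sprintf("  %d atoms, %d bonds, %d rings%s\n", nrow(x$atoms),
              nrow(x$bonds), length(x$rings),
              if (x$parent_only) " (salt/solvent stripped)" else ""))
  invisible(x)
}

#' Standardize a vector of SMILES, collecting rejections
#'
#' @param smiles Character vector of raw SMILES.
#' @return List with `molecules` (named list of `standard_molecule`, names =
#'   input positions) and `rejections` (data frame of index, smiles, reason).
#' @export
standardize_structures <- function(smiles) {
  mols <- vector("list", length(smiles))
  rej <- list()
  for (i in seq_along(smiles)) {
    m <- tryCatch(standardize_structure(smiles[[i]]), cyp3a4hybrid_parse_error = function(e) e)
    if (inherits(m, "condition")) {
      rej[[length(rej) + 1L]] <- data.frame(index = i, smiles = smiles[[i]],
                                            reason = "unparseable")
    } else {
      mols[[i]] <- m
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(index = integer(), smiles = character(), reason = character())
  list(molecules = mols, rejections = rejections)
}

#' Enumerate the canonical plus n randomized SMILES of a molecule
#'
#' Randomized serializations are produced by permuting the atom order of the
#' parsed structure uniformly at random and re-serializing; every variant
#' re-canonicalizes to the same molecule. Duplicates among the n variants
#' are allowed.
#'
#' @param mol A `standard_molecule`.
#' @param n Number of randomized variants (>= 0).
#' @param seed Integer seed; the same seed reproduces the same list.
#' @return Character vector of length `n + 1`; element 1 is the canonical
#'   SMILES.
#' @export
enumerate_random_smiles <- function(mol, n, seed = 1L) {
  stopifnot(inherits(mol, "standard_molecule"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(mol$canonical)
  sdfset <- mol$sdfset
  ab <- ChemmineR::atomblock(sdfset[[1]])
  bb <- ChemmineR::bondblock(sdfset[[1]])
  n_atoms <- nrow(ab)
  variants <- with_seed(seed, vapply(seq_len(n), function(i) {
    perm <- sample.int(n_atoms)
    inv <- order(perm)
    ab2 <- ab[perm, , drop = FALSE]
    bb2 <- bb
    if (!is.null(dim(bb2)) && nrow(bb2)) {
      bb2[, 1] <- inv[bb[, 1]]
      bb2[, 2] <- inv[bb[, 2]]
    }
    s2 <- sdfset
    ChemmineR::atomblock(s2) <- list(x = ab2)
    ChemmineR::bondblock(s2) <- list(x = bb2)
    out <- as.character(ChemmineR::sdf2smiles(s2))
    gsub("[\t\n ]+.*$", "", out)
  }, character(1)))
  c(mol$canonical, variants)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus connecting linkers are retained; side chains are pruned
#' (iteratively removing terminal non-ring atoms); atoms double-bonded to
#' the retained frame (e.g. exocyclic carbonyl oxygens) are kept. Acyclic
#' molecules map to the designated empty-scaffold key `""`.
#'
#' @param mol A `standard_molecule`.
#' @return Canonical SMILES of the scaffold, or `""` for acyclic molecules.
#' @export
murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "standard_molecule"))
  if (!length(mol$rings)) return("")
  n <- nrow(mol$atoms)
  keep <- rep(TRUE, n)
  bonds <- mol$bonds
  ring_atom <- mol$atoms$in_ring
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(bonds))) {
      if (keep[bonds$a1[k]] && keep[bonds$a2[k]]) {
        deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
        deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
      }
    }
    prune <- keep & !ring_atom & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  # retain atoms attached to the frame by a double/triple bond
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] >= 2L) {
      if (keep[bonds$a1[k]] && !keep[bonds$a2[k]]) keep[bonds$a2[k]] <- TRUE
      if (keep[bonds$a2[k]] && !keep[bonds$a1[k]]) keep[bonds$a1[k]] <- TRUE
    }
  }
  ids <- which(keep)
  sub <- ChemmineR::atomsubset(mol$sdfset[[1]], atomrows = ids)
  subset_set <- methods::new("SDFset", SDF = list(sub), ID = "scaffold")
  smi <- as.character(ChemmineR::sdf2smiles(subset_set))
  smi <- gsub("[\t\n ]+.*$", "", smi)
  out <- ob_canonical(smi)
  if (is.na(out)) "" else out
}

#' Read a raw measurement table
#'
#' @param path CSV with header columns `id`, `smiles`, `value` (extra
#'   columns are kept as metadata).
#' @return Data frame of raw records.
#' @export
read_raw_records <- function(path) {
  if (!file.exists(path)) abort2(sprintf("input file not found: %s", path), "cyp3a4hybrid_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort2(sprintf("raw CSV is missing column(s): %s", paste(miss, collapse = ", ")),
           "cyp3a4hybrid_io_error")
  }
  df
}

#' Write a curated record table
#'
#' Columns: `molecule_key`, `canonical_smiles`, `label`, `n_replicates`,
#' `aggregation_branch`.
#'
#' @param curated Data frame as produced by [curate_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curated_records <- function(curated, path) {
  utils::write.csv(curated, path, row.names = FALSE)
  invisible(path)
}
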