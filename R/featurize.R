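# Molecular representations: circular fingerprint bits, physicochemical
# descriptors, engineered feature axes, and the ring-aware dual graph.
#
# Fingerprints, SMARTS matching and the core descriptor block come from the
# OpenBabel backend (ChemmineOB); graph-derived descriptors (rotatable
# bonds, aromatic-ring count) and all engineered axes are computed from the
# parsed structure.

mol_sdfset <- function(molecules) {
  stopifnot(length(molecules) > 0)
  methods::new("SDFset",
               SDF = lapply(molecules, function(m) m$sdfset[[1]]),
               ID = make.unique(vapply(molecules, `[[`, character(1), "canonical")))
}

#' Load the SAR motif catalog
#'
#' Named SMARTS patterns (benzodioxole, pyridine, indole, imidazole,
#' piperidine, pyrazine, triazole, heterocyclic nitrogen, coordinating
#' heteroatoms) shipped as a versioned data file; each pattern matches its
#' own exemplar molecule.
#'
#' @param path Optional path to an alternative catalog JSON.
#' @return A `motif_catalog`: named list with `smarts` and `exemplar`.
#' @export
motif_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motifs.json", package = "cyp3a4hybrid")
  }
  cat_raw <- jsonlite::read_json(path)
  structure(cat_raw$motifs, class = "motif_catalog")
}

#' Count SMARTS matches in molecules
#'
#' @param molecules List of `standard_molecule`.
#' @param smarts A SMARTS pattern.
#' @return Integer vector of unique match counts per molecule.
#' @export
count_matches <- function(molecules, smarts) {
  sdfset <- mol_sdfset(molecules)
  as.integer(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
}

#' Extended-connectivity circular fingerprint
#'
#' Radius-4 (diameter-8) circular fingerprint hashed to `n_bits` binary
#' values; the backend's 4096-bit fingerprint is folded down by OR.
#'
#' @param molecules List of `standard_molecule` (or a single one).
#' @param radius Neighborhood radius (1-5; default 4).
#' @param n_bits Output length; power of two, at most 4096.
#' @return Binary 0/1 matrix, one row per molecule.
#' @export
ecfp_fingerprint <- function(molecules, radius = 4, n_bits = 2048) {
  if (inherits(molecules, "standard_molecule")) molecules <- list(molecules)
  stopifnot(radius %in% 1:5, n_bits <= 4096, bitwAnd(n_bits, n_bits - 1L) == 0)
  type <- paste0("ECFP", 2L * radius)
  fp <- ChemmineR::fingerprintOB(mol_sdfset(molecules), type)
  m <- ChemmineR::as.matrix(fp)
  while (ncol(m) > n_bits) {
    half <- ncol(m) / 2
    m <- (m[, seq_len(half), drop = FALSE] |
            m[, half + seq_len(half), drop = FALSE]) * 1L
  }
  colnames(m) <- paste0("FP_", seq_len(ncol(m)))
  rownames(m) <- NULL
  m
}

#' Tanimoto similarity between two bit vectors
#' @param a,b Binary vectors of equal length.
#' @return Similarity in `[0, 1]` (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Mean Tanimoto similarity of a molecule to a reference set
#' @param fp Binary fingerprint vector.
#' @param references Matrix of reference fingerprints (rows) or list of
#'   vectors; must be non-empty.
#' @return Mean similarity in `[0, 1]`.
#' @export
mean_similarity <- function(fp, references) {
  if (is.list(references)) references <- do.call(rbind, references)
  if (is.null(dim(references)) && length(references)) references <- rbind(references)
  if (is.null(references) || nrow(references) == 0) {
    abort2("reference set must be non-empty", "cyp3a4hybrid_feature_error")
  }
  mean(apply(references, 1, tanimoto, b = fp))
}

#' Count rotatable bonds of a molecule
#'
#' Non-ring single bonds between two heavy atoms that each carry at least
#' one further heavy neighbor.
#' @param mol A `standard_molecule`.
#' @return Integer count.
#' @export
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  sum(b$order == 1L & !b$in_ring & !b$aromatic &
        mol$atoms$degree[b$a1] >= 2L & mol$atoms$degree[b$a2] >= 2L)
}

#' Count aromatic rings of a molecule
#' @param mol A `standard_molecule`.
#' @return Number of SSSR rings whose atoms are all aromatic.
#' @export
aromatic_ring_count <- function(mol) {
  if (!length(mol$rings)) return(0L)
  sum(vapply(mol$rings, function(r) all(mol$atoms$aromatic[r]), logical(1)))
}

#' Physicochemical descriptor block
#'
#' Molecular weight, SLogP-type lipophilicity, TPSA, hydrogen-bond donor
#' and acceptor counts, molar refractivity (toolkit values) plus rotatable
#' bonds, aromatic-ring count, ring count and heavy-atom count (graph
#' values).
#'
#' @param molecules List of `standard_molecule` (or a single one).
#' @return Numeric matrix, one named-column descriptor set per molecule.
#' @export
compute_descriptors <- function(molecules) {
  if (inherits(molecules, "standard_molecule")) molecules <- list(molecules)
  pr <- ChemmineR::propOB(mol_sdfset(molecules))
  out <- cbind(
    mw = as.numeric(pr$MW),
    slogp = as.numeric(pr$logP),
    tpsa = as.numeric(pr$TPSA),
    hbd = as.numeric(pr$HBD),
    hba = as.numeric(pr$HBA2),
    molar_refractivity = as.numeric(pr$MR),
    rotatable_bonds = vapply(molecules, rotatable_bonds, integer(1)),
    aromatic_rings = vapply(molecules, aromatic_ring_count, integer(1)),
    n_rings = vapply(molecules, function(m) length(m$rings), integer(1)),
    heavy_atoms = vapply(molecules, function(m) sum(m$atoms$element != "H"), numeric(1))
  )
  colnames(out) <- paste0("desc_", colnames(out))
  out
}

#' Engineered feature axes
#'
#' Four axes: (i) lipophilicity/polarity (an ESOL-style additive
#' log-solubility estimate, TPSA, TPSA per heavy atom); (ii) charge patches
#' (counts of formally positive/negative atoms); (iii) structural motifs
#' (catalog match counts, heteroatom coordination fraction, aromatic-carbon
#' ratio); (iv) drug-likeness (Lipinski rule-of-five violation count and a
#' desirability-product score).
#'
#' @param molecules List of `standard_molecule` (or a single one).
#' @param catalog A `motif_catalog`.
#' @param descriptors Optional precomputed [compute_descriptors()] matrix.
#' @return Numeric matrix with stable column names, one row per molecule.
#' @export
engineered_features <- function(molecules, catalog = motif_catalog(),
                                descriptors = NULL) {
  if (inherits(molecules, "standard_molecule")) molecules <- list(molecules)
  if (is.null(descriptors)) descriptors <- compute_descriptors(molecules)
  d <- as.data.frame(descriptors)

  heavy <- d$desc_heavy_atoms
  arom_atoms <- vapply(molecules, function(m) sum(m$atoms$aromatic), numeric(1))
  n_c <- vapply(molecules, function(m) sum(m$atoms$element == "C"), numeric(1))
  arom_c <- vapply(molecules, function(m)
    sum(m$atoms$element == "C" & m$atoms$aromatic), numeric(1))
  n_pos <- vapply(molecules, function(m) sum(m$atoms$charge > 0), numeric(1))
  n_neg <- vapply(molecules, function(m) sum(m$atoms$charge < 0), numeric(1))
  het <- vapply(molecules, function(m)
    sum(m$atoms$element %in% c("N", "O", "S")), numeric(1))

  # ESOL-style additive aqueous solubility estimate (log mol/L)
  ap <- ifelse(heavy > 0, arom_atoms / heavy, 0)
  log_s <- 0.16 - 0.63 * d$desc_slogp - 0.0062 * d$desc_mw +
    0.066 * d$desc_rotatable_bonds - 0.74 * ap

  viol <- (d$desc_mw > 500) + (d$desc_slogp > 5) + (d$desc_hbd > 5) + (d$desc_hba > 10)
  # desirability product over MW, logP, TPSA, rotatable bonds (log-normal
  # style bumps centered on typical oral-drug values)
  bump <- function(x, mu, sigma) exp(-0.5 * ((x - mu) / sigma)^2)
  dlk <- (bump(d$desc_mw, 350, 200) * bump(d$desc_slogp, 2.5, 2.5) *
            bump(d$desc_tpsa, 75, 60) * bump(d$desc_rotatable_bonds, 4, 4))^(1 / 4)

  motif_names <- setdiff(names(catalog), "coordinating_heteroatom")
  motif_counts <- vapply(motif_names, function(nm) {
    count_matches(molecules, catalog[[nm]]$smarts)
  }, integer(length(molecules)))
  if (length(molecules) == 1L) motif_counts <- rbind(motif_counts)

  out <- cbind(
    log_solubility = log_s,
    tpsa = d$desc_tpsa,
    tpsa_per_heavy = ifelse(heavy > 0, d$desc_tpsa / heavy, 0),
    n_positive_atoms = n_pos,
    n_negative_atoms = n_neg,
    motif_counts,
    coordinating_heteroatom_fraction = ifelse(heavy > 0, het / heavy, 0),
    aromatic_carbon_ratio = ifelse(n_c > 0, arom_c / n_c, 0),
    lipinski_violations = viol,
    druglikeness = dlk
  )
  colnames(out) <- paste0("eng_", c("log_solubility", "tpsa", "tpsa_per_heavy",
                                    "n_positive_atoms", "n_negative_atoms",
                                    motif_names,
                                    "coordinating_heteroatom_fraction",
                                    "aromatic_carbon_ratio",
                                    "lipinski_violations", "druglikeness"))
  rownames(out) <- NULL
  out
}

HYBRID_CODE <- c(other = 0, s = 1, sp = 2, sp2 = 3, sp3 = 4)

#' Build the ring-aware dual graph of a molecule
#'
#' The atom/bond graph is augmented with rings (smallest set of smallest
#' rings) as explicit third structural units: ring membership masks,
#' node-ring incidence, and ring-ring adjacency (rings sharing at least one
#' atom), so that aromatic systems and fused-ring environments survive
#' message passing and readout.
#'
#' Node feature columns: atomic number, formal charge, hybridization code
#' (s/sp/sp2/sp3/other), aromatic flag, in-ring flag, attached-H count, and
#' a mask-token flag (0 for real atoms). Edge feature columns: bond order,
#' aromatic, conjugated, in-ring flags.
#'
#' @param mol A `standard_molecule`.
#' @return A `dual_graph` list: `n_atoms`, `node_features`, `edges`,
#'   `edge_features`, `rings`, `node_ring_incidence`,
#'   `ring_ring_adjacency`, `ring_mask`.
#' @export
build_dual_graph <- function(mol) {
  stopifnot(inherits(mol, "standard_molecule"))
  a <- mol$atoms
  nf <- cbind(z = a$z, charge = a$charge,
              hybrid = unname(HYBRID_CODE[a$hybrid]),
              aromatic = as.numeric(a$aromatic),
              in_ring = as.numeric(a$in_ring),
              n_h = a$n_h, masked = 0)
  b <- mol$bonds
  edges <- cbind(a1 = b$a1, a2 = b$a2)
  ef <- cbind(order = b$order, aromatic = as.numeric(b$aromatic),
              conjugated = as.numeric(b$conjugated),
              in_ring = as.numeric(b$in_ring))
  dual_graph(nrow(a), nf, edges, ef, mol$rings)
}

#' Construct a dual graph from parts
#'
#' Recomputes incidence and ring-ring adjacency from the ring list and
#' validates index ranges; used by [build_dual_graph()] and by graph
#' augmentation after topology edits.
#'
#' @param n_atoms Atom count.
#' @param node_features Numeric matrix (`n_atoms` rows).
#' @param edges Two-column integer matrix of bonds (1-based).
#' @param edge_features Numeric matrix (one row per edge).
#' @param rings List of integer atom-index vectors.
#' @return A `dual_graph`.
#' @export
dual_graph <- function(n_atoms, node_features, edges, edge_features, rings) {
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(nrow(node_features) == n_atoms,
            nrow(edge_features) == nrow(edges),
            all(edges >= 1 & edges <= n_atoms),
            all(unlist(rings) >= 1), all(unlist(rings) <= n_atoms))
  n_rings <- length(rings)
  incidence <- if (n_rings) {
    do.call(rbind, lapply(seq_len(n_rings), function(i) {
      cbind(atom = rings[[i]], ring = i)
    }))
  } else matrix(integer(), ncol = 2, dimnames = list(NULL, c("atom", "ring")))
  rr <- matrix(integer(), ncol = 2)
  if (n_rings > 1) {
    pairs <- utils::combn(n_rings, 2)
    share <- apply(pairs, 2, function(p) {
      length(intersect(rings[[p[1]]], rings[[p[2]]])) >= 1
    })
    if (any(share)) rr <- t(pairs[, share, drop = FALSE])
  }
  structure(list(n_atoms = n_atoms, node_features = node_features,
                 edges = edges, edge_features = edge_features,
                 rings = rings, node_ring_incidence = incidence,
                 ring_ring_adjacency = rr,
                 ring_mask = rep(TRUE, n_rings)),
            class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  cat(sprintf("<dual_graph> %d atoms, %d bonds, %d rings, %d ring-ring contacts\n",
              x$n_atoms, nrow(x$edges), length(x$rings), nrow(x$ring_ring_adjacency)))
  invisible(x)
}

#' Assemble the full tabular feature matrix
#'
#' Concatenates fingerprint bits, descriptors, engineered features, and
#' per-feature missingness flags for any non-finite descriptor values
#' (which are themselves replaced by 0). Column names are stable across
#' runs for a fixed configuration.
#'
#' @param molecules List of `standard_molecule`.
#' @param catalog A `motif_catalog`.
#' @param radius,n_bits Fingerprint parameters.
#' @return Numeric matrix, one row per molecule.
#' @export
feature_matrix <- function(molecules, catalog = motif_catalog(),
                           radius = 4, n_bits = 2048) {
  fp <- ecfp_fingerprint(molecules, radius, n_bits)
  de <- compute_descriptors(molecules)
  en <- engineered_features(molecules, catalog, descriptors = de)
  num <- cbind(de, en)
  miss <- !is.finite(num) * 1
  colnames(miss) <- paste0("miss_", colnames(num))
  num[!is.finite(num)] <- 0
  cbind(fp, num, miss)
}

#' Write a feature matrix as CSV plus a sidecar JSON of feature names
#' @param X Feature matrix from [feature_matrix()].
#' @param keys Molecule keys (row identifiers).
#' @param path Output CSV path; names go to `<path>.names.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, keys, path) {
  df <- data.frame(molecule_key = keys, X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(colnames(X), paste0(path, ".names.json"))
  invisible(path)
}

#' Serialize dual graphs to JSON lines
#' @param graphs List of `dual_graph`.
#' @param keys Molecule keys.
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_dual_graphs <- function(graphs, keys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    writeLines(jsonlite::toJSON(list(
      key = keys[[i]], n_atoms = g$n_atoms,
      node_features = g$node_features, edges = g$edges,
      edge_features = g$edge_features, rings = g$rings,
      node_ring_incidence = g$node_ring_incidence,
      ring_ring_adjacency = g$ring_ring_adjacency
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}
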