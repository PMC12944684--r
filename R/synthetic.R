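# Synthetic benchmark generator: molecule libraries assembled from a
# fragment grammar containing the SAR-relevant ring motifs, labels from a
# planted additive structure-activity function plus noise (clipped to the
# percent scale), optional replicates with outliers.
#
# The planted effect sizes echo the direction and magnitude of the motif
# shifts reported for CYP3A4 screening collections (benzodioxole strongly
# positive, pyridine/indole/imidazole moderately positive, piperidine and
# pyrazine mildly negative); they are fixture parameters of the benchmark,
# not measurements.

# Ring fragments are written so that both the first and the last serialized
# atom are carbons: any fragment can then be concatenated into a growing
# chain without creating invalid aromatic valences, and every motif can be
# included or excluded independently of the others (which keeps the motif
# presence indicators near-orthogonal, so marginal SAR contrasts center on
# the planted effects).
SYN_MOTIF_FRAGMENTS <- c(benzodioxole = "c1ccc2OCOc2c1",
                         pyridine = "c1ccncc1",
                         imidazole = "c1[nH]cnc1",
                         indole = "c1ccc2c(c1)[nH]cc2",
                         piperidine = "C1CCNCC1",
                         pyrazine = "c1nccnc1")
SYN_FILLER_FRAGMENTS <- c(benzene = "c1ccccc1", cyclohexane = "C1CCCCC1")
SYN_CHAINS <- c("C", "CC", "CCC", "CCO", "CCN", "COC", "CC(C)C")

default_grammar <- function() {
  list(motif_fragments = SYN_MOTIF_FRAGMENTS,
       filler_fragments = SYN_FILLER_FRAGMENTS,
       chain_fragments = SYN_CHAINS,
       p_motif = 0.22, p_filler = 0.2, max_chains = 3L)
}

#' Synthetic benchmark configuration
#'
#' @param n_molecules Library size (unique structures).
#' @param beta Named planted motif effects in percentage points.
#' @param intercept Baseline percent inhibition.
#' @param slope_logp,slope_aromatic Planted slopes on the lipophilicity
#'   descriptor (percentage points per log unit) and the aromatic-ring
#'   count. Kept small by default so that the marginal with/without
#'   contrast of each motif stays centered on its planted effect.
#' @param noise_sd Label noise SD in percentage points.
#' @param replicates_k Replicates per molecule (>= 1).
#' @param replicate_sd Replicate measurement noise SD.
#' @param outlier_rate Probability that a molecule receives one displaced
#'   (+/- 50) replicate.
#' @param grammar Fragment grammar: named `motif_fragments`,
#'   `filler_fragments`, `chain_fragments` SMILES vectors plus inclusion
#'   probabilities `p_motif`, `p_filler` and `max_chains`.
#' @param seed Integer seed; all generator output is reproducible given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_molecules = 2000L,
                             beta = c(benzodioxole = 35, imidazole = 9,
                                      pyridine = 11, indole = 16,
                                      piperidine = -5, pyrazine = -3),
                             intercept = 15, slope_logp = 0.5,
                             slope_aromatic = 0.5, noise_sd = 10,
                             replicates_k = 2L, replicate_sd = 5,
                             outlier_rate = 0.02,
                             grammar = default_grammar(), seed = 1L) {
  stopifnot(n_molecules >= 1, noise_sd >= 0, replicates_k >= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            length(grammar$chain_fragments) >= 1)
  structure(list(n_molecules = as.integer(n_molecules), beta = beta,
                 intercept = intercept, slope_logp = slope_logp,
                 slope_aromatic = slope_aromatic, noise_sd = noise_sd,
                 replicates_k = as.integer(replicates_k),
                 replicate_sd = replicate_sd, outlier_rate = outlier_rate,
                 grammar = grammar, seed = as.integer(seed)),
            class = "generator_config")
}

# one random assembly: each motif included independently, optional filler
# ring, 1..max_chains chain fragments, all shuffled and concatenated
syn_assemble <- function(grammar) {
  parts <- character(0)
  for (fr in grammar$motif_fragments) {
    if (stats::runif(1) < grammar$p_motif) parts <- c(parts, fr)
  }
  for (fr in grammar$filler_fragments) {
    if (stats::runif(1) < grammar$p_filler) parts <- c(parts, fr)
  }
  n_ch <- sample.int(grammar$max_chains, 1L)
  parts <- c(parts, sample(grammar$chain_fragments, n_ch, replace = TRUE))
  paste(sample(parts), collapse = "")
}

#' Generate a seeded library of standardized synthetic molecules
#'
#' Molecules are assembled from the fragment grammar (motif ring cores plus
#' short alkyl/ether/amine chains and secondary rings), standardized, and
#' de-duplicated by canonical SMILES.
#'
#' @param config A [generator_config()].
#' @return Named list of `standard_molecule`, keyed by canonical SMILES.
#' @export
generate_molecules <- function(config = generator_config()) {
  with_seed(derive_seed(config$seed, 1L), {
    mols <- list()
    tries <- 0L
    while (length(mols) < config$n_molecules && tries < 50L * config$n_molecules) {
      tries <- tries + 1L
      smi <- syn_assemble(config$grammar)
      m <- tryCatch(standardize_structure(smi),
                    cyp3a4hybrid_parse_error = function(e) NULL)
      if (is.null(m)) next
      if (is.null(mols[[m$canonical]])) mols[[m$canonical]] <- m
    }
    if (length(mols) < config$n_molecules) {
      abort2("fragment grammar exhausted before reaching n_molecules",
             "cyp3a4hybrid_synth_error")
    }
    mols
  })
}

#' Plant an additive structure-activity function over a library
#'
#' The noiseless label is
#' `intercept + sum(beta_motif * count_motif) + slope_logp * SLogP +
#' slope_aromatic * aromatic_rings`; Gaussian noise is added and the result
#' clipped to `[0, 100]`.
#'
#' @param molecules Named list of `standard_molecule`.
#' @param config A [generator_config()].
#' @param catalog Motif catalog supplying the SMARTS used for the planted
#'   counts.
#' @return A `ground_truth` list: `keys`, `noiseless` (pre-clip),
#'   `label` (final clipped), `motif_counts` matrix, `design` matrix.
#' @export
plant_labels <- function(molecules, config = generator_config(),
                         catalog = motif_catalog()) {
  keys <- vapply(molecules, `[[`, character(1), "canonical")
  counts <- vapply(names(config$beta), function(nm) {
    count_matches(molecules, catalog[[nm]]$smarts)
  }, integer(length(molecules)))
  if (length(molecules) == 1L) counts <- rbind(counts)
  de <- compute_descriptors(molecules)
  design <- cbind(counts, slogp = de[, "desc_slogp"],
                  aromatic_rings = de[, "desc_aromatic_rings"])
  noiseless <- config$intercept +
    as.vector(counts %*% config$beta) +
    config$slope_logp * de[, "desc_slogp"] +
    config$slope_aromatic * de[, "desc_aromatic_rings"]
  noise <- with_seed(derive_seed(config$seed, 2L),
                     stats::rnorm(length(noiseless), 0, config$noise_sd))
  label <- pmin(pmax(noiseless + noise, 0), 100)
  structure(list(keys = unname(keys), noiseless = unname(noiseless),
                 label = unname(label), motif_counts = counts,
                 design = design),
            class = "ground_truth")
}

#' Expand ground truth into raw replicate records
#'
#' Each molecule yields `replicates_k` noisy copies of its final label;
#' with probability `outlier_rate` one replicate is displaced by 50
#' percentage points (toward the interior of the scale, so the displacement
#' survives clipping). Replicates beyond the first are serialized as
#' randomized SMILES to exercise canonicalization-based merging downstream.
#'
#' @param molecules Named list of `standard_molecule` (as used for
#'   `ground_truth`).
#' @param truth A `ground_truth`.
#' @param config A [generator_config()].
#' @return Data frame with columns `id`, `smiles`, `value`.
#' @export
make_replicates <- function(molecules, truth, config = generator_config()) {
  k <- config$replicates_k
  n <- length(truth$label)
  with_seed(derive_seed(config$seed, 3L), {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      mol <- molecules[[truth$keys[i]]]
      vals <- truth$label[i] + stats::rnorm(k, 0, config$replicate_sd)
      if (k >= 2 && stats::runif(1) < config$outlier_rate) {
        j <- sample.int(k, 1L)
        vals[j] <- truth$label[i] + if (truth$label[i] > 50) -50 else 50
      }
      smis <- if (k >= 2) {
        c(mol$canonical,
          enumerate_random_smiles(mol, k - 1L,
                                  seed = derive_seed(config$seed, 1000L + i))[-1])
      } else mol$canonical
      rows[[i]] <- data.frame(id = sprintf("M%05d_r%d", i, seq_len(k)),
                              smiles = smis, value = vals,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Build a complete synthetic benchmark bundle
#'
#' Generates the library, plants labels, expands replicates, and runs the
#' standard curation; optionally writes `raw.csv`, `curated.csv` and
#' `truth.json` to a directory.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory (created if missing).
#' @param lo,hi,max_sd,clip_window Curation settings (see
#'   [curate_records()]).
#' @return List with `molecules`, `truth`, `raw`, `curated` (the
#'   [curate_records()] result), invisibly when `dir` is given.
#' @export
make_benchmark <- function(config = generator_config(), dir = NULL,
                           lo = 20, hi = 70, max_sd = 30,
                           clip_window = c(-10, 110)) {
  molecules <- generate_molecules(config)
  truth <- plant_labels(molecules, config)
  raw <- make_replicates(molecules, truth, config)
  cur <- curate_records(raw, lo = lo, hi = hi, max_sd = max_sd,
                        clip_window = clip_window)
  out <- list(molecules = molecules, truth = truth, raw = raw, curated = cur)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(raw, file.path(dir, "raw.csv"), row.names = FALSE)
    write_curated_records(cur$curated, file.path(dir, "curated.csv"))
    jsonlite::write_json(list(keys = truth$keys, noiseless = truth$noiseless,
                              label = truth$label,
                              motif_counts = truth$motif_counts,
                              beta = as.list(config$beta)),
                         file.path(dir, "truth.json"), digits = NA)
    return(invisible(out))
  }
  out
}
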