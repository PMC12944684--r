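# HTS label curation: clip/reject, replicate-outlier flagging, piecewise
# duplicate aggregation, threshold sensitivity analysis, scaffold diversity.
#
# Single-concentration percent-inhibition screens routinely report values
# slightly outside [0, 100] (assay noise) and occasionally grossly outside
# (data errors). Mild overshoot is clipped to the physical range; values
# outside the clip window, and non-numeric entries, are rejected.

#' Clip or reject raw percent-inhibition values
#'
#' Values in `[0, 100]` pass through; values between the lower window bound
#' and 0 clip to 0; values between 100 and the upper bound clip to 100;
#' anything outside the window, or non-numeric, is rejected with a reason.
#'
#' @param values Numeric vector of raw measurements (NA = non-numeric).
#' @param clip_window Length-2 numeric `(low_bound, high_bound)`.
#' @return Data frame with columns `value` (clipped, NA when rejected) and
#'   `reason` (`""`, `"out_of_window"` or `"non_numeric"`).
#' @export
clip_or_reject <- function(values, clip_window = c(-10, 110)) {
  stopifnot(length(clip_window) == 2L, clip_window[1] <= 0, clip_window[2] >= 100)
  values <- suppressWarnings(as.numeric(values))
  reason <- ifelse(is.na(values), "non_numeric",
            ifelse(values < clip_window[1] | values > clip_window[2],
                   "out_of_window", ""))
  out <- pmin(pmax(values, 0), 100)
  out[reason != ""] <- NA_real_
  data.frame(value = out, reason = reason, stringsAsFactors = FALSE)
}

#' Piecewise aggregation of replicate percent-inhibition values
#'
#' Replicate labels for one structure are reduced to a single label by the
#' interval rule: if the replicate mean is below `lo` the minimum is taken
#' (suppressing spuriously high singletons in the inactive regime), if the
#' mean exceeds `hi` the maximum is taken (preserving strong-inhibition
#' signal), otherwise the arithmetic mean is used. A mean exactly equal to
#' `lo` or `hi` falls in the mean branch. Singletons pass through with
#' branch `"single"`.
#'
#' @param values Numeric vector of clipped values in `[0, 100]`.
#' @param lo,hi Interval thresholds in percentage points (`lo < hi`).
#' @return List with `label` and `branch` (`"min"`, `"max"`, `"mean"`,
#'   `"single"`).
#' @export
aggregate_group <- function(values, lo = 20, hi = 70) {
  if (!length(values)) abort2("empty replicate group", "cyp3a4hybrid_curate_error")
  stopifnot(lo < hi, all(values >= 0 & values <= 100))
  if (length(values) == 1L) return(list(label = values[[1]], branch = "single"))
  m <- mean(values)
  if (m < lo) list(label = min(values), branch = "min")
  else if (m > hi) list(label = max(values), branch = "max")
  else list(label = m, branch = "mean")
}

#' Flag a replicate group as irreproducible
#'
#' A group whose sample standard deviation exceeds `max_sd` percentage
#' points is flagged (and excluded from curation). Singletons are never
#' flagged.
#'
#' @param values Numeric replicate values.
#' @param max_sd Maximum tolerated sample SD in percentage points.
#' @return Logical flag.
#' @export
flag_outlier_group <- function(values, max_sd = 30) {
  if (!length(values)) abort2("empty replicate group", "cyp3a4hybrid_curate_error")
  if (length(values) == 1L) return(FALSE)
  stats::sd(values) > max_sd
}

#' Curate a raw measurement table end to end
#'
#' Standardizes structures (dropping unparseable ones), clips or rejects
#' labels, groups replicates by canonical SMILES, excludes irreproducible
#' groups (outlier flagging runs before aggregation so extreme replicates
#' cannot hide inside a min/max branch), and aggregates the survivors with
#' the piecewise interval rule.
#'
#' @param raw Data frame with columns `id`, `smiles`, `value`.
#' @param lo,hi Aggregation thresholds (percentage points).
#' @param max_sd Replicate-outlier cutoff (percentage points).
#' @param clip_window Clip/reject window passed to [clip_or_reject()].
#' @return List with `curated` (data frame: `molecule_key`,
#'   `canonical_smiles`, `label`, `n_replicates`, `aggregation_branch`),
#'   `molecules` (named list of `standard_molecule` keyed by canonical
#'   SMILES) and `log` (data frame of exclusions with reasons).
#' @export
curate_records <- function(raw, lo = 20, hi = 70, max_sd = 30,
                           clip_window = c(-10, 110)) {
  stopifnot(is.data.frame(raw), all(c("id", "smiles", "value") %in% names(raw)))
  cl <- clip_or_reject(raw$value, clip_window)
  log <- data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
  drop <- cl$reason != ""
  if (any(drop)) {
    log <- rbind(log, data.frame(id = as.character(raw$id[drop]),
                                 reason = cl$reason[drop]))
  }
  keep <- which(!drop)
  std <- standardize_structures(raw$smiles[keep])
  bad <- std$rejections$index
  if (length(bad)) {
    log <- rbind(log, data.frame(id = as.character(raw$id[keep][bad]),
                                 reason = "unparseable"))
  }
  ok <- setdiff(seq_along(keep), bad)
  keys <- vapply(std$molecules[ok], `[[`, character(1), "canonical")
  vals <- cl$value[keep][ok]
  ids <- as.character(raw$id[keep][ok])

  mol_by_key <- list()
  for (j in seq_along(ok)) {
    k <- keys[[j]]
    if (is.null(mol_by_key[[k]])) mol_by_key[[k]] <- std$molecules[ok][[j]]
  }

  groups <- split(seq_along(keys), keys)
  rows <- vector("list", length(groups))
  gi <- 0L
  for (k in names(groups)) {
    idx <- groups[[k]]
    gvals <- vals[idx]
    if (flag_outlier_group(gvals, max_sd)) {
      log <- rbind(log, data.frame(id = paste(ids[idx], collapse = ";"),
                                   reason = "replicate_outlier"))
      mol_by_key[[k]] <- NULL
      next
    }
    agg <- aggregate_group(gvals, lo, hi)
    gi <- gi + 1L
    rows[[gi]] <- data.frame(molecule_key = k, canonical_smiles = k,
                             label = agg$label, n_replicates = length(gvals),
                             aggregation_branch = agg$branch,
                             stringsAsFactors = FALSE)
  }
  curated <- if (gi) do.call(rbind, rows[seq_len(gi)]) else
    data.frame(molecule_key = character(), canonical_smiles = character(),
               label = numeric(), n_replicates = integer(),
               aggregation_branch = character())
  rownames(curated) <- NULL
  list(curated = curated, molecules = mol_by_key, log = log)
}

#' Threshold sensitivity analysis for the piecewise aggregation rule
#'
#' Re-aggregates every replicate group at each `(lo, hi)` combination of the
#' requested grids and records the retained count and the mean aggregated
#' label, mirroring the robustness check that motivates the default 20/70
#' thresholds.
#'
#' @param groups List of numeric vectors (clipped replicate values, one per
#'   structure).
#' @param lo_grid,hi_grid Numeric grids of candidate thresholds; every
#'   `lo` must be below every `hi`.
#' @param max_sd Replicate-outlier cutoff applied before aggregation.
#' @return Data frame with columns `lo`, `hi`, `n_retained`, `mean_label`.
#' @export
run_sensitivity <- function(groups, lo_grid = seq(10, 30, 5),
                            hi_grid = seq(60, 80, 5), max_sd = 30) {
  stopifnot(max(lo_grid) < min(hi_grid))
  flagged <- vapply(groups, flag_outlier_group, logical(1), max_sd = max_sd)
  surviving <- groups[!flagged]
  grid <- expand.grid(lo = lo_grid, hi = hi_grid)
  grid$n_retained <- NA_integer_
  grid$mean_label <- NA_real_
  for (r in seq_len(nrow(grid))) {
    labels <- vapply(surviving, function(v) {
      aggregate_group(v, grid$lo[[r]], grid$hi[[r]])$label
    }, numeric(1))
    grid$n_retained[[r]] <- length(labels)
    grid$mean_label[[r]] <- mean(labels)
  }
  grid
}

#' Scaffold diversity of a curated set
#'
#' Counts distinct Bemis-Murcko scaffolds; all acyclic molecules share the
#' single empty-scaffold class.
#'
#' @param molecules List of `standard_molecule` objects.
#' @return List with `n_molecules`, `n_unique_scaffolds`, and the scaffold
#'   key vector.
#' @export
scaffold_summary <- function(molecules) {
  if (!length(molecules)) abort2("no molecules", "cyp3a4hybrid_curate_error")
  keys <- vapply(molecules, murcko_scaffold, character(1))
  list(n_molecules = length(molecules),
       n_unique_scaffolds = length(unique(keys)),
       scaffolds = keys)
}
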