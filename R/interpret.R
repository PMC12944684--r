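# Model interpretation: occlusion sensitivity for the graph model and
# substructure SAR statistics (point-biserial correlation, Cohen's d,
# bootstrap mean-difference intervals, Spearman property correlations).

#' Occlusion sensitivity attribution
#'
#' Masks one unit at a time (a single atom, or a ring's atom set), replaces
#' the masked atoms' features with the mask token, re-predicts, and records
#' `delta = base prediction - occluded prediction`. A positive delta means
#' the unit supports higher predicted inhibition. Masking edits features
#' only; the graph topology and ring tensors are untouched, so every
#' occluded input remains a valid graph.
#'
#' @param model A `gnn_model`, or any function mapping a `dual_graph` to a
#'   numeric prediction.
#' @param graph A `dual_graph`.
#' @param unit_kind `"atom"` or `"ring"`.
#' @return An `attribution_map`: `unit_kind` and `deltas` (one per unit).
#' @export
occlude <- function(model, graph, unit_kind = c("atom", "ring")) {
  unit_kind <- match.arg(unit_kind)
  stopifnot(inherits(graph, "dual_graph"))
  predict_one <- if (is.function(model)) model else {
    function(g) predict_gnn(model, g)
  }
  base <- predict_one(graph)
  units <- if (unit_kind == "atom") as.list(seq_len(graph$n_atoms)) else graph$rings
  deltas <- vapply(units, function(atoms) {
    g2 <- graph
    g2$node_features[atoms, ] <- 0
    g2$node_features[atoms, "masked"] <- 1
    base - predict_one(g2)
  }, numeric(1))
  structure(list(unit_kind = unit_kind, deltas = deltas),
            class = "attribution_map")
}

#' Point-biserial correlation between labels and a binary flag
#'
#' `r = (M1 - M0) / s_y * sqrt(p * q)` with the population standard
#' deviation of the labels; the p-value comes from the t transformation
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param labels Numeric values (non-constant).
#' @param presence 0/1 (or logical) group flags; both groups must be
#'   non-empty.
#' @return List with `r` and `p_value`.
#' @export
point_biserial <- function(labels, presence) {
  presence <- as.integer(as.logical(presence))
  n <- length(labels)
  stopifnot(length(presence) == n, n >= 3)
  n1 <- sum(presence); n0 <- n - n1
  if (n1 == 0 || n0 == 0) abort2("both groups must be non-empty", "cyp3a4hybrid_sar_error")
  s_pop <- sqrt(mean((labels - mean(labels))^2))
  if (s_pop == 0) abort2("labels are constant", "cyp3a4hybrid_sar_error")
  m1 <- mean(labels[presence == 1]); m0 <- mean(labels[presence == 0])
  r <- (m1 - m0) / s_pop * sqrt((n1 / n) * (n0 / n))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p_value = p)
}

#' Cohen's d standardized mean difference
#'
#' `(M1 - M0) / s_pooled` with the pooled sample standard deviation; both
#' groups must have at least two members.
#'
#' @inheritParams point_biserial
#' @return The effect size d.
#' @export
cohens_d <- function(labels, presence) {
  presence <- as.integer(as.logical(presence))
  g1 <- labels[presence == 1]; g0 <- labels[presence == 0]
  if (length(g1) < 2 || length(g0) < 2) {
    abort2("both groups need >= 2 members", "cyp3a4hybrid_sar_error")
  }
  sp <- sqrt(((length(g1) - 1) * stats::var(g1) + (length(g0) - 1) * stats::var(g0)) /
               (length(g1) + length(g0) - 2))
  (mean(g1) - mean(g0)) / sp
}

#' Mean inhibition difference with a bootstrap confidence interval
#'
#' Percentile bootstrap (resampling within each group) of
#' `mean(with) - mean(without)`.
#'
#' @inheritParams point_biserial
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `mean_diff`, `ci` (lo, hi), `n_with`, `n_without`.
#' @export
mean_difference_ci <- function(labels, presence, n_boot = 2000L, seed = 1L,
                               conf = 0.95) {
  presence <- as.integer(as.logical(presence))
  g1 <- labels[presence == 1]; g0 <- labels[presence == 0]
  if (!length(g1) || !length(g0)) abort2("both groups must be non-empty", "cyp3a4hybrid_sar_error")
  md <- mean(g1) - mean(g0)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    mean(sample(g1, replace = TRUE)) - mean(sample(g0, replace = TRUE))
  }, numeric(1)))
  a <- (1 - conf) / 2
  list(mean_diff = md,
       ci = unname(stats::quantile(boot, c(a, 1 - a))),
       n_with = length(g1), n_without = length(g0))
}

#' Spearman rank-correlation matrix of labels and descriptors
#'
#' @param data Data frame or matrix whose columns include the label and the
#'   descriptor values (>= 3 rows); ties receive average ranks.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(data) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 3)
  stats::cor(data, method = "spearman")
}

#' Substructure SAR report
#'
#' For every motif in the catalog, tests whether molecules containing the
#' substructure shift the inhibition distribution: point-biserial
#' correlation with its p-value and significance stars, Cohen's d, and the
#' bootstrap mean-difference interval. Motifs present in none (or all)
#' molecules yield `NA` statistics. Multiplicity is reduced to presence
#' (count >= 1) for the two-group statistics.
#'
#' @param labels Percent-inhibition labels.
#' @param molecules List of `standard_molecule` (ignored when
#'   `motif_counts` is given).
#' @param catalog A `motif_catalog`.
#' @param motif_counts Optional precomputed count matrix (columns = motifs).
#' @param n_boot,seed Bootstrap settings for the mean-difference interval.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values in the `p_adjusted` column.
#' @return Data frame with one row per motif.
#' @export
sar_report <- function(labels, molecules = NULL, catalog = motif_catalog(),
                       motif_counts = NULL, n_boot = 2000L, seed = 1L,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  motifs <- setdiff(names(catalog), c("coordinating_heteroatom"))
  if (is.null(motif_counts)) {
    stopifnot(!is.null(molecules), length(molecules) == length(labels))
    motif_counts <- vapply(motifs, function(nm) {
      count_matches(molecules, catalog[[nm]]$smarts)
    }, integer(length(labels)))
  }
  rows <- lapply(seq_along(motifs), function(k) {
    pres <- motif_counts[, k] >= 1
    out <- data.frame(motif = motifs[[k]], n_with = sum(pres),
                      n_without = sum(!pres), r_pb = NA_real_,
                      p_value = NA_real_, stars = "", cohens_d = NA_real_,
                      mean_diff = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      stringsAsFactors = FALSE)
    if (sum(pres) >= 2 && sum(!pres) >= 2) {
      pb <- point_biserial(labels, pres)
      ci <- mean_difference_ci(labels, pres, n_boot = n_boot,
                               seed = derive_seed(seed, k))
      out$r_pb <- pb$r
      out$p_value <- pb$p_value
      out$stars <- if (pb$p_value < 0.001) "***" else if (pb$p_value < 0.01) "**"
        else if (pb$p_value < 0.05) "*" else ""
      out$cohens_d <- cohens_d(labels, pres)
      out$mean_diff <- ci$mean_diff
      out$ci_lo <- ci$ci[1]; out$ci_hi <- ci$ci[2]
    }
    out
  })
  res <- do.call(rbind, rows)
  if (adjust == "BH") res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  res
}
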