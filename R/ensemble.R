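# SMILES test-time augmentation pooling and the final graph/tabular hybrid.

#' Test-time augmentation configuration
#' @param n_variants Number of randomized SMILES per molecule (>= 0).
#' @param seed Seed for variant enumeration.
#' @return A `tta_config` list.
#' @export
tta_config <- function(n_variants = 8L, seed = 1L) {
  stopifnot(n_variants >= 0)
  structure(list(n_variants = as.integer(n_variants), seed = as.integer(seed)),
            class = "tta_config")
}

#' Test-time augmentation over SMILES serializations
#'
#' Evaluates a structure-to-value predictor on the canonical plus
#' `n_variants` randomized serializations of one molecule and mean-pools
#' the results. For serialization-invariant predictors (anything that
#' re-canonicalizes its input, such as the graph model) the pooled value
#' equals the single-call prediction; pooling matters for predictors that
#' consume the raw string.
#'
#' @param predictor Function taking a SMILES string and returning a numeric
#'   prediction.
#' @param mol A `standard_molecule`.
#' @param config A [tta_config()].
#' @return A `prediction_bundle` list: `molecule_key`, `per_variant` (data
#'   frame of smiles/prediction), `tta_mean`.
#' @export
tta_predict <- function(predictor, mol, config = tta_config()) {
  stopifnot(is.function(predictor), inherits(mol, "standard_molecule"))
  variants <- enumerate_random_smiles(mol, config$n_variants, config$seed)
  preds <- vapply(variants, predictor, numeric(1))
  structure(list(molecule_key = mol$canonical,
                 per_variant = data.frame(smiles = variants,
                                          prediction = unname(preds),
                                          stringsAsFactors = FALSE),
                 tta_mean = mean(preds)),
            class = "prediction_bundle")
}

#' Combine named component predictions with simplex weights
#'
#' @param component_values Named numeric vector of per-component
#'   predictions for one molecule.
#' @param weights Named weights on the probability simplex; names must
#'   match `component_values`.
#' @return The weighted final prediction.
#' @export
hybrid_predict <- function(component_values, weights) {
  if (is.null(names(component_values)) || is.null(names(weights)) ||
      !setequal(names(component_values), names(weights))) {
    abort2("component value and weight names must match", "cyp3a4hybrid_ensemble_error")
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    abort2("weights must lie on the probability simplex", "cyp3a4hybrid_ensemble_error")
  }
  sum(as.numeric(weights[names(component_values)]) * as.numeric(component_values))
}

#' Train and evaluate the full hybrid pipeline
#'
#' Splits the curated data into train/validation/test, fits the tabular
#' block (components plus intra-block simplex weights on validation
#' predictions) and the graph block, fits the inter-block hybrid weights on
#' the validation set, applies optional SMILES test-time augmentation at
#' inference, and reports test-set metrics. Test labels are never touched
#' before the final evaluation.
#'
#' @param curated Curated data frame (`molecule_key`, `label`).
#' @param molecules Named list of `standard_molecule` keyed by
#'   `molecule_key`.
#' @param split Length-3 proportions (train, validation, test).
#' @param components Character vector of tabular component kinds.
#' @param encoder,mixup,contrast Graph-model configurations (see
#'   [train_gnn()]).
#' @param gnn_folds,gnn_epochs Cross-validation folds and epochs for the
#'   graph block.
#' @param tta_n Randomized SMILES variants at inference (0 disables TTA;
#'   the graph model is serialization-invariant, so TTA is a no-op for it
#'   by construction).
#' @param catalog Motif catalog for engineered features.
#' @param seed Global seed.
#' @return A `pipeline_result`: `report` (an `eval_report`), `predictions`
#'   (test-set data frame with per-component and final values),
#'   `ml_weights`, `hybrid_weights`, `val_rmse` (per block and hybrid on
#'   the weight-fitting set), and the fitted models.
#' @export
evaluate_pipeline <- function(curated, molecules,
                              split = c(0.7, 0.15, 0.15),
                              components = c("gbdt_a", "gbdt_b", "mlp"),
                              encoder = encoder_config(),
                              mixup = mixup_config(),
                              contrast = contrast_config(),
                              gnn_folds = 3L, gnn_epochs = 10L,
                              tta_n = 0L, catalog = motif_catalog(),
                              seed = 1L) {
  stopifnot(nrow(curated) >= 30, abs(sum(split) - 1) < 1e-9)
  keys <- curated$molecule_key
  mols <- molecules[keys]
  y <- curated$label

  n <- length(keys)
  idx <- with_seed(derive_seed(seed, 100L), sample.int(n))
  n_tr <- floor(split[1] * n); n_va <- floor(split[2] * n)
  tr <- idx[seq_len(n_tr)]
  va <- idx[n_tr + seq_len(n_va)]
  te <- idx[(n_tr + n_va + 1L):n]

  X <- feature_matrix(mols, catalog)
  graphs <- lapply(mols, build_dual_graph)

  # tabular block
  ml_models <- lapply(components, function(kind) {
    fit_component(X[tr, , drop = FALSE], y[tr],
                  tabular_spec(kind, seed = derive_seed(seed, 200L)))
  })
  P_va <- vapply(ml_models, predict_component, numeric(length(va)),
                 features = X[va, , drop = FALSE])
  colnames(P_va) <- components
  ml_weights <- fit_simplex_weights(P_va, y[va])
  ml_val <- as.vector(P_va %*% as.numeric(ml_weights))

  # graph block
  gnn <- train_gnn(graphs[tr], y[tr], n_folds = gnn_folds,
                   epochs = gnn_epochs, encoder = encoder, mixup = mixup,
                   contrast = contrast, seed = derive_seed(seed, 300L))
  gnn_val <- predict_gnn(gnn, graphs[va])

  # inter-block weights on the validation set
  H_va <- cbind(ml = ml_val, gnn = gnn_val)
  hybrid_weights <- fit_simplex_weights(H_va, y[va])
  hyb_val <- as.vector(H_va %*% as.numeric(hybrid_weights))
  val_rmse <- c(ml = rmse(y[va], ml_val), gnn = rmse(y[va], gnn_val),
                hybrid = rmse(y[va], hyb_val))

  # inference on the held-out test set (optionally TTA-pooled)
  predict_block <- function(test_keys) {
    if (tta_n > 0L) {
      ml_p <- numeric(length(test_keys)); gnn_p <- numeric(length(test_keys))
      for (i in seq_along(test_keys)) {
        mol <- mols[[test_keys[i]]]
        variants <- enumerate_random_smiles(mol, tta_n,
                                            seed = derive_seed(seed, 400L + i))
        vm <- lapply(variants, standardize_structure)
        Xv <- feature_matrix(vm, catalog)
        Pv <- vapply(ml_models, predict_component, numeric(length(variants)),
                     features = Xv)
        ml_p[i] <- mean(matrix(Pv, nrow = length(variants)) %*% as.numeric(ml_weights))
        gv <- lapply(vm, build_dual_graph)
        gnn_p[i] <- mean(predict_gnn(gnn, gv))
      }
      list(ml = ml_p, gnn = gnn_p)
    } else {
      pos <- match(test_keys, keys)
      Pt <- vapply(ml_models, predict_component, numeric(length(pos)),
                   features = X[pos, , drop = FALSE])
      list(ml = as.vector(matrix(Pt, nrow = length(pos)) %*% as.numeric(ml_weights)),
           gnn = predict_gnn(gnn, graphs[pos]))
    }
  }
  blocks <- predict_block(keys[te])
  final <- hybrid_weights[["ml"]] * blocks$ml + hybrid_weights[["gnn"]] * blocks$gnn
  final_clipped <- pmin(pmax(final, 0), 100)

  predictions <- data.frame(molecule_key = keys[te], label = y[te],
                            ml = blocks$ml, gnn = blocks$gnn,
                            final = final_clipped, tta_n = tta_n,
                            stringsAsFactors = FALSE)
  structure(list(report = eval_report(y[te], final_clipped),
                 predictions = predictions, ml_weights = ml_weights,
                 hybrid_weights = hybrid_weights, val_rmse = val_rmse,
                 ml_models = ml_models, gnn = gnn,
                 split_idx = list(train = tr, validation = va, test = te),
                 seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  hybrid weights:",
      paste(sprintf("%s=%.3f", names(x$hybrid_weights), x$hybrid_weights),
            collapse = " "), "\n")
  cat("  validation RMSE:",
      paste(sprintf("%s=%.3f", names(x$val_rmse), x$val_rmse), collapse = " "),
      "\n  test set:\n")
  print(x$report)
  invisible(x)
}
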