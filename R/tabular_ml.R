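# Vector-based regression block: two differently-configured gradient-boosted
# tree components and a two-hidden-layer perceptron with early stopping,
# combined by simplex-constrained least-squares ensemble weights.

#' Tabular component specification
#'
#' `gbdt_a` and `gbdt_b` are gradient-boosted tree regressors with distinct
#' depth/shrinkage profiles (a deeper fast-shrinkage booster and a shallower
#' slow-shrinkage one); `mlp` is a two-hidden-layer perceptron trained with
#' Adam and early stopping on a held-out fraction.
#'
#' @param kind One of `"gbdt_a"`, `"gbdt_b"`, `"mlp"`.
#' @param hyperparameters Named list overriding the kind's defaults.
#' @param seed Integer seed.
#' @return A `tabular_spec` list.
#' @export
tabular_spec <- function(kind = c("gbdt_a", "gbdt_b", "mlp"),
                         hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    gbdt_a = list(nrounds = 300L, max_depth = 6L, eta = 0.1,
                  subsample = 0.8, colsample_bytree = 0.8,
                  min_child_weight = 5),
    gbdt_b = list(nrounds = 500L, max_depth = 3L, eta = 0.05,
                  subsample = 0.9, colsample_bytree = 0.5,
                  min_child_weight = 1),
    mlp = list(hidden = c(64L, 32L), epochs = 800L, lr = 0.01,
               patience = 100L, val_frac = 0.1, weight_decay = 1e-3)
  )
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(kind = kind, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "tabular_spec")
}

# ---- two-hidden-layer perceptron -----------------------------------------

mlp_fit <- function(X, y, hidden, epochs, lr, patience, val_frac, seed,
                    weight_decay = 1e-3) {
  n <- nrow(X)
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  ys <- y / 100
  with_seed(seed, {
    val <- sample.int(n, max(1L, floor(val_frac * n)))
    tr <- setdiff(seq_len(n), val)
    d <- ncol(X)
    rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / a)), a, b)
    p <- list(W1 = rmat(d, hidden[1]), b1 = rep(0, hidden[1]),
              W2 = rmat(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
              W3 = matrix(stats::rnorm(hidden[2], sd = 1 / sqrt(hidden[2]))),
              b3 = 0)
    fwd <- function(p, X) {
      Z1 <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
      Z2 <- tanh(sweep(Z1 %*% p$W2, 2, p$b2, `+`))
      list(Z1 = Z1, Z2 = Z2, yhat = as.vector(Z2 %*% p$W3) + p$b3)
    }
    state <- list(m = list(), v = list())
    best <- list(p = p, val = Inf, since = 0L)
    Xtr <- Xs[tr, , drop = FALSE]; ytr <- ys[tr]
    Xva <- Xs[val, , drop = FALSE]; yva <- ys[val]
    for (ep in seq_len(epochs)) {
      f <- fwd(p, Xtr)
      res <- f$yhat - ytr
      dy <- 2 * res / length(ytr)
      dZ2 <- (dy %*% t(p$W3)) * (1 - f$Z2^2)
      dZ1 <- (dZ2 %*% t(p$W2)) * (1 - f$Z1^2)
      grads <- list(W1 = t(Xtr) %*% dZ1 + weight_decay * p$W1,
                    b1 = colSums(dZ1),
                    W2 = t(f$Z1) %*% dZ2 + weight_decay * p$W2,
                    b2 = colSums(dZ2),
                    W3 = t(f$Z2) %*% cbind(dy) + weight_decay * p$W3,
                    b3 = sum(dy))
      upd <- adam_step(p, grads, state, lr, ep)
      p <- upd$params; state <- upd$state
      vmse <- mean((fwd(p, Xva)$yhat - yva)^2)
      if (vmse < best$val - 1e-7) {
        best <- list(p = p, val = vmse, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
    list(params = best$p, mu = mu, sg = sg)
  })
}

mlp_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sg, `/`)
  p <- fit$params
  Z1 <- tanh(sweep(Xs %*% p$W1, 2, p$b1, `+`))
  Z2 <- tanh(sweep(Z1 %*% p$W2, 2, p$b2, `+`))
  (as.vector(Z2 %*% p$W3) + p$b3) * 100
}

# ---- components -----------------------------------------------------------

#' Fit one tabular regression component
#'
#' @param features Numeric feature matrix (rows = molecules).
#' @param labels Percent-inhibition labels.
#' @param spec A [tabular_spec()].
#' @return A `tabular_model`.
#' @export
fit_component <- function(features, labels, spec = tabular_spec("gbdt_a")) {
  stopifnot(nrow(features) == length(labels))
  if (nrow(features) < 10L) abort2("need at least 10 samples", "cyp3a4hybrid_ml_error")
  if (stats::sd(labels) == 0) {
    return(structure(list(kind = "constant", fit = labels[[1]], spec = spec),
                     class = "tabular_model"))
  }
  hp <- spec$hyperparameters
  fit <- if (spec$kind == "mlp") {
    mlp_fit(features, labels, hp$hidden, hp$epochs, hp$lr, hp$patience,
            hp$val_frac, spec$seed, hp$weight_decay)
  } else {
    with_seed(spec$seed,
              xgboost::xgboost(features, labels,
                               objective = "reg:squarederror",
                               nrounds = hp$nrounds, max_depth = hp$max_depth,
                               learning_rate = hp$eta, subsample = hp$subsample,
                               colsample_bytree = hp$colsample_bytree,
                               min_child_weight = hp$min_child_weight,
                               nthreads = 1L, seed = spec$seed,
                               verbosity = 0))
  }
  structure(list(kind = spec$kind, fit = fit, spec = spec),
            class = "tabular_model")
}

#' Predict with a tabular component
#' @param model A `tabular_model`.
#' @param features Feature matrix with the training columns.
#' @return Numeric predictions (percentage points, unclipped).
#' @export
predict_component <- function(model, features) {
  if (model$kind == "constant") rep(model$fit, nrow(features))
  else if (model$kind == "mlp") mlp_predict(model$fit, features)
  else stats::predict(model$fit, features)
}

# ---- simplex weights ------------------------------------------------------

# Euclidean projection onto the probability simplex (sorting algorithm)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Fit ensemble weights on the probability simplex
#'
#' Minimizes the RMSE of the weighted combination of component predictions
#' subject to nonnegative weights summing to one (projected gradient descent
#' from the uniform start, which also serves as the tie-break: exactly
#' interchangeable components keep equal weights). Since every unit vector
#' is feasible, the fitted combination is never worse on the fitting set
#' than the best single component.
#'
#' @param component_predictions `n x k` matrix, one column per component.
#' @param labels Length-`n` observed values.
#' @return A `simplex_weights` numeric vector (named after columns).
#' @export
fit_simplex_weights <- function(component_predictions, labels) {
  P <- as.matrix(component_predictions)
  n <- nrow(P); k <- ncol(P)
  if (n < 1L || length(labels) != n) {
    abort2("need component predictions and matching labels", "cyp3a4hybrid_ml_error")
  }
  w <- rep(1 / k, k)
  G <- crossprod(P) / n          # (1/n) P'P
  b <- crossprod(P, labels) / n  # (1/n) P'y
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  step <- 1 / (2 * L)
  for (it in seq_len(5000L)) {
    grad <- 2 * (G %*% w - b)
    w_new <- project_simplex(as.vector(w - step * grad))
    if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  names(w) <- colnames(P)
  structure(w, class = "simplex_weights")
}

#' Predict with a set of components and simplex weights
#' @param models List of `tabular_model`, in weight order.
#' @param weights A `simplex_weights` vector.
#' @param features Feature matrix.
#' @return Weighted predictions.
#' @export
predict_weighted <- function(models, weights, features) {
  stopifnot(length(models) == length(weights))
  P <- vapply(models, predict_component, numeric(nrow(features)),
              features = features)
  as.vector(matrix(P, nrow = nrow(features)) %*% as.numeric(weights))
}
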