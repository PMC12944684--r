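# Ring-aware graph regressor.
#
# The encoder treats rings as a third structural unit next to atoms and
# bonds. Each layer updates, in order, bond states (from endpoint atoms),
# atom states (from neighbor atoms, incident bond states, and the average
# state of the rings containing the atom), then ring states (from member
# atoms). Mean readout over atom states gives the graph embedding; a small
# nonlinear head maps it to percent inhibition. Training supports InfoNCE
# contrastive pretraining on augmented graph views and similarity-weighted
# manifold mixup of graph embeddings during supervised fine-tuning.
#
# All tensor work is batched over molecules as one block-diagonal sparse
# graph (Matrix package); gradients are computed by hand-written
# reverse-mode passes over the fixed architecture.

GM_ELEMENTS <- c(6, 7, 8, 16, 9, 17, 35)  # C N O S F Cl Br; else "other"

#' Encoder configuration
#' @param n_layers Number of bond/atom/ring update layers (>= 0).
#' @param hidden_dim State width.
#' @param readout `"mean"` or `"sum"` pooling of atom states.
#' @param seed Seed for parameter initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 2L, hidden_dim = 32L,
                           readout = c("mean", "sum"), seed = 1L) {
  readout <- match.arg(readout)
  stopifnot(n_layers >= 0, hidden_dim >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 readout = readout, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Contrastive pretraining configuration
#' @param temperature Softmax temperature (> 0).
#' @param atom_mask_rate,bond_drop_rate,subgraph_drop_rate Augmentation
#'   probabilities in `[0, 1]`.
#' @param epochs Pretraining epochs.
#' @param seed Seed for view generation and optimization.
#' @return A `contrast_config` list.
#' @export
contrast_config <- function(temperature = 0.1, atom_mask_rate = 0.15,
                            bond_drop_rate = 0.10, subgraph_drop_rate = 0.20,
                            epochs = 3L, seed = 1L) {
  stopifnot(temperature > 0,
            all(c(atom_mask_rate, bond_drop_rate, subgraph_drop_rate) >= 0),
            all(c(atom_mask_rate, bond_drop_rate, subgraph_drop_rate) <= 1))
  structure(list(temperature = temperature, atom_mask_rate = atom_mask_rate,
                 bond_drop_rate = bond_drop_rate,
                 subgraph_drop_rate = subgraph_drop_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "contrast_config")
}

#' Similarity-weighted manifold mixup configuration
#' @param alpha Beta(alpha, alpha) shape for the mixing ratio (> 0).
#' @param w_g,w_y Weights of graph-embedding and label similarity in the
#'   pair score; must sum to 1.
#' @param top_k Candidate pool size per anchor.
#' @param n_mix_per_batch Mixed samples per batch (`NULL` = batch size).
#' @param label_range Normalization constant R for label similarity
#'   (percentage points).
#' @param seed Seed for pair selection and lambda draws.
#' @return A `mixup_config` list.
#' @export
mixup_config <- function(alpha = 0.5, w_g = 0.5, w_y = 0.5, top_k = 8L,
                         n_mix_per_batch = NULL, label_range = 100,
                         seed = 1L) {
  stopifnot(alpha > 0, w_g >= 0, w_y >= 0, abs(w_g + w_y - 1) < 1e-9,
            top_k >= 1, label_range > 0)
  structure(list(alpha = alpha, w_g = w_g, w_y = w_y,
                 top_k = as.integer(top_k),
                 n_mix_per_batch = n_mix_per_batch,
                 label_range = label_range, seed = as.integer(seed)),
            class = "mixup_config")
}

# ---- graph batching -------------------------------------------------------

# encode raw dual-graph node/edge features into model input columns
gm_node_input <- function(nf) {
  n <- nrow(nf)
  zoh <- matrix(0, n, length(GM_ELEMENTS) + 1L)
  zi <- match(nf[, "z"], GM_ELEMENTS, nomatch = length(GM_ELEMENTS) + 1L)
  zoh[cbind(seq_len(n), zi)] <- 1
  hoh <- matrix(0, n, 5L)
  hoh[cbind(seq_len(n), nf[, "hybrid"] + 1L)] <- 1
  X <- cbind(zoh, hoh, nf[, "charge"], nf[, "aromatic"], nf[, "in_ring"],
             nf[, "n_h"], nf[, "masked"])
  masked <- nf[, "masked"] > 0
  if (any(masked)) {
    X[masked, ] <- 0
    X[masked, ncol(X)] <- 1
  }
  X
}

gm_edge_input <- function(ef) {
  m <- nrow(ef)
  ooh <- matrix(0, max(m, 0), 3L)
  if (m) ooh[cbind(seq_len(m), pmin(ef[, "order"], 3L))] <- 1
  cbind(ooh, ef[, "aromatic"], ef[, "conjugated"], ef[, "in_ring"])
}

GM_D_IN <- length(GM_ELEMENTS) + 1L + 5L + 5L  # 18 node input columns
GM_D_EDGE <- 6L

# assemble a block-diagonal batch over a list of dual graphs
gm_batch <- function(graphs, readout = "mean") {
  B <- length(graphs)
  n_i <- vapply(graphs, `[[`, numeric(1), "n_atoms")
  off <- cumsum(c(0, n_i[-B]))
  n <- sum(n_i)
  X <- do.call(rbind, lapply(graphs, function(g) gm_node_input(g$node_features)))
  ed <- do.call(rbind, lapply(seq_len(B), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e)) e + off[i] else e
  }))
  Xe <- do.call(rbind, lapply(graphs, function(g) gm_edge_input(g$edge_features)))
  m <- if (is.null(ed)) 0L else nrow(ed)
  S <- Matrix::sparseMatrix(i = rep(seq_len(m), 2),
                            j = as.vector(ed),
                            x = 1, dims = c(m, n))
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(n, n))
  ring_rows <- list(); r_tot <- 0L
  for (i in seq_len(B)) {
    for (r in graphs[[i]]$rings) {
      r_tot <- r_tot + 1L
      ring_rows[[r_tot]] <- cbind(atom = r + off[i], ring = r_tot)
    }
  }
  if (r_tot) {
    inc <- do.call(rbind, ring_rows)
    atom_ring_count <- tabulate(inc[, 1], nbins = n)
    Pn <- Matrix::sparseMatrix(i = inc[, 1], j = inc[, 2],
                               x = 1 / atom_ring_count[inc[, 1]],
                               dims = c(n, r_tot))
    ring_size <- tabulate(inc[, 2], nbins = r_tot)
    Qn <- Matrix::sparseMatrix(i = inc[, 2], j = inc[, 1],
                               x = 1 / ring_size[inc[, 2]],
                               dims = c(r_tot, n))
  } else {
    Pn <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(n, 0))
    Qn <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(0, n))
  }
  w <- if (readout == "mean") rep(1 / n_i, n_i) else rep(1, n)
  M <- Matrix::sparseMatrix(i = rep(seq_len(B), n_i), j = seq_len(n), x = w,
                            dims = c(B, n))
  list(B = B, n = n, m = m, r = r_tot, X = X, Xe = Xe, S = S, A = A,
       Pn = Pn, Qn = Qn, M = M)
}

# ---- parameters -----------------------------------------------------------

#' Initialize encoder and head parameters
#'
#' Seeded Gaussian initialization (fan-in scaled) of all layer weights for
#' a given [encoder_config()]; pass the result to [encode_graphs()] or use
#' [train_gnn()], which initializes per fold internally.
#'
#' @param config An `encoder_config`.
#' @param seed Integer seed (defaults to the config's).
#' @return Named list of parameter matrices.
#' @export
gm_init_params <- function(config, seed = config$seed) {
  d <- config$hidden_dim
  L <- config$n_layers
  rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = 1 / sqrt(a)), a, b)
  with_seed(seed, {
    p <- list(Win = rmat(GM_D_IN, d), bin = rep(0, d), Wein = rmat(GM_D_EDGE, d))
    for (l in seq_len(L)) {
      p[[paste0("Ew1_", l)]] <- rmat(d, d)
      p[[paste0("Ew2_", l)]] <- rmat(d, d)
      p[[paste0("Aw1_", l)]] <- rmat(d, d)
      p[[paste0("Aw2_", l)]] <- rmat(d, d)
      p[[paste0("Aw3_", l)]] <- rmat(d, d)
      p[[paste0("Aw4_", l)]] <- rmat(d, d)
      p[[paste0("Rw1_", l)]] <- rmat(d, d)
      p[[paste0("Rw2_", l)]] <- rmat(d, d)
    }
    p$Wh1 <- rmat(d, d); p$bh1 <- rep(0, d)
    p$wh2 <- matrix(stats::rnorm(d, sd = 1 / sqrt(d)), d, 1); p$bh2 <- 0
    p
  })
}

# ---- forward / backward ---------------------------------------------------

dn <- function(x) as.matrix(x)  # densify sparse products

gm_forward <- function(batch, params, config) {
  L <- config$n_layers
  cache <- list()
  H <- tanh(sweep(batch$X %*% params$Win, 2, params$bin, `+`))
  E <- tanh(batch$Xe %*% params$Wein)
  R <- dn(batch$Qn %*% H)
  cache$H0 <- H; cache$E0 <- E; cache$R0 <- R
  for (l in seq_len(L)) {
    SH <- dn(batch$S %*% H)
    Enew <- tanh(E %*% params[[paste0("Ew1_", l)]] + SH %*% params[[paste0("Ew2_", l)]])
    AH <- dn(batch$A %*% H)
    StE <- dn(Matrix::t(batch$S) %*% Enew)
    PR <- dn(batch$Pn %*% R)
    Hnew <- tanh(H %*% params[[paste0("Aw1_", l)]] + AH %*% params[[paste0("Aw2_", l)]] +
                   StE %*% params[[paste0("Aw3_", l)]] + PR %*% params[[paste0("Aw4_", l)]])
    QH <- dn(batch$Qn %*% Hnew)
    Rnew <- tanh(R %*% params[[paste0("Rw1_", l)]] + QH %*% params[[paste0("Rw2_", l)]])
    cache[[paste0("SH_", l)]] <- SH; cache[[paste0("AH_", l)]] <- AH
    cache[[paste0("StE_", l)]] <- StE; cache[[paste0("PR_", l)]] <- PR
    cache[[paste0("QH_", l)]] <- QH
    cache[[paste0("Hprev_", l)]] <- H; cache[[paste0("Eprev_", l)]] <- E
    cache[[paste0("Rprev_", l)]] <- R
    H <- Hnew; E <- Enew; R <- Rnew
    cache[[paste0("H_", l)]] <- H; cache[[paste0("E_", l)]] <- E
    cache[[paste0("R_", l)]] <- R
  }
  G <- dn(batch$M %*% H)
  list(G = G, H = H, cache = cache)
}

gm_head_forward <- function(G, params) {
  Z1 <- tanh(sweep(G %*% params$Wh1, 2, params$bh1, `+`))
  yhat <- as.vector(Z1 %*% params$wh2) + params$bh2
  list(Z1 = Z1, yhat = yhat)
}

# gradients of the head for given d(yhat); returns grads and dG
gm_head_backward <- function(G, hf, params, dyhat) {
  dZ1 <- (dyhat %*% t(params$wh2)) * (1 - hf$Z1^2)
  list(grads = list(Wh1 = t(G) %*% dZ1, bh1 = colSums(dZ1),
                    wh2 = t(hf$Z1) %*% cbind(dyhat), bh2 = sum(dyhat)),
       dG = dZ1 %*% t(params$Wh1))
}

# encoder gradients for a given dG; accumulates into a fresh grad list
gm_encoder_backward <- function(batch, params, fw, config, dG) {
  L <- config$n_layers
  ca <- fw$cache
  g <- list()
  addg <- function(nm, v) {
    g[[nm]] <<- if (is.null(g[[nm]])) v else g[[nm]] + v
  }
  HL <- if (L > 0) ca[[paste0("H_", L)]] else ca$H0
  dH <- dn(Matrix::t(batch$M) %*% dG)
  dR <- matrix(0, batch$r, ncol(dH))
  dE <- matrix(0, batch$m, ncol(dH))
  for (l in rev(seq_len(L))) {
    Rl <- ca[[paste0("R_", l)]]; Hl <- ca[[paste0("H_", l)]]
    El <- ca[[paste0("E_", l)]]
    Rprev <- ca[[paste0("Rprev_", l)]]; Hprev <- ca[[paste0("Hprev_", l)]]
    Eprev <- ca[[paste0("Eprev_", l)]]
    # ring update
    dpreR <- dR * (1 - Rl^2)
    addg(paste0("Rw1_", l), t(Rprev) %*% dpreR)
    addg(paste0("Rw2_", l), t(ca[[paste0("QH_", l)]]) %*% dpreR)
    dRprev <- dpreR %*% t(params[[paste0("Rw1_", l)]])
    dH <- dH + dn(Matrix::t(batch$Qn) %*% (dpreR %*% t(params[[paste0("Rw2_", l)]])))
    # atom update
    dpreH <- dH * (1 - Hl^2)
    addg(paste0("Aw1_", l), t(Hprev) %*% dpreH)
    addg(paste0("Aw2_", l), t(ca[[paste0("AH_", l)]]) %*% dpreH)
    addg(paste0("Aw3_", l), t(ca[[paste0("StE_", l)]]) %*% dpreH)
    addg(paste0("Aw4_", l), t(ca[[paste0("PR_", l)]]) %*% dpreH)
    dHprev <- dpreH %*% t(params[[paste0("Aw1_", l)]]) +
      dn(batch$A %*% (dpreH %*% t(params[[paste0("Aw2_", l)]])))
    dEl <- dE + dn(batch$S %*% (dpreH %*% t(params[[paste0("Aw3_", l)]])))
    dRprev <- dRprev + dn(Matrix::t(batch$Pn) %*% (dpreH %*% t(params[[paste0("Aw4_", l)]])))
    # bond update
    dpreE <- dEl * (1 - El^2)
    addg(paste0("Ew1_", l), t(Eprev) %*% dpreE)
    addg(paste0("Ew2_", l), t(ca[[paste0("SH_", l)]]) %*% dpreE)
    dEprev <- dpreE %*% t(params[[paste0("Ew1_", l)]])
    dHprev <- dHprev + dn(Matrix::t(batch$S) %*% (dpreE %*% t(params[[paste0("Ew2_", l)]])))
    dH <- dHprev; dR <- dRprev; dE <- dEprev
    # bond-init gradient flows only from the first layer's dEprev
    if (l == 1L) {
      dpreE0 <- dE * (1 - ca$E0^2)
      addg("Wein", t(batch$Xe) %*% dpreE0)
    }
  }
  if (L == 0L) dR <- dR  # no-op; ring init grads handled below
  dH <- dH + dn(Matrix::t(batch$Qn) %*% dR)  # R0 = Qn H0
  dpreH0 <- dH * (1 - ca$H0^2)
  addg("Win", t(batch$X) %*% dpreH0)
  addg("bin", colSums(dpreH0))
  if (L == 0L) addg("Wein", matrix(0, GM_D_EDGE, ncol(dH)))
  g
}

# ---- mixup primitives -----------------------------------------------------

#' Composite pair similarity score
#'
#' `S = w_g * cosine(h_i, h_j) + w_y * (1 - |y_i - y_j| / R)`, combining
#' structural similarity of graph embeddings with label proximity.
#'
#' @param h_i,h_j Embedding vectors (nonzero).
#' @param y_i,y_j Labels in percentage points with `|y_i - y_j| <= R`.
#' @param R Label range normalization constant.
#' @param w_g,w_y Similarity weights (sum to 1).
#' @return Score in `[-1, 1]`.
#' @export
pair_score <- function(h_i, h_j, y_i, y_j, R = 100, w_g = 0.5, w_y = 0.5) {
  ni <- sqrt(sum(h_i^2)); nj <- sqrt(sum(h_j^2))
  if (ni == 0 || nj == 0) abort2("zero-norm embedding", "cyp3a4hybrid_gnn_error")
  stopifnot(abs(y_i - y_j) <= R, abs(w_g + w_y - 1) < 1e-9)
  s_g <- sum(h_i * h_j) / (ni * nj)
  s_y <- 1 - abs(y_i - y_j) / R
  w_g * s_g + w_y * s_y
}

#' Draw manifold-mixup interpolation ratios
#' @param alpha Beta(alpha, alpha) shape (> 0).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of ratios strictly inside (0, 1).
#' @export
sample_mix_lambda <- function(alpha, n = 1L, seed = 1L) {
  stopifnot(alpha > 0)
  lam <- with_seed(seed, stats::rbeta(n, alpha, alpha))
  pmin(pmax(lam, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Interpolate a pair of hidden representations and labels
#' @param h_i,h_j Embedding vectors.
#' @param y_i,y_j Labels.
#' @param lambda Mixing ratio in `[0, 1]`.
#' @return A `mixed_sample` list: `h_tilde`, `y_tilde`, `lambda`.
#' @export
mix_pair <- function(h_i, h_j, y_i, y_j, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  structure(list(h_tilde = lambda * h_i + (1 - lambda) * h_j,
                 y_tilde = lambda * y_i + (1 - lambda) * y_j,
                 lambda = lambda),
            class = "mixed_sample")
}

#' Select mixup partners within a batch
#'
#' For each anchor, the `top_k` candidates by composite pair score (self
#' excluded) are considered and one partner is sampled with probability
#' proportional to `max(S, 0)`, falling back to uniform when no candidate
#' scores positive.
#'
#' @param H Batch embedding matrix (rows = samples).
#' @param y Batch labels.
#' @param config A `mixup_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return Data frame with columns `i`, `j`, `score`.
#' @export
select_mix_pairs <- function(H, y, config = mixup_config(), seed = config$seed) {
  B <- nrow(H)
  stopifnot(B >= 2)
  n_mix <- if (is.null(config$n_mix_per_batch)) B else config$n_mix_per_batch
  norms <- sqrt(rowSums(H^2))
  if (any(norms == 0)) abort2("zero-norm embedding in batch", "cyp3a4hybrid_gnn_error")
  U <- H / norms
  Sg <- U %*% t(U)
  Sy <- 1 - abs(outer(y, y, `-`)) / config$label_range
  S <- config$w_g * Sg + config$w_y * Sy
  diag(S) <- -Inf
  anchors <- rep(seq_len(B), length.out = n_mix)
  with_seed(seed, {
    out <- lapply(anchors, function(i) {
      cand <- order(S[i, ], decreasing = TRUE)[seq_len(min(config$top_k, B - 1L))]
      w <- pmax(S[i, cand], 0)
      if (sum(w) <= 0) w <- rep(1, length(cand))
      j <- cand[sample.int(length(cand), 1L, prob = w)]
      data.frame(i = i, j = j, score = S[i, j])
    })
    do.call(rbind, out)
  })
}

# ---- contrastive primitives ----------------------------------------------

#' Graph view augmentation for contrastive learning
#'
#' Applies atom masking (features replaced by the mask token), bond
#' deletion, and removal of one random connected subgraph of at most
#' `subgraph_drop_rate * n_atoms` atoms. Ring tensors are recomputed for
#' the modified topology; with all rates zero the input graph is returned
#' unchanged.
#'
#' @param graph A `dual_graph`.
#' @param config A `contrast_config`.
#' @param seed Integer seed; identical seeds give identical views.
#' @return A valid `dual_graph`.
#' @export
augment_view <- function(graph, config = contrast_config(), seed = 1L) {
  stopifnot(inherits(graph, "dual_graph"))
  if (config$atom_mask_rate == 0 && config$bond_drop_rate == 0 &&
      config$subgraph_drop_rate == 0) {
    return(graph)
  }
  with_seed(seed, {
    nf <- graph$node_features
    n <- graph$n_atoms
    edges <- graph$edges
    ef <- graph$edge_features
    # atom masking
    mask <- stats::runif(n) < config$atom_mask_rate
    if (any(mask)) {
      nf[mask, ] <- 0
      nf[mask, "masked"] <- 1
    }
    # bond deletion
    if (nrow(edges) && config$bond_drop_rate > 0) {
      keep <- stats::runif(nrow(edges)) >= config$bond_drop_rate
      edges <- edges[keep, , drop = FALSE]
      ef <- ef[keep, , drop = FALSE]
    }
    # connected-subgraph removal
    drop_n <- floor(config$subgraph_drop_rate * n)
    if (drop_n >= 1 && drop_n < n) {
      adj <- vector("list", n)
      for (k in seq_len(nrow(edges))) {
        adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
        adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
      }
      start <- sample.int(n, 1L)
      sel <- start; frontier <- start
      while (length(sel) < drop_n && length(frontier)) {
        nbrs <- setdiff(unique(unlist(adj[frontier])), sel)
        if (!length(nbrs)) break
        take <- utils::head(nbrs, drop_n - length(sel))
        sel <- c(sel, take); frontier <- take
      }
      keep_atoms <- setdiff(seq_len(n), sel)
      remap <- integer(n); remap[keep_atoms] <- seq_along(keep_atoms)
      nf <- nf[keep_atoms, , drop = FALSE]
      ekeep <- edges[, 1] %in% keep_atoms & edges[, 2] %in% keep_atoms
      edges <- matrix(remap[edges[ekeep, , drop = FALSE]], ncol = 2)
      ef <- ef[ekeep, , drop = FALSE]
      n <- length(keep_atoms)
    }
    rings <- perceive_rings(edges, n)
    nf[, "in_ring"] <- 0
    for (r in rings) nf[r, "in_ring"] <- 1
    nf[nf[, "masked"] > 0, "in_ring"] <- 0
    dual_graph(n, nf, edges, ef, rings)
  })
}

# InfoNCE loss (and gradient) over paired views: rows (1,2), (3,4), ... are
# positives; candidates for each anchor are all other rows.
info_nce_core <- function(Z, temperature, grad = FALSE) {
  n <- nrow(Z)
  stopifnot(n >= 4L, n %% 2L == 0L)
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0)) abort2("zero-norm embedding", "cyp3a4hybrid_gnn_error")
  U <- Z / norms
  sim <- U %*% t(U)
  pos <- ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)
  logits <- sim / temperature
  diag(logits) <- -Inf
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  loss <- mean(lse - logits[cbind(seq_len(n), pos)])
  if (!grad) return(list(loss = loss))
  P <- exp(logits - lse)          # row-softmax over candidates
  dS <- P / temperature
  dS[cbind(seq_len(n), pos)] <- dS[cbind(seq_len(n), pos)] - 1 / temperature
  diag(dS) <- 0
  dS <- dS / n
  dU <- (dS + t(dS)) %*% U
  # through row normalization: dz = (dU - (dU . u) u) / ||z||
  proj <- rowSums(dU * U)
  dZ <- (dU - U * proj) / norms
  list(loss = loss, dZ = dZ)
}

#' InfoNCE contrastive loss over paired embeddings
#'
#' Rows `(1,2), (3,4), ...` are positive pairs (two augmented views of the
#' same molecule). For each anchor the loss is the cross-entropy of picking
#' its positive among all other `2B - 1` views under temperature-scaled
#' cosine similarities.
#'
#' @param Z Numeric matrix of `2B` embeddings (`B >= 2`), positives paired
#'   by adjacency.
#' @param temperature Softmax temperature (> 0).
#' @return Nonnegative scalar loss.
#' @export
info_nce_loss <- function(Z, temperature = 0.1) {
  info_nce_core(Z, temperature)$loss
}

# ---- training -------------------------------------------------------------

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gmat * 0
      state$v[[nm]] <- gmat * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Encode dual graphs into graph-level embeddings
#'
#' Runs the ring-aware encoder forward pass. Output is invariant to atom
#' index permutation of isomorphic graphs (all aggregations are symmetric
#' and the readout pools atom states).
#'
#' @param graphs List of `dual_graph` (or a single one).
#' @param params Encoder parameters from `gm_init_params` or a trained
#'   model's fold parameters.
#' @param config The `encoder_config` used with `params`.
#' @return Matrix of embeddings, one row per graph.
#' @export
encode_graphs <- function(graphs, params, config) {
  if (inherits(graphs, "dual_graph")) graphs <- list(graphs)
  batch <- gm_batch(graphs, config$readout)
  gm_forward(batch, params, config)$G
}

Y_SCALE <- 100  # labels are trained on the unit scale internally

#' Train the ring-aware graph regressor with cross-validation
#'
#' Optional InfoNCE contrastive pretraining of the encoder on augmented
#' graph views is followed by supervised fine-tuning with squared-error
#' loss over real samples plus similarity-weighted manifold-mixup samples.
#' Mixed embeddings are built only from training-fold members and forwarded
#' only through the prediction head. Every sample receives exactly one
#' out-of-fold prediction.
#'
#' @param graphs List of `dual_graph`.
#' @param labels Percent-inhibition labels in `[0, 100]`.
#' @param n_folds Cross-validation folds (>= 2; must not exceed sample
#'   count).
#' @param epochs Supervised epochs per fold.
#' @param encoder An `encoder_config`.
#' @param mixup A `mixup_config`, or `NULL` to disable mixup (plain
#'   supervised training).
#' @param contrast A `contrast_config`, or `NULL` to skip pretraining.
#' @param batch_size Molecules per minibatch.
#' @param lr Adam learning rate.
#' @param seed Global seed; all fold splits, initializations, view and
#'   mixup draws derive from it.
#' @return A `gnn_model` with per-fold parameters, fold assignment,
#'   out-of-fold predictions (`oof`), and per-fold training-loss history.
#' @export
train_gnn <- function(graphs, labels, n_folds = 5L, epochs = 30L,
                      encoder = encoder_config(), mixup = mixup_config(),
                      contrast = contrast_config(), batch_size = 64L,
                      lr = 0.01, seed = 1L) {
  n <- length(graphs)
  stopifnot(length(labels) == n)
  if (n < n_folds) abort2("fewer samples than folds", "cyp3a4hybrid_gnn_error")
  folds <- with_seed(derive_seed(seed, 1L),
                     sample(rep_len(seq_len(n_folds), n)))
  oof <- rep(NA_real_, n)
  fold_params <- vector("list", n_folds)
  loss_history <- vector("list", n_folds)
  y <- labels / Y_SCALE

  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    params <- gm_init_params(encoder, seed = derive_seed(seed, 10L + f))
    # fixed batch partition for this fold
    part <- with_seed(derive_seed(seed, 20L + f), sample(tr))
    batches_idx <- split(part, ceiling(seq_along(part) / batch_size))

    # contrastive pretraining on augmented views
    if (!is.null(contrast) && contrast$epochs > 0) {
      state <- list(m = list(), v = list()); t_ad <- 0L
      for (ep in seq_len(contrast$epochs)) {
        for (bi in seq_along(batches_idx)) {
          idx <- batches_idx[[bi]]
          if (length(idx) < 2L) next
          vseed <- derive_seed(seed, 1000L * f + 100L * ep + bi)
          views <- vector("list", 2L * length(idx))
          for (k in seq_along(idx)) {
            views[[2L * k - 1L]] <- augment_view(graphs[[idx[k]]], contrast,
                                                 seed = derive_seed(vseed, 2L * k))
            views[[2L * k]] <- augment_view(graphs[[idx[k]]], contrast,
                                            seed = derive_seed(vseed, 2L * k + 1L))
          }
          vb <- gm_batch(views, encoder$readout)
          fw <- gm_forward(vb, params, encoder)
          nce <- info_nce_core(fw$G, contrast$temperature, grad = TRUE)
          grads <- gm_encoder_backward(vb, params, fw, encoder, nce$dZ)
          t_ad <- t_ad + 1L
          upd <- adam_step(params, grads, state, lr, t_ad)
          params <- upd$params; state <- upd$state
        }
      }
    }

    # supervised fine-tuning
    pre <- lapply(batches_idx, function(idx) gm_batch(graphs[idx], encoder$readout))
    state <- list(m = list(), v = list()); t_ad <- 0L
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- with_seed(derive_seed(seed, 30000L + 100L * f + ep),
                       sample(seq_along(pre)))
      ep_loss <- 0; ep_n <- 0
      for (bi in ord) {
        idx <- batches_idx[[bi]]
        yb <- y[idx]
        fw <- gm_forward(pre[[bi]], params, encoder)
        hf <- gm_head_forward(fw$G, params)
        res <- hf$yhat - yb
        n_real <- length(idx)
        use_mix <- !is.null(mixup) && n_real >= 2L &&
          (is.null(mixup$n_mix_per_batch) || mixup$n_mix_per_batch > 0)
        if (use_mix) {
          mseed <- derive_seed(seed, 50000L + 100L * f + 10L * ep + bi)
          pairs <- select_mix_pairs(fw$G, yb * Y_SCALE, mixup, seed = mseed)
          lam <- sample_mix_lambda(mixup$alpha, nrow(pairs),
                                   seed = derive_seed(mseed, 7L))
          Gmix <- lam * fw$G[pairs$i, , drop = FALSE] +
            (1 - lam) * fw$G[pairs$j, , drop = FALSE]
          ymix <- lam * yb[pairs$i] + (1 - lam) * yb[pairs$j]
          hm <- gm_head_forward(Gmix, params)
          res_m <- hm$yhat - ymix
          n_tot <- n_real + length(res_m)
          loss <- (sum(res^2) + sum(res_m^2)) / n_tot
          hb <- gm_head_backward(fw$G, hf, params, 2 * res / n_tot)
          hbm <- gm_head_backward(Gmix, hm, params, 2 * res_m / n_tot)
          grads <- mapply(`+`, hb$grads, hbm$grads, SIMPLIFY = FALSE)
          dG <- hb$dG  # mixed samples feed the head only (embeddings detached)
        } else {
          loss <- mean(res^2)
          hb <- gm_head_backward(fw$G, hf, params, 2 * res / n_real)
          grads <- hb$grads
          dG <- hb$dG
        }
        enc_grads <- gm_encoder_backward(pre[[bi]], params, fw, encoder, dG)
        grads <- c(grads, enc_grads)
        t_ad <- t_ad + 1L
        upd <- adam_step(params, grads, state, lr, t_ad)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss * n_real; ep_n <- ep_n + n_real
      }
      losses[ep] <- ep_loss / ep_n
    }
    fold_params[[f]] <- params
    loss_history[[f]] <- losses
    # out-of-fold predictions
    if (length(te)) {
      tb <- gm_batch(graphs[te], encoder$readout)
      tfw <- gm_forward(tb, params, encoder)
      oof[te] <- gm_head_forward(tfw$G, params)$yhat * Y_SCALE
    }
  }
  structure(list(fold_params = fold_params, folds = folds, oof = oof,
                 encoder = encoder, mixup = mixup, contrast = contrast,
                 loss_history = loss_history, seed = seed),
            class = "gnn_model")
}

#' Predict percent inhibition with a trained graph model
#'
#' Averages the predictions of the per-fold parameter sets.
#'
#' @param model A `gnn_model`.
#' @param graphs List of `dual_graph` (or a single one).
#' @return Numeric predictions in percentage points (unclipped).
#' @export
predict_gnn <- function(model, graphs) {
  if (inherits(graphs, "dual_graph")) graphs <- list(graphs)
  batch <- gm_batch(graphs, model$encoder$readout)
  preds <- vapply(model$fold_params, function(p) {
    fw <- gm_forward(batch, p, model$encoder)
    gm_head_forward(fw$G, p)$yhat * Y_SCALE
  }, numeric(length(graphs)))
  if (length(graphs) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = length(graphs)))
}

#' @export
print.gnn_model <- function(x, ...) {
  cat(sprintf("<gnn_model> %d folds, %d layers, hidden dim %d\n",
              length(x$fold_params), x$encoder$n_layers, x$encoder$hidden_dim))
  invisible(x)
}
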