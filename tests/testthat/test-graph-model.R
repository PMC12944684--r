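test_that("encoder output is invariant under graph isomorphism", {
  cfg <- encoder_config(n_layers = 2, hidden_dim = 12, seed = 3)
  params <- cyp3a4hybrid:::gm_init_params(cfg)
  g <- fx_graphs()$acetanilide
  base <- encode_graphs(g, params, cfg)
  set.seed(99)
  for (i in seq_len(20)) {
    g2 <- permute_graph(g, sample(g$n_atoms))
    expect_lt(max(abs(encode_graphs(g2, params, cfg) - base)), 1e-6)
  }
})

test_that("zero-depth encoding equals the readout of projected node features", {
  cfg <- encoder_config(n_layers = 0, hidden_dim = 8, seed = 5)
  params <- cyp3a4hybrid:::gm_init_params(cfg)
  g <- fx_graphs()$piperidine
  got <- encode_graphs(g, params, cfg)
  X <- cyp3a4hybrid:::gm_node_input(g$node_features)
  hand <- colMeans(tanh(sweep(X %*% params$Win, 2, params$bin, `+`)))
  expect_equal(as.vector(got), unname(hand), tolerance = 1e-12)
})

test_that("ring-free molecules encode without a ring stage", {
  cfg <- encoder_config(n_layers = 2, hidden_dim = 8, seed = 2)
  params <- cyp3a4hybrid:::gm_init_params(cfg)
  emb <- encode_graphs(fx_graphs()$butane, params, cfg)
  expect_true(all(is.finite(emb)))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- encoder_config(n_layers = 2, hidden_dim = 6, seed = 3)
  params <- cyp3a4hybrid:::gm_init_params(cfg)
  graphs <- fx_graphs()[c("benzodioxole", "pyridine_ether", "butane")]
  batch <- cyp3a4hybrid:::gm_batch(graphs, "mean")
  y <- c(0.3, 0.6, 0.2)
  loss_fn <- function(p) {
    fw <- cyp3a4hybrid:::gm_forward(batch, p, cfg)
    mean((cyp3a4hybrid:::gm_head_forward(fw$G, p)$yhat - y)^2)
  }
  fw <- cyp3a4hybrid:::gm_forward(batch, params, cfg)
  hf <- cyp3a4hybrid:::gm_head_forward(fw$G, params)
  hb <- cyp3a4hybrid:::gm_head_backward(fw$G, hf, params, 2 * (hf$yhat - y) / 3)
  grads <- c(hb$grads, cyp3a4hybrid:::gm_encoder_backward(batch, params, fw, cfg, hb$dG))
  set.seed(11)
  for (nm in c("Win", "Wein", "Ew2_1", "Aw4_2", "Rw1_1", "Wh1", "bin")) {
    i <- sample(length(params[[nm]]), 1)
    eps <- 1e-6
    p <- params
    p[[nm]][i] <- params[[nm]][i] + eps; up <- loss_fn(p)
    p[[nm]][i] <- params[[nm]][i] - eps; dn_ <- loss_fn(p)
    num <- (up - dn_) / (2 * eps)
    expect_equal(as.matrix(grads[[nm]])[i], num, tolerance = 1e-4)
  }
})

test_that("graph augmentation yields valid seeded views", {
  g <- fx_graphs()$acetanilide
  cfg0 <- contrast_config(atom_mask_rate = 0, bond_drop_rate = 0,
                          subgraph_drop_rate = 0)
  expect_identical(augment_view(g, cfg0, seed = 1), g)

  cfg1 <- contrast_config(atom_mask_rate = 1, bond_drop_rate = 0,
                          subgraph_drop_rate = 0)
  a1 <- augment_view(g, cfg1, seed = 1)
  expect_true(all(a1$node_features[, "masked"] == 1))
  expect_identical(a1$edges, g$edges)

  cfg2 <- contrast_config(atom_mask_rate = 0.3, bond_drop_rate = 0.3,
                          subgraph_drop_rate = 0.3)
  v1 <- augment_view(g, cfg2, seed = 7)
  expect_identical(v1, augment_view(g, cfg2, seed = 7))
  # ring tensors recomputed for the surviving topology
  expect_true(all(unlist(v1$rings) <= v1$n_atoms))
  expect_true(all(v1$edges <= v1$n_atoms))
})

test_that("InfoNCE attains its degenerate closed form and symmetries", {
  for (B in c(2, 8, 32)) {
    Z <- matrix(rep(rnorm(5), each = 2 * B), 2 * B, 5)
    expect_equal(info_nce_loss(Z, 0.1), log(2 * B - 1), tolerance = 1e-6)
  }
  # loss is invariant to reordering the (paired) views
  set.seed(4)
  Z <- matrix(rnorm(12 * 6), 12, 6)
  perm_pairs <- sample(6)
  idx <- as.vector(rbind(2 * perm_pairs - 1, 2 * perm_pairs))
  expect_equal(info_nce_loss(Z, 0.2), info_nce_loss(Z[idx, ], 0.2),
               tolerance = 1e-12)
  # near-perfect alignment with orthogonal negatives at small tau -> ~0
  Zo <- diag(6)[rep(1:3, each = 2), ]
  expect_lt(info_nce_loss(Zo, 0.01), 1e-6)
})

test_that("pair score combines cosine and label similarity", {
  h <- c(1, 2, 3)
  expect_equal(pair_score(h, h, 40, 40), 1)
  expect_equal(pair_score(h, c(3, 2, 1), 10, 90, R = 100, w_g = 1, w_y = 0),
               sum(h * c(3, 2, 1)) / sum(h^2))
  # w 0.5/0.5 with s_g = 0.8, s_y = 0.6
  a <- c(1, 0); b <- c(0.8, 0.6)
  expect_equal(pair_score(a, b, 0, 40, R = 100), 0.5 * 0.8 + 0.5 * 0.6)
  expect_equal(pair_score(a, b, 10, 70, R = 100),
               pair_score(b, a, 70, 10, R = 100))  # symmetry
  expect_error(pair_score(c(0, 0), h, 1, 2), class = "cyp3a4hybrid_gnn_error")
})

test_that("mixup draws are Beta-symmetric and interpolation is convex", {
  lam <- sample_mix_lambda(0.5, n = 1e5, seed = 9)
  expect_true(all(lam > 0 & lam < 1))
  expect_equal(mean(lam), 0.5, tolerance = 0.01)
  lam2 <- sample_mix_lambda(0.5, n = 1e4, seed = 10)
  ks <- suppressWarnings(stats::ks.test(lam2, 1 - sample_mix_lambda(0.5, 1e4, 11)))
  expect_gt(ks$p.value, 0.01)
  expect_identical(lam, sample_mix_lambda(0.5, n = 1e5, seed = 9))

  h_i <- c(1, 5, -2); h_j <- c(0, 3, 4)
  m1 <- mix_pair(h_i, h_j, 20, 60, 1)
  expect_equal(m1$h_tilde, h_i); expect_equal(m1$y_tilde, 20)
  expect_equal(mix_pair(h_i, h_j, 20, 60, 0.5)$y_tilde, 40)
  for (l in sample_mix_lambda(0.3, 50, seed = 2)) {
    m <- mix_pair(h_i, h_j, 20, 60, l)
    expect_true(all(m$h_tilde >= pmin(h_i, h_j) - 1e-12 &
                      m$h_tilde <= pmax(h_i, h_j) + 1e-12))
    expect_true(m$y_tilde >= 20 && m$y_tilde <= 60)
  }
})

test_that("mix partner selection follows the positive-score weights", {
  H2 <- rbind(c(1, 0), c(0, 1))
  p2 <- select_mix_pairs(H2, c(10, 20), mixup_config(), seed = 1)
  expect_identical(p2$j, c(2L, 1L))

  # one dominant candidate wins with probability 1
  H <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  y <- c(50, 50, 50, 50)
  cfgm <- mixup_config(w_g = 1, w_y = 0, top_k = 3)
  for (s in 1:20) {
    p <- select_mix_pairs(H, y, cfgm, seed = s)
    expect_identical(p$j[p$i == 1], 2L)
  }
})

test_that("training decreases loss, covers out-of-fold, and is seeded", {
  graphs <- fx_graphs()
  gs <- rep(unname(graphs), length.out = 24)
  y <- vapply(gs, function(g) 3 * g$n_atoms + 2 * length(g$rings), numeric(1))
  m1 <- train_gnn(gs, y, n_folds = 3, epochs = 15, batch_size = 8,
                  encoder = encoder_config(1, 8, seed = 1),
                  mixup = NULL, contrast = NULL, seed = 5)
  expect_true(all(is.finite(m1$oof)))
  expect_length(m1$oof, 24)
  for (h in m1$loss_history) expect_lt(h[length(h)], h[1])
  m2 <- train_gnn(gs, y, n_folds = 3, epochs = 15, batch_size = 8,
                  encoder = encoder_config(1, 8, seed = 1),
                  mixup = NULL, contrast = NULL, seed = 5)
  expect_identical(m1$oof, m2$oof)
  expect_error(train_gnn(gs[1:2], y[1:2], n_folds = 3),
               class = "cyp3a4hybrid_gnn_error")
})

test_that("disabling mixup reduces to plain supervised training", {
  gs <- rep(unname(fx_graphs()), length.out = 15)
  y <- runif(15, 0, 100)
  base <- train_gnn(gs, y, n_folds = 3, epochs = 5, batch_size = 8,
                    mixup = NULL, contrast = NULL,
                    encoder = encoder_config(1, 8, seed = 2), seed = 9)
  zero <- train_gnn(gs, y, n_folds = 3, epochs = 5, batch_size = 8,
                    mixup = mixup_config(n_mix_per_batch = 0),
                    contrast = NULL,
                    encoder = encoder_config(1, 8, seed = 2), seed = 9)
  expect_identical(base$oof, zero$oof)
})

test_that("the full training path with pretraining and mixup runs seeded", {
  gs <- rep(unname(fx_graphs()), length.out = 20)
  y <- runif(20, 0, 100)
  m <- train_gnn(gs, y, n_folds = 2, epochs = 4, batch_size = 10,
                 encoder = encoder_config(1, 8, seed = 2),
                 mixup = mixup_config(), contrast = contrast_config(epochs = 1),
                 seed = 4)
  expect_true(all(is.finite(m$oof)))
  p <- predict_gnn(m, fx_graphs()$benzene)
  expect_length(p, 1)
  expect_identical(p, predict_gnn(m, fx_graphs()$benzene))
})
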