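test_that("occlusion deltas match closed forms on stub models", {
  g <- fx_graphs()$benzodioxole
  # constant model: no unit matters
  const <- occlude(function(gr) 7.5, g, unit_kind = "atom")
  expect_equal(const$deltas, rep(0, g$n_atoms))
  expect_length(const$deltas, g$n_atoms)

  # additive stub: prediction = sum of the n_h channel; occluding atom i
  # removes exactly its contribution
  additive <- function(gr) sum(gr$node_features[, "n_h"])
  att <- occlude(additive, g, unit_kind = "atom")
  expect_equal(att$deltas, unname(g$node_features[, "n_h"]))

  # ring units: one delta per ring, equal to the ring's summed contribution
  attr_ring <- occlude(additive, g, unit_kind = "ring")
  expect_length(attr_ring$deltas, length(g$rings))
  expect_equal(attr_ring$deltas,
               vapply(g$rings, function(r) sum(g$node_features[r, "n_h"]),
                      numeric(1)))
})

test_that("occlusion on a trained graph model returns finite per-atom deltas", {
  gs <- rep(unname(fx_graphs()), length.out = 15)
  y <- runif(15, 0, 100)
  m <- train_gnn(gs, y, n_folds = 2, epochs = 2, mixup = NULL,
                 contrast = NULL, encoder = encoder_config(1, 8, seed = 1),
                 seed = 2)
  att <- occlude(m, fx_graphs()$imidazole, "atom")
  expect_length(att$deltas, 5L)
  expect_true(all(is.finite(att$deltas)))
})

test_that("point-biserial matches the hand formula and Pearson cross-check", {
  pb <- point_biserial(c(10, 20, 80, 90), c(0, 0, 1, 1))
  expect_equal(pb$r, 0.9899, tolerance = 1e-4)
  expect_error(point_biserial(c(10, 20, 30), c(1, 1, 1)),
               class = "cyp3a4hybrid_sar_error")
  # exact balance of symmetric labels across groups gives r = 0
  expect_equal(point_biserial(c(10, 90, 10, 90), c(0, 0, 1, 1))$r, 0)

  set.seed(14)
  for (i in seq_len(100)) {
    n <- sample(10:60, 1)
    labels <- runif(n, 0, 100)
    pres <- rbinom(n, 1, 0.4)
    if (length(unique(pres)) < 2) next
    got <- point_biserial(labels, pres)
    expect_equal(got$r, cor(labels, pres), tolerance = 1e-12)
    expect_equal(got$p_value, cor.test(labels, pres)$p.value, tolerance = 1e-9)
  }
})

test_that("Cohen's d uses the pooled sample SD", {
  expect_equal(cohens_d(c(80, 90, 10, 20), c(1, 1, 0, 0)), 9.899,
               tolerance = 1e-3)
  expect_equal(cohens_d(c(30, 50, 20, 60), c(1, 1, 0, 0)), 0)
  expect_error(cohens_d(c(10, 20, 30), c(1, 0, 0)),
               class = "cyp3a4hybrid_sar_error")
})

test_that("bootstrap mean-difference CI brackets the estimate, seeded", {
  labels <- c(80, 90, 10, 20); pres <- c(1, 1, 0, 0)
  ci <- mean_difference_ci(labels, pres, n_boot = 500, seed = 5)
  expect_equal(ci$mean_diff, 70)
  expect_true(ci$ci[1] <= 70 && ci$ci[2] >= 70)
  ci2 <- mean_difference_ci(labels, pres, n_boot = 500, seed = 5)
  expect_identical(ci$ci, ci2$ci)
  set.seed(3)
  for (i in 1:10) {
    lb <- runif(20, 0, 100); pr <- rbinom(20, 1, 0.5)
    if (length(unique(pr)) < 2) next
    c3 <- mean_difference_ci(lb, pr, n_boot = 300, seed = i)
    expect_true(c3$ci[1] <= c3$mean_diff && c3$ci[2] >= c3$mean_diff)
  }
})

test_that("spearman matrix is rank-based with unit diagonal", {
  x <- c(1, 2, 3, 5, 8)
  m <- spearman_matrix(cbind(a = x, b = x^3, c = rev(x)))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)   # monotone transform preserves ranks
  expect_equal(m["a", "c"], -1)  # reversed ranks
  expect_equal(m, t(m))
})

test_that("SAR report recovers planted effect signs with covered CIs", {
  bench <- fx_bench()
  cfg0 <- generator_config(n_molecules = 150, seed = 11)
  mols <- bench$molecules
  betas <- cfg0$beta

  # two-group stats agree in sign for every motif, across label redraws
  n_cover <- 0L; n_rep <- 10L
  for (rep_i in seq_len(n_rep)) {
    cfg <- generator_config(n_molecules = 150, seed = 100 + rep_i)
    truth <- plant_labels(mols, cfg)
    sar <- sar_report(truth$label, mols, n_boot = 400, seed = rep_i)
    rows <- sar[match(names(betas), sar$motif), ]
    # sign consistency across the three statistics
    ok <- is.finite(rows$r_pb)
    expect_true(all(sign(rows$r_pb[ok]) == sign(rows$mean_diff[ok])))
    expect_true(all(sign(rows$cohens_d[ok]) == sign(rows$mean_diff[ok])))
    bd <- rows[rows$motif == "benzodioxole", ]
    if (bd$ci_lo <= betas[["benzodioxole"]] &&
        bd$ci_hi >= betas[["benzodioxole"]]) {
      n_cover <- n_cover + 1L
    }
  }
  expect_gte(n_cover, ceiling(0.9 * n_rep))
})
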