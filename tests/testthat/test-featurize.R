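test_that("fingerprints are deterministic fixed-length bit vectors", {
  mols <- fx_mols()
  fp <- ecfp_fingerprint(mols[c("benzene", "ethanol")])
  expect_identical(dim(fp), c(2L, 2048L))
  expect_true(all(fp %in% c(0, 1)))
  expect_true(all(rowSums(fp) >= 1))
  expect_identical(fp, ecfp_fingerprint(mols[c("benzene", "ethanol")]))
  expect_equal(tanimoto(fp[1, ], fp[1, ]), 1)
  # serialization invariance: the kekulized form maps to the same bits
  fp2 <- ecfp_fingerprint(standardize_structure("C1=CC=CC=C1"))
  expect_identical(unname(fp[1, ]), unname(fp2[1, ]))
})

test_that("mean similarity averages pairwise Tanimoto coefficients", {
  mols <- fx_mols()
  fp <- ecfp_fingerprint(mols[c("benzene", "toluene", "ethanol")])
  expect_equal(mean_similarity(fp[1, ], fp[1, , drop = FALSE]), 1)
  hand <- mean(c(tanimoto(fp[1, ], fp[1, ]), tanimoto(fp[1, ], fp[2, ]),
                 tanimoto(fp[1, ], fp[3, ])))
  expect_equal(mean_similarity(fp[1, ], fp), hand)
  disjoint <- rep(0, 2048); disjoint[which(fp[1, ] == 0)[1]] <- 1
  expect_equal(mean_similarity(fp[1, ], rbind(disjoint)), 0)
  expect_error(mean_similarity(fp[1, ], matrix(0, 0, 2048)),
               class = "cyp3a4hybrid_feature_error")
})

test_that("descriptor block carries the expected chemistry", {
  mols <- fx_mols()
  d <- compute_descriptors(mols[c("benzene", "butane", "ethanol")])
  expect_equal(unname(d[1, "desc_aromatic_rings"]), 1)
  expect_equal(unname(d[2, "desc_rotatable_bonds"]), 1)
  expect_equal(unname(d[3, "desc_hbd"]), 1)
  expect_equal(unname(d[, "desc_heavy_atoms"]), c(6, 4, 3))
  expect_gt(d[1, "desc_mw"], 77); expect_lt(d[1, "desc_mw"], 79)
})

test_that("motif catalog patterns parse and match their exemplars", {
  cat <- fx_catalog()
  for (nm in names(cat)) {
    ex <- standardize_structure(cat[[nm]]$exemplar)
    expect_gte(count_matches(list(ex), cat[[nm]]$smarts), 1)
  }
  # specificity: benzodioxole pattern does not match plain benzene
  expect_identical(count_matches(fx_mols()["benzene"],
                                 cat$benzodioxole$smarts), 0L)
})

test_that("engineered features cover the four axes", {
  mols <- fx_mols()
  e <- engineered_features(mols[c("ethanol", "imidazole", "benzene")],
                           fx_catalog())
  expect_equal(unname(e[1, "eng_lipinski_violations"]), 0)
  expect_equal(unname(e[2, "eng_imidazole"]), 1)
  expect_equal(unname(e[3, "eng_aromatic_carbon_ratio"]), 1)
  expect_equal(unname(e[1, "eng_aromatic_carbon_ratio"]), 0)
  # solubility proxy decreases with lipophilicity (monotone plausibility)
  chain <- lapply(c("CCO", "CCCCCCCCCC"), standardize_structure)
  e2 <- engineered_features(chain, fx_catalog())
  expect_gt(e2[1, "eng_log_solubility"], e2[2, "eng_log_solubility"])
  expect_true(all(is.finite(e)))
})

test_that("dual graphs expose consistent ring tensors", {
  g <- fx_graphs()$benzene
  expect_equal(g$n_atoms, 6)
  expect_equal(nrow(g$edges), 6)
  expect_length(g$rings, 1)
  expect_equal(nrow(g$node_ring_incidence), 6)
  expect_equal(nrow(g$ring_ring_adjacency), 0)

  gn <- fx_graphs()$naphthalene
  expect_equal(gn$n_atoms, 10)
  expect_equal(nrow(gn$edges), 11)
  expect_length(gn$rings, 2)
  expect_equal(nrow(gn$ring_ring_adjacency), 1)
  # incidence covers exactly the ring atoms
  for (i in seq_along(gn$rings)) {
    inc_atoms <- gn$node_ring_incidence[gn$node_ring_incidence[, "ring"] == i, "atom"]
    expect_setequal(inc_atoms, gn$rings[[i]])
  }

  ge <- build_dual_graph(standardize_structure("CC"))
  expect_length(ge$rings, 0)
  expect_equal(nrow(ge$node_ring_incidence), 0)
  expect_length(ge$ring_mask, 0)

  # index validation
  expect_error(dual_graph(2, matrix(0, 2, 7,
                                    dimnames = list(NULL, colnames(g$node_features))),
                          rbind(c(1, 3)), matrix(0, 1, 4), list()))
})

test_that("feature matrix has stable names and no undefined values", {
  mols <- fx_mols()[c("benzene", "ethanol", "imidazole")]
  X <- feature_matrix(mols, fx_catalog())
  expect_true(all(is.finite(X)))
  expect_identical(colnames(X)[1], "FP_1")
  expect_true(all(c("desc_mw", "desc_slogp", "eng_druglikeness",
                    "miss_desc_mw") %in% colnames(X)))
  X2 <- feature_matrix(mols, fx_catalog())
  expect_identical(colnames(X), colnames(X2))
  expect_identical(X, X2)
})
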