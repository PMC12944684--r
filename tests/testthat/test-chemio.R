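test_that("canonicalization is a function of the molecular graph", {
  a <- standardize_structure("C1=CC=CC=C1")
  b <- standardize_structure("c1ccccc1")
  expect_identical(a$canonical, b$canonical)

  # idempotence on arbitrary valid inputs
  for (smi in c("CCO.Cl", "OCC", "c1ccc2OCOc2c1CCN", "CC(=O)[O-].[Na+]")) {
    m <- standardize_structure(smi)
    expect_identical(standardize_structure(m$canonical)$canonical, m$canonical)
  }
})

test_that("salt and solvent fragments are stripped to the parent", {
  m <- standardize_structure("CCO.Cl")
  expect_identical(m$canonical, standardize_structure("CCO")$canonical)
  expect_true(m$parent_only)
  # the organic fragment wins even when the inorganic one is larger
  m2 <- standardize_structure("CCO.[Na+].[Cl-]")
  expect_identical(m2$canonical, "CCO")
})

test_that("unparseable structures are rejected with a reason", {
  expect_error(standardize_structure("C1CC"), class = "cyp3a4hybrid_parse_error")
  expect_error(standardize_structure(""), class = "cyp3a4hybrid_parse_error")
  out <- standardize_structures(c("CCO", "xxx", "CCN"))
  expect_identical(out$rejections$index, 2L)
  expect_identical(out$rejections$reason, "unparseable")
  expect_null(out$molecules[[2]])
  expect_s3_class(out$molecules[[1]], "standard_molecule")
})

test_that("random SMILES enumeration honors its contract", {
  m <- fx_mols()$pyridine_ether
  expect_identical(enumerate_random_smiles(m, 0), m$canonical)
  out <- enumerate_random_smiles(m, 5, seed = 42)
  expect_length(out, 6L)
  expect_identical(out[[1]], m$canonical)
  for (s in out) {
    expect_identical(standardize_structure(s)$canonical, m$canonical)
  }
  expect_identical(out, enumerate_random_smiles(m, 5, seed = 42))
  expect_false(identical(out, enumerate_random_smiles(m, 5, seed = 43)))
})

test_that("Murcko scaffolds keep rings and linkers, drop side chains", {
  mols <- fx_mols()
  benzene_key <- mols$benzene$canonical
  expect_identical(murcko_scaffold(mols$ethylbenzene), benzene_key)
  expect_identical(murcko_scaffold(mols$toluene), benzene_key)
  expect_identical(murcko_scaffold(mols$benzene), benzene_key)  # fixed point
  expect_identical(murcko_scaffold(mols$butane), "")

  # idempotence on the scaffold itself
  sc <- murcko_scaffold(mols$acetanilide)
  expect_identical(murcko_scaffold(standardize_structure(sc)), sc)

  # biphenyl-type linker retained
  bip <- standardize_structure("CCc1ccccc1c1ccccc1CC")
  expect_identical(murcko_scaffold(bip),
                   standardize_structure("c1ccccc1c1ccccc1")$canonical)
})

test_that("ring perception finds the smallest set of smallest rings", {
  g_benzene <- fx_mols()$benzene
  expect_length(g_benzene$rings, 1L)
  expect_length(g_benzene$rings[[1]], 6L)

  naph <- fx_mols()$naphthalene
  expect_length(naph$rings, 2L)
  expect_true(all(lengths(naph$rings) == 6L))

  expect_length(standardize_structure("CC")$rings, 0L)

  # pure-graph path: two fused triangles sharing an edge
  edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(2, 4), c(4, 3))
  rings <- perceive_rings(edges, 4)
  expect_length(rings, 2L)
  expect_true(all(lengths(rings) == 3L))
})

test_that("atom tables carry chemically correct features", {
  imid <- fx_mols()$imidazole
  expect_identical(sum(imid$atoms$element == "N"), 2L)
  # exactly one ring NH; the pyridine-type N carries no hydrogen
  expect_identical(sort(imid$atoms$n_h[imid$atoms$element == "N"]), c(0L, 1L))
  expect_true(all(imid$atoms$aromatic))

  eth <- fx_mols()$ethanol
  expect_false(any(eth$atoms$aromatic))
  expect_identical(eth$atoms$n_h[eth$atoms$element == "O"], 1L)
})

test_that("raw CSV round-trips through read/write helpers", {
  raw <- data.frame(id = c("a", "b"), smiles = c("CCO", "CCN"),
                    value = c(10, 20))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(raw, p, row.names = FALSE)
  back <- read_raw_records(p)
  expect_identical(back$smiles, raw$smiles)
  expect_error(read_raw_records(tempfile()), class = "cyp3a4hybrid_io_error")
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(raw[, c("id", "value")], p2, row.names = FALSE)
  expect_error(read_raw_records(p2), class = "cyp3a4hybrid_io_error")
})
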