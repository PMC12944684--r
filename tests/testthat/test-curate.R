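test_that("clip window separates mild overshoot from gross errors", {
  out <- clip_or_reject(c(103.5, -2, 250, 50, NA), clip_window = c(-10, 110))
  expect_equal(out$value, c(100, 0, NA, 50, NA))
  expect_identical(out$reason, c("", "", "out_of_window", "", "non_numeric"))
})

test_that("piecewise aggregation follows the interval rule", {
  expect_equal(aggregate_group(c(2, 30)), list(label = 2, branch = "min"))
  expect_equal(aggregate_group(c(60, 95)), list(label = 95, branch = "max"))
  expect_equal(aggregate_group(c(30, 50)), list(label = 40, branch = "mean"))
  expect_equal(aggregate_group(55), list(label = 55, branch = "single"))
  # boundary means fall in the mean branch
  expect_identical(aggregate_group(c(10, 30))$branch, "mean")
  expect_identical(aggregate_group(c(60, 80))$branch, "mean")
  expect_error(aggregate_group(numeric(0)), class = "cyp3a4hybrid_curate_error")
})

test_that("aggregation agrees with a brute-force rule on random groups", {
  brute <- function(v, lo = 20, hi = 70) {
    if (length(v) == 1) return(v)
    m <- sum(v) / length(v)
    if (m < lo) min(v) else if (m > hi) max(v) else m
  }
  set.seed(101)
  for (i in seq_len(1000)) {
    v <- runif(sample(1:6, 1), 0, 100)
    got <- aggregate_group(v)
    expect_identical(got$label, brute(v))
    # label bounded by the replicate envelope; permutation invariance
    expect_true(got$label >= min(v) && got$label <= max(v))
    expect_identical(aggregate_group(v[sample.int(length(v))])$label, got$label)
  }
})

test_that("replicate outlier flagging uses the sample SD", {
  expect_true(flag_outlier_group(c(10, 90), max_sd = 30))   # sd 56.57
  expect_false(flag_outlier_group(c(40, 42), max_sd = 30))  # sd 1.41
  expect_false(flag_outlier_group(50, max_sd = 30))         # singleton
  # retained count is monotone in max_sd
  set.seed(7)
  groups <- replicate(200, runif(3, 0, 100), simplify = FALSE)
  kept <- vapply(c(50, 30, 20, 10), function(ms) {
    sum(!vapply(groups, flag_outlier_group, logical(1), max_sd = ms))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("curation merges serializations and logs exclusions", {
  raw <- data.frame(
    id = 1:7,
    smiles = c("CCO", "OCC", "c1ccccc1", "CCCC", "CCN", "xxx", "CCCO"),
    value = c(30, 50, 103.5, -2, 250, 10, 60))
  cu <- curate_records(raw)
  expect_setequal(cu$log$reason, c("out_of_window", "unparseable"))
  eth <- cu$curated[cu$curated$molecule_key == "CCO", ]
  expect_identical(eth$n_replicates, 2L)
  expect_identical(eth$aggregation_branch, "mean")
  expect_equal(eth$label, 40)
  expect_equal(cu$curated$label[cu$curated$molecule_key == "c1ccccc1"], 100)
  # irreproducible groups are excluded before aggregation
  raw2 <- data.frame(id = 1:2, smiles = c("CCO", "OCC"), value = c(5, 95))
  cu2 <- curate_records(raw2, max_sd = 30)
  expect_identical(nrow(cu2$curated), 0L)
  expect_identical(cu2$log$reason, "replicate_outlier")
})

test_that("threshold sensitivity reproduces the baseline at (20, 70)", {
  set.seed(31)
  groups <- replicate(120, runif(sample(1:4, 1), 0, 100), simplify = FALSE)
  rep <- run_sensitivity(groups, lo_grid = c(10, 20, 30), hi_grid = c(60, 70, 80))
  expect_identical(nrow(rep), 9L)
  base_row <- rep[rep$lo == 20 & rep$hi == 70, ]
  surv <- groups[!vapply(groups, flag_outlier_group, logical(1), max_sd = 30)]
  base_labels <- vapply(surv, function(v) aggregate_group(v, 20, 70)$label, numeric(1))
  expect_equal(base_row$n_retained, length(base_labels))
  expect_equal(base_row$mean_label, mean(base_labels))
  # singleton groups are unaffected by the thresholds
  singles <- as.list(runif(50, 0, 100))
  rep2 <- run_sensitivity(singles, c(10, 30), c(60, 80))
  expect_true(all(rep2$n_retained == 50))
  expect_equal(max(rep2$mean_label) - min(rep2$mean_label), 0)
})

test_that("scaffold summary counts distinct Murcko classes", {
  mols <- fx_mols()
  s1 <- scaffold_summary(mols[c("benzene", "toluene", "ethylbenzene")])
  expect_equal(s1$n_molecules, 3)
  expect_equal(s1$n_unique_scaffolds, 1)
  s2 <- scaffold_summary(mols[c("butane", "pentane")])
  expect_equal(s2$n_unique_scaffolds, 1)  # shared empty-scaffold class
  s3 <- scaffold_summary(mols["naphthalene"])
  expect_equal(unlist(s3[1:2]), c(n_molecules = 1, n_unique_scaffolds = 1))
  expect_error(scaffold_summary(list()), class = "cyp3a4hybrid_curate_error")
})
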