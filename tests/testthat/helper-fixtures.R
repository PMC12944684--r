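# Shared fixtures, parsed once per test run.

.fx <- new.env(parent = emptyenv())

fx_smiles <- c(
  benzene = "c1ccccc1", toluene = "Cc1ccccc1", ethylbenzene = "CCc1ccccc1",
  butane = "CCCC", pentane = "CCCCC", ethanol = "CCO",
  imidazole = "c1c[nH]cn1", benzodioxole = "c1ccc2OCOc2c1",
  naphthalene = "c1ccc2ccccc2c1", pyridine_ether = "CCOc1ccncc1",
  acetanilide = "CC(=O)Nc1ccccc1", piperidine = "C1CCNCC1"
)

fx_mols <- function() {
  if (is.null(.fx$mols)) .fx$mols <- lapply(fx_smiles, standardize_structure)
  .fx$mols
}

fx_graphs <- function() {
  if (is.null(.fx$graphs)) .fx$graphs <- lapply(fx_mols(), build_dual_graph)
  .fx$graphs
}

fx_catalog <- function() {
  if (is.null(.fx$catalog)) .fx$catalog <- motif_catalog()
  .fx$catalog
}

# small synthetic benchmark shared by ensemble/cli/interpret tests
fx_bench <- function() {
  if (is.null(.fx$bench)) {
    .fx$bench <- make_benchmark(generator_config(n_molecules = 150, seed = 11))
  }
  .fx$bench
}

# random permutation of a dual graph's atom indices (relabeled isomorph)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  dual_graph(g$n_atoms, g$node_features[perm, , drop = FALSE],
             matrix(inv[g$edges], ncol = 2), g$edge_features,
             lapply(g$rings, function(r) inv[r]))
}
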