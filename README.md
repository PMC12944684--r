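# cyp3a4hybrid

Hybrid graph/tabular machine learning for predicting continuous **CYP3A4 %
inhibition** from molecular structure.

CYP3A4 metabolizes a large fraction of small-molecule drugs, and inhibiting
it is a principal driver of drug–drug interactions. Single-concentration
(10 µM) high-throughput screens report a continuous percent-inhibition
value per compound; modeling that value directly — rather than a binary
inhibitor label — preserves the ranking information that medicinal
chemists act on. This package implements a complete regression pipeline for
such data, exercisable end to end on synthetic molecules, for
cheminformatics and ADMET modelers who want every stage (curation,
featurization, training, ensembling, interpretation) as composable,
testable R functions.

## What it implements

**Label curation.** HTS percent-inhibition values are clipped to [0, 100]
(mild assay overshoot) or rejected (gross errors, non-numeric), structures
are desalted and canonicalized, and replicate measurements of one
structure are merged by a piecewise interval rule: with replicate mean
$\bar y$,

$$\text{label} = \begin{cases} \min(y) & \bar y < 20 \\ \text{mean}(y) & 20 \le \bar y \le 70 \\ \max(y) & \bar y > 70 \end{cases}$$

so spuriously high singleton readings cannot create false actives in the
inactive regime and strong inhibition is not diluted by averaging.
Replicate groups with sample SD above a cutoff are excluded; a sensitivity
analysis over the (lower, upper) threshold grid and a Bemis–Murcko
scaffold diversity summary complete the module.

**Featurization.** Four representations: 2048-bit radius-4 circular
fingerprints; a physicochemical descriptor block (MW, SLogP, TPSA, HBD,
HBA, molar refractivity, rotatable bonds, aromatic rings); engineered
feature axes (solubility/polarity proxies, charge-patch indicators, SAR
motif counts, Lipinski violations and a drug-likeness score); and a
ring-aware **dual graph** whose ring tensors (membership masks, node–ring
incidence, ring–ring adjacency) expose aromatic systems and fused rings as
first-class structural units.

**Ring-aware graph regressor.** Each encoder layer updates bond, then
atom, then ring states; atom updates aggregate neighboring atoms, incident
bonds, and the average state of the rings containing the atom. Training
supports InfoNCE contrastive pretraining on augmented graph views (atom
masking, bond deletion, subgraph removal) and **similarity-weighted
manifold mixup**: within each batch, pairs are scored by

$$S(i,j) = w_g \cos(h_i, h_j) + w_y \left(1 - |y_i - y_j|/R\right),$$

a partner is sampled proportionally to $\max(S, 0)$, and hidden
representations and labels are interpolated with $\lambda \sim
\mathrm{Beta}(\alpha, \alpha)$; interpolated samples feed only the
prediction head. All forward/backward passes are batched sparse-matrix
operations; training is fully seeded.

**Tabular block and hybrid ensemble.** Two differently-configured
gradient-boosted tree regressors and a two-hidden-layer perceptron are
combined by least-squares weights constrained to the probability simplex
(fit on validation predictions, so the ensemble is never worse there than
its best member); the tabular and graph blocks are then combined the same
way. SMILES test-time augmentation (canonical + N randomized
serializations, mean-pooled) is available at inference.

**Evaluation.** Alongside RMSE, R² and Pearson correlation, the composite

$$\text{Custom Metric} = 0.5\,(1 - \text{RMSE}/R) + 0.5\,\text{PCC}, \qquad R = 100$$

balances absolute accuracy against preservation of the inhibition ranking.

**Interpretation.** Occlusion sensitivity (mask one atom or ring, record
the prediction shift) for the graph model; substructure SAR statistics —
point-biserial correlation with significance stars, Cohen's d, bootstrap
mean-difference intervals — plus Spearman property correlation matrices.

**Synthetic benchmark.** A seeded generator assembles molecules from a
fragment grammar containing the SAR-relevant motifs (benzodioxole,
imidazole, pyridine, indole, piperidine, pyrazine) and plants an additive
structure–activity function with Gaussian noise, clipped to [0, 100], with
optional replicates and outliers — so every pipeline stage, including
parameter recovery, is testable without any external download.

## Worked example

```r
library(cyp3a4hybrid)

cfg   <- generator_config(n_molecules = 300, seed = 7)
bench <- make_benchmark(cfg)            # generate + replicate + curate
cu    <- bench$curated$curated

res <- evaluate_pipeline(cu, bench$molecules,
                         gnn_folds = 3, gnn_epochs = 5, seed = 11)
res
#> <pipeline_result>
#>   hybrid weights: ml=1.000 gnn=0.000
#>   validation RMSE: ml=12.322 gnn=19.650 hybrid=12.322
#>   test set:
#> <eval_report> n = 46
#>   RMSE   12.8236  (NRMSE 0.1282, range 100)
#>   R2      0.5685
#>   PCC     0.7569
#>   Custom Metric 0.8143

sar <- sar_report(cu$label, bench$molecules[cu$molecule_key], seed = 3)
sar[1:2, c("motif", "r_pb", "stars", "mean_diff")]
#>          motif      r_pb stars mean_diff
#> 1 benzodioxole 0.7096271   *** 40.629107
#> 2     pyridine 0.0347176         2.184196
```

The test-set report says the hybrid predicts held-out percent inhibition
with RMSE ≈ 12.8 points and rank correlation ≈ 0.76; the SAR table
recovers the benzodioxole effect planted by the generator (+35 points)
with high point-biserial correlation, while this particular 300-molecule
draw leaves the smaller pyridine effect below significance.

A command-line wrapper covering the same stages ships in
`exec/cyp3a4hybrid` (subcommands `make-benchmark`, `curate`, `featurize`,
`evaluate`, `sar`, `pipeline`).

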