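# dualmda

Dual-channel attention encoders for miRNA–disease association (MDA)
prediction in R.

Aberrant microRNA expression tracks the onset and progression of many
complex diseases, and computational ranking of candidate miRNA–disease
pairs guides which associations get tested at the bench. `dualmda` frames
the task as link prediction on the bipartite heterogeneous network
`G = [[0, A], [Aᵀ, 0]]` built from a binary incidence matrix
`A ∈ {0,1}^{M×N}` of confirmed associations, and scores unobserved pairs
with a model that encodes every node through two parallel channels:

1. **Graph-attention channel** — family-specific similarity features
   (Wang-style disease semantic similarity on a MeSH-like DAG; best-match
   miRNA functional similarity; Gaussian interaction profile kernels as
   fallback) are GCN-pre-encoded over the similarity networks, then passed
   through multi-head graph attention over `G` with jumping-knowledge layer
   merging.
2. **Transformer channel** — self-attention over all `M + N` nodes with two
   structural encodings of the graph: a learned degree-bucket embedding
   added to the inputs, and a learned scalar bias per shortest-path-distance
   bucket (BFS distances clipped at 8, unreachable pairs in their own
   bucket) added to the attention logits,
   `softmax(QKᵀ/√d + B_φ(G))V`.

The channels are fused by elementwise maximum pooling and pairs are scored
by an MLP on the concatenated node embeddings, trained with balanced
binary cross-entropy (Adam, negative sampling of zero cells). A tape-based
reverse-mode autodiff engine included in the package supplies the
gradients; its output is verified against finite differences in the test
suite. Cross-validation rebuilds every input (GIP profiles, similarity
adjacencies, SPD) from training positives only, so no validation label
leaks into the features.

The package also ships a block-model synthetic data generator (latent
disease/miRNA blocks, tunable within/background association rates, a
random rooted ontology whose subtrees mirror the blocks) so the entire
pipeline is exercisable offline, plus evaluation (rank AUC, step-integrated
AUPR, confusion metrics) and a small CLI.

## Worked example

```r
library(dualmda)
scfg  <- synth_config(n_mirna = 60, n_disease = 40, seed = 7)
dag   <- simulate_dag(scfg)          # rooted ontology with block subtrees
assoc <- simulate_associations(scfg) # block-model bipartite incidence
assoc
#> <mda_assoc> 60 miRNAs x 40 diseases, 217 associations (synthetic)

graph_stats(assoc)
#> Property   Full Data  miRNA   Disease
#> # nodes    100        60      40
#> # edges    217        -       -
#> # density  0.0904     -       -
#> # degree   4.340      3.617   5.425
#> # Ave_cen  0.0438     0.0365  0.0548

cv <- mda_cv(assoc, dag, cfg = mda_desk_config(), seed = 7)
cv
#> cross-validation summary (mean over folds):
#>  variant      auc     auc_sd      aupr    aupr_sd       acc        f1
#>     full 0.791932 0.05726935 0.7872149 0.06682321 0.7326638 0.7201141
```

The table is the stratified five-fold cross-validation summary: held-out
AUC ~0.79 on a 60×40 block-model network whose Bayes-optimal AUC is itself
bounded well below 1 (labels are Bernoulli given block co-membership —
see the vignette), so the model is recovering essentially all of the
plantable relational signal. `# degree` rows are the mean degrees overall
and per node family; `# Ave_cen` the mean normalised degree centralities.

Pair-level use: `model <- mda_train(build_model_inputs(assoc, dag = dag,
cfg = cfg), train_df, cfg = cfg, seed = 1)` then
`predict(model, pairs)` returns calibrated-range probabilities for any
(miRNA, disease) id pairs, and `model_embeddings(model)` exposes the GAT,
transformer and fused node embeddings.

Ablations mirror the standard degenerate variants:
`config_variant(cfg, "dae_a")` (plain transformer, graph attributes
zeroed), `"dae_b"` (vanilla GAT), `"dae_c"` (GAT channel only), `"dae_d"`
(transformer channel only); fusion variants via
`mda_config(fusion = "lin" | "dot" | "mean" | "add")`.

## Command line

```sh
exec/dualmda simulate --n-mirna 60 --n-disease 40 --seed 7 --out run1
exec/dualmda stats    --data run1
exec/dualmda build-sim --data run1 --out run1/sims
exec/dualmda cv       --data run1 --seed 7 --out run1/cv
exec/dualmda train    --data run1 --seed 7 --out run1
exec/dualmda predict  --model run1/model.rds --out run1/predictions.tsv
```

All stages log to stderr and write plain-text artifacts; every flag can
also be given through a JSON config file (`--config cfg.json`).

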