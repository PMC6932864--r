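# gitnet

Attention-based modeling of how somatic genomic alterations (SGAs)
reshape a tumor's transcriptome.

A tumor carries anywhere from a few to hundreds of SGAs — somatic
mutations and copy-number alterations — but only a minority are
*drivers* that perturb cellular signaling and change gene expression;
the rest are functionally silent *passengers*. `gitnet` implements the
**genomic impact transformer (GIT)**, an encoder–decoder neural network
that learns this genotype-to-transcriptome map and, as a by-product,
ranks candidate drivers and produces reusable per-tumor representations.
It is aimed at computational cancer biologists who want a
self-contained, dependency-light R implementation of the approach,
together with a synthetic-cohort simulator that makes every claim
testable at desk scale.

## The model

Each SGA gene *g* and cancer type *s* owns a learned embedding vector
(*e<sub>g</sub>*, *e<sub>s</sub>* ∈ ℝ<sup>d</sup>). For a tumor with SGA
set {g₁, …, g<sub>m</sub>} the encoder forms a tumor embedding by
attention-weighted pooling,

> e<sub>t</sub> = 1 · e<sub>s</sub> + Σ<sub>g</sub> α<sub>g</sub> · e<sub>g</sub>,

where the cancer-type weight is fixed at 1 and the α<sub>g</sub> come
from a multi-head self-attention module with parameters {W₀, Θ, ε}:
per head, score u<sub>h</sub>(g) = Θ<sub>h</sub>ᵀ tanh(W₀ e<sub>g</sub>),
softmax over the tumor's genes, average over heads, scale by a trainable
ε > 0 (so Σ α<sub>g</sub> = ε). The decoder maps e<sub>t</sub> to
per-gene DEG probabilities,

> ŷ = σ(W₂ · ReLU(W₁ · ReLU(e<sub>t</sub>) + b₁) + b₂),

trained end-to-end with ℓ₂-regularized cross entropy (mini-batch Adam;
gradients hand-derived and finite-difference checked). Gene embeddings
are initialized by **Gene2Vec**, skip-gram with negative sampling over
within-tumor SGA co-occurrence, and refined during supervised training.
Aggregated attention weights rank candidate driver genes; tumor
embeddings feed survival (elastic-net Cox) and drug-response (lasso)
pipelines.

## Worked example

Everything below runs on a simulated cohort with planted ground truth:
latent pathways, each linking a disjoint set of driver genes to a module
of DEG targets; one driver per active pathway per tumor (mutual
exclusivity); Poisson passengers with no expression effect.

```r
library(gitnet)

cfg <- sim_config(n_tumors = 600, n_genes = 300, n_deg_genes = 100,
                  n_cancer_types = 4, n_pathways = 10,
                  drivers_per_pathway = 5, deg_targets_per_pathway = 10,
                  pathways_per_tumor = 2, passenger_rate = 15, seed = 1)
g  <- generate_cohort(cfg)
sp <- make_split(g$cohort, split_spec(seed = 1))   # fixed 1/3:1/3:1/3

emb <- pretrain_gene2vec(g$cohort, gene2vec_config(d = 32, epochs = 5, seed = 1))
fit <- train_git(sp$train, sp$valid,
                 git_config(d = 32, heads = 4, attention_hidden = 16,
                            decoder_hidden = 128, dropout_rate = 0.1,
                            init_embeddings = emb, seed = 1),
                 train_config(max_epochs = 30, seed = 1))
fit
#> <git_fit> 30 epochs; best validation F1 0.5459 at epoch 30

evaluate_model(fit, sp$test)
#> precision 0.7576 | recall 0.4152 | F1 0.5364 | accuracy 0.8288
```

Micro-averaged over all tumor × DEG cells of the held-out third: at this
deliberately small cohort size the model calls DEGs at 76% precision and
recovers 42% of them (a 5% bit-flip noise floor bounds what is
attainable; the 2,000-tumor default cohort used by the acceptance suite
reaches F1 ≈ 0.79). The same cohort supports the driver analysis:
aggregate attention per gene (mean α over the tumors containing it)
against alteration frequency,

```r
rk <- attention_landscape(fit, g$cohort, scope = "pan")
head(rk, 3)
#>    gene aggregate_attention alteration_frequency
#> 1 g0150           0.9232712           0.03666667
#> 2 g0025           0.8470890           0.03000000
#> 3 g0277           0.8350451           0.03000000

lab <- driver_labels(g$truth, g$cohort)
mean(rk$aggregate_attention[lab[rk$gene] == 1]) /
  mean(rk$aggregate_attention[lab[rk$gene] == 0])
#> [1] 40.10842
```

Planted drivers receive, on average, forty times the attention of
passengers at comparable alteration frequencies. Tumor embeddings carry
phenotype signal beyond DEG prediction:

```r
embs <- extract_embeddings(fit, g$cohort, variant = "full")
survival_pipeline(embs, g$survival, folds = 10, seed = 1)$concordance
#> [1] 0.6871683
```

a pooled 10-fold cross-validated concordance index well above the 0.5
chance level, driven by the planted pathway hazard weights.

## Command-line interface

A thin Rscript wrapper exposes the pipelines as subcommands
(`simulate`, `pretrain`, `train`, `evaluate`, `ablation`,
`analyze-embeddings`, `rank-drivers`, `extract-embeddings`, `survival`,
`drug-response`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gitnet.R", package = "gitnet"))')
Rscript "$CLI" simulate --out-dir cohort/ --seed 3
Rscript "$CLI" pretrain --sga cohort/sga.tsv --deg cohort/deg.tsv \
    --d 64 --epochs 5 --out cohort/embeddings.tsv
```

All file formats are plain tab-separated text, documented in
`?read_cohort`, `?read_annotations`, `?read_embedding_table`.
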