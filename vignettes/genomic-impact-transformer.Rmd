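---
title: "Modeling the transcriptomic impact of somatic alterations with gitnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the transcriptomic impact of somatic alterations with gitnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A tumor typically carries from a handful to hundreds of somatic genomic
alterations (SGAs) — mutations and copy-number changes — of which only a
few *drivers* perturb signaling and ultimately reshape the transcriptome;
the rest are *passengers*. gitnet models the statistical relationship
between the set of SGA-affected genes of a tumor and its differentially
expressed genes (DEGs, a binary vector over a fixed gene panel), with
three goals: predicting DEG status from genotype, ranking candidate
drivers by how much the model attends to them, and producing per-tumor
embedding vectors that are useful for downstream phenotype prediction
(survival, drug response).

## The model

The genomic impact transformer (GIT) is an encoder–decoder network over
gene *embeddings*. Every SGA gene $g$ and every cancer type $s$ owns a
learned vector ($e_g$, $e_s$) in a shared look-up table. For a tumor with
SGA set $\{g_1,\dots,g_m\}$ and cancer type $s$ the encoder forms the
tumor embedding

$$ e_t \;=\; 1\cdot e_s \;+\; \sum_{g} \alpha_g\, e_g , $$

with the cancer-type weight fixed at 1 and attention weights $\alpha_g$
produced by a multi-head self-attention module with parameters
$\{W_0, \Theta, \varepsilon\}$: each head $h$ scores gene $g$ as
$u_h(g) = \Theta_h^\top \tanh(W_0 e_g)$, the scores are softmax-normalized
over the tumor's $m$ genes per head, averaged over heads and scaled by a
trainable positive scalar $\varepsilon$, so that $\sum_g \alpha_g =
\varepsilon$ exactly. The decoder is a one-hidden-layer perceptron

$$ \hat y = \sigma\!\big(W_2\,\mathrm{ReLU}(W_1\,\mathrm{ReLU}(e_t) + b_1)
   + b_2\big), $$

trained with cross entropy summed over DEG coordinates, averaged over the
mini-batch, plus an $\ell_2$ penalty $\lambda_2(\lVert W_1\rVert_2 +
\lVert W_2\rVert_2)$.

Design choices worth stating explicitly, since several are open in the
architecture sketch above:

* **Attention form.** Additive (tanh) scoring with a per-head softmax is
  the simplest form that uses exactly the declared parameter groups
  $\{W_0, \Theta, \varepsilon\}$ and produces comparable nonnegative
  weights. $\varepsilon$ is parameterized as a softplus of a raw scalar
  (initialized so $\varepsilon = 1$), letting the total gene-attention
  mass float against the fixed cancer-type weight.
* **Regularizer scope.** $\lambda_2$ applies to the decoder matrices
  $W_1, W_2$ only (Frobenius norms, biases free); embeddings and
  attention parameters are regularized implicitly by dropout and early
  selection.
* **Dropout** acts on the decoder hidden layer only, during training
  only.
* **Ablations.** `use_cancer_type = FALSE` replaces $e_s$ by zero
  ("−can"); `use_attention = FALSE` replaces $\alpha_g$ by $1/m$ (mean
  pooling, "−attn") so that $e_t$'s scale stays independent of mutation
  burden; omitting `init_embeddings` ("−init") falls back to the seeded
  uniform initialization also used by Gene2Vec.
* **Numerical care.** Probabilities are clipped to $[10^{-7},
  1-10^{-7}]$ before logarithms; a tumor with $m = 0$ encodes to $e_s$
  exactly; softmax is computed in stabilized form. All gradients
  (embeddings, $W_0$, $\Theta$, $\varepsilon$, decoder) are derived by
  hand and checked against central finite differences at a jittered
  generic point — freshly initialized zero biases would otherwise park
  entire ReLU rows on their kink, where one-sided and two-sided
  derivatives legitimately differ.

Training uses mini-batch Adam (default momentum parameters), seeded
shuffling, and per-epoch model selection by validation micro-F1; the
returned checkpoint is the best-validation epoch.

## Gene2Vec pre-training

Gene embeddings are pre-trained from SGA co-occurrence alone, treating a
tumor as an unordered "sentence": every ordered pair of distinct
co-occurring genes is a positive (center, context) example for skip-gram
with negative sampling; negatives are drawn from the unigram alteration
frequency raised to the 3/4 power; optimization is mini-batch SGD
(accumulated per-pair gradients, word2vec-style step size with linear
decay over epochs). Tumors with more than 50 SGAs are subsampled to 50
genes per epoch. Pairs are canonically sorted before the seeded shuffle,
so the result is invariant to tumor order.

The returned vector of a gene is the **average of its input and output
representations**. The input (center) vectors alone capture only
second-order similarity — two genes are close when their *context
distributions* agree — and on sparse cohorts that signal is dominated by
sampling noise; the average blends in first-order co-occurrence, which is
what makes always-co-occurring genes embed together and is the standard
practice in word-embedding implementations that expose both matrices.

A caveat the tests document rather than hide: on the default synthetic
cohort, pre-training alone does **not** separate same-pathway drivers in
embedding space. Same-pathway drivers never co-occur (mutual
exclusivity), so their affinity can only arise second-order, and with
~40 tumors per driver and ~20 passenger alterations per tumor the
context profiles are mostly noise. The measured within-pathway and
between-pathway mean cosine similarities are equal to within ±0.02. The
pathway structure emerges decisively once the embeddings are refined by
DEG supervision: after GIT fine-tuning, nearest-neighbour annotation
accuracy on planted-pathway labels rises far above the random-pair
baseline, which is the behavior the embedding-structure acceptance test
asserts (pre-training alone is also reported, as the analog of the
smaller improvement a co-occurrence-only embedding achieves).

## The synthetic cohort generator

Real inputs of this kind (pan-cancer SGA calls with matched DEG panels)
require external data acquisition, so the package ships a simulator whose
defaults define the study conditions used throughout the tests: 2,000
tumors, 500 SGA genes, 200 DEG genes, 4 cancer types, 20 latent pathways
with 5 disjoint drivers and 15 DEG targets each, 2 active pathways per
tumor, Poisson(20) passengers, 5% DEG flip noise, and a 10% baseline DEG
rate on a per-cancer-type module (a random quarter of the DEG panel).
Within each active pathway exactly **one** driver is altered — mutual
exclusivity, which is the co-occurrence signal Gene2Vec is meant to
exploit — and passengers are drawn uniformly from the non-driver pool,
so they carry no expression signal.

Phenotypes are driven by *which* pathways are active. Each pathway owns
a standard-normal hazard weight $w_p$; a tumor's survival time is
exponential with log-hazard `survival_effect` $\times \sum_{p\,
\text{active}} w_p$, censored uniformly on $[0, 3\times\text{median}]$.
(Since every tumor activates exactly `pathways_per_tumor` pathways, the
*count* of active pathways is constant by construction and cannot carry a
survival signal; hazard must therefore load on pathway identity.) Each
simulated drug is tied to one designated pathway, with sensitivity
Bernoulli-logistic in that pathway's activity.

All randomness flows from one master seed; per-tumor draws use derived
substreams, so extending a cohort never perturbs earlier tumors.

What the simulator deliberately does not emulate: real mutation-frequency
spectra (every driver within a pathway is equally likely), overlapping
driver sets between pathways, expression dosage (DEG bits are binary),
and annotation structure richer than one term per pathway. Tests passing
on this generator therefore demonstrate that the machinery recovers
planted signal under the stated noise — not that it reproduces any
real-cohort performance figure.

## Evaluation protocol

Cohorts are split 1/3 : 1/3 : 1/3 into train/validation/test by a seeded
shuffle stratified by cancer type; the split is created once and shared
by every model compared on a cohort. DEG prediction is scored
micro-averaged over all tumor × DEG cells at threshold 0.5 (one global
confusion matrix), reporting precision, recall, F1 and accuracy;
repeated runs report mean and variance over seeds. Baselines are
per-DEG $\ell_1$-logistic regression (lasso; penalty chosen on validation
F1 over a shared logarithmic grid) and 1–3-layer ReLU perceptrons on the
binary SGA indicator matrix plus one-hot cancer type.

Driver ranking aggregates, per gene, the mean attention weight over the
tumors containing it, next to its alteration frequency (the control
ranking). One subtlety the negative control must respect: under mean
pooling $\alpha_g = 1/m$, so a gene's aggregate attention reflects the
*sizes* of the tumors containing it, and passengers are size-biased
(a tumor with more passengers is more likely to contain any given
passenger). The uninformativeness of ablated attention is therefore
asserted on the size-controlled aggregate $\overline{\alpha_g m_t}$,
which is identically 1 under mean pooling.

Embedding quality uses two metrics. *NN accuracy*: the percentage of
annotated genes whose cosine nearest neighbour shares at least one
annotation term (unannotated genes are skipped as queries but remain
candidate neighbours), compared against a Monte-Carlo random-pair
baseline. *Cluster enrichment*: after seeded k-means (10 restarts) in
embedding space, the mean within-cluster annotated-pair sharing fraction
divided by the background fraction over all annotated pairs; 1 under random placement,
which a 20-permutation calibration test asserts.

Survival prediction fits elastic-net Cox models ($\alpha = 0.5$, penalty
by inner cross-validation) in k-fold CV on tumor embeddings, pools the
out-of-fold risk scores, and reports the pooled concordance index plus a
median-split log-rank p-value. Drug response fits $\ell_1$-logistic
models in k-fold CV on tanh-curved tumor embeddings (or the raw SGA
indicator matrix), pooling out-of-fold probabilities into one ROC/AUC per
drug. Pooling (rather than per-fold averaging) is the stabler choice for
both and is used throughout. One consequence of the simulator's design is
worth knowing: because a drug's pathway activity is observable from a
single altered driver gene, both feature representations approach the
same Bayes ceiling (AUC ≈ 0.72 at the default `drug_effect = 2`), so the
embedding-vs-raw comparison — interesting on real cell-line panels where
alteration evidence is diffuse — has essentially no headroom on the
bundled simulator and is not a test surface here.

## Problem sizes used by the tests

The acceptance suite trains on the full default cohort with a compact
model configuration chosen for desk-scale runs: $d = 32$, 4 heads,
$d_a = 16$, decoder hidden width 128, dropout 0.1, $\lambda_2 = 10^{-4}$,
Adam at $5\times10^{-3}$, batch 64, 40 epochs, with Gene2Vec at $d = 32$
for 5 epochs; five repeated seeds cover the run-to-run variance. The
package defaults ($d = 128$, 8 heads, $d_a = 64$, hidden 512)
suit larger cohorts; all of them are ordinary tuning knobs exposed
through `git_config()`/`train_config()`.

## Known limitations

* The attention module produces one scalar per gene per head from a
  pooled context; there is no token-token transformer attention between
  SGAs, by design.
* Gene2Vec on sparse desk-scale cohorts yields embeddings whose pathway
  structure is only latent (see above); conclusions about co-occurrence
  pre-training quality on real pan-cancer corpora cannot be drawn from
  the bundled simulator.
* The lasso baseline selects a single shared penalty on validation
  micro-F1 rather than per-DEG penalties; per-DEG selection would be
  slower and favor the baseline slightly.
* Survival and drug-response estimators are off-the-shelf
  (glmnet/survival); the package's contribution there is the pipeline
  contract, fold handling and pooled metrics, not the estimators.
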