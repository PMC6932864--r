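# Small deterministic fixtures built in code.

tiny_sim <- function(seed = 7, n_tumors = 30)
  sim_config(n_tumors = n_tumors, n_genes = 24, n_deg_genes = 12,
             n_cancer_types = 2, n_pathways = 3, drivers_per_pathway = 3,
             deg_targets_per_pathway = 4, pathways_per_tumor = 1,
             passenger_rate = 4, deg_flip_noise = 0.02,
             cancer_type_deg_rate = 0.1, seed = seed)

tiny_cohort <- function(seed = 7, n_tumors = 30)
  generate_cohort(tiny_sim(seed, n_tumors))$cohort

tiny_git_config <- function(...) {
  defaults <- list(d = 8, heads = 2, attention_hidden = 4,
                   decoder_hidden = 16, dropout_rate = 0.1,
                   l2_lambda = 1e-4, seed = 1)
  do.call(git_config, modifyList(defaults, list(...)))
}

# hand-rolled cosine for oracle comparisons
cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

auroc_of <- function(score, labels)
  as.numeric(pROC::auc(pROC::roc(labels, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
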