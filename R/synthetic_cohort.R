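# Synthetic tumor cohorts with planted driver pathways.
#
# Each latent pathway links a disjoint set of driver genes to a module of
# DEG targets.  A tumor activates a few pathways; within each active pathway
# exactly one driver is altered, encoding the mutual exclusivity of
# alterations hitting a common pathway.  Passenger alterations carry no
# expression signal.  Phenotypes (survival hazard, drug sensitivity) are
# driven by which pathways are active.

#' Simulation configuration
#'
#' @param n_tumors,n_genes,n_deg_genes,n_cancer_types cohort dimensions.
#' @param n_pathways number of latent pathways.
#' @param drivers_per_pathway drivers per pathway (disjoint across pathways).
#' @param deg_targets_per_pathway DEG targets per pathway (may overlap).
#' @param pathways_per_tumor distinct pathways activated per tumor.
#' @param passenger_rate mean passenger alterations per tumor (Poisson).
#' @param deg_flip_noise probability each DEG bit is flipped.
#' @param cancer_type_deg_rate probability each gene of a cancer type's
#'   baseline module is differentially expressed.
#' @param survival_effect log-hazard scale of pathway activity.
#' @param n_drugs number of simulated drugs, each tied to one pathway.
#' @param drug_effect logistic slope of drug sensitivity on the activity of
#'   the drug's pathway.
#' @param seed master seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tumors = 2000, n_genes = 500, n_deg_genes = 200,
                       n_cancer_types = 4, n_pathways = 20,
                       drivers_per_pathway = 5, deg_targets_per_pathway = 15,
                       pathways_per_tumor = 2, passenger_rate = 20,
                       deg_flip_noise = 0.05, cancer_type_deg_rate = 0.1,
                       survival_effect = 0.8, n_drugs = 4, drug_effect = 2,
                       seed = 0) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_sim_config <- function() sim_config()

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_tumors", "n_genes", "n_deg_genes", "n_cancer_types",
              "n_pathways", "drivers_per_pathway", "deg_targets_per_pathway",
              "pathways_per_tumor")
  for (k in counts)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1 || cfg[[k]] != round(cfg[[k]]))
      stop("sim_config field '", k, "' must be a positive integer")
  for (k in c("deg_flip_noise", "cancer_type_deg_rate"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1)
      stop("sim_config field '", k, "' must be a probability in [0,1]")
  if (cfg$passenger_rate < 0) stop("passenger_rate must be nonnegative")
  if (cfg$n_drugs < 0) stop("n_drugs must be nonnegative")
  if (cfg$drivers_per_pathway * cfg$n_pathways > cfg$n_genes)
    stop("drivers_per_pathway * n_pathways exceeds n_genes; ",
         "pathway driver sets cannot be disjoint")
  if (cfg$pathways_per_tumor > cfg$n_pathways)
    stop("pathways_per_tumor exceeds n_pathways")
  if (cfg$deg_targets_per_pathway > cfg$n_deg_genes)
    stop("deg_targets_per_pathway exceeds n_deg_genes")
  cfg
}

#' Scale a simulation configuration
#'
#' Multiplies the cohort dimensions by `factor` (minimum sizes enforced so
#' the result stays valid); useful for quick desk-scale runs.
#' @param config a `sim_config`.
#' @param factor positive scale factor.
#' @export
scale_sim_config <- function(config, factor) {
  stopifnot(factor > 0)
  config$n_tumors <- max(3L, as.integer(round(config$n_tumors * factor)))
  config$n_genes <- max(config$n_pathways * config$drivers_per_pathway + 1L,
                        as.integer(round(config$n_genes * factor)))
  config$n_deg_genes <- max(config$deg_targets_per_pathway,
                            as.integer(round(config$n_deg_genes * factor)))
  validate_sim_config(config)
}

# Independent per-tumor RNG substream: adding tumors never perturbs the
# draws of earlier ones.
.substream_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 1000003) * 2017 + as.numeric(i) * 7919
  as.integer(s %% 2147483587) + 1L
}

#' Generate a synthetic cohort with planted ground truth
#'
#' For each tumor: a cancer type is drawn uniformly; `pathways_per_tumor`
#' distinct pathways are activated, each contributing exactly one altered
#' driver gene (mutual exclusivity within a pathway); Poisson-many passenger
#' genes are added from the non-driver pool; the DEG vector is the union of
#' the active pathways' target modules plus Bernoulli baseline expression of
#' the cancer type's module, with each bit finally flipped with probability
#' `deg_flip_noise`.  Survival times are exponential with log-hazard
#' `survival_effect` times the summed (standard-normal) hazard weights of
#' the active pathways, censored uniformly on `[0, 3 * median]`; per-drug
#' sensitivity is Bernoulli with logistic probability in the activity of the
#' drug's designated pathway.  Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (an `sga_cohort`), `truth` (a
#'   `synthetic_truth` with the planted pathways, per-tumor drivers, latent
#'   hazards and sensitivity probabilities), `survival` (data.frame
#'   `tumor_id`, `time`, `event`), and `drug_response` (binary matrix).
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  gene_vocab <- sprintf("g%04d", seq_len(config$n_genes))
  deg_vocab <- sprintf("d%04d", seq_len(config$n_deg_genes))
  type_vocab <- sprintf("ct%02d", seq_len(config$n_cancer_types))
  pathway_ids <- sprintf("pw%02d", seq_len(config$n_pathways))
  drug_ids <- if (config$n_drugs > 0) sprintf("drug%02d", seq_len(config$n_drugs))

  # --- global planted structure -------------------------------------------
  set.seed(config$seed)
  driver_pool <- sample(gene_vocab,
                        config$n_pathways * config$drivers_per_pathway)
  pathway_drivers <- split(driver_pool,
                           rep(pathway_ids, each = config$drivers_per_pathway))
  pathway_drivers <- pathway_drivers[pathway_ids]
  passenger_pool <- setdiff(gene_vocab, driver_pool)
  pathway_targets <- setNames(lapply(pathway_ids, function(p)
    sort(sample(deg_vocab, config$deg_targets_per_pathway))), pathway_ids)
  baseline_size <- max(1L, config$n_deg_genes %/% 4L)
  type_baseline <- setNames(lapply(type_vocab, function(s)
    sort(sample(deg_vocab, baseline_size))), type_vocab)
  pathway_hazard_w <- setNames(rnorm(config$n_pathways), pathway_ids)
  drug_pathway <- if (config$n_drugs > 0)
    setNames(sample(pathway_ids, config$n_drugs,
                    replace = config$n_drugs > config$n_pathways), drug_ids)

  # --- per-tumor draws (independent substreams) ---------------------------
  n <- config$n_tumors
  tumor_id <- sprintf("t%05d", seq_len(n))
  cancer_type <- character(n)
  sga <- vector("list", n)
  deg <- matrix(0L, n, config$n_deg_genes, dimnames = list(tumor_id, deg_vocab))
  tumor_drivers <- vector("list", n)
  tumor_pathways <- vector("list", n)
  log_hazard <- numeric(n)
  surv_raw <- numeric(n)
  cens_u <- numeric(n)
  drug_prob <- matrix(NA_real_, n, config$n_drugs,
                      dimnames = list(tumor_id, drug_ids))
  drug_label <- matrix(NA_integer_, n, config$n_drugs,
                       dimnames = list(tumor_id, drug_ids))

  for (i in seq_len(n)) {
    set.seed(.substream_seed(config$seed, i))
    cancer_type[i] <- sample(type_vocab, 1)
    pws <- sort(sample(pathway_ids, config$pathways_per_tumor))
    drivers <- vapply(pws, function(p) {
      ds <- pathway_drivers[[p]]
      ds[sample.int(length(ds), 1)]
    }, "")
    k <- rpois(1, config$passenger_rate)
    k <- min(k, length(passenger_pool))
    passengers <- if (k > 0) sample(passenger_pool, k) else character()
    sga[[i]] <- sort(unique(c(drivers, passengers)))
    tumor_drivers[[i]] <- sort(unname(drivers))
    tumor_pathways[[i]] <- pws

    bits <- integer(config$n_deg_genes)
    names(bits) <- deg_vocab
    bits[unique(unlist(pathway_targets[pws], use.names = FALSE))] <- 1L
    base <- type_baseline[[cancer_type[i]]]
    if (config$cancer_type_deg_rate > 0) {
      on <- base[runif(length(base)) < config$cancer_type_deg_rate]
      bits[on] <- 1L
    }
    if (config$deg_flip_noise > 0) {
      flip <- runif(config$n_deg_genes) < config$deg_flip_noise
      bits[flip] <- 1L - bits[flip]
    }
    deg[i, ] <- bits

    log_hazard[i] <- config$survival_effect * sum(pathway_hazard_w[pws])
    surv_raw[i] <- rexp(1, rate = exp(log_hazard[i]))
    cens_u[i] <- runif(1)
    for (j in seq_len(config$n_drugs)) {
      active <- drug_pathway[j] %in% pws
      drug_prob[i, j] <- plogis(config$drug_effect * (2 * active - 1))
      drug_label[i, j] <- rbinom(1, 1, drug_prob[i, j])
    }
  }
  names(tumor_drivers) <- tumor_id
  names(tumor_pathways) <- tumor_id
  names(log_hazard) <- tumor_id

  cens_time <- cens_u * 3 * median(surv_raw)
  survival <- data.frame(tumor_id = tumor_id,
                         time = pmin(surv_raw, cens_time),
                         event = as.integer(surv_raw <= cens_time))

  cohort <- new_cohort(tumor_id, cancer_type, sga, deg,
                       gene_vocab = gene_vocab, deg_vocab = deg_vocab,
                       cancer_type_vocab = type_vocab)
  truth <- structure(
    list(pathway_drivers = pathway_drivers,
         pathway_targets = pathway_targets,
         passenger_pool = passenger_pool,
         type_baseline = type_baseline,
         tumor_drivers = tumor_drivers,
         tumor_active_pathways = tumor_pathways,
         log_hazard = log_hazard,
         pathway_hazard_weights = pathway_hazard_w,
         drug_pathway = drug_pathway,
         drug_sensitivity_prob = drug_prob),
    class = "synthetic_truth")
  list(cohort = cohort, truth = truth, survival = survival,
       drug_response = drug_label)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d pathways (%d drivers, %d targets each), %d tumors\n",
              length(x$pathway_drivers),
              length(x$pathway_drivers[[1]]), length(x$pathway_targets[[1]]),
              length(x$tumor_drivers)))
  invisible(x)
}

#' Planted pathway membership as an annotation map
#'
#' Each driver gene is annotated with the identifier of its pathway; the
#' synthetic analog of a functional-term annotation used by the embedding
#' quality metrics.
#' @param truth a `synthetic_truth`.
#' @export
pathway_annotations <- function(truth) {
  genes <- unlist(truth$pathway_drivers, use.names = FALSE)
  terms <- rep(names(truth$pathway_drivers), lengths(truth$pathway_drivers))
  as_annotation_map(split(terms, genes))
}

#' Gene-level driver labels of a synthetic cohort
#' @param truth a `synthetic_truth`.
#' @param cohort the matching cohort.
#' @return named 0/1 vector over `cohort$gene_vocab`: 1 for planted pathway
#'   drivers, 0 for passengers.
#' @export
driver_labels <- function(truth, cohort) {
  drivers <- unlist(truth$pathway_drivers, use.names = FALSE)
  setNames(as.integer(cohort$gene_vocab %in% drivers), cohort$gene_vocab)
}
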