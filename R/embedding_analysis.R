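# Embedding-quality metrics, gene clustering, and the attention landscape
# used to rank candidate driver genes.

.term_sets <- function(annotations, genes) {
  sets <- lapply(genes, function(g) annotation_terms(annotations, g))
  names(sets) <- genes
  sets
}

# gene x term incidence for fast pair-share computation
.term_incidence <- function(sets) {
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  M <- matrix(0L, length(sets), length(terms),
              dimnames = list(names(sets), terms))
  for (i in seq_along(sets))
    M[i, sets[[i]]] <- 1L
  M
}

# fraction of unordered pairs of `genes` sharing >= 1 term
.share_fraction <- function(M) {
  n <- nrow(M)
  if (n < 2) return(NA_real_)
  shared <- tcrossprod(M) > 0
  (sum(shared) - n) / (n * (n - 1))
}

#' Nearest-neighbour annotation accuracy of an embedding
#'
#' For every listed gene with a nonempty annotation set, its cosine nearest
#' neighbour among the other listed genes is found (ties broken
#' lexicographically); the accuracy is the percentage of such genes that
#' share at least one annotation term with that neighbour.  Genes without
#' annotations are skipped as queries but remain candidate neighbours.
#'
#' @param table an [embedding_table()].
#' @param annotations an `annotation_map`.
#' @param genes genes to evaluate (default: all genes in the table).
#' @return percentage in \[0, 100\].
#' @export
nn_accuracy <- function(table, annotations, genes = rownames(table)) {
  genes <- intersect(genes, rownames(table))
  if (length(genes) < 2) stop("need at least 2 genes with vectors")
  sets <- .term_sets(annotations, genes)
  annotated <- genes[lengths(sets) > 0]
  if (length(annotated) < 2) stop("need at least 2 annotated genes")
  V <- .row_normalize(unclass(table)[genes, , drop = FALSE])
  sims <- tcrossprod(V)
  diag(sims) <- -Inf
  hits <- vapply(annotated, function(g) {
    s <- sims[g, ]
    best <- max(s)
    nb <- sort(names(s)[s == best])[1]  # lexicographic tie-break
    length(intersect(sets[[g]], sets[[nb]])) > 0
  }, NA)
  100 * mean(hits)
}

#' Chance level of annotation sharing among random gene pairs
#'
#' Monte-Carlo estimate of the probability that a uniformly random ordered
#' pair of distinct listed genes shares at least one annotation term.
#'
#' @param annotations an `annotation_map`.
#' @param genes gene universe to draw from.
#' @param n_pairs number of sampled pairs.
#' @param seed RNG seed.
#' @return list with `percent`, its standard error `se` (both on the 0-100
#'   scale) and `n_pairs`.
#' @export
random_pair_baseline <- function(annotations, genes, n_pairs = 10000,
                                 seed = 1) {
  if (length(genes) < 2) stop("need at least 2 genes")
  set.seed(seed)
  sets <- .term_sets(annotations, genes)
  a <- sample.int(length(genes), n_pairs, replace = TRUE)
  b <- sample.int(length(genes) - 1L, n_pairs, replace = TRUE)
  b <- ifelse(b >= a, b + 1L, b)  # uniform over distinct ordered pairs
  share <- vapply(seq_len(n_pairs), function(i)
    length(intersect(sets[[a[i]]], sets[[b[i]]])) > 0, NA)
  p <- mean(share)
  list(percent = 100 * p,
       se = 100 * sqrt(p * (1 - p) / n_pairs),
       n_pairs = n_pairs)
}

#' Annotation enrichment of embedding-space clusters
#'
#' Genes are clustered by k-means (seeded, `nstart` restarts, best inertia)
#' in embedding space.  Enrichment is the mean, over clusters with at least
#' two annotated genes, of the fraction of within-cluster annotated-gene
#' pairs sharing an annotation term, divided by the same fraction over all
#' annotated-gene pairs.  Randomly placed genes give enrichment ~1.
#'
#' @inheritParams nn_accuracy
#' @param k number of clusters (`2 <= k <=` number of genes).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @export
cluster_enrichment <- function(table, annotations, k, seed = 1, nstart = 10) {
  V <- unclass(table)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(V)) stop("k = ", k, " exceeds the number of genes ", nrow(V))
  cl <- .seeded_kmeans(V, k, seed = seed, nstart = nstart)$cluster
  sets <- .term_sets(annotations, rownames(V))
  annotated <- names(sets)[lengths(sets) > 0]
  if (length(annotated) < 2) stop("need at least 2 annotated genes")
  M <- .term_incidence(sets[annotated])
  background <- .share_fraction(M)
  if (is.na(background) || background == 0)
    stop("no annotation sharing among gene pairs; enrichment undefined")
  within <- vapply(split(annotated, cl[annotated]), function(g)
    if (length(g) >= 2) .share_fraction(M[g, , drop = FALSE]) else NA_real_,
    0)
  mean(within, na.rm = TRUE) / background
}

#' Enrichment as a function of cluster granularity
#'
#' @inheritParams cluster_enrichment
#' @param k_list cluster counts to evaluate (sorted, deduplicated).
#' @return data.frame (`enrichment_curve`) with columns `k`, `enrichment`.
#' @export
enrichment_curve <- function(table, annotations, k_list, seed = 1,
                             nstart = 10) {
  k_list <- sort(unique(as.integer(k_list)))
  out <- data.frame(k = k_list,
                    enrichment = vapply(k_list, function(k)
                      cluster_enrichment(table, annotations, k, seed = seed,
                                         nstart = nstart), 0))
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Attention landscape / driver ranking
# ---------------------------------------------------------------------------

.scope_cohort <- function(cohort, scope) {
  if (identical(scope, "pan")) return(cohort)
  if (!scope %in% cohort$cancer_type_vocab)
    stop("unknown scope '", scope, "'; expected 'pan' or one of: ",
         paste(cohort$cancer_type_vocab, collapse = ", "))
  cohort[which(cohort$cancer_type == scope)]
}

.rank_driver_table <- function(df) {
  df <- df[order(-df$aggregate_attention, -df$alteration_frequency,
                 df$gene), ]
  rownames(df) <- NULL
  class(df) <- c("driver_ranking", "data.frame")
  df
}

#' Attention landscape: rank genes by aggregate attention
#'
#' For each gene altered in the in-scope tumors, the aggregate attention is
#' the mean of its per-tumor attention weights over the tumors containing
#' it, reported next to its alteration frequency.  Ranking is by aggregate
#' attention (ties: frequency, then gene name).
#'
#' @param model a trained `git_model` (or `git_fit`).
#' @param cohort cohort sharing the model's vocabularies.
#' @param scope `"pan"` for the whole cohort or one cancer-type label.
#' @return a `driver_ranking` data.frame with columns `gene`,
#'   `aggregate_attention`, `alteration_frequency`.
#' @export
attention_landscape <- function(model, cohort, scope = "pan") {
  if (inherits(model, "git_fit")) model <- model$model
  sub <- .scope_cohort(cohort, scope)
  if (n_tumors(sub) == 0) stop("no tumors in scope '", scope, "'")
  fw <- git_forward(model, sub, training = FALSE)
  av <- unlist(fw$alphas, use.names = FALSE)
  gv <- unlist(lapply(fw$alphas, names), use.names = FALSE)
  agg <- tapply(av, gv, mean)
  freq <- table(gv)[names(agg)] / n_tumors(sub)
  .rank_driver_table(data.frame(gene = names(agg),
                                aggregate_attention = as.numeric(agg),
                                alteration_frequency = as.numeric(freq)))
}

#' Frequency-based gene ranking (control)
#'
#' The benchmark ranking by alteration frequency, with the same columns as
#' [attention_landscape()] (aggregate attention set to the frequency so the
#' ordering is by frequency).
#' @inheritParams attention_landscape
#' @export
frequency_ranking <- function(cohort, scope = "pan") {
  sub <- .scope_cohort(cohort, scope)
  if (n_tumors(sub) == 0) stop("no tumors in scope '", scope, "'")
  cnt <- table(unlist(sub$sga, use.names = FALSE))
  freq <- as.numeric(cnt) / n_tumors(sub)
  .rank_driver_table(data.frame(gene = names(cnt),
                                aggregate_attention = freq,
                                alteration_frequency = freq))
}

#' Two-dimensional PCA coordinates of embeddings
#'
#' Thin wrapper around [stats::prcomp()] for quick visualisation of gene or
#' tumor embeddings.
#' @param x an embedding table or numeric matrix (rows = entities).
#' @param n_components number of components.
#' @export
embedding_pca <- function(x, n_components = 2) {
  p <- prcomp(unclass(x), rank. = n_components)
  coords <- p$x
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  coords
}
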