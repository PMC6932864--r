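# Gene2Vec: skip-gram with negative sampling over within-tumor SGA
# co-occurrence.  A tumor is an unordered "sentence" of altered genes, so
# every ordered pair of distinct co-occurring genes is a positive
# (center, context) example; negatives are drawn from the unigram
# alteration-frequency distribution raised to the 3/4 power.

#' Gene2Vec configuration
#'
#' @param d embedding dimension.
#' @param epochs training epochs (0 returns the seeded random init).
#' @param learning_rate SGD step size per positive pair.
#' @param negative_samples negatives per positive pair.
#' @param batch_size pairs per mini-batch; the per-pair gradients of a
#'   batch are accumulated into one step, the vectorized equivalent (to
#'   first order) of processing the pairs sequentially.
#' @param max_genes_per_tumor tumors with more SGAs are subsampled to this
#'   many genes per epoch to bound the pair count.
#' @param seed RNG seed.
#' @export
gene2vec_config <- function(d = 128, epochs = 5, learning_rate = 0.025,
                            negative_samples = 5, batch_size = 64,
                            max_genes_per_tumor = 50, seed = 1) {
  stopifnot(d >= 2, epochs >= 0, learning_rate > 0, negative_samples >= 1,
            batch_size >= 1, max_genes_per_tumor >= 2)
  structure(as.list(environment()), class = "gene2vec_config")
}

.ordered_pairs <- function(idx) {
  m <- length(idx)
  if (m < 2) return(NULL)
  cbind(center = rep(idx, each = m - 1L),
        context = unlist(lapply(seq_len(m), function(j) idx[-j]),
                         use.names = FALSE))
}

#' Pre-train gene embeddings from SGA co-occurrence
#'
#' Mini-batch SGD on the skip-gram negative-sampling objective.  Pairs are
#' canonically sorted before the seeded shuffle, so results do not depend on
#' tumor order.  Genes that never co-occur retain their random
#' initialization.  The returned vector of a gene is the average of its
#' input (center) and output (context) representations, so cosine
#' similarity reflects both first-order co-occurrence and second-order
#' context sharing.
#'
#' @param cohort an `sga_cohort`.
#' @param config a [gene2vec_config()].
#' @return an [embedding_table()] over `cohort$gene_vocab` with attribute
#'   `epoch_loss` (mean loss per positive pair, one entry per epoch).
#' @export
pretrain_gene2vec <- function(cohort, config = gene2vec_config()) {
  if (n_tumors(cohort) == 0) stop("cannot pre-train on an empty cohort")
  genes <- cohort$gene_vocab
  nG <- length(genes)
  d <- config$d
  set.seed(config$seed)
  Win <- matrix(runif(nG * d, -0.5 / d, 0.5 / d), nG, d,
                dimnames = list(genes, NULL))
  if (config$epochs == 0)
    return(structure(embedding_table(Win), epoch_loss = numeric()))

  sga_idx <- lapply(cohort$sga, function(g) match(g, genes))
  if (!any(lengths(sga_idx) >= 2))
    stop("no tumor has two or more SGAs; no co-occurrence pairs to train on")
  counts <- tabulate(unlist(sga_idx, use.names = FALSE), nbins = nG)
  neg_prob <- counts^0.75
  if (sum(neg_prob) == 0) stop("no SGA occurrences in cohort")
  neg_prob <- neg_prob / sum(neg_prob)

  small <- sga_idx[lengths(sga_idx) <= config$max_genes_per_tumor]
  large <- sga_idx[lengths(sga_idx) > config$max_genes_per_tumor]
  base_pairs <- do.call(rbind, lapply(small, .ordered_pairs))

  Win_t <- t(Win)                       # d x n: contiguous column per gene
  Wout_t <- matrix(0, d, nG)
  neg_cdf <- cumsum(neg_prob)
  epoch_loss <- numeric(config$epochs)
  # word2vec-style linear decay of the step size over epochs
  lrs <- if (config$epochs == 1) config$learning_rate else
    seq(config$learning_rate, config$learning_rate / 10,
        length.out = config$epochs)

  for (ep in seq_len(config$epochs)) {
    pairs <- base_pairs
    if (length(large)) {
      extra <- do.call(rbind, lapply(large, function(idx)
        .ordered_pairs(sample(idx, config$max_genes_per_tumor))))
      pairs <- rbind(pairs, extra)
    }
    # canonical order, then seeded shuffle: invariant to tumor order
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    epoch_loss[ep] <- .sgns_epoch(Win_t, Wout_t, pairs[, 1L], pairs[, 2L],
                                  neg_cdf, config$negative_samples, lrs[ep],
                                  config$batch_size)
  }
  emb <- (t(Win_t) + t(Wout_t)) / 2
  dimnames(emb) <- list(genes, NULL)
  structure(embedding_table(emb), epoch_loss = epoch_loss)
}

# ---------------------------------------------------------------------------
# Cosine geometry helpers
# ---------------------------------------------------------------------------

.row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1  # zero vectors get similarity 0 to everything
  m / nrm
}

.cosine_to_query <- function(table, gene) {
  q <- table[gene, ]
  qn <- sqrt(sum(q^2))
  if (qn == 0) return(setNames(rep(0, nrow(table)), rownames(table)))
  sims <- as.vector(.row_normalize(unclass(table)) %*% (q / qn))
  setNames(sims, rownames(table))
}

#' Nearest genes in embedding space
#'
#' Top-k neighbours of a query gene by cosine similarity, excluding the
#' query itself; ties are broken lexicographically.
#' @param table an `embedding_table`.
#' @param gene query identifier (must be in the table).
#' @param k number of neighbours.
#' @return data.frame with columns `gene` and `similarity`, k rows.
#' @export
nearest_genes <- function(table, gene, k = 5) {
  if (!gene %in% rownames(table)) stop("unknown gene: ", gene)
  sims <- .cosine_to_query(table, gene)
  sims <- sims[names(sims) != gene]
  ord <- order(-sims, names(sims))
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(gene = names(sims)[top], similarity = unname(sims[top]))
}
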