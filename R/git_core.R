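# The genomic impact transformer (GIT).
#
# Encoder: each SGA-affected gene g of a tumor is looked up in an embedding
# table; a multi-head additive self-attention module scores every gene
# (u_h(g) = Theta_h . tanh(W0 e_g)), softmax-normalizes per head over the
# tumor's genes, averages heads, and scales by a trainable positive scalar
# eps, giving weights alpha_g with sum(alpha) = eps.  The tumor embedding is
#   e_t = 1 * e_s + sum_g alpha_g * e_g
# with the cancer-type embedding e_s entering at fixed weight 1.
# Decoder: yhat = sigmoid(W2 ReLU(W1 ReLU(e_t) + b1) + b2), trained with
# l2-regularized cross entropy.  All gradients are derived by hand and
# verified against central finite differences in the test suite.

#' GIT model configuration
#'
#' @param d embedding dimension.
#' @param heads number of attention heads H.
#' @param attention_hidden width of the shared attention projection (d_a).
#' @param decoder_hidden width of the decoder hidden layer.
#' @param dropout_rate dropout on the decoder hidden layer during training.
#' @param l2_lambda weight of the l2 regularizer (sum of Frobenius norms of
#'   the decoder matrices W1, W2).
#' @param use_cancer_type include the cancer-type embedding (the "can"
#'   ablation removes it).
#' @param use_attention use attention weights (the "attn" ablation replaces
#'   them with mean pooling, alpha_g = 1/m).
#' @param init_embeddings optional [embedding_table()] used to initialize
#'   gene embeddings (the "init" ablation omits it: seeded random init).
#' @param seed seed for parameter initialization.
#' @export
git_config <- function(d = 128, heads = 8, attention_hidden = 64,
                       decoder_hidden = 512, dropout_rate = 0.5,
                       l2_lambda = 1e-4, use_cancer_type = TRUE,
                       use_attention = TRUE, init_embeddings = NULL,
                       seed = 1) {
  stopifnot(d >= 1, heads >= 1, attention_hidden >= 1, decoder_hidden >= 1,
            dropout_rate >= 0, dropout_rate < 1, l2_lambda >= 0)
  structure(as.list(environment()), class = "git_config")
}

.xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a GIT model for a cohort
#'
#' @param cohort an `sga_cohort` supplying the vocabularies.
#' @param config a [git_config()].
#' @return a `git_model`: embedding table over genes and cancer types,
#'   attention parameters (`W0`, `Theta`, raw `eps`), and decoder weights.
#' @export
init_git_model <- function(cohort, config = git_config()) {
  genes <- cohort$gene_vocab
  types <- cohort$cancer_type_vocab
  if (length(intersect(genes, types)))
    stop("gene and cancer-type vocabularies overlap; identifiers must be disjoint")
  d <- config$d
  D <- length(cohort$deg_vocab)
  set.seed(config$seed)
  emb <- matrix(runif((length(genes) + length(types)) * d, -0.5 / d, 0.5 / d),
                length(genes) + length(types), d,
                dimnames = list(c(genes, types), NULL))
  if (!is.null(config$init_embeddings)) {
    tab <- config$init_embeddings
    if (ncol(tab) != d)
      stop("init_embeddings dimension ", ncol(tab), " != configured d = ", d)
    hit <- intersect(genes, rownames(tab))
    emb[hit, ] <- unclass(tab)[hit, , drop = FALSE]
  }
  model <- structure(
    list(emb = emb,
         W0 = .xavier(config$attention_hidden, d),
         Theta = .xavier(config$heads, config$attention_hidden),
         eps_raw = log(exp(1) - 1),  # softplus(eps_raw) = 1
         W1 = .xavier(config$decoder_hidden, d),
         b1 = numeric(config$decoder_hidden),
         W2 = .xavier(D, config$decoder_hidden),
         b2 = numeric(D),
         config = config,
         gene_vocab = genes,
         deg_vocab = cohort$deg_vocab,
         cancer_type_vocab = types),
    class = "git_model")
  model
}

#' @export
print.git_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<git_model> d=%d, %d heads (d_a=%d), decoder hidden=%d\n",
                     "  %d genes + %d cancer types, %d DEGs; eps=%.4f\n",
                     "  cancer type: %s, attention: %s\n"),
              cfg$d, cfg$heads, cfg$attention_hidden, cfg$decoder_hidden,
              length(x$gene_vocab), length(x$cancer_type_vocab),
              length(x$deg_vocab), softplus(x$eps_raw),
              if (cfg$use_cancer_type) "on" else "off (ablated)",
              if (cfg$use_attention) "on" else "off (mean pooling)"))
  invisible(x)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# ---------------------------------------------------------------------------
# Attention
# ---------------------------------------------------------------------------

# Full attention internals for one tumor; E_g is the m x d matrix of gene
# embeddings.  Returns alpha plus the tensors needed for backpropagation.
.attention_forward <- function(E_g, W0, Theta, eps) {
  U <- tanh(E_g %*% t(W0))            # m x d_a
  S <- U %*% t(Theta)                 # m x H, scores per head
  S <- sweep(S, 2, apply(S, 2, max))  # numerically stable softmax
  A <- exp(S)
  A <- sweep(A, 2, colSums(A), "/")   # per-head softmax over the m genes
  alpha <- eps * rowMeans(A)
  list(alpha = alpha, A = A, U = U)
}

#' Multi-head self-attention weights over a tumor's genes
#'
#' For each head h the score of gene g is `Theta[h,] . tanh(W0 e_g)`;
#' per-head weights are the softmax over the tumor's m genes; the final
#' weight is `eps` times the head average, so the weights are positive and
#' sum exactly to `eps`.
#'
#' @param gene_embeddings m x d matrix (one row per SGA-affected gene).
#' @param W0 d_a x d shared projection matrix.
#' @param Theta H x d_a per-head score vectors.
#' @param eps positive scalar scaling the total gene attention mass.
#' @return numeric vector of m positive weights summing to `eps`; empty for
#'   m = 0.
#' @export
attention_weights <- function(gene_embeddings, W0, Theta, eps = 1) {
  gene_embeddings <- rbind(gene_embeddings)
  if (nrow(gene_embeddings) == 0) return(numeric())
  stopifnot(eps > 0)
  unname(.attention_forward(gene_embeddings, W0, Theta, eps)$alpha)
}

# ---------------------------------------------------------------------------
# Encoder
# ---------------------------------------------------------------------------

#' Encode one tumor into its tumor embedding
#'
#' Computes `e_t = 1 * e_s + sum_g alpha_g e_g`.  With the attention module
#' ablated, `alpha_g = 1/m` (mean pooling); with the cancer-type input
#' ablated, `e_s` is replaced by zero.  A tumor with no SGAs encodes to
#' `e_s` exactly.
#'
#' @param model a `git_model`.
#' @param sga_genes character vector of SGA-affected genes (may be empty).
#' @param cancer_type cancer-type label.
#' @return list with `embedding` (length-d vector), `alphas` (named gene
#'   weights), and `cancer_type_weight` (always 1).
#' @export
encode_tumor <- function(model, sga_genes, cancer_type) {
  unknown <- setdiff(sga_genes, model$gene_vocab)
  if (length(unknown))
    stop("unknown gene(s): ", paste(head(unknown, 5), collapse = ", "))
  if (!cancer_type %in% model$cancer_type_vocab)
    stop("unknown cancer type: ", cancer_type)
  m <- length(sga_genes)
  d <- model$config$d
  et <- if (model$config$use_cancer_type) model$emb[cancer_type, ] else numeric(d)
  alphas <- setNames(numeric(0), character(0))
  if (m > 0) {
    E_g <- model$emb[sga_genes, , drop = FALSE]
    alpha <- if (model$config$use_attention)
      .attention_forward(E_g, model$W0, model$Theta, softplus(model$eps_raw))$alpha
    else rep(1 / m, m)
    et <- et + as.vector(crossprod(E_g, alpha))
    alphas <- setNames(alpha, sga_genes)
  }
  list(embedding = et, alphas = alphas, cancer_type_weight = 1)
}

# Batched encoder used by training and prediction.  sga_idx: list of integer
# vectors indexing rows of model$emb; type_idx: integer vector.  Returns ET
# (B x d) and, when keep = TRUE, the per-tumor stash for backprop.
.encode_batch <- function(model, sga_idx, type_idx, keep = FALSE) {
  B <- length(sga_idx)
  d <- model$config$d
  eps <- softplus(model$eps_raw)
  ET <- matrix(0, B, d)
  stash <- if (keep) vector("list", B)
  for (i in seq_len(B)) {
    idx <- sga_idx[[i]]
    m <- length(idx)
    et <- if (model$config$use_cancer_type) model$emb[type_idx[i], ] else numeric(d)
    if (m > 0) {
      E_g <- model$emb[idx, , drop = FALSE]
      if (model$config$use_attention) {
        at <- .attention_forward(E_g, model$W0, model$Theta, eps)
        alpha <- at$alpha
      } else {
        at <- NULL
        alpha <- rep(1 / m, m)
      }
      et <- et + as.vector(crossprod(E_g, alpha))
      if (keep) stash[[i]] <- list(idx = idx, E_g = E_g, alpha = alpha,
                                   A = at$A, U = at$U)
    } else if (keep) {
      stash[[i]] <- list(idx = idx)
    }
    ET[i, ] <- et
  }
  list(ET = ET, stash = stash)
}

# ---------------------------------------------------------------------------
# Decoder
# ---------------------------------------------------------------------------

#' Decode a tumor embedding into DEG probabilities
#'
#' `yhat = sigmoid(W2 ReLU(W1 ReLU(e_t) + b1) + b2)`; note the ReLU applied
#' to the tumor embedding itself before the hidden layer.  Dropout acts on
#' the hidden layer only, and only when `training = TRUE`.
#'
#' @param model a `git_model`.
#' @param e_t a length-d vector or a B x d matrix of tumor embeddings.
#' @param training apply dropout (stochastic) when TRUE.
#' @return probability vector over the DEG vocabulary (or B x D matrix).
#' @export
git_decode <- function(model, e_t, training = FALSE) {
  single <- is.null(dim(e_t))
  ET <- rbind(e_t)
  if (ncol(ET) != model$config$d)
    stop("tumor embedding has dimension ", ncol(ET), ", expected ",
         model$config$d)
  out <- .decode_batch(model, ET, training = training)$Yh
  colnames(out) <- model$deg_vocab
  if (single) out[1, ] else out
}

.decode_batch <- function(model, ET, training = FALSE) {
  R1 <- pmax(ET, 0)
  Z1 <- R1 %*% t(model$W1)
  Z1 <- sweep(Z1, 2, model$b1, "+")
  H1 <- pmax(Z1, 0)
  p <- model$config$dropout_rate
  M <- if (training && p > 0)
    matrix((runif(length(H1)) >= p) / (1 - p), nrow(H1), ncol(H1))
  else NULL
  Hd <- if (is.null(M)) H1 else H1 * M
  Z2 <- Hd %*% t(model$W2)
  Z2 <- sweep(Z2, 2, model$b2, "+")
  list(Yh = plogis(Z2), R1 = R1, Z1 = Z1, Hd = Hd, M = M)
}

# ---------------------------------------------------------------------------
# Loss
# ---------------------------------------------------------------------------

#' Regularized cross-entropy loss
#'
#' Cross entropy `-sum_i [(1-y_i) log(1-yhat_i) + y_i log yhat_i]` summed
#' over DEG coordinates, averaged over the batch, plus
#' `l2_lambda * (||W1||_2 + ||W2||_2)` over the decoder matrices
#' (Frobenius norms; biases unregularized).  Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param y binary vector or matrix of observed DEG labels.
#' @param yhat predicted probabilities, same shape.
#' @param model optional `git_model` supplying `l2_lambda` and the decoder
#'   matrices; omit for the bare cross entropy.
#' @export
git_loss <- function(y, yhat, model = NULL) {
  y <- rbind(y); yhat <- rbind(yhat)
  if (!identical(dim(y), dim(yhat)))
    stop("y and yhat have different shapes: ", paste(dim(y), collapse = "x"),
         " vs ", paste(dim(yhat), collapse = "x"))
  yhat <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  ce <- -sum((1 - y) * log(1 - yhat) + y * log(yhat)) / nrow(y)
  reg <- 0
  if (!is.null(model) && model$config$l2_lambda > 0)
    reg <- model$config$l2_lambda *
      (sqrt(sum(model$W1^2)) + sqrt(sum(model$W2^2)))
  ce + reg
}

# ---------------------------------------------------------------------------
# Forward pass over a cohort
# ---------------------------------------------------------------------------

.cohort_indices <- function(model, cohort) {
  unknown <- setdiff(unique(unlist(cohort$sga, use.names = FALSE)),
                     model$gene_vocab)
  if (length(unknown))
    stop("cohort contains genes unknown to the model: ",
         paste(head(unknown, 5), collapse = ", "))
  if (!all(cohort$cancer_type %in% model$cancer_type_vocab))
    stop("cohort contains cancer types unknown to the model")
  list(sga_idx = lapply(cohort$sga, function(g)
         match(g, rownames(model$emb))),
       type_idx = match(cohort$cancer_type, rownames(model$emb)))
}

#' Run the GIT model over a cohort
#'
#' @param model a `git_model`.
#' @param cohort an `sga_cohort` whose symbols are covered by the model.
#' @param training apply decoder dropout (stochastic) when TRUE; evaluation
#'   mode is fully deterministic.
#' @return list with `prob` (tumor x DEG probability matrix), `alphas`
#'   (per-tumor named attention weights), and `embeddings` (tumor x d
#'   matrix of tumor embeddings e_t).
#' @export
git_forward <- function(model, cohort, training = FALSE) {
  ix <- .cohort_indices(model, cohort)
  enc <- .encode_batch(model, ix$sga_idx, ix$type_idx, keep = TRUE)
  dec <- .decode_batch(model, enc$ET, training = training)
  prob <- dec$Yh
  dimnames(prob) <- list(cohort$tumor_id, model$deg_vocab)
  alphas <- lapply(seq_along(ix$sga_idx), function(i) {
    st <- enc$stash[[i]]
    if (length(st$idx)) setNames(st$alpha, rownames(model$emb)[st$idx])
    else setNames(numeric(0), character(0))
  })
  names(alphas) <- cohort$tumor_id
  emb <- enc$ET
  rownames(emb) <- cohort$tumor_id
  list(prob = prob, alphas = alphas, embeddings = emb)
}

#' @export
predict.git_model <- function(object, cohort, ...) {
  git_forward(object, cohort, training = FALSE)$prob
}

# ---------------------------------------------------------------------------
# Backward pass (hand-derived gradients)
# ---------------------------------------------------------------------------

# Loss and gradients for a batch given by integer positions into `prep`
# (precomputed cohort indices + label matrix).  training toggles dropout.
.git_loss_grads <- function(model, sga_idx, type_idx, Y, training = FALSE) {
  B <- length(sga_idx)
  enc <- .encode_batch(model, sga_idx, type_idx, keep = TRUE)
  dec <- .decode_batch(model, enc$ET, training = training)
  Yh <- dec$Yh
  Yc <- pmin(pmax(Yh, 1e-7), 1 - 1e-7)
  lambda <- model$config$l2_lambda
  n1 <- sqrt(sum(model$W1^2)); n2 <- sqrt(sum(model$W2^2))
  loss <- -sum((1 - Y) * log(1 - Yc) + Y * log(Yc)) / B + lambda * (n1 + n2)

  g <- list(emb = matrix(0, nrow(model$emb), ncol(model$emb)),
            W0 = matrix(0, nrow(model$W0), ncol(model$W0)),
            Theta = matrix(0, nrow(model$Theta), ncol(model$Theta)),
            eps_raw = 0,
            W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)

  dZ2 <- (Yh - Y) / B                       # B x D
  g$W2 <- crossprod(dZ2, dec$Hd)            # D x h
  g$b2 <- colSums(dZ2)
  dHd <- dZ2 %*% model$W2                   # B x h
  dH1 <- if (is.null(dec$M)) dHd else dHd * dec$M
  dZ1 <- dH1 * (dec$Z1 > 0)
  g$W1 <- crossprod(dZ1, dec$R1)            # h x d
  g$b1 <- colSums(dZ1)
  dR1 <- dZ1 %*% model$W1                   # B x d
  dET <- dR1 * (enc$ET > 0)

  if (lambda > 0) {
    if (n1 > 0) g$W1 <- g$W1 + lambda * model$W1 / n1
    if (n2 > 0) g$W2 <- g$W2 + lambda * model$W2 / n2
  }

  eps <- softplus(model$eps_raw)
  H <- model$config$heads
  for (i in seq_len(B)) {
    st <- enc$stash[[i]]
    det <- dET[i, ]
    if (model$config$use_cancer_type) {
      ti <- type_idx[i]
      g$emb[ti, ] <- g$emb[ti, ] + det
    }
    m <- length(st$idx)
    if (m == 0) next
    # e_t += sum alpha_g e_g
    g$emb[st$idx, ] <- g$emb[st$idx, ] + st$alpha %o% det
    dalpha <- as.vector(st$E_g %*% det)
    if (model$config$use_attention) {
      g$eps_raw <- g$eps_raw +
        sum(dalpha * (st$alpha / eps)) * plogis(model$eps_raw)
      dA <- matrix(dalpha * (eps / H), m, H)
      cs <- colSums(st$A * dA)
      dS <- st$A * sweep(dA, 2, cs)
      g$Theta <- g$Theta + crossprod(dS, st$U)       # H x d_a
      dU <- dS %*% model$Theta                       # m x d_a
      dZu <- dU * (1 - st$U^2)
      g$W0 <- g$W0 + crossprod(dZu, st$E_g)          # d_a x d
      g$emb[st$idx, ] <- g$emb[st$idx, ] + dZu %*% model$W0
    }
  }
  list(loss = loss, grads = g, Yh = Yh)
}

.param_names <- c("emb", "W0", "Theta", "eps_raw", "W1", "b1", "W2", "b2")

.flatten_params <- function(model) {
  unlist(lapply(.param_names, function(p) as.numeric(model[[p]])))
}

.set_params <- function(model, theta) {
  pos <- 0L
  for (p in .param_names) {
    n <- length(model[[p]])
    v <- theta[pos + seq_len(n)]
    model[[p]] <- if (is.matrix(model[[p]]))
      matrix(v, nrow(model[[p]]), ncol(model[[p]]),
             dimnames = dimnames(model[[p]]))
    else if (n == 1L) v else as.numeric(v)
    pos <- pos + n
  }
  model
}

# Central finite-difference check of every parameter group.  Returns the
# maximum relative error between analytic and numeric gradients.  The
# parameters are jittered to a generic point first: freshly initialized
# biases are exactly zero, which can park a whole ReLU row on its kink,
# where one-sided and two-sided derivatives legitimately differ.
git_gradient_check <- function(model, cohort, h = 1e-4, jitter = 0.05,
                               seed = 1) {
  if (jitter > 0) {
    set.seed(seed)
    theta0 <- .flatten_params(model)
    model <- .set_params(model, theta0 + rnorm(length(theta0), 0, jitter))
  }
  ix <- .cohort_indices(model, cohort)
  Y <- cohort$deg
  ana <- .git_loss_grads(model, ix$sga_idx, ix$type_idx, Y, training = FALSE)
  ga <- unlist(lapply(.param_names, function(p) as.numeric(ana$grads[[p]])))
  theta <- .flatten_params(model)
  gn <- numeric(length(theta))
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + h
    lp <- .git_loss_grads(.set_params(model, tp), ix$sga_idx, ix$type_idx,
                          Y, training = FALSE)$loss
    tm <- theta; tm[j] <- tm[j] - h
    lm <- .git_loss_grads(.set_params(model, tm), ix$sga_idx, ix$type_idx,
                          Y, training = FALSE)$loss
    gn[j] <- (lp - lm) / (2 * h)
  }
  denom <- pmax(abs(ga) + abs(gn), 1e-6)
  max(abs(ga - gn) / denom)
}

# ---------------------------------------------------------------------------
# Checkpointing
# ---------------------------------------------------------------------------

#' Save / load a GIT model checkpoint
#'
#' The checkpoint holds the configuration, the vocabularies and every
#' parameter array; reloading reproduces evaluation-mode outputs bit for
#' bit.
#' @param model a `git_model`.
#' @param path file path.
#' @export
save_git_model <- function(model, path) {
  stopifnot(inherits(model, "git_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_git_model
#' @export
load_git_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "git_model")) stop("not a git_model checkpoint: ", path)
  model
}
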