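# Training loops, splits, baselines and classification metrics.

#' Train/validation/test split specification
#'
#' @param fractions named numeric vector `c(train=, valid=, test=)` summing
#'   to 1; default equal thirds.
#' @param seed shuffle seed; the assignment is fixed once created and is
#'   shared across all models compared on the cohort.
#' @export
split_spec <- function(fractions = c(train = 1/3, valid = 1/3, test = 1/3),
                       seed = 1) {
  if (length(fractions) != 3 || is.null(names(fractions)) ||
      !identical(sort(names(fractions)), c("test", "train", "valid")))
    stop("fractions must be a named vector with train, valid, test")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (any(fractions <= 0)) stop("fractions must be positive")
  structure(list(fractions = fractions[c("train", "valid", "test")],
                 seed = seed), class = "split_spec")
}

#' Split a cohort into train/validation/test sets
#'
#' Seeded shuffle, stratified by cancer type: tumors are ordered by type
#' (shuffled within type) and group labels are dealt by a greedy quota rule,
#' so group sizes are exact when attainable and every cancer type is spread
#' across the groups.
#'
#' @param cohort an `sga_cohort` with at least 3 tumors.
#' @param spec a [split_spec()].
#' @return list with cohorts `train`, `valid`, `test` and the named
#'   `assignment` factor.
#' @export
make_split <- function(cohort, spec = split_spec()) {
  n <- n_tumors(cohort)
  if (n < 3) stop("need at least 3 tumors to split, got ", n)
  set.seed(spec$seed)
  ord <- order(cohort$cancer_type, sample.int(n))
  fr <- spec$fractions
  # global targets by largest remainder
  raw <- fr * n
  target <- floor(raw)
  rem <- n - sum(target)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    target[extra] <- target[extra] + 1L
  }
  groups <- names(fr)
  assigned <- setNames(numeric(3), groups)
  lab <- character(n)
  for (i in seq_len(n)) {
    deficit <- fr * i - assigned
    deficit[assigned >= target] <- -Inf
    g <- groups[which.max(deficit)]
    lab[ord[i]] <- g
    assigned[g] <- assigned[g] + 1
  }
  assignment <- factor(setNames(lab, cohort$tumor_id),
                       levels = c("train", "valid", "test"))
  list(train = cohort[which(lab == "train")],
       valid = cohort[which(lab == "valid")],
       test = cohort[which(lab == "test")],
       assignment = assignment)
}

#' Optimization configuration
#'
#' @param optimizer `"adam"` (default momentum parameters) or `"sgd"`.
#' @param learning_rate step size.
#' @param batch_size mini-batch size (tumors).
#' @param max_epochs training epochs; model selection picks the epoch with
#'   the best validation F1.
#' @param weight_decay optional additive l2 weight decay inside the
#'   optimizer (distinct from the model's `l2_lambda` loss term).
#' @param runs number of repeated runs used by [ablation_suite()].
#' @param seed seed for shuffling, dropout and repeats.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 5e-3,
                         batch_size = 64, max_epochs = 40, weight_decay = 0,
                         runs = 5, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            weight_decay >= 0, runs >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 weight_decay = weight_decay, runs = runs, seed = seed),
            class = "train_config")
}

# --- optimizer -------------------------------------------------------------

.adam_init <- function(model)
  list(m = lapply(model[.param_names], function(p) p * 0),
       v = lapply(model[.param_names], function(p) p * 0),
       t = 0L)

.opt_step <- function(model, grads, state, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer == "sgd") {
    for (p in .param_names) {
      g <- grads[[p]]
      if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * model[[p]]
      model[[p]] <- model[[p]] - lr * g
    }
    return(list(model = model, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; e <- 1e-8
  state$t <- state$t + 1L
  for (p in .param_names) {
    g <- grads[[p]]
    if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * model[[p]]
    state$m[[p]] <- b1 * state$m[[p]] + (1 - b1) * g
    state$v[[p]] <- b2 * state$v[[p]] + (1 - b2) * g^2
    mh <- state$m[[p]] / (1 - b1^state$t)
    vh <- state$v[[p]] / (1 - b2^state$t)
    model[[p]] <- model[[p]] - lr * mh / (sqrt(vh) + e)
  }
  list(model = model, state = state)
}

# Drop symbols a model does not know, with a warning (validation/test
# cohorts may contain rare symbols absent from the training vocabulary).
.conform_cohort <- function(cohort, gene_vocab, type_vocab, deg_vocab) {
  if (!identical(cohort$deg_vocab, deg_vocab))
    stop("DEG vocabularies differ between cohorts")
  bad_genes <- setdiff(unique(unlist(cohort$sga, use.names = FALSE)),
                       gene_vocab)
  if (length(bad_genes)) {
    warning("dropping ", length(bad_genes),
            " gene(s) unknown to the model: ",
            paste(head(bad_genes, 5), collapse = ", "))
    cohort$sga <- lapply(cohort$sga, setdiff, y = bad_genes)
  }
  keep <- cohort$cancer_type %in% type_vocab
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " tumor(s) with unknown cancer type")
    cohort <- cohort[which(keep)]
  }
  cohort
}

#' Train a GIT model
#'
#' Mini-batch training of the full model (embeddings, attention, decoder)
#' by backpropagation; per-epoch training loss and validation F1 are
#' logged, and the parameters of the best-validation-F1 epoch are returned.
#'
#' @param train,valid training and validation `sga_cohort`s (symbols of
#'   `valid` unknown to `train` are dropped with a warning).
#' @param git_config a [git_config()].
#' @param train_config a [train_config()].
#' @param threshold probability threshold used for the validation F1.
#' @param verbose emit a per-epoch record (loss, validation F1) to stderr.
#' @return a `git_fit`: list with `model` (best checkpoint), `log`
#'   (data.frame epoch/train_loss/valid_f1) and `best_epoch`.
#' @export
train_git <- function(train, valid, git_config = git_config(),
                      train_config = train_config(), threshold = 0.5,
                      verbose = FALSE) {
  model <- init_git_model(train, git_config)
  valid <- .conform_cohort(valid, model$gene_vocab, model$cancer_type_vocab,
                           model$deg_vocab)
  set.seed(train_config$seed)
  ix <- .cohort_indices(model, train)
  Y <- train$deg
  n <- n_tumors(train)
  state <- .adam_init(model)
  best_f1 <- -Inf; best <- model; best_epoch <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    valid_f1 = numeric())
  for (ep in seq_len(train_config$max_epochs)) {
    ordr <- sample.int(n)
    starts <- seq(1L, n, by = train_config$batch_size)
    tot <- 0
    for (s in starts) {
      b <- ordr[s:min(s + train_config$batch_size - 1L, n)]
      res <- .git_loss_grads(model, ix$sga_idx[b], ix$type_idx[b],
                             Y[b, , drop = FALSE], training = TRUE)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      tot <- tot + res$loss * length(b)
      upd <- .opt_step(model, res$grads, state, train_config)
      model <- upd$model; state <- upd$state
    }
    vf1 <- evaluate_model(model, valid, threshold = threshold)$f1
    log <- rbind(log, data.frame(epoch = ep, train_loss = tot / n,
                                 valid_f1 = vf1))
    if (verbose)
      message(sprintf("epoch %3d | train loss %.5f | valid F1 %.4f",
                      ep, tot / n, vf1))
    if (vf1 > best_f1) {
      best_f1 <- vf1; best <- model; best_epoch <- ep
    }
  }
  structure(list(model = best, log = log, best_epoch = best_epoch),
            class = "git_fit")
}

#' @export
print.git_fit <- function(x, ...) {
  cat(sprintf("<git_fit> %d epochs; best validation F1 %.4f at epoch %d\n",
              nrow(x$log), max(x$log$valid_f1), x$best_epoch))
  invisible(x)
}

#' @export
predict.git_fit <- function(object, cohort, ...) predict(object$model, cohort)

# ---------------------------------------------------------------------------
# Metrics
# ---------------------------------------------------------------------------

.micro_metrics <- function(Y, P, threshold) {
  pred <- P >= threshold
  tp <- sum(pred & Y == 1); fp <- sum(pred & Y == 0)
  fn <- sum(!pred & Y == 1); tn <- sum(!pred & Y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / (tp + fp + fn + tn),
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("precision %.4f | recall %.4f | F1 %.4f | accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Evaluate DEG predictions on a cohort
#'
#' Micro-averaged over all tumor-by-DEG cells: predictions `yhat >=
#' threshold` are compared to the labels through a single global confusion
#' matrix.
#'
#' @param model a `git_model`, `git_fit`, or baseline model with a
#'   `predict(model, cohort)` method returning a probability matrix.
#' @param cohort evaluation cohort (non-empty).
#' @param threshold binarization threshold in (0,1).
#' @return a `metric_report` with precision, recall, f1, accuracy and the
#'   confusion counts.
#' @export
evaluate_model <- function(model, cohort, threshold = 0.5) {
  if (n_tumors(cohort) == 0) stop("cannot evaluate on an empty cohort")
  stopifnot(threshold > 0, threshold < 1)
  P <- predict(model, cohort)
  .micro_metrics(cohort$deg, P, threshold)
}

# ---------------------------------------------------------------------------
# Baselines: per-DEG lasso logistic regression and plain MLPs on the binary
# SGA indicator matrix (plus one-hot cancer type).
# ---------------------------------------------------------------------------

.design_matrix <- function(cohort) {
  genes <- cohort$gene_vocab; types <- cohort$cancer_type_vocab
  n <- n_tumors(cohort)
  ii <- rep(seq_len(n), lengths(cohort$sga))
  jj <- match(unlist(cohort$sga, use.names = FALSE), genes)
  X <- Matrix::sparseMatrix(
    i = c(ii, seq_len(n)),
    j = c(jj, length(genes) + match(cohort$cancer_type, types)),
    x = 1, dims = c(n, length(genes) + length(types)),
    dimnames = list(cohort$tumor_id, c(genes, paste0("type:", types))))
  X
}

#' Train a baseline DEG predictor
#'
#' `"lasso"` fits an independent l1-penalized logistic regression per DEG
#' gene on the binary SGA indicators plus one-hot cancer type; the penalty
#' is chosen on validation micro-F1 over a small logarithmic grid (shared
#' across DEGs).  `"mlp1"`/`"mlp2"`/`"mlp3"` are feed-forward ReLU networks
#' with 1-3 hidden layers on the same input, trained with Adam and
#' selected by validation F1.
#'
#' @param kind one of `"lasso"`, `"mlp1"`, `"mlp2"`, `"mlp3"`.
#' @param train,valid cohorts.
#' @param train_config a [train_config()] (used by the MLPs).
#' @param hidden hidden-layer width of the MLP baselines.
#' @param lambda_grid penalty grid for the lasso.
#' @param threshold validation threshold.
#' @return a model with a `predict(model, cohort)` method.
#' @export
train_baseline <- function(kind, train, valid,
                           train_config = train_config(), hidden = 64,
                           lambda_grid = 10^seq(-1.5, -3.5, length.out = 9),
                           threshold = 0.5) {
  kinds <- c("lasso", "mlp1", "mlp2", "mlp3")
  if (!kind %in% kinds)
    stop("unknown baseline kind '", kind, "'; expected one of ",
         paste(kinds, collapse = ", "))
  valid <- .conform_cohort(valid, train$gene_vocab, train$cancer_type_vocab,
                           train$deg_vocab)
  if (kind == "lasso")
    .train_lasso(train, valid, lambda_grid, threshold)
  else
    .train_mlp(train, valid, n_layers = as.integer(substring(kind, 4)),
               hidden = hidden, cfg = train_config, threshold = threshold)
}

.train_lasso <- function(train, valid, lambda_grid, threshold) {
  X <- .design_matrix(train)
  Xv <- .design_matrix(valid)
  Y <- train$deg
  D <- ncol(Y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  nl <- length(lambda_grid)
  coefs <- vector("list", nl)  # per lambda: (p+1) x D coefficient matrix
  for (l in seq_len(nl))
    coefs[[l]] <- matrix(0, ncol(X) + 1L, D)
  for (j in seq_len(D)) {
    y <- Y[, j]
    if (min(tabulate(y + 1L, 2L)) < 8) {  # too rare for a stable fit:
      # fall back to the intercept-only model (glmnet itself flags
      # classes below 8 observations)
      p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
      for (l in seq_len(nl)) coefs[[l]][1, j] <- qlogis(p0)
      next
    }
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                          lambda = lambda_grid, standardize = FALSE)
    cf <- as.matrix(rbind(fit$a0, fit$beta))
    got <- match(signif(fit$lambda, 8), signif(lambda_grid, 8))
    for (k in seq_along(got))
      if (!is.na(got[k])) coefs[[got[k]]][, j] <- cf[, k]
  }
  f1s <- vapply(seq_len(nl), function(l) {
    P <- plogis(as.matrix(Xv %*% coefs[[l]][-1, ]) +
                  rep(coefs[[l]][1, ], each = nrow(Xv)))
    .micro_metrics(valid$deg, P, threshold)$f1
  }, 0)
  best <- which.max(f1s)
  structure(list(coef = coefs[[best]], lambda = lambda_grid[best],
                 valid_f1 = f1s, lambda_grid = lambda_grid,
                 gene_vocab = train$gene_vocab,
                 cancer_type_vocab = train$cancer_type_vocab,
                 deg_vocab = train$deg_vocab),
            class = "baseline_lasso")
}

#' @export
predict.baseline_lasso <- function(object, cohort, ...) {
  cohort <- suppressWarnings(
    .conform_cohort(cohort, object$gene_vocab, object$cancer_type_vocab,
                    object$deg_vocab))
  X <- .design_matrix(cohort)
  P <- plogis(as.matrix(X %*% object$coef[-1, ]) +
                rep(object$coef[1, ], each = nrow(X)))
  dimnames(P) <- list(cohort$tumor_id, object$deg_vocab)
  P
}

.train_mlp <- function(train, valid, n_layers, hidden, cfg, threshold) {
  X <- as.matrix(.design_matrix(train))
  Xv <- as.matrix(.design_matrix(valid))
  Y <- train$deg; Yv <- valid$deg
  set.seed(cfg$seed)
  sizes <- c(ncol(X), rep(hidden, n_layers), ncol(Y))
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- .xavier(sizes[l + 1L], sizes[l])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  L <- length(W)
  mW <- lapply(W, `*`, 0); vW <- mW; mb <- lapply(b, `*`, 0); vb <- mb
  t_ad <- 0L; b1 <- 0.9; b2 <- 0.999
  n <- nrow(X)
  best_f1 <- -Inf; bestW <- W; bestb <- b
  forward <- function(W, b, X) {
    A <- X
    for (l in seq_len(L - 1L))
      A <- pmax(sweep(A %*% t(W[[l]]), 2, b[[l]], "+"), 0)
    plogis(sweep(A %*% t(W[[L]]), 2, b[[L]], "+"))
  }
  for (ep in seq_len(cfg$max_epochs)) {
    ordr <- sample.int(n)
    for (s in seq(1L, n, by = cfg$batch_size)) {
      bidx <- ordr[s:min(s + cfg$batch_size - 1L, n)]
      A <- list(X[bidx, , drop = FALSE])
      Z <- list()
      for (l in seq_len(L - 1L)) {
        Z[[l]] <- sweep(A[[l]] %*% t(W[[l]]), 2, b[[l]], "+")
        A[[l + 1L]] <- pmax(Z[[l]], 0)
      }
      Yh <- plogis(sweep(A[[L]] %*% t(W[[L]]), 2, b[[L]], "+"))
      if (!all(is.finite(Yh)))
        stop("baseline MLP diverged at epoch ", ep)
      dZ <- (Yh - Y[bidx, , drop = FALSE]) / length(bidx)
      t_ad <- t_ad + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(dZ, A[[l]]); gb <- colSums(dZ)
        if (l > 1L) dZ <- (dZ %*% W[[l]]) * (Z[[l - 1L]] > 0)
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        W[[l]] <- W[[l]] - cfg$learning_rate *
          (mW[[l]] / (1 - b1^t_ad)) / (sqrt(vW[[l]] / (1 - b2^t_ad)) + 1e-8)
        b[[l]] <- b[[l]] - cfg$learning_rate *
          (mb[[l]] / (1 - b1^t_ad)) / (sqrt(vb[[l]] / (1 - b2^t_ad)) + 1e-8)
      }
    }
    f1 <- .micro_metrics(Yv, forward(W, b, Xv), threshold)$f1
    if (f1 > best_f1) { best_f1 <- f1; bestW <- W; bestb <- b }
  }
  structure(list(W = bestW, b = bestb, n_layers = n_layers,
                 gene_vocab = train$gene_vocab,
                 cancer_type_vocab = train$cancer_type_vocab,
                 deg_vocab = train$deg_vocab, valid_f1 = best_f1),
            class = "baseline_mlp")
}

#' @export
predict.baseline_mlp <- function(object, cohort, ...) {
  cohort <- suppressWarnings(
    .conform_cohort(cohort, object$gene_vocab, object$cancer_type_vocab,
                    object$deg_vocab))
  A <- as.matrix(.design_matrix(cohort))
  L <- length(object$W)
  for (l in seq_len(L - 1L))
    A <- pmax(sweep(A %*% t(object$W[[l]]), 2, object$b[[l]], "+"), 0)
  P <- plogis(sweep(A %*% t(object$W[[L]]), 2, object$b[[L]], "+"))
  dimnames(P) <- list(cohort$tumor_id, object$deg_vocab)
  P
}

# ---------------------------------------------------------------------------
# Ablation suite
# ---------------------------------------------------------------------------

.git_variant_config <- function(base, variant, init) {
  cfg <- base
  cfg$init_embeddings <- init
  switch(variant,
         "git" = cfg,
         "git-can" = { cfg$use_cancer_type <- FALSE; cfg },
         "git-attn" = { cfg$use_attention <- FALSE; cfg },
         "git-init" = { cfg$init_embeddings <- NULL; cfg },
         stop("unknown GIT variant: ", variant))
}

#' Run the model-comparison and ablation suite
#'
#' Trains the requested model variants on one fixed split (the same split
#' for every variant) over `runs` repeated seeds and reports the mean and
#' variance of each test metric.  GIT variants: `"git"` (full model),
#' `"git-can"` (no cancer-type input), `"git-attn"` (mean pooling instead
#' of attention), `"git-init"` (random instead of pre-trained embedding
#' initialization); baselines: `"lasso"`, `"mlp1"`, `"mlp2"`, `"mlp3"`.
#'
#' @param cohort the full cohort.
#' @param variants character vector of variants to run.
#' @param git_config,train_config,g2v_config configurations; Gene2Vec
#'   pre-training (run once per seed on the whole cohort) supplies the
#'   initialization of the `git`, `git-can` and `git-attn` variants.
#' @param split a [split_spec()].
#' @param threshold binarization threshold.
#' @return an `ablation_table`: data.frame with one row per variant
#'   (mean/var of each metric over runs); per-run results in
#'   `attr(, "runs")`.
#' @export
ablation_suite <- function(cohort,
                           variants = c("git", "git-can", "git-attn",
                                        "git-init", "lasso", "mlp1", "mlp2",
                                        "mlp3"),
                           git_config = git_config(),
                           train_config = train_config(),
                           g2v_config = gene2vec_config(d = git_config$d),
                           split = split_spec(), threshold = 0.5) {
  if (g2v_config$d != git_config$d)
    stop("gene2vec dimension must match git_config$d")
  sp <- make_split(cohort, split)
  git_variants <- intersect(variants, c("git", "git-can", "git-attn",
                                        "git-init"))
  need_init <- length(setdiff(git_variants, "git-init")) > 0
  per_run <- list()
  for (r in seq_len(train_config$runs)) {
    seed_r <- train_config$seed + r - 1L
    init <- if (need_init) {
      g2v <- g2v_config; g2v$seed <- seed_r
      pretrain_gene2vec(cohort, g2v)
    }
    for (v in variants) {
      model <- if (v %in% git_variants) {
        gcfg <- .git_variant_config(git_config, v, init)
        gcfg$seed <- seed_r
        tcfg <- train_config; tcfg$seed <- seed_r
        train_git(sp$train, sp$valid, gcfg, tcfg, threshold = threshold)
      } else {
        tcfg <- train_config; tcfg$seed <- seed_r
        train_baseline(v, sp$train, sp$valid, train_config = tcfg,
                       threshold = threshold)
      }
      met <- evaluate_model(model, sp$test, threshold = threshold)
      per_run[[length(per_run) + 1L]] <-
        data.frame(variant = v, run = r, precision = met$precision,
                   recall = met$recall, f1 = met$f1,
                   accuracy = met$accuracy)
    }
  }
  runs_df <- do.call(rbind, per_run)
  agg <- function(f) sapply(split(runs_df, runs_df$variant), function(d)
    sapply(d[c("precision", "recall", "f1", "accuracy")], f))
  mu <- agg(mean); va <- agg(function(x) if (length(x) > 1) var(x) else 0)
  out <- data.frame(variant = colnames(mu), t(mu),
                    f1_var = va["f1", ], accuracy_var = va["accuracy", ],
                    row.names = NULL)
  out <- out[match(intersect(variants, out$variant), out$variant), ]
  attr(out, "runs") <- runs_df
  class(out) <- c("ablation_table", "data.frame")
  out
}
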