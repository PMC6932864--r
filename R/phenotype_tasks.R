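# Downstream phenotype pipelines: tumor-embedding extraction and
# stratification, tumor clustering, survival modeling, and drug-response
# classification.

#' Extract tumor embeddings from a trained model
#'
#' Evaluation-mode encoding of every tumor.  Variants: `"full"` is the raw
#' tumor embedding `e_t`; `"stratified"` subtracts the cancer-type
#' embedding (`e_t - e_s`), removing the tissue component so tumors with
#' identical SGA impact coincide regardless of cancer type; `"tanh"`
#' applies `tanh(e_t)` elementwise (the representation used for
#' drug-response classification).
#'
#' @param model a `git_model` or `git_fit`.
#' @param cohort cohort to encode.
#' @param variant `"full"`, `"stratified"` or `"tanh"`.
#' @return tumor x d matrix (rownames = tumor ids) with attribute
#'   `variant`.
#' @export
extract_embeddings <- function(model, cohort,
                               variant = c("full", "stratified", "tanh")) {
  variant <- match.arg(variant)
  if (inherits(model, "git_fit")) model <- model$model
  E <- git_forward(model, cohort, training = FALSE)$embeddings
  if (variant == "stratified")
    E <- E - model$emb[cohort$cancer_type, , drop = FALSE]
  else if (variant == "tanh")
    E <- tanh(E)
  attr(E, "variant") <- variant
  E
}

#' Cluster tumors in embedding space
#'
#' Seeded k-means with `nstart` restarts (best inertia kept).
#' @param matrix tumor x d embedding matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return named integer cluster labels.
#' @export
cluster_tumors <- function(matrix, k, seed = 1, nstart = 10) {
  cl <- .seeded_kmeans(matrix, k, seed = seed, nstart = nstart)$cluster
  setNames(cl, rownames(matrix))
}

# Hartigan-Wong refuses k == nrow(x); fall back to Lloyd there.
.seeded_kmeans <- function(x, k, seed, nstart) {
  set.seed(seed)
  kmeans(x, centers = k, nstart = nstart, iter.max = 100,
         algorithm = if (k >= nrow(x)) "Lloyd" else "Hartigan-Wong")
}

.fold_assign <- function(n, folds, strata = NULL) {
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Survival prediction from tumor embeddings
#'
#' Elastic-net Cox proportional hazards models are fit in a k-fold
#' cross-validation: each fold's risk scores come from a model trained on
#' the other folds (penalty chosen by inner cross-validation), the
#' out-of-fold scores are pooled, and the overall concordance index is
#' computed on the pooled scores.  Tumors are then split at the median risk
#' into two groups compared by a log-rank test.
#'
#' @param matrix tumor x d feature matrix (e.g. [extract_embeddings()]).
#' @param survival data.frame with `tumor_id`, `time`, `event` covering all
#'   rows of `matrix`.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed RNG seed for fold assignment and the inner CV.
#' @param alpha elastic-net mixing parameter (0 = ridge, 1 = lasso).
#' @return list with `concordance` (pooled CI), `risk` (named out-of-fold
#'   scores, higher = shorter predicted survival), `logrank_p` (median-split
#'   log-rank p-value) and `group` (median-split labels).
#' @export
survival_pipeline <- function(matrix, survival, folds = 10, seed = 1,
                              alpha = 0.5) {
  if (folds < 2) stop("folds must be at least 2")
  ids <- rownames(matrix)
  j <- match(ids, survival$tumor_id)
  if (anyNA(j))
    stop("survival entries missing for: ",
         paste(head(ids[is.na(j)], 5), collapse = ", "))
  time <- survival$time[j]; event <- survival$event[j]
  if (all(event == 0))
    stop("all observations censored; concordance undefined")
  set.seed(seed)
  fold <- .fold_assign(length(ids), folds, strata = event)
  risk <- numeric(length(ids))
  X <- as.matrix(matrix)
  for (f in seq_len(folds)) {
    tr <- fold != f
    risk[!tr] <- tryCatch({
      cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE],
                              survival::Surv(time[tr], event[tr]),
                              family = "cox", alpha = alpha, nfolds = 5)
      as.numeric(predict(cv, newx = X[!tr, , drop = FALSE],
                         s = "lambda.min"))
    }, error = function(e) rep(0, sum(!tr)))  # null model: constant risk
  }
  names(risk) <- ids
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  group <- factor(ifelse(risk > median(risk), "high_risk", "low_risk"))
  logrank_p <- if (nlevels(droplevels(group)) == 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  } else NA_real_
  list(concordance = unname(cc$concordance), risk = risk,
       logrank_p = logrank_p, group = group)
}

#' Cross-validated drug-response classification
#'
#' For each drug with enough labeled samples in both classes, an
#' l1-regularized logistic regression (lasso) is trained in a k-fold
#' cross-validation on the given feature representation (tanh-curved tumor
#' embeddings or the raw binary SGA matrix); out-of-fold predicted
#' probabilities are pooled into one ROC curve and AUC per drug.
#'
#' @param features sample x feature matrix (dense or sparse), rownames =
#'   sample ids.
#' @param responses binary matrix (samples x drugs, NA = unlabeled) as from
#'   [read_drug_response_table()], or a named 0/1 vector for a single drug.
#' @param folds cross-validation folds.
#' @param seed RNG seed.
#' @param min_per_class minimum labeled samples required per class; drugs
#'   below it are skipped with a warning.
#' @return named list per evaluated drug: `auc`, `n`, `prob` (named
#'   out-of-fold probabilities), `labels`, and `roc` (data.frame `fpr`,
#'   `tpr`, `threshold`).
#' @export
drug_response_pipeline <- function(features, responses, folds = 10, seed = 1,
                                   min_per_class = 10) {
  if (is.vector(responses))
    responses <- matrix(responses, ncol = 1,
                        dimnames = list(names(responses), "drug"))
  out <- list()
  for (drug in colnames(responses)) {
    y_all <- responses[, drug]
    ids <- intersect(rownames(features), names(y_all)[!is.na(y_all)])
    y <- y_all[ids]
    if (min(sum(y == 1), sum(y == 0)) < min_per_class) {
      warning("skipping drug '", drug, "': fewer than ", min_per_class,
              " labeled samples in a class")
      next
    }
    set.seed(seed)
    fold <- .fold_assign(length(ids), folds, strata = y)
    X <- features[ids, , drop = FALSE]
    prob <- numeric(length(ids))
    for (f in seq_len(folds)) {
      tr <- fold != f
      prob[!tr] <- tryCatch({
        cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                                family = "binomial", alpha = 1, nfolds = 5)
        as.numeric(predict(cv, newx = X[!tr, , drop = FALSE],
                           s = "lambda.min", type = "response"))
      }, error = function(e) rep(mean(y[tr]), sum(!tr)))
    }
    names(prob) <- ids
    roc <- pROC::roc(response = y, predictor = prob, levels = c(0, 1),
                     direction = "<", quiet = TRUE)
    out[[drug]] <- list(
      auc = as.numeric(pROC::auc(roc)), n = length(ids), prob = prob,
      labels = y,
      roc = data.frame(fpr = rev(1 - roc$specificities),
                       tpr = rev(roc$sensitivities),
                       threshold = rev(roc$thresholds)))
  }
  out
}

#' Binary SGA indicator matrix of a cohort
#'
#' The raw sparse representation used as the baseline feature set for
#' drug-response prediction (gene columns only, no cancer-type one-hot).
#' @param cohort an `sga_cohort`.
#' @export
sga_matrix <- function(cohort) {
  n <- n_tumors(cohort)
  ii <- rep(seq_len(n), lengths(cohort$sga))
  jj <- match(unlist(cohort$sga, use.names = FALSE), cohort$gene_vocab)
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n, length(cohort$gene_vocab)),
                       dimnames = list(cohort$tumor_id, cohort$gene_vocab))
}
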