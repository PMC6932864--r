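test_that("splits are exact, disjoint, exhaustive and reproducible", {
  co <- tiny_cohort(seed = 1, n_tumors = 300)
  sp <- make_split(co, split_spec(seed = 4))
  expect_equal(n_tumors(sp$train), 100)
  expect_equal(n_tumors(sp$valid), 100)
  expect_equal(n_tumors(sp$test), 100)
  ids <- c(sp$train$tumor_id, sp$valid$tumor_id, sp$test$tumor_id)
  expect_setequal(ids, co$tumor_id)
  expect_equal(anyDuplicated(ids), 0L)
  sp2 <- make_split(co, split_spec(seed = 4))
  expect_identical(sp$assignment, sp2$assignment)
  # stratified: each cancer type lands in each group in near-equal shares
  tab <- table(co$cancer_type, sp$assignment)
  expect_true(all(abs(tab - rowSums(tab) / 3) <= 1))
  expect_error(make_split(co[1:2]), "at least 3")
  expect_error(split_spec(c(train = 0.6, valid = 0.3, test = 0.2)), "sum to 1")
})

test_that("micro-averaged metrics match closed-form confusion counts", {
  mm <- gitnet:::.micro_metrics
  # TP=2 FP=1 FN=1 TN=6
  y <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2, 5)
  p <- matrix(c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.2, 0.3, 0.2, 0.1), 2, 5)
  m <- mm(y, p, 0.5)
  expect_equal(m$counts, c(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  # perfect predictions
  perf <- mm(y, y, 0.5)
  expect_equal(c(perf$precision, perf$recall, perf$f1, perf$accuracy),
               rep(1, 4))
  # all-negative predictor on 10% positives: accuracy .9, recall 0, F1 0
  y2 <- matrix(c(1, rep(0, 9)), 1)
  neg <- mm(y2, matrix(0, 1, 10), 0.5)
  expect_equal(neg$accuracy, 0.9)
  expect_equal(neg$recall, 0)
  expect_equal(neg$f1, 0)
})

test_that("GIT training lowers the loss and is reproducible seed for seed", {
  co <- tiny_cohort(seed = 10, n_tumors = 90)
  sp <- make_split(co, split_spec(seed = 1))
  tcfg <- train_config(max_epochs = 8, batch_size = 16, seed = 5)
  fit1 <- train_git(sp$train, sp$valid, tiny_git_config(), tcfg)
  fit2 <- train_git(sp$train, sp$valid, tiny_git_config(), tcfg)
  expect_lt(fit1$log$train_loss[8], fit1$log$train_loss[1])
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$model, fit2$model)
  met <- evaluate_model(fit1, sp$test)
  expect_true(all(unlist(met[c("precision", "recall", "f1", "accuracy")]) >= 0))
  expect_error(evaluate_model(fit1, sp$test[integer()]), "empty")
})

test_that("lasso recovers a planted one-driver signal as the top coefficient", {
  set.seed(3)
  n <- 120
  ids <- sprintf("t%03d", 1:n)
  genes <- sprintf("g%02d", 1:10)
  sga <- lapply(1:n, function(i) sort(sample(genes, 3)))
  y <- vapply(sga, function(g) as.integer("g05" %in% g), 0L)
  deg <- cbind(d1 = y, d2 = 0L)
  rownames(deg) <- ids
  co <- new_cohort(ids, rep("ct1", n), sga, deg)
  sp <- make_split(co, split_spec(seed = 2))
  fit <- train_baseline("lasso", sp$train, sp$valid)
  beta <- fit$coef[-1, 1]  # coefficients for DEG d1
  names(beta) <- c(genes, "type:ct1")
  expect_equal(names(which.max(abs(beta))), "g05")
  met <- evaluate_model(fit, sp$test)
  expect_gt(met$f1, 0.95)
})

test_that("MLP baselines train and produce valid metric reports", {
  co <- tiny_cohort(seed = 12, n_tumors = 90)
  sp <- make_split(co, split_spec(seed = 3))
  tcfg <- train_config(max_epochs = 15, batch_size = 16, seed = 1)
  for (kind in c("mlp1", "mlp2")) {
    fit <- train_baseline(kind, sp$train, sp$valid, train_config = tcfg,
                          hidden = 16)
    met <- evaluate_model(fit, sp$test)
    expect_true(met$f1 >= 0 && met$f1 <= 1)
    expect_true(met$accuracy > 0.5)  # majority class is negative
  }
  expect_error(train_baseline("boost", sp$train, sp$valid), "unknown baseline")
})

test_that("the ablation suite reports the requested variants reproducibly", {
  co <- tiny_cohort(seed = 20, n_tumors = 120)
  variants <- c("git", "git-attn", "lasso")
  run_suite <- function()
    ablation_suite(co, variants = variants,
                   git_config = tiny_git_config(),
                   train_config = train_config(max_epochs = 6,
                                               batch_size = 16, runs = 2,
                                               seed = 1),
                   g2v_config = gene2vec_config(d = 8, epochs = 2, seed = 1),
                   split = split_spec(seed = 7))
  tab <- run_suite()
  expect_setequal(tab$variant, variants)
  runs <- attr(tab, "runs")
  expect_equal(nrow(runs), length(variants) * 2)
  expect_true(all(runs$f1 >= 0 & runs$f1 <= 1))
  # bit-for-bit reproducible with the same seeds
  expect_identical(as.data.frame(run_suite()), as.data.frame(tab))
})

test_that("validation symbols unknown to the training vocabulary are dropped", {
  co <- tiny_cohort(seed = 30, n_tumors = 40)
  sp <- make_split(co, split_spec(seed = 1))
  valid <- sp$valid
  valid$gene_vocab <- c(valid$gene_vocab, "gX")
  valid$sga[[1]] <- c(valid$sga[[1]], "gX")
  expect_warning(
    train_git(sp$train, valid, tiny_git_config(),
              train_config(max_epochs = 1, batch_size = 16, seed = 1)),
    "unknown to the model")
})
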