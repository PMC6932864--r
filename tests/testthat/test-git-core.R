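test_that("attention weights reduce to eps for one gene and split symmetrically", {
  set.seed(1)
  W0 <- matrix(rnorm(6), 3, 2); Theta <- matrix(rnorm(6), 2, 3)
  e1 <- c(0.3, -0.2)
  expect_equal(attention_weights(rbind(e1), W0, Theta, eps = 0.7), 0.7)
  a <- attention_weights(rbind(e1, e1), W0, Theta, eps = 0.7)
  expect_equal(a, c(0.35, 0.35))
  expect_identical(attention_weights(matrix(0, 0, 2), W0, Theta), numeric())
})

test_that("attention matches an independent step-by-step recomputation", {
  W0 <- matrix(c(0.2, -0.4, 0.1, 0.3, -0.2, 0.5), 3, 2)   # d_a=3, d=2
  Theta <- matrix(c(0.7, -0.3, 0.2, 0.1, -0.5, 0.4), 2, 3) # H=2
  eps <- 1.3
  E <- rbind(c(0.5, -1), c(-0.2, 0.3), c(1, 0.8))          # m=3
  # oracle: explicit loops
  m <- nrow(E); H <- nrow(Theta)
  scores <- matrix(0, m, H)
  for (g in 1:m) for (h in 1:H)
    scores[g, h] <- sum(Theta[h, ] * tanh(W0 %*% E[g, ]))
  A <- apply(scores, 2, function(s) exp(s) / sum(exp(s)))
  want <- eps * rowMeans(A)
  expect_equal(attention_weights(E, W0, Theta, eps), want, tolerance = 1e-12)
  expect_equal(sum(want), eps)
})

test_that("attention weights are positive and sum to eps on random tumors", {
  co <- tiny_cohort(seed = 6, n_tumors = 25)
  model <- init_git_model(co, tiny_git_config())
  eps <- gitnet:::softplus(model$eps_raw)
  fw <- git_forward(model, co)
  for (a in fw$alphas) {
    if (!length(a)) next
    expect_true(all(a > 0))
    expect_lt(abs(sum(a) - eps), 1e-6)
  }
})

test_that("encoding follows the additive composition and its ablations", {
  co <- tiny_cohort(seed = 2)
  model <- init_git_model(co, tiny_git_config())
  type <- co$cancer_type_vocab[1]
  es <- model$emb[type, ]

  # no SGAs: e_t = e_s exactly, no attention weights
  enc0 <- encode_tumor(model, character(), type)
  expect_identical(enc0$embedding, es)
  expect_length(enc0$alphas, 0)
  expect_identical(enc0$cancer_type_weight, 1)

  # mean-pooling ablation: e_t = e_s + (e1 + e2)/2
  cfg <- tiny_git_config(use_attention = FALSE)
  mp <- init_git_model(co, cfg)
  gs <- co$gene_vocab[1:2]
  enc <- encode_tumor(mp, gs, type)
  expect_equal(enc$embedding,
               mp$emb[type, ] + colMeans(mp$emb[gs, ]), tolerance = 1e-12)
  expect_equal(unname(enc$alphas), c(0.5, 0.5))

  # cancer-type ablation: output invariant to the label
  nc <- init_git_model(co, tiny_git_config(use_cancer_type = FALSE))
  e1 <- encode_tumor(nc, gs, co$cancer_type_vocab[1])
  e2 <- encode_tumor(nc, gs, co$cancer_type_vocab[2])
  expect_identical(e1$embedding, e2$embedding)

  expect_error(encode_tumor(model, "not-a-gene", type), "unknown gene")
  expect_error(encode_tumor(model, gs, "not-a-type"), "unknown cancer type")
})

test_that("encoding is invariant to the order of a tumor's SGA list", {
  co <- tiny_cohort(seed = 3)
  model <- init_git_model(co, tiny_git_config())
  gs <- co$gene_vocab[c(2, 5, 9, 11)]
  a <- encode_tumor(model, gs, co$cancer_type_vocab[1])
  b <- encode_tumor(model, rev(gs), co$cancer_type_vocab[1])
  expect_equal(a$embedding, b$embedding, tolerance = 1e-12)
  expect_equal(a$alphas[gs], b$alphas[gs], tolerance = 1e-12)
})

test_that("decoder implements sigma(W2 ReLU(W1 ReLU(e_t)+b1)+b2)", {
  co <- tiny_cohort(seed = 4)
  model <- init_git_model(co, tiny_git_config(dropout_rate = 0))

  # all-zero parameters: every output is sigma(0) = 0.5
  z <- model
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  expect_equal(unname(git_decode(z, rnorm(8))),
               rep(0.5, length(co$deg_vocab)))

  # all-negative embedding with b1 = 0: ReLU kills e_t, output constant
  k <- model; k$b1[] <- 0
  y1 <- git_decode(k, rep(-1, 8))
  y2 <- git_decode(k, rep(-3, 8))
  expect_equal(y1, y2, tolerance = 1e-12)

  # tiny hand-set instance against manual arithmetic
  h <- model
  h$W1 <- matrix(0, nrow(h$W1), 8); h$W1[1, 1] <- 2; h$W1[2, 2] <- -1
  h$b1[] <- 0; h$b1[1] <- 0.5
  h$W2 <- matrix(0, nrow(h$W2), ncol(h$W2)); h$W2[1, 1] <- 1.5
  h$b2[] <- 0; h$b2[1] <- -0.25
  et <- c(1, -2, rep(0, 6))
  hidden <- pmax(c(2 * 1 + 0.5, rep(0, nrow(h$W1) - 1)), 0)
  want1 <- plogis(1.5 * hidden[1] - 0.25)
  got <- git_decode(h, et)
  expect_equal(unname(got[1]), want1, tolerance = 1e-12)
  expect_equal(unname(got[-1]), rep(0.5, length(got) - 1))

  expect_error(git_decode(model, rnorm(5)), "dimension")
})

test_that("cross entropy matches closed forms and validates shapes", {
  expect_equal(git_loss(c(1, 0), c(0.5, 0.5)), 2 * log(2), tolerance = 1e-12)
  expect_lt(git_loss(c(1, 0, 1), c(1, 0, 1)), 3 * 1e-5)
  expect_error(git_loss(c(1, 0), c(0.5, 0.5, 0.5)), "shapes")
  # model argument adds the Frobenius-norm penalty of the decoder matrices
  co <- tiny_cohort(seed = 5)
  model <- init_git_model(co, tiny_git_config(l2_lambda = 0.1))
  pen <- 0.1 * (sqrt(sum(model$W1^2)) + sqrt(sum(model$W2^2)))
  expect_equal(git_loss(c(1, 0), c(0.5, 0.5), model), 2 * log(2) + pen)
})

test_that("evaluation-mode forward is deterministic and matches per-tumor composition", {
  co <- tiny_cohort(seed = 6, n_tumors = 15)
  model <- init_git_model(co, tiny_git_config())
  f1 <- git_forward(model, co)
  f2 <- git_forward(model, co)
  expect_identical(f1, f2)
  for (i in c(1, 7, 15)) {
    enc <- encode_tumor(model, co$sga[[i]], unname(co$cancer_type[i]))
    expect_equal(unname(f1$prob[i, ]),
                 unname(git_decode(model, enc$embedding)), tolerance = 1e-12)
    expect_equal(f1$alphas[[i]], enc$alphas, tolerance = 1e-12)
    expect_equal(unname(f1$embeddings[i, ]), unname(enc$embedding),
                 tolerance = 1e-12)
  }
})

test_that("a tumor without SGAs decodes its cancer-type embedding", {
  co <- tiny_cohort(seed = 7, n_tumors = 5)
  co$sga[[2]] <- character()
  model <- init_git_model(co, tiny_git_config())
  fw <- git_forward(model, co)
  es <- model$emb[unname(co$cancer_type[2]), ]
  expect_equal(unname(fw$prob[2, ]), unname(git_decode(model, es)),
               tolerance = 1e-12)
})

test_that("checkpoints reload with bit-exact evaluation outputs", {
  co <- tiny_cohort(seed = 8, n_tumors = 10)
  model <- init_git_model(co, tiny_git_config())
  f <- withr::local_tempfile(fileext = ".rds")
  save_git_model(model, f)
  back <- load_git_model(f)
  expect_identical(git_forward(back, co), git_forward(model, co))
})

test_that("analytic gradients of all parameter groups match finite differences", {
  cfg <- sim_config(n_tumors = 5, n_genes = 8, n_deg_genes = 6,
                    n_cancer_types = 2, n_pathways = 2,
                    drivers_per_pathway = 2, deg_targets_per_pathway = 3,
                    pathways_per_tumor = 1, passenger_rate = 3, seed = 7)
  co <- generate_cohort(cfg)$cohort
  for (variant in list(git_config(d = 4, heads = 2, attention_hidden = 3,
                                  decoder_hidden = 5, dropout_rate = 0,
                                  l2_lambda = 1e-3, seed = 3),
                       git_config(d = 4, heads = 2, attention_hidden = 3,
                                  decoder_hidden = 5, dropout_rate = 0,
                                  l2_lambda = 0, use_cancer_type = FALSE,
                                  seed = 3))) {
    model <- init_git_model(co, variant)
    expect_lt(gitnet:::git_gradient_check(model, co), 1e-4)
  }
})
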