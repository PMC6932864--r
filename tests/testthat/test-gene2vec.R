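# A deterministic toy corpus where genes gA and gB always co-occur while gC
# never shares a tumor with gA.
cooccurrence_cohort <- function(n = 200, seed = 1) {
  set.seed(seed)
  filler <- sprintf("f%02d", 1:12)
  ids <- sprintf("s%03d", seq_len(n))
  sga <- lapply(seq_len(n), function(i) {
    extra <- sample(filler, 3)
    if (i %% 2 == 0) sort(c("gA", "gB", extra)) else sort(c("gC", extra))
  })
  deg <- matrix(0L, n, 2, dimnames = list(ids, c("d1", "d2")))
  new_cohort(ids, rep("ct1", n), sga, deg)
}

test_that("zero epochs returns the seeded random initialization", {
  co <- tiny_cohort(seed = 1, n_tumors = 10)
  cfg <- gene2vec_config(d = 6, epochs = 0, seed = 42)
  tab1 <- pretrain_gene2vec(co, cfg)
  tab2 <- pretrain_gene2vec(co, cfg)
  expect_identical(unclass(tab1), unclass(tab2))
  expect_identical(rownames(tab1), co$gene_vocab)
  d <- 6
  expect_true(all(abs(unclass(tab1)) <= 0.5 / d))
})

test_that("training runs on a single-tumor corpus and the loss decreases", {
  co <- new_cohort("t1", "ct1", list(c("gA", "gB")),
                   matrix(0L, 1, 1, dimnames = list(NULL, "d1")))
  tab <- pretrain_gene2vec(co, gene2vec_config(d = 4, epochs = 10,
                                               negative_samples = 2, seed = 1))
  expect_true(all(is.finite(unclass(tab))))
  loss <- attr(tab, "epoch_loss")
  expect_lt(loss[10], loss[1])
})

test_that("epoch loss decreases on a structured corpus", {
  co <- cooccurrence_cohort(n = 120, seed = 2)
  loss <- attr(pretrain_gene2vec(co, gene2vec_config(d = 8, epochs = 5,
                                                     seed = 3)), "epoch_loss")
  expect_lt(loss[5], loss[1])
  expect_lt(mean(diff(loss)), 0)
})

test_that("always-co-occurring genes embed closer than never-co-occurring", {
  hits <- vapply(1:5, function(s) {
    tab <- pretrain_gene2vec(cooccurrence_cohort(n = 200, seed = 1),
                             gene2vec_config(d = 8, epochs = 8, seed = s))
    cosine(tab["gA", ], tab["gB", ]) > cosine(tab["gA", ], tab["gC", ])
  }, NA)
  expect_gte(sum(hits), 4)
})

test_that("results are invariant to tumor order", {
  co <- cooccurrence_cohort(n = 60, seed = 4)
  perm <- co[sample(seq_len(60))]
  cfg <- gene2vec_config(d = 6, epochs = 3, seed = 9)
  expect_identical(unclass(pretrain_gene2vec(co, cfg)),
                   unclass(pretrain_gene2vec(perm, cfg)))
})

test_that("empty and pair-free cohorts are rejected", {
  empty <- new_cohort(character(), character(), list(),
                      matrix(integer(), 0, 1, dimnames = list(NULL, "d1")),
                      gene_vocab = "g1", cancer_type_vocab = "ct1")
  expect_error(pretrain_gene2vec(empty), "empty cohort")
  solo <- new_cohort("t1", "ct1", list("g1"),
                     matrix(0L, 1, 1, dimnames = list(NULL, "d1")))
  expect_error(pretrain_gene2vec(solo), "two or more SGAs")
})

test_that("nearest_genes matches exact geometry and a brute-force scan", {
  tab <- embedding_table(matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
                                dimnames = list(c("A", "B", "C"), NULL)))
  expect_equal(nearest_genes(tab, "A", 1),
               data.frame(gene = "B", similarity = 1))
  expect_equal(nearest_genes(tab, "A", 2),
               data.frame(gene = c("B", "C"), similarity = c(1, 0)))
  expect_error(nearest_genes(tab, "Z", 1), "unknown gene")

  set.seed(8)
  m <- matrix(rnorm(50 * 5), 50, 5,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  rtab <- embedding_table(m)
  for (q in c("g01", "g17", "g50")) {
    sims <- vapply(setdiff(rownames(m), q),
                   function(x) cosine(m[q, ], m[x, ]), 0)
    ord <- order(-sims, names(sims))
    want <- data.frame(gene = names(sims)[ord][1:3],
                       similarity = unname(sims[ord][1:3]))
    expect_equal(nearest_genes(rtab, q, 3), want, tolerance = 1e-12)
  }
})

test_that("pre-training on the default cohort converges; pathway affinity emerges only with supervision", {
  fx <- acc_fixture()
  loss <- attr(acc_env$g2v_seed1, "epoch_loss")
  expect_length(loss, 5)
  expect_true(all(diff(loss) <= 0))  # epoch-averaged loss non-increasing

  pw <- rep(names(fx$g$truth$pathway_drivers),
            lengths(fx$g$truth$pathway_drivers))
  names(pw) <- unlist(fx$g$truth$pathway_drivers)
  margin <- function(m) {
    V <- m[fx$drivers, , drop = FALSE]
    V <- V / sqrt(rowSums(V^2))
    S <- tcrossprod(V); diag(S) <- NA
    same <- outer(pw[fx$drivers], pw[fx$drivers], "==")
    mean(S[same], na.rm = TRUE) - mean(S[!same], na.rm = TRUE)
  }
  # co-occurrence alone: mutual exclusivity leaves the within-pathway
  # margin within noise of zero at this cohort size (observed ~ -0.001)
  expect_lt(abs(margin(unclass(acc_env$g2v_seed1))), 0.02)
  # after DEG-supervised refinement the margin is decisively positive
  expect_gt(margin(acc_env$finetuned_seed1), 0.2)
})
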