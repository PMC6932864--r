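grouped_embedding <- function() {
  # two tight groups in 2-D: {A1,A2} near (1,0), {B1,B2} near (0,1)
  m <- rbind(A1 = c(1, 0.02), A2 = c(0.98, 0), B1 = c(0.02, 1),
             B2 = c(0, 0.97))
  embedding_table(m)
}

test_that("nn_accuracy is exact on constructed separations", {
  tab <- grouped_embedding()
  ann <- as_annotation_map(list(A1 = "TA", A2 = "TA", B1 = "TB", B2 = "TB"))
  expect_equal(nn_accuracy(tab, ann), 100)
  disjoint <- as_annotation_map(list(A1 = "T1", A2 = "T2", B1 = "T3",
                                     B2 = "T4"))
  expect_equal(nn_accuracy(tab, disjoint), 0)
  expect_error(nn_accuracy(tab, as_annotation_map(list(A1 = "T1"))),
               "at least 2 annotated")
})

test_that("nn_accuracy agrees with a brute-force all-pairs scan", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:100)
  m <- matrix(rnorm(100 * 6), 100, 6, dimnames = list(genes, NULL))
  terms <- sprintf("T%d", 1:8)
  ann <- as_annotation_map(setNames(
    lapply(1:100, function(i) sample(terms, sample(0:2, 1))), genes))
  # oracle
  sets <- lapply(genes, function(g) annotation_terms(ann, g))
  names(sets) <- genes
  annotated <- genes[lengths(sets) > 0]
  hits <- vapply(annotated, function(g) {
    sims <- vapply(setdiff(genes, g), function(x) cosine(m[g, ], m[x, ]), 0)
    nb <- sort(names(sims)[sims == max(sims)])[1]
    length(intersect(sets[[g]], sets[[nb]])) > 0
  }, NA)
  expect_equal(nn_accuracy(embedding_table(m), ann), 100 * mean(hits))
})

test_that("nn_accuracy is invariant to rotation and uniform scaling", {
  set.seed(22)
  m <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  ann <- as_annotation_map(setNames(
    as.list(sample(c("T1", "T2", "T3"), 40, TRUE)), rownames(m)))
  rot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  base <- nn_accuracy(embedding_table(m), ann)
  expect_equal(nn_accuracy(embedding_table(3.7 * m %*% rot), ann), base)
})

test_that("random-pair baseline matches closed-form sharing probabilities", {
  genes <- sprintf("g%02d", 1:40)
  all_share <- as_annotation_map(setNames(as.list(rep("T", 40)), genes))
  expect_equal(random_pair_baseline(all_share, genes, 500, seed = 1)$percent,
               100)
  halves <- as_annotation_map(setNames(
    as.list(rep(c("T1", "T2"), each = 20)), genes))
  rb <- random_pair_baseline(halves, genes, n_pairs = 10000, seed = 2)
  p_true <- 100 * (20 - 1) / (40 - 1)  # P(same half) for ordered pairs
  expect_lt(abs(rb$percent - p_true), 3 * rb$se)
  expect_identical(random_pair_baseline(halves, genes, 1000, seed = 5),
                   random_pair_baseline(halves, genes, 1000, seed = 5))
})

test_that("cluster enrichment is exact on a constructed two-cluster case", {
  tab <- grouped_embedding()
  ann <- as_annotation_map(list(A1 = "TA", A2 = "TA", B1 = "TB", B2 = "TB"))
  # background pair-share fraction: 2 sharing pairs of 6 = 1/3; within = 1
  expect_equal(cluster_enrichment(tab, ann, k = 2, seed = 1), 3)
  expect_error(cluster_enrichment(tab, ann, k = 9, seed = 1), "exceeds")
})

test_that("label permutation drives enrichment to one on average", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:120)
  tab <- embedding_table(matrix(rnorm(120 * 5), 120, 5,
                                dimnames = list(genes, NULL)))
  vals <- vapply(1:20, function(i) {
    ann <- as_annotation_map(setNames(
      as.list(sample(rep(sprintf("T%d", 1:6), 20))), genes))
    cluster_enrichment(tab, ann, k = 6, seed = i)
  }, 0)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("enrichment curves handle singleton and empty k lists", {
  tab <- grouped_embedding()
  ann <- as_annotation_map(list(A1 = "TA", A2 = "TA", B1 = "TB", B2 = "TB"))
  cur <- enrichment_curve(tab, ann, k_list = 2, seed = 1)
  expect_equal(nrow(cur), 1)
  expect_equal(cur$enrichment, 3)
  empty <- enrichment_curve(tab, ann, k_list = integer(), seed = 1)
  expect_equal(nrow(empty), 0)
  multi <- enrichment_curve(tab, ann, k_list = c(3, 2, 3), seed = 1)
  expect_identical(multi$k, c(2L, 3L))  # sorted, deduplicated
})

test_that("attention landscape aggregates per-gene weights and frequencies", {
  co <- tiny_cohort(seed = 40, n_tumors = 1)
  co$sga[[1]] <- co$gene_vocab[3]
  model <- init_git_model(co, tiny_git_config())
  rk <- attention_landscape(model, co, "pan")
  expect_equal(nrow(rk), 1)
  expect_equal(rk$gene, co$gene_vocab[3])
  fw <- git_forward(model, co)
  expect_equal(rk$aggregate_attention, unname(fw$alphas[[1]]))
  expect_equal(rk$alteration_frequency, 1)
  expect_error(attention_landscape(model, co, "ct99"), "unknown scope")

  # aggregate weights are positive and bounded by the per-tumor total eps
  co2 <- tiny_cohort(seed = 43, n_tumors = 30)
  m2 <- init_git_model(co2, tiny_git_config())
  rk2 <- attention_landscape(m2, co2, "pan")
  eps <- gitnet:::softplus(m2$eps_raw)
  expect_true(all(rk2$aggregate_attention > 0))
  expect_true(all(rk2$aggregate_attention <= eps + 1e-12))
})

test_that("frequency ranking matches direct counting and ties with uniform attention", {
  co <- tiny_cohort(seed = 41, n_tumors = 25)
  rk <- frequency_ranking(co, "pan")
  cnt <- table(unlist(co$sga))
  expect_setequal(rk$gene, names(cnt))
  expect_equal(rk$alteration_frequency,
               sort(as.numeric(cnt), decreasing = TRUE) / 25)
  expect_true(!is.unsorted(rev(rk$aggregate_attention)))

  # single-gene tumors: every alpha equals eps, so the attention landscape
  # must order genes exactly like the frequency control
  co2 <- tiny_cohort(seed = 42, n_tumors = 30)
  co2$sga <- lapply(seq_len(30), function(i)
    co2$gene_vocab[1 + (i %% 4)])
  model <- init_git_model(co2, tiny_git_config())
  rk_a <- attention_landscape(model, co2, "pan")
  rk_f <- frequency_ranking(co2, "pan")
  expect_identical(rk_a$gene, rk_f$gene)
})
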