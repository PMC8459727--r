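small_expr <- function(seed = 5, genes = 30, n = 6) {
  set.seed(seed)
  m <- matrix(rnorm(genes * n, 5), genes, n,
              dimnames = list(sprintf("G%03d", 1:genes),
                              sprintf("s%d", 1:n)))
  expression_dataset(m, setNames(rep(c("A", "B"), each = n / 2),
                                 colnames(m)))
}

test_that("ranking metrics behave at the boundary cases", {
  ds <- small_expr()
  # identical values in both groups -> score exactly 0
  ds$values["G001", ] <- 3.3
  rl <- rank_genes(ds)
  expect_equal(rl$score[rl$gene == "G001"], 0)

  # exchanging the roles of the two classes negates every score
  rl2 <- rank_genes(ds, positive_class = "B")
  expect_equal(rl2$score[match(rl$gene, rl2$gene)], -rl$score)
})

test_that("signal-to-noise scores match a direct recomputation", {
  fam <- simulate_database_family(n_groups = 3, genes_per_set = 20,
                                  universe_size = 500, seed = 51)
  sim <- simulate_expression(fam$truth$universe, 10, fam$truth, seed = 52)
  rl <- rank_genes(sim$expr)
  # independent recomputation from the matrix, per the metric definition
  a <- sim$expr$values[, sim$expr$labels == "A"]
  b <- sim$expr$values[, sim$expr$labels == "B"]
  sa <- apply(a, 1, sd); sb <- apply(b, 1, sd)
  ma <- rowMeans(a); mb <- rowMeans(b)
  expect_score <- (ma - mb) /
    (pmax(sa, 0.2 * abs(ma), 1e-8) + pmax(sb, 0.2 * abs(mb), 1e-8))
  expect_equal(rl$score, unname(expect_score[rl$gene]))
  # planted genes dominate the top of the ranking: every one of the
  # planted set's genes outranks the median null gene
  planted <- fam$truth$planted_sets[[1]]$genes
  expect_lt(mean(match(planted, rl$gene)), 0.25 * nrow(rl))
})

test_that("unweighted ES hits the +1/-1 extremes for a single top/bottom gene", {
  rl <- ranked_list(c("A", "B", "C", "D"), c(3, 2, 1, 0.5))
  top <- enrichment_score(rl, "A", w = 0)
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, "A")
  bottom <- enrichment_score(rl, "D", w = 0)
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, "D")
  expect_error(enrichment_score(rl, c("A", "B", "C", "D")), "whole")
  expect_error(enrichment_score(rl, "ZZZ"), "no gene")
})

test_that("ES equals the straight-line brute-force recomputation", {
  set.seed(61)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    rl <- ranked_list(sprintf("g%02d", 1:N), scores)
    m <- sample(1:(N - 1), 1)
    genes <- sample(rl$gene, m)
    w <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(rl, genes, w = w)$es
    expect_es_matches_oracle(es, rl$score, rl$gene %in% genes, w)
  }
})

test_that("ES agrees with an independent reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(62)
  for (i in 1:25) {
    N <- sample(20:100, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    rl <- ranked_list(sprintf("g%03d", 1:N), scores)
    genes <- sample(rl$gene, sample(3:10, 1))
    stats <- setNames(rl$score, rl$gene)
    ref <- fgsea::calcGseaStat(stats, which(rl$gene %in% genes),
                               gseaParam = 1)
    expect_equal(enrichment_score(rl, genes, w = 1)$es, ref,
                 tolerance = 1e-10)
  }
})

test_that("running sum ends at zero and matches the reported ES extremum", {
  set.seed(63)
  rl <- ranked_list(sprintf("g%02d", 1:40), rnorm(40))
  es <- enrichment_score(rl, sample(rl$gene, 8))
  expect_equal(es$running_sum[40], 0, tolerance = 1e-12)
  expect_equal(es$es,
               es$running_sum[which.max(abs(es$running_sum))],
               tolerance = 1e-12)
})

test_that("two-group GSEA is reproducible and recovers planted signal", {
  fam <- simulate_database_family(n_groups = 4, genes_per_set = 30,
                                  universe_size = 800, seed = 71)
  sim <- simulate_expression(fam$truth$universe, 10, fam$truth, seed = 72)
  r1 <- run_gsea(sim$expr, fam$collections$DB1, B = 200, seed = 9)
  r2 <- run_gsea(sim$expr, fam$collections$DB1, B = 200, seed = 9)
  expect_identical(r1, r2)
  planted_id <- unname(fam$truth$planted_sets[[1]]$ids["DB1"])
  row <- r1[r1$set_id == planted_id, ]
  expect_gt(row$nes, 0)
  expect_lt(row$p_nominal, 0.05)
  # leading edge is a subset of the set's in-ranking genes
  le <- strsplit(row$leading_edge, ",")[[1]]
  expect_true(all(le %in% fam$collections$DB1$sets[[planted_id]]$genes))
  # nominal p is add-one smoothed, never exactly zero
  expect_true(all(r1$p_nominal > 0))
  expect_true(all(r1$q_fdr >= 0 & r1$q_fdr <= 1))
})

test_that("exchanging the class roles negates every observed ES", {
  fam <- simulate_database_family(n_groups = 4, genes_per_set = 20,
                                  universe_size = 600, seed = 73)
  sim <- simulate_expression(fam$truth$universe, 8, fam$truth, seed = 74)
  fwd <- run_gsea(sim$expr, fam$collections$DB1, B = 128, seed = 1)
  rev <- run_gsea(sim$expr, fam$collections$DB1, B = 128, seed = 1,
                  positive_class = "B")
  expect_equal(rev$es[match(fwd$set_id, rev$set_id)], -fwd$es,
               tolerance = 1e-12)
})

test_that("tiny sample sizes fall back to enumerating all label splits", {
  fam <- simulate_database_family(n_groups = 2, genes_per_set = 10,
                                  universe_size = 200, seed = 75)
  sim <- simulate_expression(fam$truth$universe, 3, fam$truth, seed = 76)
  expect_warning(res <- run_gsea(sim$expr, fam$collections$DB1, B = 500,
                                 seed = 2),
                 "enumerating all")
  expect_equal(attr(res, "metadata")$B, choose(6, 3))
})

test_that("pre-ranked GSEA finds a top block and calibrates on random sets", {
  set.seed(81)
  rl <- ranked_list(sprintf("g%03d", 1:100), seq(3, -3, length.out = 100))
  cl <- gene_set_collection("PR", list(
    gene_set("TOP", "top 10", sprintf("g%03d", 1:10)),
    gene_set("RAND", "random", sprintf("g%03d", sample(100, 10)))))
  res <- run_prerank(rl, cl, B = 500, seed = 3)
  expect_gt(res$nes[res$set_id == "TOP"], 0)
  expect_lt(res$p_nominal[res$set_id == "TOP"], 0.05)

  # median nominal p across uniformly random sets is near 1/2
  ps <- replicate(60, {
    cl1 <- gene_set_collection("R1", list(
      gene_set("S", "s", sample(rl$gene, 10))))
    run_prerank(rl, cl1, B = 100)$p_nominal
  })
  expect_gt(median(ps), 0.3)
  expect_lt(median(ps), 0.7)

  # degenerate all-zero ranking is rejected
  expect_error(run_prerank(ranked_list(letters[1:5], rep(0, 5)), cl),
               "degenerate")
  # a set larger than the ranked list cannot be scored
  big <- gene_set_collection("BIG", list(
    gene_set("B", "b", sprintf("x%04d", 1:600))))
  expect_error(suppressMessages(run_prerank(rl, big, B = 100)),
               "size filters")
})
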