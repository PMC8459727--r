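## Independent oracles and fixture builders. These deliberately share no
## code with the package internals they check.

## exact hypergeometric upper tail by direct enumeration of the support;
## every binomial coefficient and term is an exact integer in doubles for
## N <= 30 (all terms <= choose(30, 15) < 2^53)
oracle_fisher_tail <- function(k, n, K, N) {
  i <- seq(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## straight-line recomputation of the running-sum enrichment score:
## one pass over every rank position, tracking the extremes
oracle_es <- function(scores_ranked, hit, w) {
  N <- length(hit)
  m <- sum(hit)
  denom_hit <- sum(abs(scores_ranked[hit])^w)
  run <- 0
  best_pos <- -Inf
  best_neg <- Inf
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(scores_ranked[i])^w / denom_hit else
      -1 / (N - m)
    if (run > best_pos) best_pos <- run
    if (run < best_neg) best_neg <- run
  }
  c(pos = best_pos, neg = best_neg)
}

## assert an ES against the oracle extremes: the deviation of greatest
## magnitude wins; on an exact magnitude tie either sign is a valid
## maximum-deviation answer, so only the magnitude is asserted
expect_es_matches_oracle <- function(es, scores_ranked, hit, w,
                                     tol = 1e-12) {
  ext <- oracle_es(scores_ranked, hit, w)
  margin <- ext[["pos"]] + ext[["neg"]]  # |pos| - |neg|
  if (margin > 1e-9) expect_equal(es, ext[["pos"]], tolerance = tol)
  else if (margin < -1e-9) expect_equal(es, ext[["neg"]], tolerance = tol)
  else expect_equal(abs(es), ext[["pos"]], tolerance = 1e-9)
}

## brute-force connected components by iterated neighborhood expansion
oracle_components <- function(nodes, edges) {
  comp <- seq_along(nodes)
  names(comp) <- nodes
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- edges$from[r]; b <- edges$to[r]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

## brute-force Venn regions from per-gene membership vectors
oracle_regions <- function(sets) {
  genes <- sort(unique(unlist(sets)))
  sig <- vapply(genes, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), character(1))
  split(genes, sig)
}

## random gene-set collection for round-trip / property tests
random_collection <- function(n_sets = 5, universe = sprintf("G%03d", 1:80),
                              database = "RND") {
  sets <- lapply(seq_len(n_sets), function(i)
    gene_set(sprintf("S%02d", i), sprintf("set %d", i),
             sample(universe, sample(3:15, 1))))
  gene_set_collection(database, sets)
}

## two-database collections + groups with a designed consensus pattern:
## groups 1-5 significant everywhere, 6-8 mixed, 9-10 sign-conflicting
consensus_fixture <- function(seed = 101) {
  fam <- simulate_database_family(n_groups = 10, dbs_per_group = 2,
                                  genes_per_set = 20, universe_size = 600,
                                  seed = seed)
  groups <- suppressWarnings(
    build_equivalence_groups(fam$mappings, fam$collections))
  gids <- names(groups)
  stopifnot(length(gids) == 10)
  rows <- list()
  for (g in seq_len(10)) {
    ids <- fam$truth$equivalence_map[[g]]$ids
    p <- if (g <= 5) c(0.01, 0.03) else if (g <= 8) c(0.01, 0.4)
         else c(0.01, 0.02)
    nes <- if (g <= 8) c(2.1, 1.7) else c(1.9, -1.8)
    for (d in 1:2)
      rows[[length(rows) + 1]] <- data.frame(
        set_id = unname(ids[d]), database = names(ids)[d],
        p_adj = p[d], nes = nes[d], stringsAsFactors = FALSE)
  }
  list(groups = groups, results = do.call(rbind, rows), family = fam)
}

## gene-level discrepancy fixture: 13 shared genes centered at zero,
## 18 genes exclusive to the second database's set, all over-expressed
discrepancy_fixture <- function() {
  shared <- sprintf("SH%02d", 1:13)
  a_only <- sprintf("AX%02d", 1:10)
  b_only <- sprintf("BX%02d", 1:18)
  colls <- list(
    gene_set_collection("DBA", list(
      gene_set("PA", "pathway A rep", c(shared, a_only)))),
    gene_set_collection("DBB", list(
      gene_set("PB", "pathway B rep", c(shared, b_only)))))
  mp <- data.frame(source_db = "DBA", source_id = "PA",
                   source_name = "pathway A rep",
                   relation = "equivalentTo",
                   target_db = "DBB", target_id = "PB",
                   target_name = "pathway B rep",
                   stringsAsFactors = FALSE)
  groups <- build_equivalence_groups(mp, colls)
  dge <- dge_table(c(shared, a_only, b_only),
                   c(seq(-0.1, 0.1, length.out = 13),
                     seq(-0.15, 0.15, length.out = 10),
                     seq(1.5, 2.5, length.out = 18)),
                   rep(0.01, 41))
  list(groups = groups, group = groups[[1]], dge = dge,
       shared = shared, a_only = a_only, b_only = b_only)
}
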