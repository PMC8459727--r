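mk_group <- function(id = "DC:0001", dbs = c("KEGG", "Reactome")) {
  structure(list(group_id = id, group_name = "Test pathway",
                 members = data.frame(database = dbs,
                                      set_id = paste0(dbs, "_p"),
                                      stringsAsFactors = FALSE),
                 member_genes = setNames(rep(list(c("A", "B")),
                                             length(dbs)), dbs),
                 genes = c("A", "B")),
            class = "equivalence_group")
}

test_that("classification covers the concordant/contradictory taxonomy", {
  g <- mk_group()
  # significant in one database but not the other
  r <- classify_group(g, list(KEGG = list(p_adj = 0.01),
                              Reactome = list(p_adj = 0.2)),
                      alpha = 0.05, method_kind = "ORA_like")
  expect_equal(r$label, "contradictory_significance")

  # significant everywhere with agreeing NES signs
  r <- classify_group(g, list(KEGG = list(p_adj = 0.01, nes = 2.1),
                              Reactome = list(p_adj = 0.03, nes = 1.7)),
                      alpha = 0.05, method_kind = "score_based")
  expect_equal(r$label, "concordant_significant")
  expect_equal(r$per_database$direction, c("+", "+"))

  # significant everywhere but the NES signs disagree: the direction
  # conflict takes precedence over significance concordance
  r <- classify_group(mk_group(dbs = c("KEGG", "PathBank")),
                      list(KEGG = list(p_adj = 0.01, nes = 1.9),
                           PathBank = list(p_adj = 0.02, nes = -1.8)),
                      alpha = 0.05, method_kind = "score_based")
  expect_equal(r$label, "contradictory_direction")

  # a result in a single database is not comparable
  r <- classify_group(g, list(WikiPathways = list(p_adj = 0.01)),
                      method_kind = "ORA_like")
  expect_equal(r$label, "single_database")

  # non-significant everywhere is its own (concordant) label
  r <- classify_group(g, list(KEGG = list(p_adj = 0.4),
                              Reactome = list(p_adj = 0.9)),
                      method_kind = "ORA_like")
  expect_equal(r$label, "concordant_nonsignificant")
})

test_that("classification is invariant to database ordering", {
  g <- mk_group(dbs = c("KEGG", "Reactome", "PathBank"))
  res <- list(KEGG = list(p_adj = 0.01, nes = 1.9),
              Reactome = list(p_adj = 0.2, nes = 1.1),
              PathBank = list(p_adj = 0.03, nes = -2))
  labs <- vapply(1:10, function(i) {
    classify_group(g, res[sample(names(res))])$label
  }, character(1))
  expect_equal(unique(labs), "contradictory_significance")
})

test_that("the designed 10-group fixture returns summary {5, 3, 2}", {
  fx <- consensus_fixture()
  ct <- consensus_table(fx$groups, fx$results, alpha = 0.05)
  expect_equal(unname(ct$summary["concordant_significant"]), 5L)
  expect_equal(unname(ct$summary["contradictory_significance"]), 3L)
  expect_equal(unname(ct$summary["contradictory_direction"]), 2L)
  # label partition: one label per multi-database group, counts sum
  expect_equal(sum(ct$summary), nrow(ct$records))
  expect_true(all(table(ct$records$group_id) == 1L))
})

test_that("alpha = 1 leaves only all-significant labels", {
  fx <- consensus_fixture()
  ct <- consensus_table(fx$groups, fx$results, alpha = 1)
  expect_true(all(ct$records$label %in%
                    c("concordant_significant", "contradictory_direction")))
})

test_that("empty results produce an empty table and zero summary", {
  fx <- consensus_fixture()
  ct <- consensus_table(fx$groups, fx$results[0, ])
  expect_equal(nrow(ct$records), 0L)
  expect_equal(sum(ct$summary), 0L)
})

test_that("rows for unknown pathways are collected, not dropped", {
  fx <- consensus_fixture()
  res <- rbind(fx$results,
               data.frame(set_id = "GHOST", database = "DB1",
                          p_adj = 0.01, nes = 1))
  expect_warning(ct <- consensus_table(fx$groups, res), "unknown pathways")
  expect_equal(ct$unresolved$set_id, "GHOST")
  expect_equal(sum(ct$summary), 10L)
})

test_that("meta-database rows are displayed but never labeled", {
  fx <- consensus_fixture()
  meta_row <- data.frame(set_id = names(fx$groups)[1], database = "META",
                         p_adj = 0.001, nes = 2.5)
  ct <- consensus_table(fx$groups, rbind(fx$results, meta_row))
  expect_equal(sum(ct$summary), 10L)
  expect_equal(ct$records$META.p_adj[ct$records$group_id ==
                                       names(fx$groups)[1]], 0.001)
})

test_that("method comparison counts shared concordant groups", {
  fx <- consensus_fixture()
  ct <- consensus_table(fx$groups, fx$results)
  # identical record sets agree everywhere
  cmp <- compare_methods(ct, ct)
  expect_equal(unname(cmp$summary["common_concordant"]), 5L)
  expect_equal(unname(cmp$summary["neither"]), 5L)
  expect_equal(unname(cmp$summary["n_common"]), 10L)

  # designed disagreement: flip two groups to non-significant on one side
  res_b <- fx$results
  flip <- fx$results$set_id %in%
    fx$results$set_id[seq_len(4)]  # groups 1-2 (2 rows each)
  res_b$p_adj[flip] <- 0.9
  ct_b <- consensus_table(fx$groups, res_b)
  cmp2 <- compare_methods(ct, ct_b)
  # groups 1-2 become concordant_nonsignificant on side B: still
  # concordant under the label family, so common_concordant is unchanged
  expect_equal(unname(cmp2$summary["common_concordant"]), 5L)

  # empty side: intersection is empty, all counts zero
  cmp3 <- suppressWarnings(compare_methods(ct, ct$records[0, ]))
  expect_equal(unname(cmp3$summary["n_common"]), 0L)
  expect_equal(unname(cmp3$summary["common_concordant"]), 0L)
})

test_that("imported tables follow the upload contract", {
  fx <- consensus_fixture()
  ids <- fx$family$truth$equivalence_map[[1]]$ids
  up <- data.frame(set_id = c(unname(ids), "NOPE"),
                   database = c(names(ids), "DB1"),
                   p = c(0.01, 0.2, 0.5), stringsAsFactors = FALSE)
  expect_warning(imp <- import_results(up, fx$groups, method = "EnrichNet"),
                 "no known pathway")
  expect_equal(nrow(imp), 2L)
  expect_equal(attr(imp, "unresolved")$set_id, "NOPE")
  # ORA-kind upload without NES: direction is n/a downstream
  ct <- consensus_table(fx$groups, imp, method_kind = "ORA_like")
  expect_equal(nrow(ct$records), 1L)
  expect_true(all(ct$record_list[[1]]$per_database$direction == "n/a"))

  expect_error(import_results(up[, "set_id", drop = FALSE], fx$groups),
               "missing column")
  expect_error(import_results(rbind(up, up[1, ]), fx$groups), "duplicate")
})
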