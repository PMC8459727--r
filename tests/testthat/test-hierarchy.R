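po_row <- function(sid, tid, tdb = "CATEGORY") {
  data.frame(source_db = "DB", source_id = sid, source_name = sid,
             relation = "isPartOf", target_db = tdb, target_id = tid,
             target_name = tid, stringsAsFactors = FALSE)
}

chain_fixture <- function(ids, category = "metabolism") {
  colls <- list(gene_set_collection("DB", lapply(ids, function(i)
    gene_set(i, i, paste0("G", i, 1:3)))))
  groups <- build_equivalence_groups(
    data.frame(source_db = character(0), source_id = character(0),
               source_name = character(0), relation = character(0),
               target_db = character(0), target_id = character(0),
               target_name = character(0)), colls)
  list(colls = colls, groups = groups)
}

test_that("a cycle in the is-part-of graph is a fatal error naming it", {
  fx <- chain_fixture(c("x", "y"))
  mp <- rbind(po_row("x", "y", "DB"), po_row("y", "x", "DB"))
  expect_error(build_hierarchy(mp, fx$groups), "cycle")
})

test_that("depth is counted from the roots and bounded at 4", {
  fx <- chain_fixture(c("a", "b", "c", "d", "e"))
  # chain a <- b <- c <- d under a root: depth 5 including the category
  mp <- rbind(po_row("a", "metabolism"),
              po_row("b", "a", "DB"), po_row("c", "b", "DB"),
              po_row("d", "c", "DB"))
  h <- suppressWarnings(build_hierarchy(mp, fx$groups))
  expect_equal(h$max_depth_observed, 5L)
  expect_false(h$valid)
  expect_true("depth_exceeded" %in% h$issues$issue)

  # one level shorter is valid
  mp4 <- rbind(po_row("a", "metabolism"),
               po_row("b", "a", "DB"), po_row("c", "b", "DB"))
  h4 <- suppressWarnings(build_hierarchy(mp4, fx$groups))
  expect_equal(h4$max_depth_observed, 4L)
  expect_true(h4$valid)
})

test_that("declared category roots are the hierarchy roots", {
  fam <- simulate_database_family(n_groups = 12, dbs_per_group = 2,
                                  genes_per_set = 10, universe_size = 900,
                                  seed = 31)
  groups <- build_equivalence_groups(fam$mappings, fam$collections)
  h <- build_hierarchy(fam$mappings, groups)
  expect_equal(sort(h$roots),
               sort(c("metabolism", "immune", "signaling",
                      "communication and transport", "cell death",
                      "disease", "DNA repair and replication", "others")))
  expect_true(igraph::is_dag(h$graph))
  expect_true(h$valid)
  # every pathway node reaches a root (generator attaches all groups)
  expect_false("orphan" %in% h$issues$issue)
})

test_that("nodes without a path to a root are reported as orphans", {
  fx <- chain_fixture(c("a", "b"))
  mp <- po_row("a", "metabolism")
  expect_warning(h <- build_hierarchy(mp, fx$groups), "no path")
  expect_true("b" %in% h$issues$node[h$issues$issue == "orphan"])
})

test_that("circle-pack export applies method color semantics", {
  fx <- chain_fixture(c("a", "b"))
  mp <- rbind(po_row("a", "metabolism"), po_row("b", "metabolism"))
  h <- build_hierarchy(mp, fx$groups)
  res <- data.frame(node_id = c("a", "b"),
                    p_adj = c(0.20, 0.01), nes = c(1.2, -1.8))
  cp <- export_circlepack(h, res, method = "GSEA", alpha = 0.05)
  nodes <- cp[[which(vapply(cp, `[[`, character(1), "id") == "metabolism")]]
  kids <- nodes$children
  a <- kids[[which(vapply(kids, `[[`, character(1), "id") == "a")]]
  b <- kids[[which(vapply(kids, `[[`, character(1), "id") == "b")]]
  # non-significant -> gray (significant = FALSE, no color value)
  expect_false(a$significant)
  expect_true(is.na(a$color_value))
  # significant -> signed NES drives the red/blue gradient
  expect_true(b$significant)
  expect_equal(b$color_value, -1.8)
  expect_equal(b$size, 3L)

  # ORA semantics: significance flag only, no NES color
  cp2 <- export_circlepack(h, res[, c("node_id", "p_adj")], method = "ORA")
  n2 <- cp2[[which(vapply(cp2, `[[`, character(1), "id") == "metabolism")]]
  b2 <- n2$children[[which(vapply(n2$children, `[[`, character(1),
                                  "id") == "b")]]
  expect_true(b2$significant)
  expect_true(is.na(b2$color_value))
})

test_that("a DAG node with k parents appears k times in the packed tree", {
  fx <- chain_fixture(c("p", "q", "shared"))
  mp <- rbind(po_row("p", "metabolism"), po_row("q", "immune"),
              po_row("shared", "p", "DB"), po_row("shared", "q", "DB"))
  h <- build_hierarchy(mp, fx$groups)
  cp <- export_circlepack(h, data.frame(node_id = "shared", p_adj = 1),
                          method = "ORA")
  count_id <- function(node, id) {
    sum(vapply(node$children, count_id, numeric(1), id = id)) +
      as.numeric(node$id == id)
  }
  total <- sum(vapply(cp, count_id, numeric(1), id = "shared"))
  expect_equal(total, 2)
})

test_that("results for unknown nodes go under the unmapped root", {
  fx <- chain_fixture("a")
  mp <- po_row("a", "metabolism")
  h <- build_hierarchy(mp, fx$groups)
  res <- data.frame(node_id = c("a", "ghost"), p_adj = c(0.01, 0.01))
  expect_warning(cp <- export_circlepack(h, res, method = "ORA"),
                 "unmapped")
  ids <- vapply(cp, `[[`, character(1), "id")
  expect_true("unmapped" %in% ids)
  um <- cp[[which(ids == "unmapped")]]
  expect_equal(um$children[[1]]$id, "ghost")
  # JSON serialization round-trips the tree shape
  js <- circlepack_json(cp)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, length(cp))
})
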