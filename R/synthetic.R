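#' Simulate a family of overlapping gene-set databases
#'
#' Generates `dbs_per_group` synthetic pathway databases in which each of
#' `n_groups` pathways is represented once per database as a variant gene
#' set: the variants share a core and carry database-exclusive genes, sized
#' so that every pairwise Jaccard index falls inside `jaccard_range`
#' (mimicking how real databases represent the same biological pathway
#' with substantially, but not fully, overlapping gene sets). Pairwise
#' `equivalentTo` mapping records are emitted for every variant pair, and
#' each pathway group is assigned to one of the eight top-level categories
#' with an `isPartOf` record, so the full equivalence + hierarchy pipeline
#' is exercised. Gene pools of distinct groups are disjoint.
#'
#' @param n_groups number of pathway groups.
#' @param dbs_per_group number of databases (2-4 named `DB1`, `DB2`, ...).
#' @param jaccard_range length-2 numeric, target interval for the pairwise
#'   Jaccard index of variant sets; `c(1, 1)` yields identical variants.
#' @param genes_per_set genes in each variant set.
#' @param universe_size total genes available (`G00001`, ...).
#' @param planted data.frame with columns `group` (index), `direction`
#'   (`"up"`/`"down"`) and `effect` (mean shift in units of the
#'   within-group standard deviation) naming the pathways that carry
#'   signal; `NULL` plants signal in the first group, up, effect 1.
#' @param seed integer seed; the same seed reproduces the family exactly.
#' @return list with `collections` (list of [gene_set_collection()]),
#'   `mappings` (mapping record data.frame) and `truth` (ground truth:
#'   `planted_sets`, `equivalence_map`, per-group core/exclusive gene
#'   assignments, `categories`, `seed`).
#' @export
simulate_database_family <- function(n_groups = 10L, dbs_per_group = 3L,
                                     jaccard_range = c(0.4, 0.6),
                                     genes_per_set = 50L,
                                     universe_size = 2000L,
                                     planted = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dbs_per_group < 2L || dbs_per_group > 4L)
    pc_stop("dbs_per_group must be in [2, 4]")
  s <- as.integer(genes_per_set)
  j <- mean(jaccard_range)
  ## two size-s sets with core c: Jaccard = c / (2s - c)
  core <- as.integer(round(2 * s * j / (1 + j)))
  jac <- function(cc) cc / (2 * s - cc)
  while (core < s && jac(core) < jaccard_range[1L]) core <- core + 1L
  while (core > 0L && jac(core) > jaccard_range[2L]) core <- core - 1L
  if (jac(core) < jaccard_range[1L] || jac(core) > jaccard_range[2L])
    pc_stop("no core size achieves a pairwise Jaccard in [",
            jaccard_range[1L], ", ", jaccard_range[2L], "] for sets of ",
            s, " genes; nearest feasible value is ", signif(jac(core), 3))
  excl <- s - core
  need <- n_groups * (core + dbs_per_group * excl)
  if (need > universe_size)
    pc_stop("universe_size = ", universe_size, " too small: ", need,
            " genes required for ", n_groups, " disjoint groups ",
            "(reduce n_groups or genes_per_set)")

  universe <- sprintf("G%05d", seq_len(universe_size))
  pool <- sample(universe, need)
  dbs <- paste0("DB", seq_len(dbs_per_group))
  if (is.null(planted))
    planted <- data.frame(group = 1L, direction = "up", effect = 1)

  offset <- 0L
  collections <- lapply(dbs, function(db) NULL)
  sets_by_db <- stats::setNames(rep(list(list()), dbs_per_group), dbs)
  mappings <- list()
  truth_groups <- list()
  categories <- sample(DEFAULT_CATEGORY_ROOTS, n_groups, replace = TRUE)
  for (g in seq_len(n_groups)) {
    core_genes <- pool[offset + seq_len(core)]; offset <- offset + core
    ids <- sprintf("%s_PW%03d", dbs, g)
    member_genes <- list()
    for (d in seq_len(dbs_per_group)) {
      eg <- pool[offset + seq_len(excl)]; offset <- offset + excl
      member_genes[[dbs[d]]] <- c(core_genes, eg)
      sets_by_db[[dbs[d]]] <-
        c(sets_by_db[[dbs[d]]],
          list(gene_set(ids[d], sprintf("Pathway %d", g),
                        member_genes[[dbs[d]]])))
    }
    pairs <- utils::combn(dbs_per_group, 2L)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; jdx <- pairs[2L, p]
      mappings[[length(mappings) + 1L]] <- data.frame(
        source_db = dbs[i], source_id = ids[i],
        source_name = sprintf("Pathway %d", g),
        relation = "equivalentTo",
        target_db = dbs[jdx], target_id = ids[jdx],
        target_name = sprintf("Pathway %d", g),
        stringsAsFactors = FALSE)
    }
    mappings[[length(mappings) + 1L]] <- data.frame(
      source_db = dbs[1L], source_id = ids[1L],
      source_name = sprintf("Pathway %d", g),
      relation = "isPartOf",
      target_db = "CATEGORY", target_id = categories[g],
      target_name = categories[g], stringsAsFactors = FALSE)
    truth_groups[[g]] <- list(group = g, ids = stats::setNames(ids, dbs),
                              core = core_genes,
                              member_genes = member_genes,
                              category = categories[g])
  }
  collections <- lapply(dbs, function(db)
    gene_set_collection(db, sets_by_db[[db]]))
  names(collections) <- dbs

  if (!all(planted$direction %in% c("up", "down")))
    pc_stop("planted direction must be 'up' or 'down'")
  if (any(planted$effect <= 0)) pc_stop("planted effect sizes must be > 0")
  planted_sets <- lapply(seq_len(nrow(planted)), function(i) {
    g <- planted$group[i]
    list(group = g, ids = truth_groups[[g]]$ids,
         direction = planted$direction[i], effect = planted$effect[i],
         genes = sort(unique(unlist(truth_groups[[g]]$member_genes))))
  })

  list(collections = collections,
       mappings = do.call(rbind, mappings),
       truth = list(planted_sets = planted_sets,
                    equivalence_map = truth_groups,
                    universe = universe, categories = categories,
                    core_size = core, exclusive_size = excl,
                    seed = seed))
}

#' Simulate two-group expression with planted pathway signal
#'
#' Generates a genes x samples matrix of log2-scale values: every gene is
#' `Normal(mu0, baseline_sd)` in both classes, except the planted pathway
#' genes, whose class-A mean is shifted by `+effect * baseline_sd` (up) or
#' `-effect * baseline_sd` (down). Because values are on the log2 scale,
#' the expected log2 fold change (A minus B) of a planted gene equals
#' `effect * baseline_sd` exactly. A companion differential-expression
#' table is computed by per-gene Welch t-tests with Benjamini-Hochberg
#' adjustment — synthetic fixture support for the gene-level annotation
#' path, not a count-model DGE analysis.
#'
#' @param universe character vector of gene symbols to simulate (e.g.
#'   `truth$universe` from [simulate_database_family()]).
#' @param n_per_group samples per class (>= 2).
#' @param truth truth object from [simulate_database_family()]; its
#'   `planted_sets` define which genes are shifted. Pass
#'   `list(planted_sets = list())` for a pure null dataset.
#' @param baseline_sd within-group standard deviation (log2 units).
#' @param mu0 baseline mean (log2 units).
#' @param seed integer seed.
#' @return list with `expr` (an [expression_dataset()]; classes `"A"`,
#'   `"B"`) and `dge` (a [dge_table()]).
#' @export
simulate_expression <- function(universe, n_per_group = 20L, truth,
                                baseline_sd = 1, mu0 = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_per_group < 2L) pc_stop("n_per_group must be >= 2")
  G <- length(universe); n <- 2L * n_per_group
  X <- matrix(stats::rnorm(G * n, mu0, baseline_sd), G, n,
              dimnames = list(universe,
                              sprintf("S%03d", seq_len(n))))
  labels <- stats::setNames(rep(c("A", "B"), each = n_per_group),
                            colnames(X))
  for (ps in truth$planted_sets) {
    idx <- match(ps$genes, universe)
    if (anyNA(idx))
      pc_stop("planted genes missing from the simulated universe")
    shift <- ps$effect * baseline_sd * if (ps$direction == "up") 1 else -1
    X[idx, labels == "A"] <- X[idx, labels == "A"] + shift
  }
  expr <- expression_dataset(X, labels)

  ## companion DGE table: per-gene Welch t-test, BH-adjusted
  a <- X[, labels == "A", drop = FALSE]
  b <- X[, labels == "B", drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se <- sqrt(va / ncol(a) + vb / ncol(b))
  tstat <- (ma - mb) / se
  df <- (va / ncol(a) + vb / ncol(b))^2 /
    ((va / ncol(a))^2 / (ncol(a) - 1) + (vb / ncol(b))^2 / (ncol(b) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  dge <- dge_table(universe, ma - mb, stats::p.adjust(p, method = "BH"))

  list(expr = expr, dge = dge)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits the standard file formats for a simulated family: one GMT per
#' database, the mapping TSV, expression and design TSVs, the DGE TSV and
#' a truth JSON — a self-contained input bundle for the command-line
#' workflow.
#'
#' @param family output of [simulate_database_family()].
#' @param sim output of [simulate_expression()] (optional).
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_fixture_bundle <- function(family, sim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (cl in family$collections) {
    f <- file.path(dir, paste0(cl$database, ".gmt"))
    write_gmt(cl, f)
    files[paste0("gmt_", cl$database)] <- f
  }
  files["mappings"] <- file.path(dir, "mappings.tsv")
  write_mapping_table(family$mappings, files["mappings"])
  if (!is.null(sim)) {
    files["expression"] <- file.path(dir, "expression.tsv")
    m <- sim$expr$values
    utils::write.table(data.frame(gene = rownames(m), m,
                                  check.names = FALSE),
                       files["expression"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["design"] <- file.path(dir, "design.tsv")
    utils::write.table(data.frame(sample = names(sim$expr$labels),
                                  class = unname(sim$expr$labels)),
                       files["design"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["dge"] <- file.path(dir, "dge.tsv")
    utils::write.table(sim$dge, files["dge"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files["truth"] <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(family$truth, auto_unbox = TRUE, digits = NA,
                              null = "null"), files["truth"])
  files
}
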