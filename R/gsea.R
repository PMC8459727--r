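#' Rank genes by differential expression between two classes
#'
#' Produces the ranked list that drives gene set enrichment analysis. The
#' first class recorded in the dataset's design (`expr$classes[1]`) is the
#' "A" (positive) class: positive scores mean higher expression in A.
#'
#' Metrics:
#' \describe{
#'   \item{`signal_to_noise`}{\eqn{(\mu_A - \mu_B) / (\sigma_A + \sigma_B)}
#'     with each class standard deviation floored at
#'     \eqn{\max(0.2\,|\mu|, \epsilon)} — the usual variance-stabilizing
#'     convention of the rank-based enrichment method.}
#'   \item{`log2_ratio_of_means`}{\eqn{\log_2(\mu_A / \mu_B)}; requires
#'     strictly positive class means (intended for non-logged normalized
#'     values); usable when a class has fewer samples than variance
#'     estimation needs.}
#'   \item{`t_like`}{Welch-type statistic
#'     \eqn{(\mu_A - \mu_B) / \sqrt{\sigma_A^2/n_A + \sigma_B^2/n_B}} with
#'     the same floor on the standard deviations.}
#' }
#' Ties are broken by ascending gene symbol so the ordering (and every
#' downstream enrichment score) is deterministic.
#'
#' @param expr an [expression_dataset()].
#' @param metric ranking metric; see Details.
#' @param positive_class class label treated as "A"; defaults to the first
#'   class in the design. Exchanging the two classes negates every score.
#' @return a [ranked_list()] in descending score order.
#' @export
rank_genes <- function(expr, metric = c("signal_to_noise",
                                        "log2_ratio_of_means", "t_like"),
                       positive_class = NULL) {
  stopifnot(inherits(expr, "expression_dataset"))
  metric <- match.arg(metric)
  is_a <- expr$labels == resolve_positive_class(expr, positive_class)
  if (metric != "log2_ratio_of_means" && (sum(is_a) < 2L || sum(!is_a) < 2L))
    pc_stop("variance-based metric '", metric, "' needs >= 2 samples per ",
            "class; consider metric = 'log2_ratio_of_means'")
  s <- metric_scores(expr$values, is_a, metric)
  ranked_list(rownames(expr$values), s)
}

resolve_positive_class <- function(expr, positive_class) {
  if (is.null(positive_class)) return(expr$classes[1L])
  if (!positive_class %in% expr$classes)
    pc_stop("positive_class '", positive_class, "' is not one of the ",
            "design classes: ", paste(expr$classes, collapse = ", "))
  positive_class
}

## vectorized score computation; is_a is the logical A-class mask
metric_scores <- function(values, is_a, metric, eps = 1e-8) {
  a <- values[, is_a, drop = FALSE]
  b <- values[, !is_a, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  if (metric == "log2_ratio_of_means") {
    if (any(ma <= 0 | mb <= 0))
      pc_stop("log2_ratio_of_means requires strictly positive class means")
    return(log2(ma / mb))
  }
  sa <- apply(a, 1L, stats::sd); sb <- apply(b, 1L, stats::sd)
  sa <- pmax(sa, 0.2 * abs(ma), eps)
  sb <- pmax(sb, 0.2 * abs(mb), eps)
  if (metric == "signal_to_noise") (ma - mb) / (sa + sb)
  else (ma - mb) / sqrt(sa^2 / ncol(a) + sb^2 / ncol(b))
}

## core ES on sorted hit positions.
## pos: sorted positions (1..N) of the set's genes in the ranking;
## wts: |score|^w at those positions (same order); N: ranked-list length.
## Hits advance the running sum by wts/sum(wts), misses retreat by 1/(N-m);
## ES is the deviation of greatest magnitude (tie -> positive).
## Returns c(es, hit_index_of_extremum).
es_core <- function(pos, wts, N) {
  m <- length(pos)
  tot <- sum(wts)
  if (tot <= 0)
    pc_stop("degenerate ranking: all hit scores are zero, the weighted ",
            "enrichment score is undefined")
  miss <- 1 / (N - m)
  cw <- cumsum(wts) / tot
  drop_ <- (pos - seq_len(m)) * miss
  after <- cw - drop_            # running sum just after each hit
  before <- c(0, cw[-m]) - drop_ # running sum just before each hit
  i_max <- which.max(after); i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) c(after[i_max], i_max)
  else c(before[i_min], i_min)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing the running sum
#' by \eqn{|s_i|^w / \sum_{hits} |s_j|^w} at genes in the set (hits) and
#' decrementing by \eqn{1/(N - |S|)} at genes outside it. The enrichment
#' score (ES) is the running-sum value of greatest absolute magnitude; the
#' leading edge is the hits at or before the extremum for positive ES, and
#' at or after it for negative ES.
#'
#' @param ranked a [ranked_list()].
#' @param genes gene set (character vector of symbols); at least one must
#'   appear in the ranked list, and the set must not cover it entirely.
#' @param w weight exponent on the ranking score (`w = 1` is the standard
#'   weighted statistic; `w = 0` gives the classic Kolmogorov-Smirnov form).
#' @return list with `es`, `running_sum` (length-N numeric) and
#'   `leading_edge` (character vector of genes, in rank order).
#' @export
enrichment_score <- function(ranked, genes, w = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  genes <- unique(normalize_symbols(genes))
  N <- nrow(ranked)
  hit <- ranked$gene %in% genes
  m <- sum(hit)
  if (m == 0L) pc_stop("no gene of the set appears in the ranked list")
  if (m == N) pc_stop("gene set covers the whole ranked list; the miss ",
                      "decrement is undefined")
  pos <- which(hit)
  wts <- if (w == 0) rep(1, m) else abs(ranked$score[pos])^w
  esr <- es_core(pos, wts, N)
  es <- esr[1L]; i_ext <- esr[2L]
  inc <- numeric(N)
  inc[pos] <- wts / sum(wts)
  inc[-pos] <- -1 / (N - m)
  running <- cumsum(inc)
  leading <- if (es >= 0) ranked$gene[pos[seq_len(i_ext)]]
             else ranked$gene[pos[seq(i_ext, m)]]
  list(es = es, running_sum = running, leading_edge = leading)
}

## normalized ES, nominal p and ratio-of-tails FDR q from per-set nulls.
## es: observed ES per set; null: list of per-set null ES vectors.
gsea_summarize <- function(es, null) {
  n_sets <- length(es)
  nes <- p_nom <- rep(NA_real_, n_sets)
  null_nes <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    e <- es[i]; nu <- null[[i]]
    pos <- nu[nu >= 0]; neg <- nu[nu < 0]
    mp <- if (length(pos)) mean(pos) else NA_real_
    mn <- if (length(neg)) mean(abs(neg)) else NA_real_
    ## sign-matched normalization: positive and negative nulls scaled apart
    nn <- nu
    nn[nu >= 0] <- if (is.na(mp)) NA_real_ else nu[nu >= 0] / mp
    nn[nu < 0]  <- if (is.na(mn)) NA_real_ else nu[nu < 0] / mn
    null_nes[[i]] <- nn[is.finite(nn)]
    same <- if (e >= 0) pos else neg
    denom <- if (e >= 0) mp else mn
    nes[i] <- if (is.na(denom) || denom == 0) NA_real_ else abs(e) / denom *
      sign(e + (e == 0))
    p_nom[i] <- (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
  }
  pool <- unlist(null_nes, use.names = FALSE)
  n_pool_pos <- max(1L, sum(pool >= 0))
  n_pool_neg <- max(1L, sum(pool < 0))
  obs <- nes[is.finite(nes)]
  n_obs_pos <- max(1L, sum(obs >= 0))
  n_obs_neg <- max(1L, sum(obs < 0))
  q <- rep(NA_real_, n_sets)
  for (i in seq_len(n_sets)) {
    v <- nes[i]
    if (!is.finite(v)) next
    if (v >= 0) {
      num <- sum(pool >= v) / n_pool_pos
      den <- sum(obs >= v) / n_obs_pos
    } else {
      num <- sum(pool <= v) / n_pool_neg
      den <- sum(obs <= v) / n_obs_neg
    }
    q[i] <- min(1, if (den > 0) num / den else 1)
  }
  list(nes = nes, p_nominal = p_nom, q_fdr = q)
}

## positions + weights of each set under one ranking order.
## ord: ranking permutation (gene indices in rank order);
## scores: per-gene scores (original gene order); idx: set gene indices.
set_positions <- function(ord, scores, idx, w) {
  rnk <- integer(length(ord))
  rnk[ord] <- seq_along(ord)
  pos <- sort(rnk[idx])
  wts <- if (w == 0) rep(1, length(pos)) else abs(scores[ord[pos]])^w
  list(pos = pos, wts = wts)
}

#' Two-group gene set enrichment analysis
#'
#' For each gene set: the observed ES on the ranking of the full dataset; a
#' null ES distribution from `B` phenotype (class-label) permutations,
#' re-computing the ranking metric for every permutation; the NES as the
#' observed ES divided by the mean magnitude of the same-sign null ES
#' values; a one-sided nominal p as the add-one-smoothed tail frequency
#' within the same-sign null; and an FDR q by the ratio-of-tails rule over
#' the pooled sign-normalized null NES versus the observed NES (positive
#' and negative sides handled separately).
#'
#' With a fixed `seed` the full output is reproducible. When the number of
#' distinct label assignments is at most `B`, all of them are enumerated
#' instead of sampled (with a warning).
#'
#' @param expr an [expression_dataset()].
#' @param collection a [gene_set_collection()].
#' @param B number of permutations (>= 100 recommended; a warning is
#'   emitted below that).
#' @param seed integer seed for the permutation generator.
#' @param metric ranking metric, see [rank_genes()].
#' @param w weight exponent, see [enrichment_score()].
#' @param min_size,max_size gene-set size filter, applied to the overlap
#'   with the ranked genes.
#' @param positive_class class treated as "A" by the ranking metric; see
#'   [rank_genes()].
#' @return data.frame with columns `set_id`, `database`, `size`, `es`,
#'   `nes`, `p_nominal`, `q_fdr`, `leading_edge` (comma-joined), ordered by
#'   `p_nominal`; attribute `metadata` records seed, B, metric, w, scheme
#'   and filters.
#' @export
run_gsea <- function(expr, collection, B = 1000L, seed = NULL,
                     metric = "signal_to_noise", w = 1,
                     min_size = 5L, max_size = 500L,
                     positive_class = NULL) {
  stopifnot(inherits(expr, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  if (B < 1L) pc_stop("B must be >= 1")
  if (B < 100L) pc_warn("B = ", B, " permutations; >= 100 recommended")
  if (!is.null(seed)) set.seed(seed)

  X <- expr$values
  genes <- rownames(X)
  is_a <- expr$labels == resolve_positive_class(expr, positive_class)
  n <- ncol(X); n_a <- sum(is_a)

  obs_scores <- metric_scores(X, is_a, metric)
  obs_ord <- order(-obs_scores, genes)

  keep <- filter_sets(collection, genes, min_size, max_size)
  sets <- keep$sets; set_idx <- keep$idx

  ## label permutations: enumerate when the space is small, else sample
  n_distinct <- choose(n, n_a)
  if (n_distinct <= B) {
    pc_warn("only ", n_distinct, " distinct label assignments exist; ",
            "enumerating all instead of sampling B = ", B)
    perms <- utils::combn(n, n_a, simplify = FALSE)
  } else {
    perms <- replicate(B, sample.int(n, n_a), simplify = FALSE)
  }

  null_es <- null_es_phenotype(X, genes, perms, set_idx, metric, w)
  res <- assemble_gsea_results(expr_scores = obs_scores, ord = obs_ord,
                               genes = genes, sets = sets,
                               set_idx = set_idx, null_es = null_es, w = w,
                               database = collection$database)
  attr(res, "metadata") <- list(
    method = "GSEA", scheme = "phenotype", B = length(perms), seed = seed,
    metric = metric, w = w, min_size = min_size, max_size = max_size,
    classes = expr$classes, excluded = keep$excluded)
  res
}

## null ES matrix (sets x permutations) under phenotype permutation;
## class means/sds recomputed for every permutation via matrix products
null_es_phenotype <- function(X, genes, perms, set_idx, metric, w) {
  n <- ncol(X)
  M <- matrix(0, n, length(perms))
  for (b in seq_along(perms)) M[perms[[b]], b] <- 1
  n_a <- length(perms[[1L]]); n_b <- n - n_a
  SA <- X %*% M; SB <- rowSums(X) - SA
  ma <- SA / n_a; mb <- SB / n_b
  if (metric == "log2_ratio_of_means") {
    if (any(ma <= 0 | mb <= 0))
      pc_stop("log2_ratio_of_means requires strictly positive class means")
    S <- log2(ma / mb)
  } else {
    X2 <- X^2
    QA <- X2 %*% M; QB <- rowSums(X2) - QA
    va <- pmax((QA - n_a * ma^2) / (n_a - 1), 0)
    vb <- pmax((QB - n_b * mb^2) / (n_b - 1), 0)
    sa <- pmax(sqrt(va), 0.2 * abs(ma), 1e-8)
    sb <- pmax(sqrt(vb), 0.2 * abs(mb), 1e-8)
    S <- if (metric == "signal_to_noise") (ma - mb) / (sa + sb)
         else (ma - mb) / sqrt(sa^2 / n_a + sb^2 / n_b)
  }
  out <- matrix(NA_real_, length(set_idx), length(perms))
  for (b in seq_along(perms)) {
    sc <- S[, b]
    ord <- order(-sc, genes)
    for (i in seq_along(set_idx)) {
      pw <- set_positions(ord, sc, set_idx[[i]], w)
      out[i, b] <- es_core(pw$pos, pw$wts, length(genes))[1L]
    }
  }
  out
}

#' Pre-ranked gene set enrichment analysis
#'
#' As [run_gsea()], but starting from a user-supplied ranked list and
#' generating the null by gene-set permutation: for each set, `B` random
#' gene sets of the same size are drawn from the ranked genes and scored.
#' An all-zero score vector is rejected as a degenerate ranking.
#'
#' @param ranked a [ranked_list()] (e.g. from a `.rnk` file or
#'   [rank_genes()]).
#' @inheritParams run_gsea
#' @return as [run_gsea()]; metadata records `scheme = "gene_set"`.
#' @export
run_prerank <- function(ranked, collection, B = 1000L, seed = NULL, w = 1,
                        min_size = 5L, max_size = 500L) {
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  if (B < 1L) pc_stop("B must be >= 1")
  if (B < 100L) pc_warn("B = ", B, " permutations; >= 100 recommended")
  if (all(ranked$score == 0))
    pc_stop("degenerate ranking: all scores are zero")
  if (!is.null(seed)) set.seed(seed)

  genes <- ranked$gene
  N <- length(genes)
  scores <- ranked$score
  keep <- filter_sets(collection, genes, min_size, max_size)
  sets <- keep$sets; set_idx <- keep$idx

  ord <- seq_len(N)  # ranked input is already in rank order
  null_es <- matrix(NA_real_, length(set_idx), B)
  aw <- if (w == 0) rep(1, N) else abs(scores)^w
  for (i in seq_along(set_idx)) {
    m <- length(set_idx[[i]])
    for (b in seq_len(B)) {
      pos <- sort(sample.int(N, m))
      null_es[i, b] <- es_core(pos, aw[pos], N)[1L]
    }
  }
  res <- assemble_gsea_results(expr_scores = scores, ord = ord,
                               genes = genes, sets = sets,
                               set_idx = set_idx, null_es = null_es, w = w,
                               database = collection$database)
  attr(res, "metadata") <- list(
    method = "GSEA-preranked", scheme = "gene_set", B = B, seed = seed,
    w = w, min_size = min_size, max_size = max_size,
    excluded = keep$excluded)
  res
}

## shared: size filter on overlap with the ranked/measured genes
filter_sets <- function(collection, genes, min_size, max_size) {
  idx <- lapply(collection$sets, function(s)
    which(genes %in% s$genes))
  sizes <- lengths(idx)
  ok <- sizes >= min_size & sizes <= max_size & sizes < length(genes)
  if (!all(ok))
    message(sum(!ok), " gene set(s) excluded by size filters [",
            min_size, ", ", max_size, "] (overlap with measured genes)")
  if (!any(ok))
    pc_stop("no gene set survives the size filters [", min_size, ", ",
            max_size, "]")
  list(sets = collection$sets[ok], idx = idx[ok],
       excluded = names(collection$sets)[!ok])
}

## shared: observed ES + leading edge, then NES/p/q from the null matrix
assemble_gsea_results <- function(expr_scores, ord, genes, sets, set_idx,
                                  null_es, w, database) {
  N <- length(genes)
  n_sets <- length(sets)
  es <- numeric(n_sets); le <- character(n_sets)
  for (i in seq_len(n_sets)) {
    pw <- set_positions(ord, expr_scores, set_idx[[i]], w)
    esr <- es_core(pw$pos, pw$wts, N)
    es[i] <- esr[1L]
    hit_genes <- genes[ord[pw$pos]]
    le[i] <- paste(if (esr[1L] >= 0) hit_genes[seq_len(esr[2L])]
                   else hit_genes[seq(esr[2L], length(hit_genes))],
                   collapse = ",")
  }
  st <- gsea_summarize(es, split(null_es, seq_len(n_sets)))
  res <- data.frame(
    set_id = vapply(sets, `[[`, character(1), "set_id"),
    database = database,
    size = lengths(set_idx),
    es = es, nes = st$nes, p_nominal = st$p_nominal, q_fdr = st$q_fdr,
    leading_edge = le, stringsAsFactors = FALSE)
  res <- res[order(res$p_nominal, -abs(res$nes), res$set_id), ]
  rownames(res) <- NULL
  res
}
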