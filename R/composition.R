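#' Odds-ratio tissue-distribution enrichment
#'
#' For every (cluster, group) cell of a cluster-by-group count table, forms
#' the 2x2 table (cluster/not-cluster vs group/not-group), computes the odds
#' ratio with the Haldane-Anscombe correction (0.5 added to all four cells
#' when any is zero), the two-sided Fisher exact p, and flags depletion at
#' the conventional OR < 0.5 cutoff.
#'
#' @param counts Integer matrix, clusters x groups, with dimnames; at least
#'   2 rows and 2 columns, positive total, no all-zero row or column margin.
#' @return Long-format data.frame: `cluster`, `group`, `odds_ratio`,
#'   `log_or`, `fisher_p`, `depleted` (odds_ratio < 0.5).
#' @export
odds_ratio_enrichment <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop_coloc("data_error", "count table needs >= 2 clusters and >= 2 groups")
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0)
    stop_coloc("data_error", "counts must be nonnegative integers with positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_coloc("degenerate_margin", "a cluster or group has zero cells")
  tot <- sum(counts); rs <- rowSums(counts); cs <- colSums(counts)
  out <- expand.grid(cluster = rownames(counts), group = colnames(counts),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(cl, g) {
    a <- counts[cl, g]
    b <- rs[cl] - a
    c2 <- cs[g] - a
    d <- tot - a - b - c2
    p <- fisher.test(matrix(c(a, b, c2, d), nrow = 2, byrow = TRUE))$p.value
    if (min(a, b, c2, d) == 0) { a <- a + 0.5; b <- b + 0.5; c2 <- c2 + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c2)
    c(or, log(or), p)
  }, out$cluster, out$group)
  out$odds_ratio <- res[1, ]
  out$log_or <- res[2, ]
  out$fisher_p <- res[3, ]
  out$depleted <- out$odds_ratio < 0.5
  out
}

#' Shannon equitability of a composition
#'
#' `H = -sum p_i ln p_i` over the positive frequencies, normalized by
#' `ln S` where `S` is the size of the declared label universe -- including
#' zero-count classes, so missing subpopulations lower equitability. A
#' universe of a single class has equitability 0 by definition.
#'
#' @param counts Nonnegative count vector over the full label universe
#'   (zero entries allowed), positive total.
#' @param S Universe size; defaults to `length(counts)`.
#' @return List with `H` (Shannon entropy, nats), `equitability` in \[0, 1\],
#'   and `S`.
#' @export
shannon_equitability <- function(counts, S = length(counts)) {
  if (any(counts < 0)) stop_coloc("data_error", "counts must be nonnegative")
  if (sum(counts) == 0) stop_coloc("empty_group", "group has no cells")
  p <- counts[counts > 0] / sum(counts)
  H <- -sum(p * log(p))
  list(H = H,
       equitability = if (S <= 1) 0 else H / log(S),
       S = as.integer(S))
}

#' Per-group Shannon equitability of a count table
#'
#' Applies [shannon_equitability()] down the columns (groups) of a
#' cluster-by-group count table, with the cluster set as the shared label
#' universe.
#'
#' @param counts Clusters x groups count matrix.
#' @return data.frame: `group`, `H`, `equitability`, `S`.
#' @export
diversity_by_group <- function(counts) {
  counts <- as.matrix(counts)
  rows <- lapply(colnames(counts), function(g) {
    e <- shannon_equitability(counts[, g], S = nrow(counts))
    data.frame(group = g, H = e$H, equitability = e$equitability, S = e$S,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample cluster fractions from per-cell records
#'
#' @param cells data.frame with columns `sample` and `cluster` (one row per
#'   cell); a `samples` argument may widen the expected sample set, in which
#'   case samples without cells are excluded with a warning.
#' @param samples Optional expected sample labels.
#' @return Numeric matrix, samples x clusters, rows summing to 1.
#' @export
compute_fractions <- function(cells, samples = NULL) {
  if (!all(c("sample", "cluster") %in% names(cells)))
    stop_coloc("data_error", "cells needs columns sample and cluster")
  samples <- samples %||% unique(cells$sample)
  empty <- setdiff(samples, unique(cells$sample))
  if (length(empty)) {
    warning(sprintf("excluding sample(s) with zero cells: %s",
                    paste(empty, collapse = ", ")))
    samples <- setdiff(samples, empty)
  }
  cells <- cells[cells$sample %in% samples, ]
  tab <- table(factor(cells$sample, levels = samples), cells$cluster)
  frac <- tab / rowSums(tab)
  matrix(frac, nrow = nrow(tab), dimnames = dimnames(tab))
}
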