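#' Build a k-nearest-neighbour spot graph
#'
#' Euclidean distances between spot coordinates; each spot's neighbourhood is
#' its `k` nearest other spots (the focal spot is excluded). Exact distance
#' ties are broken by ascending spot index, so the graph is deterministic;
#' duplicated coordinates are allowed (distance-0 neighbours are valid).
#'
#' @param spots Spot table (`spot_id`, `x`, `y`).
#' @param k Neighbourhood size, `1 <= k <= nrow(spots) - 1`.
#' @return A `neighbor_graph`: list with `idx` (n x k integer matrix of
#'   neighbour row indices, ordered by increasing distance), `k`, `metric`
#'   and `spot_id`.
#' @export
build_knn <- function(spots, k) {
  validate_spot_table(spots)
  n <- nrow(spots)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k >= n)
    stop_coloc("invalid_k", sprintf("k must be an integer in [1, %d]", n - 1))
  d <- as.matrix(dist(spots[, c("x", "y")]))
  idx <- matrix(0L, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  structure(list(idx = idx, k = as.integer(k), metric = "euclidean",
                 spot_id = spots$spot_id),
            class = "neighbor_graph")
}

# Resolve a target specification (spot ids, logical mask, or indices)
# against the graph's spot ordering.
resolve_targets <- function(targets, graph) {
  n <- length(graph$spot_id)
  if (is.logical(targets)) {
    stopifnot(length(targets) == n)
    t_idx <- which(targets)
  } else if (is.character(targets)) {
    t_idx <- match(targets, graph$spot_id)
    if (anyNA(t_idx)) stop_coloc("no_targets", "unknown target spot ids")
  } else {
    t_idx <- as.integer(targets)
    if (any(t_idx < 1 | t_idx > n)) stop_coloc("no_targets", "target index out of range")
  }
  if (length(t_idx) == 0) stop_coloc("no_targets", "target set is empty")
  t_idx
}

response_vector <- function(comp, graph, response) {
  if (!response %in% colnames(comp))
    stop_coloc("data_error", sprintf("response cell type '%s' not in composition", response))
  comp <- comp[match(graph$spot_id, rownames(comp)), , drop = FALSE]
  if (anyNA(comp[, response]))
    stop_coloc("data_error", "composition rows do not match graph spot ids")
  comp[, response]
}

#' Mean response proportion in target-spot neighbourhoods
#'
#' `M = (1/|T|) * sum over targets t of (1/k) * sum over neighbours j of r_j`
#' where `r` is the response cell-type proportion; the focal spot's own value
#' never contributes (neighbours only).
#'
#' @param comp Composition matrix (spots x cell types, rownames = spot ids).
#' @param graph A [build_knn()] graph over the same spots.
#' @param targets Target spots: spot ids, logical mask, or row indices.
#' @param response Response cell-type column name.
#' @return The scalar neighbourhood mean.
#' @export
neighborhood_mean <- function(comp, graph, targets, response) {
  t_idx <- resolve_targets(targets, graph)
  r <- response_vector(comp, graph, response)
  mean(r[as.vector(graph$idx[t_idx, , drop = FALSE])])
}

#' Coordinate-preserving spatial permutation test
#'
#' Tests whether the response cell type is enriched in target-spot
#' neighbourhoods beyond what random spatial arrangement explains. Each
#' iteration permutes the response proportion vector uniformly at random
#' across all spots -- coordinates, target set and graph stay fixed -- and
#' recomputes the neighbourhood mean, preserving the marginal distribution
#' while destroying spatial structure. The enrichment ratio is
#' `E = observed_mean / perm_mean` (mean of the null means) and the
#' one-sided p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams neighborhood_mean
#' @param n_perm Number of permutations (>= 1); 1000 by default.
#' @param seed Seed for the permutation stream (optional but recommended).
#' @return A `permutation_test` list: `observed_mean`, `null_means`,
#'   `perm_mean`, `E`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(comp, graph, targets, response,
                             n_perm = 1000, seed = NULL) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop_coloc("invalid_config", "n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  t_idx <- resolve_targets(targets, graph)
  r <- response_vector(comp, graph, response)
  n <- length(r)
  nbr <- as.vector(graph$idx[t_idx, , drop = FALSE])
  cnt <- tabulate(nbr, nbins = n)
  m <- length(nbr)
  observed <- sum(cnt * r) / m
  run <- function() {
    vapply(seq_len(n_perm), function(p) sum(cnt * r[sample.int(n)]) / m,
           numeric(1))
  }
  null_means <- if (is.null(seed)) run() else with_seed(seed, run())
  perm_mean <- mean(null_means)
  if (perm_mean == 0 && observed != 0)
    stop_coloc("degenerate_statistic", "null mean is zero with nonzero observed mean")
  structure(list(observed_mean = observed, null_means = null_means,
                 perm_mean = perm_mean,
                 E = if (perm_mean == 0) NA_real_ else observed / perm_mean,
                 p_value = (1 + sum(null_means >= observed)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Spatial permutation test (n_perm = %d)\n", x$n_perm))
  cat(sprintf("  observed neighbourhood mean: %.6g\n", x$observed_mean))
  cat(sprintf("  permutation mean:            %.6g\n", x$perm_mean))
  cat(sprintf("  enrichment ratio E:          %.4f\n", x$E))
  cat(sprintf("  one-sided p (add-one):       %.4g\n", x$p_value))
  invisible(x)
}

#' Enrichment curve over a grid of neighbourhood sizes
#'
#' Runs the permutation test at every `k` in the grid and records the
#' enrichment ratio `E(k)` together with the consecutive absolute changes
#' `delta_i = |E(k_i) - E(k_(i-1))|`. Each grid point draws from its own
#' seed stream derived from the master seed, so extending the grid never
#' perturbs earlier points. The stable interval and selected `k*` are filled
#' in by [select_k()], which is applied before returning.
#'
#' @inheritParams permutation_test
#' @param spots Spot table matching `comp`.
#' @param k_grid Strictly increasing integer grid; default 5, 10, ..., 50.
#'   Values `>= nrow(spots)` are dropped with a warning.
#' @param delta_threshold Stability threshold on `delta` (default 0.05).
#' @return An `enrichment_curve`: `k_grid`, `E`, `p_value` per k, `delta`,
#'   `delta_threshold`, plus the [select_k()] fields.
#' @export
scan_k <- function(comp, spots, targets, response, k_grid = seq(5L, 50L, 5L),
                   n_perm = 1000, delta_threshold = 0.05, seed = NULL) {
  if (length(k_grid) == 0 || any(diff(k_grid) <= 0))
    stop_coloc("invalid_grid", "k_grid must be non-empty and strictly increasing")
  n <- nrow(spots)
  keep <- k_grid <= n - 1
  if (!all(keep)) {
    warning(sprintf("k grid truncated to k <= %d (only %d spots)", n - 1, n))
    k_grid <- k_grid[keep]
  }
  if (length(k_grid) == 0)
    stop_coloc("invalid_grid", "no usable k values after truncation")
  E <- p <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    g <- build_knn(spots, k_grid[i])
    pt <- permutation_test(comp, g, targets, response, n_perm = n_perm,
                           seed = if (is.null(seed)) NULL
                                  else stage_seed(seed, paste0("scan_k", k_grid[i])))
    E[i] <- pt$E
    p[i] <- pt$p_value
  }
  curve <- structure(list(k_grid = as.integer(k_grid), E = E, p_value = p,
                          delta = abs(diff(E)),
                          delta_threshold = delta_threshold),
                     class = "enrichment_curve")
  select_k(curve)
}

#' Dual-criterion stable-k selection
#'
#' `delta_i = |E(k_i) - E(k_(i-1))|` is attached to the right endpoint
#' `k_i`. The stable interval starts at the first `k_i` with
#' `delta_i < delta_threshold` and ends at the last k before `delta` next
#' exceeds the threshold (or at the final grid k if it never does). Within
#' the stable interval, `k*` is the k with peak enrichment ratio, ties broken
#' toward smaller k. If no `delta` falls below the threshold there is no
#' stable interval: `k*` falls back to the global argmax of `E` (smallest-k
#' tie-break) and `fallback` is set.
#'
#' @param curve An `enrichment_curve` with at least 2 grid points.
#' @return The curve with `stable_start`, `stable_end`, `k_star`, `fallback`
#'   filled in.
#' @export
select_k <- function(curve) {
  stopifnot(inherits(curve, "enrichment_curve"))
  k <- curve$k_grid; E <- curve$E
  if (length(k) < 2) stop_coloc("invalid_grid", "need at least 2 grid points")
  delta <- curve$delta
  thr <- curve$delta_threshold
  s <- which(delta < thr)[1]          # delta[i] belongs to k[i + 1]
  if (is.na(s)) {
    curve$stable_start <- curve$stable_end <- NA_integer_
    curve$k_star <- k[which.max(E)]
    curve$fallback <- TRUE
    return(curve)
  }
  after <- which(delta > thr)
  after <- after[after > s]
  e <- if (length(after)) after[1] else length(delta) + 1L   # index into k of interval end + 1
  stable_idx <- seq.int(s + 1L, e)    # k indices in [stable_start, stable_end]
  curve$stable_start <- k[s + 1L]
  curve$stable_end <- k[e]
  best <- stable_idx[which.max(E[stable_idx])]
  curve$k_star <- k[best]
  curve$fallback <- FALSE
  curve
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat("Enrichment curve E(k):\n")
  print(data.frame(k = x$k_grid, E = round(x$E, 4),
                   delta = c(NA, round(x$delta, 4))), row.names = FALSE)
  if (isTRUE(x$fallback)) {
    cat(sprintf("No stable interval (all delta >= %.3g); fallback k* = %d\n",
                x$delta_threshold, x$k_star))
  } else if (!is.null(x$k_star)) {
    cat(sprintf("Stable interval [%d, %d]; k* = %d\n",
                x$stable_start, x$stable_end, x$k_star))
  }
  invisible(x)
}

#' Assign a cellular identity to each spot from deconvolved proportions
#'
#' The `argmax` rule labels every spot with its most abundant cell type,
#' ties broken toward the lexicographically smallest cell-type name. The
#' `threshold` rule labels a spot only if some cell type reaches proportion
#' `tau` (spots below it stay `NA`); a spot meeting `tau` for several types
#' takes the largest, then the lexicographic tie-break.
#'
#' @param comp Composition matrix (spots x cell types).
#' @param rule `"argmax"` or `"threshold"`.
#' @param tau Threshold in (0, 1], required for the threshold rule.
#' @return A `spot_identity`: named character vector (spot id -> label,
#'   possibly `NA`), with the rule and tau as attributes.
#' @export
call_spot_identity <- function(comp, rule = c("argmax", "threshold"), tau = NULL) {
  rule <- match.arg(rule)
  cts <- colnames(comp)
  if (rule == "threshold") {
    if (is.null(tau) || !is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1)
      stop_coloc("invalid_threshold", "tau must lie in (0, 1]")
  }
  lab <- apply(comp, 1, function(row) {
    cand <- if (rule == "argmax") which(row == max(row))
            else which(row >= tau)
    if (length(cand) == 0) return(NA_character_)
    cand <- cand[row[cand] == max(row[cand])]
    sort(cts[cand])[1]
  })
  names(lab) <- rownames(comp)
  structure(lab, rule = rule, tau = tau, class = "spot_identity")
}

#' Global Moran's I with row-standardized k-NN weights
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with directed k-NN weights `w_ij = 1/k` for j among i's k nearest
#' neighbours (so `S0 = n`). Expected value under exchangeability is
#' `-1/(n-1)`. Significance comes from permuting the values over spots:
#' two-sided add-one p on the deviation `|I - E[I]|`. With n = 2 the
#' statistic is the forced closed form `I = -1` and no permutation p is
#' computed.
#'
#' @param spots Spot table.
#' @param values Numeric field per spot (non-constant).
#' @param k_weights Neighbourhood size for the weight matrix.
#' @param n_perm Permutations for the significance test (default 999).
#' @param seed Optional seed for the permutation stream.
#' @return A `moran_result`: `I`, `expected_I`, `p_value`, `weight_scheme`,
#'   `k_weights`, `n_perm`, `seed`.
#' @export
morans_i <- function(spots, values, k_weights, n_perm = 999, seed = NULL) {
  validate_spot_table(spots)
  n <- nrow(spots)
  stopifnot(length(values) == n)
  if (var(values) == 0)
    stop_coloc("zero_variance", "values are constant; Moran's I is undefined")
  graph <- build_knn(spots, min(k_weights, n - 1))
  xc <- values - mean(values)
  denom <- sum(xc^2)
  nbr_mean <- function(z) rowMeans(matrix(z[graph$idx], nrow = n))
  I_of <- function(z) sum(z * nbr_mean(z)) / sum(z^2)
  I <- I_of(xc)
  eI <- -1 / (n - 1)
  p <- NA_real_
  if (n >= 3 && n_perm >= 1) {
    run <- function() {
      vapply(seq_len(n_perm), function(i) I_of(xc[sample.int(n)]), numeric(1))
    }
    I_null <- if (is.null(seed)) run() else with_seed(seed, run())
    p <- (1 + sum(abs(I_null - eI) >= abs(I - eI))) / (1 + n_perm)
  }
  structure(list(I = I, expected_I = eI, p_value = p,
                 weight_scheme = "knn_row_standardized",
                 k_weights = graph$k, n_perm = if (n >= 3) n_perm else 0L,
                 seed = seed),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (expected %.4f under exchangeability)\n",
              x$I, x$expected_I))
  if (!is.na(x$p_value))
    cat(sprintf("  two-sided permutation p = %.4g (n_perm = %d, %s weights, k = %d)\n",
                x$p_value, x$n_perm, x$weight_scheme, x$k_weights))
  invisible(x)
}

#' Spatial correlation between two per-spot fields
#'
#' Spearman rank correlation (average-rank ties) by default, Pearson by
#' flag; two-sided p from [stats::cor.test()].
#'
#' @param field_a,field_b Numeric fields of equal length >= 3, non-constant.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `spatial_correlation`: `R`, `p_value`, `method`.
#' @export
spatial_correlation <- function(field_a, field_b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(field_a) != length(field_b) || length(field_a) < 3)
    stop_coloc("data_error", "fields must have equal length >= 3")
  if (var(field_a) == 0 || var(field_b) == 0)
    stop_coloc("zero_variance", "correlation undefined for a constant field")
  ct <- suppressWarnings(cor.test(field_a, field_b, method = method, exact = FALSE))
  structure(list(R = unname(ct$estimate), p_value = ct$p.value, method = method),
            class = "spatial_correlation")
}
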