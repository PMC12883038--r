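#' Construct a gene signature
#'
#' @param name Non-empty signature name.
#' @param genes Non-empty character vector of unique gene symbols.
#' @return A `signature_set` list with `name` and `genes`.
#' @export
signature_set <- function(name, genes) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop_coloc("invalid_config", "signature name must be a non-empty string")
  if (length(genes) == 0)
    stop_coloc("empty_signature", "signature has no genes")
  if (anyDuplicated(genes))
    stop_coloc("invalid_config", "signature genes must be unique")
  structure(list(name = name, genes = as.character(genes)), class = "signature_set")
}

#' Derive a signature from a differential-expression table
#'
#' Keeps genes with `log2FC` strictly above `log2fc_min` and p strictly
#' below `p_max` (defaults: log2FC > 1 and p < .05), preserving the input
#' order.
#'
#' @param de_table data.frame with columns `gene`, `log2FC`, `pval`.
#' @param log2fc_min Lower bound on log2 fold change (exclusive).
#' @param p_max Upper bound on the p-value (exclusive), in (0, 1].
#' @param name Name for the resulting signature.
#' @return A [signature_set()].
#' @export
derive_signature <- function(de_table, log2fc_min = 1, p_max = 0.05,
                             name = "signature") {
  req <- c("gene", "log2FC", "pval")
  if (!all(req %in% names(de_table)))
    stop_coloc("data_error", "de_table needs columns gene, log2FC, pval")
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1)
    stop_coloc("invalid_config", "p_max must lie in (0, 1]")
  if (any(!is.finite(de_table$log2FC)) ||
      any(de_table$pval < 0 | de_table$pval > 1 | !is.finite(de_table$pval)))
    stop_coloc("data_error", "log2FC must be finite and pval in [0, 1]")
  keep <- de_table$log2FC > log2fc_min & de_table$pval < p_max
  if (!any(keep))
    stop_coloc("empty_signature", "no gene passes the thresholds")
  signature_set(name, de_table$gene[keep])
}

# Drop signature genes absent from the expression matrix: warn if at least
# half survive, error otherwise.
match_signature <- function(expr, sig) {
  present <- sig$genes %in% rownames(expr)
  if (!any(present))
    stop_coloc("missing_genes", sprintf("no gene of signature '%s' is in the matrix", sig$name))
  if (mean(present) < 0.5)
    stop_coloc("missing_genes",
               sprintf("only %d/%d genes of signature '%s' are in the matrix",
                       sum(present), length(present), sig$name))
  if (!all(present))
    warning(sprintf("signature '%s': dropping %d absent gene(s)",
                    sig$name, sum(!present)))
  sig$genes[present]
}

#' Single-sample gene-set (ssGSEA-style) scores
#'
#' For each sample, genes are ranked by expression (descending; average
#' ranks at ties, positional ties broken by gene order) and the score is the
#' running-sum difference between the weighted ECDF of in-set genes (weight
#' = rank^alpha, normalized) and the uniform ECDF of out-of-set genes,
#' summed over all ranked positions. Raw sums are returned; with
#' `normalize = TRUE` scores are divided by their range across samples.
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param sig A [signature_set()]; at least one gene must be present, and at
#'   least half, otherwise an error is raised.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide by (max - min) across samples (default FALSE).
#' @return A `score_vector`: named numeric vector (one score per sample)
#'   with a `method = "ssgsea"` attribute.
#' @export
ssgsea_score <- function(expr, sig, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  genes <- match_signature(expr, sig)
  in_set <- rownames(expr) %in% genes
  N <- nrow(expr)
  n_out <- N - sum(in_set)
  scores <- apply(expr, 2, function(x) {
    r <- rank(x, ties.method = "average")
    ord <- order(-x, seq_len(N))
    inmask <- in_set[ord]
    w <- r[ord]^alpha
    w[!inmask] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- if (n_out > 0) cumsum(!inmask) / n_out else numeric(N)
    sum(p_in - p_out)
  })
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, method = "ssgsea", class = "score_vector")
}

#' Mean-expression signature scores
#'
#' Per sample, the arithmetic mean of expression over the signature genes
#' present in the matrix. The cheap rank-free score used for spot-level
#' signature maps.
#'
#' @inheritParams ssgsea_score
#' @return A `score_vector` with a `method = "mean"` attribute.
#' @export
mean_score <- function(expr, sig) {
  stopifnot(is.matrix(expr))
  genes <- match_signature(expr, sig)
  scores <- colMeans(expr[genes, , drop = FALSE])
  structure(scores, method = "mean", class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("Signature scores (method = %s) for %d samples\n",
              attr(x, "method"), length(x)))
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}
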