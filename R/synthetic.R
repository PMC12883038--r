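#' Configuration for the synthetic spatial-data generator
#'
#' Bundles and validates the parameters of the synthetic Visium-like study:
#' a spot layout, a Gaussian smoothing bandwidth that controls spatial
#' autocorrelation of the two designated cell-type abundance fields, and a
#' latent correlation `rho` that controls how strongly the "target" and
#' "response" cell types co-localize.
#'
#' @param n_spots Number of spots (>= 4).
#' @param layout `"square_grid"` (unit-spaced lattice) or `"uniform_random"`.
#' @param spatial_scale Gaussian kernel bandwidth, in coordinate units (> 0).
#' @param rho Latent target-response co-localization strength in \[-1, 1\].
#' @param n_celltypes Total number of cell types (>= 2); the first two are
#'   the designated `"target"` and `"response"` types.
#' @param noise_sd Gaussian noise added to the filler cell-type weights (>= 0).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_spots = 400, layout = c("square_grid", "uniform_random"),
                             spatial_scale = 2, rho = 0, n_celltypes = 5,
                             noise_sd = 0.1, seed = 1L) {
  layout <- match.arg(layout)
  bad <- character()
  if (!is.numeric(n_spots) || length(n_spots) != 1 || n_spots < 4 || n_spots != round(n_spots))
    bad <- c(bad, "n_spots must be an integer >= 4")
  if (!is.numeric(spatial_scale) || spatial_scale <= 0)
    bad <- c(bad, "spatial_scale must be > 0")
  if (!is.numeric(rho) || length(rho) != 1 || rho < -1 || rho > 1 || !is.finite(rho))
    bad <- c(bad, "rho must lie in [-1, 1]")
  if (!is.numeric(n_celltypes) || n_celltypes < 2 || n_celltypes != round(n_celltypes))
    bad <- c(bad, "n_celltypes must be an integer >= 2")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    bad <- c(bad, "noise_sd must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    bad <- c(bad, "seed must be a finite number")
  if (length(bad)) stop_coloc("invalid_config", paste(bad, collapse = "; "))
  structure(list(n_spots = as.integer(n_spots), layout = layout,
                 spatial_scale = spatial_scale, rho = rho,
                 n_celltypes = as.integer(n_celltypes), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a spot table
#'
#' `square_grid` places the first `n_spots` points of the tightest
#' `ceiling(sqrt(n))` x `ceiling(sqrt(n))` unit-spaced lattice;
#' `uniform_random` draws coordinates i.i.d. uniform on
#' `[0, ceiling(sqrt(n))]^2`.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame with columns `spot_id`, `x`, `y`.
#' @export
generate_spots <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_spots
  m <- ceiling(sqrt(n))
  if (config$layout == "square_grid") {
    g <- expand.grid(x = 0:(m - 1), y = 0:(m - 1))
    xy <- g[seq_len(n), ]
  } else {
    xy <- with_seed(stage_seed(config$seed, "spots"), {
      data.frame(x = runif(n, 0, m), y = runif(n, 0, m))
    })
  }
  data.frame(spot_id = sprintf("spot%04d", seq_len(n)),
             x = xy$x, y = xy$y, stringsAsFactors = FALSE)
}

# Gaussian-kernel smooth of a per-spot field, bandwidth h, truncated at 4h.
# The result is standardized to zero mean / unit sd so the logistic map
# downstream sees the same dynamic range at every bandwidth.
smooth_field <- function(xy, z, h) {
  d <- as.matrix(dist(xy))
  w <- exp(-d^2 / (2 * h^2))
  w[d > 4 * h] <- 0
  w <- w / rowSums(w)
  s <- as.vector(w %*% z)
  (s - mean(s)) / stats::sd(s)
}

#' Generate a deconvolved composition matrix with planted co-localization
#'
#' Draws two i.i.d. standard-normal per-spot fields `z1`, `z2`; `z1` is
#' smoothed with a Gaussian kernel of bandwidth `spatial_scale` (truncated
#' at 4 bandwidths) and standardized to give the latent target field
#' `v = z1_smooth`. The latent response field shares the target's smooth
#' spatial component in proportion to the co-localization strength,
#' `u = rho * v + sqrt(1 - rho^2) * z2`, with the idiosyncratic part `z2`
#' left spatially unstructured -- so at `rho = 0` the response field carries
#' no spatial autocorrelation of its own and the permutation null is
#' exchangeable, while `cor(v, u) = rho` by construction at every rho. Both
#' fields are mapped through the logistic function to abundance weights for
#' the `"target"` and `"response"` cell types; the remaining
#' `n_celltypes - 2` filler types get i.i.d. Gamma(2, 1) weights plus
#' Gaussian noise, and each row is normalized to sum to 1.
#'
#' @param spots A spot table from [generate_spots()].
#' @param config A [synthetic_config()].
#' @return A list with `composition` (spots x cell types matrix of
#'   proportions, rownames = spot ids) and `truth` (data.frame of the latent
#'   fields `v`, `u` per spot, for parameter-recovery checks).
#' @export
generate_composition <- function(spots, config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_spot_table(spots)
  if (config$n_celltypes < 2)
    stop_coloc("invalid_config", "need at least 2 cell types")
  n <- nrow(spots)
  with_seed(stage_seed(config$seed, "composition"), {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    v <- smooth_field(spots[, c("x", "y")], z1, config$spatial_scale)
    u <- config$rho * v + sqrt(1 - config$rho^2) * z2
    n_other <- config$n_celltypes - 2L
    w <- cbind(target = plogis(v), response = plogis(u))
    if (n_other > 0) {
      other <- matrix(rgamma(n * n_other, shape = 2, rate = 1), ncol = n_other) +
        config$noise_sd * matrix(rnorm(n * n_other), ncol = n_other)
      other <- pmax(other, 1e-6)
      colnames(other) <- paste0("other", seq_len(n_other))
      w <- cbind(w, other)
    }
    comp <- w / rowSums(w)
    rownames(comp) <- spots$spot_id
    list(composition = comp,
         truth = data.frame(spot_id = spots$spot_id, v = v, u = u,
                            stringsAsFactors = FALSE))
  })
}

#' Generate an expression matrix with planted signature structure
#'
#' Baseline expression is log-normal with gene-specific mean levels shared
#' across samples; the signature genes are shifted upward by `effect` on the
#' log scale in `high_samples` only.
#'
#' @param n_genes Number of genes; the gene universe is `g1 ... g<n_genes>`.
#' @param samples Character vector of sample labels.
#' @param signature Non-empty subset of the gene universe to up-shift.
#' @param high_samples Subset of `samples` carrying the shift.
#' @param effect Log-scale shift (>= 0).
#' @param seed Seed for the generator stream.
#' @return A genes x samples numeric matrix with dimnames.
#' @export
generate_expression <- function(n_genes, samples, signature, high_samples,
                                effect = 1, seed = 1L) {
  genes <- paste0("g", seq_len(n_genes))
  if (length(signature) == 0)
    stop_coloc("invalid_config", "signature must be non-empty")
  if (!all(signature %in% genes))
    stop_coloc("invalid_config", "signature genes must lie in the gene universe g1..gN")
  if (!all(high_samples %in% samples))
    stop_coloc("invalid_config", "high_samples must be a subset of samples")
  if (effect < 0) stop_coloc("invalid_config", "effect must be >= 0")
  with_seed(stage_seed(seed, "expression"), {
    mu <- rnorm(n_genes, mean = 2, sd = 1)
    expr <- matrix(rlnorm(n_genes * length(samples), meanlog = mu, sdlog = 0.5),
                   nrow = n_genes, dimnames = list(genes, samples))
    if (effect > 0 && length(high_samples)) {
      expr[signature, high_samples] <- expr[signature, high_samples] * exp(effect)
    }
    expr
  })
}
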