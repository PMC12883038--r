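# Independent oracle implementations used across the suite. These are coded
# straight from the mathematical definitions (explicit loops, exhaustive
# enumeration) and share no code path with the package internals they check.

# All permutations of 1..n, one per row.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Brute-force kNN by full sort of pairwise distances, ties by index.
oracle_knn <- function(spots, k) {
  n <- nrow(spots)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2 <- (spots$x - spots$x[i])^2 + (spots$y - spots$y[i])^2
    ord <- order(d2, seq_len(n))
    out[i, ] <- ord[ord != i][seq_len(k)]
  }
  out
}

# Loop-based neighbourhood mean, straight from the formula.
oracle_neighborhood_mean <- function(r, idx, t_idx) {
  acc <- 0
  for (t in t_idx) {
    s <- 0
    for (j in idx[t, ]) s <- s + r[j]
    acc <- acc + s / ncol(idx)
  }
  acc / length(t_idx)
}

# Exact permutation p: proportion of ALL response permutations whose
# neighbourhood mean reaches the observed one.
oracle_exact_p <- function(r, idx, t_idx) {
  n <- length(r)
  obs <- oracle_neighborhood_mean(r, idx, t_idx)
  perms <- all_perms(n)
  hits <- 0L
  for (p in seq_len(nrow(perms))) {
    if (oracle_neighborhood_mean(r[perms[p, ]], idx, t_idx) >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / nrow(perms)
}

# Moran's I from the explicit double sum with row-standardized kNN weights.
oracle_moran <- function(spots, values, k) {
  n <- length(values)
  idx <- oracle_knn(spots, k)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) w[i, idx[i, ]] <- 1 / k
  xb <- mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (values[i] - xb) * (values[j] - xb)
  (n / sum(w)) * num / sum((values - xb)^2)
}

# Single-sample rank-weighted running-sum score, coded independently from
# the ECDF-difference definition.
oracle_ssgsea <- function(x, in_set, alpha) {
  N <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(-x, seq_len(N))
  p_in <- p_out <- 0
  w_tot <- sum(r[ord][in_set[ord]]^alpha)
  n_out <- sum(!in_set)
  score <- 0
  for (pos in seq_len(N)) {
    g <- ord[pos]
    if (in_set[g]) p_in <- p_in + r[g]^alpha / w_tot
    else p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  score
}

# Small random spatial instance for oracle checks.
random_instance <- function(seed, n_min = 4, n_max = 7) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  spots <- data.frame(spot_id = paste0("s", 1:n),
                      x = runif(n, 0, 3), y = runif(n, 0, 3))
  k <- sample(1:(n - 1), 1)
  n_t <- sample(1:(n - 1), 1)
  list(spots = spots, k = k,
       t_idx = sort(sample(n, n_t)),
       r = round(runif(n), 3))
}

# Wrap a response vector as a 2-column composition for the package API.
as_comp <- function(r, spot_id) {
  comp <- cbind(response = r, filler = 1 - r)
  rownames(comp) <- spot_id
  comp
}
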