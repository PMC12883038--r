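toy_spots <- function(x, y = rep(0, length(x))) {
  data.frame(spot_id = paste0("s", seq_along(x)), x = x, y = y)
}

test_that("kNN graph handles collinear ties and completeness", {
  sp <- toy_spots(c(0, 1, 2))
  g <- build_knn(sp, 1)
  expect_equal(as.vector(g$idx), c(2L, 1L, 2L))  # middle spot ties to lower index
  sp2 <- toy_spots(runif(8), runif(8))
  g2 <- build_knn(sp2, 7)
  for (i in 1:8) expect_setequal(g2$idx[i, ], setdiff(1:8, i))
  expect_error(build_knn(sp, 3), class = "invalid_k")
  expect_error(build_knn(sp, 0), class = "invalid_k")
})

test_that("kNN graph matches the sort-and-slice distance oracle", {
  set.seed(17)
  sp <- data.frame(spot_id = paste0("s", 1:50),
                   x = runif(50, 0, 10), y = runif(50, 0, 10))
  expect_identical(build_knn(sp, 7)$idx, oracle_knn(sp, 7))
  # duplicated coordinates: distance-0 neighbours allowed, deterministic
  sp$x[2] <- sp$x[1]; sp$y[2] <- sp$y[1]
  expect_identical(build_knn(sp, 3)$idx, oracle_knn(sp, 3))
})

test_that("neighbourhood mean follows the stated formula", {
  # unit square, target = corner spot, k = 2: the two side corners (dist 1)
  # beat the diagonal (dist sqrt(2)); M = (1 + 0.5)/2
  sp <- toy_spots(c(0, 1, 0, 1), c(0, 0, 1, 1))
  comp <- as_comp(c(0, 1, 0.5, 0.9), sp$spot_id)
  g <- build_knn(sp, 2)
  expect_equal(neighborhood_mean(comp, g, "s1", "response"), 0.75)
  # constant field: M = c for any k/targets
  compc <- as_comp(rep(0.3, 4), sp$spot_id)
  expect_equal(neighborhood_mean(compc, g, c("s1", "s3"), "response"), 0.3)
  expect_error(neighborhood_mean(comp, g, character(0), "response"),
               class = "no_targets")
  # random instances against the loop oracle
  for (s in 1:100) {
    inst <- random_instance(s)
    g <- build_knn(inst$spots, inst$k)
    got <- neighborhood_mean(as_comp(inst$r, inst$spots$spot_id), g,
                             inst$t_idx, "response")
    expect_equal(got, oracle_neighborhood_mean(inst$r, g$idx, inst$t_idx),
                 tolerance = 1e-12)
  }
})

test_that("permutation test degenerates correctly on a constant field", {
  sp <- toy_spots(runif(20), runif(20))
  comp <- as_comp(rep(0.4, 20), sp$spot_id)
  pt <- permutation_test(comp, build_knn(sp, 5), 1:3, "response",
                         n_perm = 50, seed = 1)
  expect_equal(pt$E, 1)
  expect_equal(pt$p_value, 1)
})

test_that("Monte-Carlo p approaches the exhaustive enumeration p", {
  # small toy, large n_perm, compared with full enumeration of all 5! shuffles
  set.seed(23)
  sp <- toy_spots(runif(5, 0, 2), runif(5, 0, 2))
  r <- c(0.9, 0.1, 0.4, 0.8, 0.2)
  g <- build_knn(sp, 2)
  pt <- permutation_test(as_comp(r, sp$spot_id), g, c(1, 4), "response",
                         n_perm = 20000, seed = 7)
  expect_lt(abs(pt$p_value - oracle_exact_p(r, g$idx, c(1, 4))), 0.02)
})

test_that("permutation results are bit-reproducible and order-invariant", {
  set.seed(31)
  sp <- data.frame(spot_id = paste0("s", 1:60), x = runif(60), y = runif(60))
  comp <- as_comp(runif(60), sp$spot_id)
  g <- build_knn(sp, 6)
  a <- permutation_test(comp, g, 1:6, "response", n_perm = 100, seed = 9)
  b <- permutation_test(comp, g, 1:6, "response", n_perm = 100, seed = 9)
  expect_identical(a, b)
  expect_equal(a$p_value, (1 + sum(a$null_means >= a$observed_mean)) / 101)

  # permuting spot row order (consistently) leaves observed statistics fixed
  ord <- sample(60)
  sp2 <- sp[ord, ]; comp2 <- comp[ord, ]
  g2 <- build_knn(sp2, 6)
  t_ids <- sp$spot_id[1:6]
  expect_equal(neighborhood_mean(comp2, g2, t_ids, "response"),
               neighborhood_mean(comp, g, t_ids, "response"), tolerance = 1e-12)
  m1 <- morans_i(sp, comp[, "response"], 6, n_perm = 0)
  m2 <- morans_i(sp2, comp2[, "response"], 6, n_perm = 0)
  expect_equal(m1$I, m2$I, tolerance = 1e-12)
})

test_that("k scan truncates the grid, is deterministic, and flattens on a constant field", {
  sp <- toy_spots(runif(30, 0, 5), runif(30, 0, 5))
  comp <- as_comp(rep(0.25, 30), sp$spot_id)
  expect_warning(cv <- scan_k(comp, sp, 1:5, "response", n_perm = 20, seed = 2),
                 "truncated")
  expect_equal(cv$k_grid, c(5L, 10L, 15L, 20L, 25L))
  expect_equal(cv$E, rep(1, 5))
  expect_equal(cv$delta, rep(0, 4))
  set.seed(41)
  sp2 <- data.frame(spot_id = paste0("s", 1:80), x = runif(80, 0, 9), y = runif(80, 0, 9))
  comp2 <- as_comp(runif(80), sp2$spot_id)
  c1 <- scan_k(comp2, sp2, 1:8, "response", k_grid = seq(5, 25, 5),
               n_perm = 50, seed = 77)
  c2 <- scan_k(comp2, sp2, 1:8, "response", k_grid = seq(5, 25, 5),
               n_perm = 50, seed = 77)
  expect_identical(c1, c2)
  expect_error(scan_k(comp2, sp2, 1:8, "response", k_grid = c(10, 5)),
               class = "invalid_grid")
})

test_that("stable-k selection reproduces the documented traces", {
  mk <- function(E) structure(list(k_grid = seq(5L, 50L, 5L), E = E,
                                   delta = abs(diff(E)), delta_threshold = 0.05),
                              class = "enrichment_curve")
  # hand-traced curve: stable interval [25, 50], peak at k = 30
  cv <- select_k(mk(c(1.00, 1.50, 1.90, 2.00, 2.02, 2.03, 2.01, 2.00, 1.99, 1.98)))
  expect_equal(cv$stable_start, 25)
  expect_equal(cv$stable_end, 50)
  expect_equal(cv$k_star, 30)
  expect_false(cv$fallback)
  # flat curve: first delta already stable, smallest-k tie-break
  cv2 <- select_k(mk(rep(1.2, 10)))
  expect_equal(cv2$stable_start, 10)
  expect_equal(cv2$stable_end, 50)
  expect_equal(cv2$k_star, 10)
  # alternating curve: no stable interval, explicit fallback to global peak
  cv3 <- select_k(mk(rep(c(1, 2), 5)))
  expect_true(cv3$fallback)
  expect_true(is.na(cv3$stable_start))
  expect_equal(cv3$k_star, 10)
})

test_that("spot identity applies argmax and threshold rules with tie-breaks", {
  comp <- rbind(c(0.6, 0.3, 0.1),
                c(0.5, 0.5, 0.0),
                c(0.35, 0.33, 0.32))
  colnames(comp) <- c("beta", "alpha", "gamma")
  rownames(comp) <- paste0("s", 1:3)
  id <- call_spot_identity(comp, "argmax")
  expect_equal(unname(id["s1"]), "beta")
  expect_equal(unname(id["s2"]), "alpha")  # lexicographic tie-break
  idt <- call_spot_identity(comp, "threshold", tau = 0.3)
  expect_equal(unname(idt["s3"]), "beta")  # only the largest above tau
  idt2 <- call_spot_identity(comp, "threshold", tau = 0.7)
  expect_true(is.na(idt2["s3"]))
  expect_error(call_spot_identity(comp, "threshold", tau = 1.5),
               class = "invalid_threshold")
})

test_that("Moran's I closed forms and formula oracle", {
  # n = 2, symmetric unit weights: I = -1 regardless of the values
  m <- morans_i(toy_spots(c(0, 1)), c(0.2, 0.9), k_weights = 1)
  expect_equal(m$I, -1)
  expect_true(is.na(m$p_value))
  # alternating values on a line, k = 1
  sp <- toy_spots(0:3)
  vals <- c(1, -1, 1, -1)
  m2 <- morans_i(sp, vals, k_weights = 1, n_perm = 0)
  expect_equal(m2$I, oracle_moran(sp, vals, 1), tolerance = 1e-12)
  expect_equal(m2$expected_I, -1 / 3)
  # random instances against the double-sum oracle
  for (s in 1:50) {
    inst <- random_instance(s + 300, n_min = 5, n_max = 7)
    got <- morans_i(inst$spots, inst$r, inst$k, n_perm = 0)
    expect_equal(got$I, oracle_moran(inst$spots, inst$r, inst$k), tolerance = 1e-12)
  }
  expect_error(morans_i(sp, rep(1, 4), 1), class = "zero_variance")
})

test_that("exhaustive permutation mean of Moran's I equals -1/(n-1)", {
  set.seed(53)
  sp <- data.frame(spot_id = paste0("s", 1:5), x = runif(5), y = runif(5))
  vals <- c(3.2, -1.1, 0.4, 2.2, -0.6)
  perms <- all_perms(5)
  Is <- vapply(seq_len(nrow(perms)), function(i) {
    morans_i(sp, vals[perms[i, ]], k_weights = 2, n_perm = 0)$I
  }, numeric(1))
  expect_equal(mean(Is), -0.25, tolerance = 1e-12)
})

test_that("spatial correlation follows the rank definition", {
  a <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 7, 0.3)
  expect_equal(spatial_correlation(a, a)$R, 1)
  expect_equal(spatial_correlation(a, max(a) - a)$R, -1)
  set.seed(61)
  b <- rnorm(10)
  got <- spatial_correlation(a, b)
  expect_equal(got$R, cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(spatial_correlation(a, b, method = "pearson")$R, cor(a, b),
               tolerance = 1e-12)
  expect_error(spatial_correlation(a, rep(1, 10)), class = "zero_variance")
})
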