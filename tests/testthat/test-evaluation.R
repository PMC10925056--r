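test_that("normalized entropy hits its boundary cases", {
  lab <- rep(1:3, each = 10)
  expect_equal(normalized_entropy(lab, lab)$normalized, 0)
  # one cluster, uniform reference over l classes -> maximal disorder
  expect_equal(normalized_entropy(rep(1, 12), rep(1:4, 3))$normalized, 1)
  expect_error(normalized_entropy(1:4, rep("x", 4)), "categories")
})

test_that("entropy matches term-by-term summation on a hand-checked table", {
  # contingency [[3,1],[0,4]], n = 8, l = 2
  labels <- rep(c("A", "B"), c(4, 4))
  reference <- c("x", "x", "x", "y", "y", "y", "y", "y")
  got <- normalized_entropy(labels, reference)
  hand <- -(3 * log(3 / 4) + 1 * log(1 / 4)) / (8 * log(2))
  expect_equal(got$normalized, hand, tolerance = 1e-14)
  expect_equal(entropy_oracle(got$counts), got$normalized,
               tolerance = 1e-14)
})

test_that("entropy equals the weighted per-cluster form and is label-invariant", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    lab <- sample(1:4, n, replace = TRUE)
    ref <- sample(letters[1:3], n, replace = TRUE)
    er <- normalized_entropy(lab, ref)
    # H = sum (n_q / n) H_q with consistently normalized H_q
    expect_equal(er$overall,
                 sum(rowSums(er$counts) / er$n * er$per_cluster_entropy),
                 tolerance = 1e-12)
    expect_equal(er$normalized, er$overall / er$h_max, tolerance = 1e-12)
    # relabeling clusters and categories changes nothing
    perm_lab <- c(9, 7, 8, 5)[lab]
    perm_ref <- setNames(c("Q", "R", "S"), letters[1:3])[ref]
    expect_equal(normalized_entropy(perm_lab, perm_ref)$normalized,
                 er$normalized, tolerance = 1e-12)
  }
})

test_that("scrambling a zero fraction reproduces the observed entropy", {
  lab <- rep(1:3, each = 8)
  ref <- rep(c("a", "b", "c"), each = 8)
  sc <- scramble_null(lab, ref, fraction = 0, reps = 20, seed = 1)
  expect_true(all(sc$values == sc$observed))
})

test_that("scrambling cannot decrease entropy in expectation for a matched labeling", {
  lab <- rep(1:3, each = 20)
  ref <- rep(c("a", "b", "c"), each = 20)
  sc <- scramble_null(lab, ref, fraction = 0.25, reps = 200, seed = 2)
  expect_gte(mean(sc$values), sc$observed)
})

test_that("the scramble distribution agrees with an independent sampler", {
  set.seed(5)
  lab <- sample(1:3, 100, replace = TRUE)
  ref <- sample(c("a", "b", "c", "d"), 100, replace = TRUE)
  sc <- scramble_null(lab, ref, fraction = 0.25, reps = 200, seed = 7)
  # independent Monte-Carlo re-implementation
  cats <- unique(ref)
  set.seed(99)
  indep <- replicate(200, {
    r2 <- ref
    idx <- sample(100, 25)
    r2[idx] <- cats[sample.int(length(cats), 25, replace = TRUE)]
    normalized_entropy(lab, r2)$normalized
  })
  se <- sqrt(var(sc$values) / 200 + var(indep) / 200)
  expect_lt(abs(mean(sc$values) - mean(indep)), 3 * se)
})

test_that("forced dropout masks the requested count, disjointly and reproducibly", {
  sim <- small_sim(n_cells = 30, n_modules = 40, seed = 4)
  X <- sim_matrix(sim, min_sites = 15)
  n_obs <- sum(!is.na(X))
  fd <- forced_dropout(X, 0.5, seed = 9)
  expect_equal(nrow(fd$heldout), round(0.5 * n_obs))
  # held-out positions are NA in the masked matrix and observed in X
  idx <- cbind(fd$heldout$row, fd$heldout$col)
  expect_true(all(is.na(fd$masked[idx])))
  expect_true(all(!is.na(X[idx])))
  # everything else is untouched
  untouched <- !is.na(fd$masked)
  expect_identical(fd$masked[untouched], X[untouched])
  # no starved rows or columns, and the same seed reproduces the mask
  expect_true(all(rowSums(!is.na(fd$masked)) > 0))
  expect_true(all(colSums(!is.na(fd$masked)) > 0))
  fd2 <- forced_dropout(X, 0.5, seed = 9)
  expect_identical(fd$masked, fd2$masked)
})

test_that("imputation error grows with the dropout fraction", {
  sim <- simulate_splicing(n_cells = 60, n_clusters = 2, n_modules = 50,
                           seed = 23)
  X <- sim_matrix(sim)
  ib <- imputation_benchmark(X, fractions = c(0.1, 0.3, 0.9), seed = 1,
                             reps = 2)
  expect_true(all(diff(ib$summary$mean) > 0))
  expect_equal(nrow(ib$t_tests), 3L)
  # single fraction: no pairwise tests, no error
  ib1 <- imputation_benchmark(X, fractions = 0.2, seed = 1, reps = 1)
  expect_null(ib1$t_tests)
  # determinism
  ib2 <- imputation_benchmark(X, fractions = 0.2, seed = 1, reps = 1)
  expect_identical(ib1$summary, ib2$summary)
})

test_that("an unperturbed robustness run reproduces the baseline labels", {
  sim <- small_sim(n_cells = 45, n_modules = 40, seed = 6)
  X <- sim_matrix(sim)
  rs <- robustness_suite(X, "site-deletion", grid = 0, seed = 2,
                         k_clusters = 3, k = 5, n_pcs = 10, graph_k = 5)
  expect_equal(rs$results$entropy, 0)
  rs2 <- robustness_suite(X, "cell-subsample", grid = c(0.75, 0.5),
                          seed = 2, k_clusters = 3, k = 5, n_pcs = 10,
                          graph_k = 5)
  expect_equal(rs2$results$n_cells,
               c(round(0.75 * ncol(X)), round(0.5 * ncol(X))))
  expect_true(all(rs2$results$entropy >= 0 & rs2$results$entropy <= 1))
})

test_that("within-cell shuffling preserves column sums and is seeded", {
  M <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("c", 1:5)))
  S1 <- shuffle_within_cells(M, seed = 3)
  S2 <- shuffle_within_cells(M, seed = 3)
  expect_identical(S1, S2)
  expect_equal(colSums(S1), colSums(M))
  expect_false(identical(S1, M))
})

test_that("shuffling the indicator degrades clustering against truth", {
  sim <- simulate_splicing(n_cells = 60, n_clusters = 3, n_modules = 50,
                           seed = 31)
  X <- sim_matrix(sim)
  R <- missing_indicator(X)
  Z <- knn_impute(X, k = 10, iterations = 3)$Z
  truth <- sim$labels[colnames(X)]
  npc <- min(20, min(2 * nrow(Z), ncol(Z)) - 1)
  run <- function(Rmat) {
    co <- reduce_pca(feature_matrix(Z, Rmat), npc)
    spectral_cluster(co, 3, graph_k = 10, seed = 1)$labels
  }
  h_orig <- normalized_entropy(run(R), truth)$normalized
  h_shuf <- normalized_entropy(run(shuffle_within_cells(R, seed = 8)),
                               truth)$normalized
  expect_gte(h_shuf, h_orig)
})
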