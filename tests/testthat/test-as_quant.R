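test_that("junctions sharing a splice site form modules; singletons are dropped", {
  tab <- make_tab(c("chr1", "chr1"), c(100, 100), c(200, 300), "+",
                  c("c1", "c1"), c(5, 5))
  mods <- build_as_modules(tab)
  expect_equal(length(unique(mods$module_id)), 1L)
  expect_equal(nrow(mods), 2L)
  expect_true(all(mods$side == "L"))
  expect_true(all(mods$anchor == 100))

  lone <- make_tab("chr1", 500, 900, "+", "c1", 5)
  expect_equal(nrow(build_as_modules(lone)), 0L)
})

test_that("a junction can belong to a shared-left and a shared-right module", {
  # (100,200), (100,300), (150,300): brute-force grouping says one L-module
  # at 100 (members 200, 300) and one R-module at 300 (members 100, 150)
  tab <- make_tab(rep("chr1", 3), c(100, 100, 150), c(200, 300, 300), "+",
                  rep("c1", 3), rep(5, 3))
  mods <- build_as_modules(tab)
  # brute-force oracle over all end-sharing pairs
  jx <- unique(tab[, c("start", "end")])
  expected <- list()
  for (side in c("L", "R")) {
    key <- if (side == "L") jx$start else jx$end
    for (a in unique(key))
      if (sum(key == a) >= 2)
        expected[[paste(side, a)]] <- sort(paste(jx$start[key == a],
                                                 jx$end[key == a]))
  }
  got <- split(paste(mods$start, mods$end),
               paste(mods$side, mods$anchor))
  got <- lapply(got, sort)
  expect_equal(got[order(names(got))], expected[order(names(expected))])
  # the (100,300) junction appears in both modules
  expect_equal(sum(mods$start == 100 & mods$end == 300), 2L)
})

test_that("strand separates module grouping", {
  tab <- make_tab(rep("chr1", 2), c(100, 100), c(200, 300), c("+", "-"),
                  rep("c1", 2), c(5, 5))
  expect_equal(nrow(build_as_modules(tab)), 0L)
})

test_that("probabilities are count ratios gated by the per-cell module depth filter", {
  tab <- make_tab(rep("chr1", 6), rep(100, 6), rep(c(200, 300), 3), "+",
                  rep(c("c1", "c2", "c3"), each = 2),
                  c(30, 10,  8, 7,  21, 0))
  # c3 has counts {21, 0}: junction (100,300) absent there; rebuild with
  # explicit zero handled as absence
  tab <- tab[tab$count > 0, ]
  class(tab) <- c("junction_counts", "data.frame")
  mods <- build_as_modules(tab)
  X <- as_probabilities(tab, mods, min_module_reads = 20)
  expect_equal(unname(X[, "c1"]), c(0.75, 0.25))      # 30/40, 10/40
  expect_true(all(is.na(X[, "c2"])))                  # sum 15 <= 20
  expect_equal(unname(X[, "c3"]), c(1.0, 0.0))        # sum 21 > 20, boundary
})

test_that("a module sum of exactly the threshold is discarded (strict >)", {
  tab <- make_tab(rep("chr1", 2), c(100, 100), c(200, 300), "+", "c1",
                  c(15, 5))
  mods <- build_as_modules(tab)
  X <- as_probabilities(tab, mods, min_module_reads = 20)
  expect_true(all(is.na(X)))
  X2 <- as_probabilities(tab, mods, min_module_reads = 19)
  expect_equal(unname(X2[, 1]), c(0.75, 0.25))
})

test_that("observed module probabilities sum to one per (module, cell)", {
  sim <- small_sim(n_cells = 20, n_modules = 15, seed = 5)
  mods <- build_as_modules(sim$junctions)
  X <- as_probabilities(sim$junctions, mods)
  for (m in unique(mods$module_id)) {
    sub <- X[mods$module_id == m, , drop = FALSE]
    sums <- colSums(sub)
    expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
    # within a module a cell is all-observed or all-missing
    expect_true(all(colSums(is.na(sub)) %in% c(0L, nrow(sub))))
  }
  # site count equals the total module membership, <= 2 sites per junction
  expect_equal(nrow(X), nrow(mods))
  jkey <- paste(mods$start, mods$end)
  expect_true(all(table(jkey) <= 2))
})

test_that("raising the depth threshold never turns missing into observed", {
  sim <- small_sim(n_cells = 15, n_modules = 10, seed = 7)
  mods <- build_as_modules(sim$junctions)
  X20 <- as_probabilities(sim$junctions, mods, min_module_reads = 20)
  X40 <- as_probabilities(sim$junctions, mods, min_module_reads = 40)
  expect_true(all(is.na(X40[is.na(X20)])))
})

test_that("coverage filtering reaches the brute-force fixed point", {
  # site observed in too few cells is removed
  X <- matrix(NA_real_, 3, 12,
              dimnames = list(paste0("s", 1:3), paste0("c", 1:12)))
  X[1, 1:9] <- 0.5; X[2, ] <- 0.4; X[3, ] <- 0.6
  Xf <- filter_as_matrix(X, min_cells_per_site = 10,
                         min_sites_per_cell = 1)
  expect_equal(rownames(Xf), c("s2", "s3"))

  # already-valid matrix is unchanged (fixed point / idempotence)
  expect_identical(filter_as_matrix(Xf, 10, 1), Xf)

  # cascading removal agrees with an exhaustive alternate-until-stable
  # oracle over a batch of random sparsity patterns; patterns whose fixed
  # point is empty must error instead
  set.seed(11)
  for (rep in 1:10) {
    Y <- matrix(runif(20 * 15), 20, 15,
                dimnames = list(paste0("s", 1:20), paste0("c", 1:15)))
    Y[sample(length(Y), 110)] <- NA
    mc <- 7; ms <- 9
    Z <- Y
    repeat {
      before <- dim(Z)
      Z <- Z[rowSums(!is.na(Z)) >= mc, , drop = FALSE]
      Z <- Z[, colSums(!is.na(Z)) >= ms, drop = FALSE]
      if (identical(before, dim(Z))) break
    }
    if (any(dim(Z) == 0L)) {
      expect_error(filter_as_matrix(Y, mc, ms), "density")
    } else {
      got <- filter_as_matrix(Y, mc, ms)
      expect_identical(got, Z)
      expect_true(all(rowSums(!is.na(got)) >= mc))
      expect_true(all(colSums(!is.na(got)) >= ms))
    }
  }
})

test_that("over-aggressive thresholds raise an error pointing at the density map", {
  X <- matrix(c(0.5, NA, NA, 0.5), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  expect_error(filter_as_matrix(X, 10, 10), "density")
})

test_that("the indicator marks exactly the missing entries", {
  X <- matrix(c(0.2, NA, NA, 1.0), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  expect_equal(unname(missing_indicator(X)), matrix(c(0, 1, 1, 0), 2, 2))
  expect_true(all(missing_indicator(matrix(0.3, 2, 2)) == 0))
  expect_true(all(missing_indicator(X * NA) == 1))
})

test_that("coverage density reports marginals and missingness", {
  X <- matrix(c(0.2, NA, 0.3, 1.0), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  cd <- coverage_density(X)
  expect_equal(cd$missingness, 0.25)
  expect_equal(unname(cd$site_coverage), c(2, 1))
  expect_equal(unname(cd$cell_coverage), c(1, 2))
  expect_equal(coverage_density(matrix(0.5, 2, 2))$missingness, 0)
})

test_that("simulated per-cell coverage matches the binomial expectation", {
  sim <- simulate_splicing(n_cells = 40, n_modules = 120,
                           module_silencing_rate = 0.88,
                           depth_mean = 500, depth_dispersion = 50,
                           seed = 13)
  mods <- build_as_modules(sim$junctions)
  X <- as_probabilities(sim$junctions, mods)
  cd <- coverage_density(X)
  # with depth >> filter, observed fraction ~ 1 - silencing = 0.12
  expect_equal(mean(cd$cell_coverage) / nrow(X), 0.12, tolerance = 0.15)
})
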