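test_that("categorization uses strict thresholds and keeps missingness", {
  v <- c(0.95, 0.5, 0.6, 0.4, 0.61, 0.39, NA)
  got <- categorize_events(v)
  expect_equal(got, c("present", "indeterminate", "indeterminate",
                      "indeterminate", "present", "absent", NA))
  expect_error(categorize_events(v, present_thr = 0.3, absent_thr = 0.4))
})

test_that("Fisher p-values match known tables", {
  # perfectly polarized 10/0 vs 0/10: p = 2 / C(20,10)
  X <- rbind(s1 = c(rep(0.95, 10), rep(0.05, 10)))
  colnames(X) <- paste0("c", 1:20)
  lab <- setNames(rep(1:2, each = 10), colnames(X))
  res <- diff_splicing(X, lab, 1, 2)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$flagged)

  # balanced 5/5 vs 5/5: p = 1, not flagged
  X2 <- rbind(s1 = c(rep(c(0.95, 0.05), 5), rep(c(0.95, 0.05), 5)))
  colnames(X2) <- paste0("c", 1:20)
  res2 <- diff_splicing(X2, lab, 1, 2)
  expect_equal(res2$p_value, 1)
  expect_false(res2$flagged)
})

test_that("Fisher p-values agree with hypergeometric enumeration on small tables", {
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b + cc + d == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
    expect_equal(p_pkg, fisher_oracle(a, b, cc, d), tolerance = 1e-12)
  }
})

test_that("tests are symmetric in group order and joint label swaps", {
  set.seed(14)
  X <- matrix(sample(c(0.05, 0.95, 0.5, NA), 5 * 30, replace = TRUE),
              5, 30, dimnames = list(paste0("s", 1:5), paste0("c", 1:30)))
  lab <- setNames(rep(1:2, 15), colnames(X))
  r12 <- diff_splicing(X, lab, 1, 2)
  r21 <- diff_splicing(X, lab, 2, 1)
  expect_equal(r12$p_value, r21$p_value, tolerance = 1e-12)
  expect_equal(r12$mean_diff, -r21$mean_diff, tolerance = 1e-12)
  # swapping present/absent jointly (1 - X) preserves p-values
  rsw <- diff_splicing(1 - X, lab, 1, 2)
  shared <- intersect(r12$site_id, rsw$site_id)
  expect_equal(r12$p_value[match(shared, r12$site_id)],
               rsw$p_value[match(shared, rsw$site_id)], tolerance = 1e-12)
})

test_that("summaries come from raw observed entries only", {
  X <- rbind(s1 = c(0.9, 0.8, NA, 0.1, NA, 0.2))
  colnames(X) <- paste0("c", 1:6)
  lab <- setNames(rep(1:2, each = 3), colnames(X))
  res <- diff_splicing(X, lab, 1, 2)
  expect_equal(res$mean_diff, mean(c(0.9, 0.8)) - mean(c(0.1, 0.2)))
  expect_equal(res$median_diff, median(c(0.9, 0.8)) - median(c(0.1, 0.2)))
  expect_equal(res$detection_a, 2 / 3)
  expect_equal(res$detection_b, 2 / 3)
})

test_that("polarized simulated modules are flagged between their clusters", {
  sim <- simulate_splicing(n_cells = 80, n_clusters = 2, n_modules = 40,
                           informative_fraction = 0.5,
                           module_silencing_rate = 0.3, seed = 27)
  X <- sim_matrix(sim)
  lab <- sim$labels[colnames(X)]
  res <- diff_splicing(X, lab, 1, 2)
  ids <- spliceclust:::parse_site_ids(res$site_id)
  info_module <- ids$anchor <= round(0.5 * 40) * 10000
  # with 2 clusters only the two cluster-dominant junctions of an
  # informative module are differential; its remaining junction is rare
  # in both clusters
  jidx <- (ids$end - ids$anchor) / 100
  expect_gt(mean(res$flagged[info_module & jidx <= 2]), 0.9)
  expect_lt(mean(res$flagged[!info_module]), 0.1)
})

test_that("top events are ranked by p with deterministic tie-breaks", {
  res <- data.frame(site_id = c("s2", "s1", "s3", "s4"),
                    p_value = c(1e-5, 1e-5, 1e-3, 0.5),
                    mean_diff = c(0.5, 0.4, -0.3, 0.2),
                    flagged = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  got <- top_events(res, 10, direction_aware = FALSE)
  expect_equal(got$site_id, c("s1", "s2", "s3"))  # tie broken by id
  dirred <- top_events(res, 1, direction_aware = TRUE)
  expect_setequal(dirred$direction, c("up", "down"))

  # agreement with a full sort oracle on random results
  set.seed(41)
  big <- data.frame(site_id = sprintf("s%04d", sample(1000)),
                    p_value = round(runif(1000), 3),
                    mean_diff = rnorm(1000), flagged = TRUE,
                    stringsAsFactors = FALSE)
  got2 <- top_events(big, 50, direction_aware = FALSE)
  oracle <- big[order(big$p_value, big$site_id), ][1:50, ]
  expect_equal(got2$site_id, oracle$site_id)
})

test_that("junctions map to the most inclusive, then nearest, gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "test", "gene", 50, 500, ".", "+", ".",
          'gene_id "GENE_IN"', sep = "\t"),
    paste("chr1", "test", "gene", 900, 1400, ".", "+", ".",
          'gene_id "GENE_X"', sep = "\t"),
    paste("chr1", "test", "gene", 1250, 1600, ".", "+", ".",
          'gene_id "GENE_Y"', sep = "\t"),
    paste("chr2", "test", "gene", 10, 100, ".", "+", ".",
          'gene_id "GENE_FAR"', sep = "\t")), gtf)
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100, 1000, 5000), end = c(200, 1500, 6000),
    strand = "+", stringsAsFactors = FALSE)
  got <- map_junctions_to_genes(sites, gtf, window = 1000)
  expect_equal(got[1], "GENE_IN")        # unique containment
  # junction 1000-1500: GENE_X covers 1000-1400 (80%), GENE_Y 1250-1500 (50%)
  expect_equal(got[2], "GENE_X")
  expect_true(is.na(got[3]))             # nothing within the window
})
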