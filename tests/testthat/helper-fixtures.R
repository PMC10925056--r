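# shared fixture builders -- everything is generated in code

# minimal junction table from parallel vectors
make_tab <- function(chrom, start, end, strand, cell_id, count) {
  spliceclust:::new_junction_counts(data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, cell_id = cell_id, count = as.integer(count),
    stringsAsFactors = FALSE))
}

# write .junc lines to a temp file, return the path
write_junc_file <- function(lines, name = "cellA.junc", dir = tempdir()) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# small simulated dataset sized for fast tests
small_sim <- function(n_cells = 90, n_clusters = 3, n_modules = 80,
                      seed = 1, ...) {
  simulate_splicing(n_cells = n_cells, n_clusters = n_clusters,
                    n_modules = n_modules, seed = seed, ...)
}

# quantified + filtered matrix from a simulation
sim_matrix <- function(sim, min_cells = 5, min_sites = 20) {
  mods <- build_as_modules(sim$junctions)
  filter_as_matrix(as_probabilities(sim$junctions, mods),
                   min_cells_per_site = min_cells,
                   min_sites_per_cell = min_sites)
}

# independent two-sided Fisher oracle: exhaustive hypergeometric
# enumeration over all tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  lo <- max(0L, col1 - row2); hi <- min(row1, col1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent normalized-entropy oracle: direct term-by-term summation
entropy_oracle <- function(counts) {
  n <- sum(counts)
  l <- ncol(counts)
  acc <- 0
  for (q in seq_len(nrow(counts))) {
    nq <- sum(counts[q, ])
    if (nq == 0) next
    for (j in seq_len(l)) {
      nqj <- counts[q, j]
      if (nqj > 0) acc <- acc + nqj * log(nqj / nq)
    }
  }
  -acc / (n * log(l))
}
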