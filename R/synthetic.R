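#' Simulate per-cell junction counts with known cluster structure
#'
#' Generates the data regime the pipeline is built for: each cell belongs
#' to one of `n_clusters` clusters; each AS module is a set of
#' `junctions_per_module` junctions sharing a 5' splice site; per (cell,
#' module) sequencing depth is negative-binomial (overdispersed), the
#' module is silenced (zero reads) with probability
#' `module_silencing_rate` — together with the depth filter this drives
#' the high missingness typical of single-cell splicing data — and
#' junction counts are a multinomial draw from the module's cluster-
#' specific probabilities. Informative modules polarize a different
#' dominant junction per cluster (probability `polarization`, remainder
#' uniform); uninformative modules share one polarized junction across all
#' clusters, so they carry no cluster signal.
#'
#' @param n_cells number of cells (default 300).
#' @param n_clusters number of clusters (default 3).
#' @param cluster_proportions cluster mixing proportions (default equal).
#' @param n_modules number of AS modules (default 500).
#' @param junctions_per_module junctions per module, >= 2 (default 3).
#' @param informative_fraction fraction of modules whose dominant junction
#'   differs between clusters (default 0.6).
#' @param polarization dominant-junction probability, in
#'   (1/junctions_per_module, 1] (default 0.9).
#' @param depth_mean,depth_dispersion negative-binomial mean and size of
#'   the per-(cell, module) read depth (defaults 50 and 5).
#' @param module_silencing_rate probability a module yields zero reads in
#'   a cell (default 0.73, giving roughly 75% matrix missingness at the
#'   default depth model and a 20-read module filter).
#' @param seed RNG seed.
#' @return A `splice_sim` object: list with `junctions`
#'   (`junction_counts` table), `labels` (named integer vector of true
#'   clusters), `truth` (true site x cell probability matrix),
#'   `module_probs`, and the configuration.
#' @export
simulate_splicing <- function(n_cells = 300, n_clusters = 3,
                              cluster_proportions = NULL,
                              n_modules = 500, junctions_per_module = 3,
                              informative_fraction = 0.6,
                              polarization = 0.9,
                              depth_mean = 50, depth_dispersion = 5,
                              module_silencing_rate = 0.73, seed = 1) {
  J <- as.integer(junctions_per_module)
  if (J < 2L) stop("junctions_per_module must be >= 2")
  if (polarization <= 1 / J || polarization > 1)
    stop("polarization must lie in (1/junctions_per_module, 1]")
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must sum to 1")
  stopifnot(module_silencing_rate >= 0, module_silencing_rate <= 1,
            informative_fraction >= 0, informative_fraction <= 1)
  set.seed(seed)
  labels <- sample.int(n_clusters, n_cells, replace = TRUE,
                       prob = cluster_proportions)
  # guarantee every cluster is represented
  missing_cl <- setdiff(seq_len(n_clusters), unique(labels))
  if (length(missing_cl))
    labels[sample.int(n_cells, length(missing_cl))] <- missing_cl
  cells <- sprintf("cell%03d", seq_len(n_cells))
  names(labels) <- cells

  n_inf <- round(informative_fraction * n_modules)
  informative <- seq_len(n_modules) <= n_inf
  # module m: junctions share left anchor; coordinates unique per module
  # so no incidental shared-right modules arise
  anchors <- seq_len(n_modules) * 10000L
  rest <- (1 - polarization) / (J - 1L)

  # cluster-specific probability vectors per module
  module_probs <- array(rest, dim = c(n_modules, J, n_clusters))
  for (m in seq_len(n_modules)) {
    for (cl in seq_len(n_clusters)) {
      dom <- if (informative[m]) ((cl - 1L) %% J) + 1L else 1L
      module_probs[m, , cl] <- rest
      module_probs[m, dom, cl] <- polarization
    }
  }

  chrom <- character(0); jstart <- integer(0); jend <- integer(0)
  cell_v <- character(0); count_v <- integer(0)
  truth <- matrix(NA_real_, n_modules * J, n_cells)
  site_ids <- character(n_modules * J)
  for (m in seq_len(n_modules)) {
    a <- anchors[m]
    ends <- a + 100L * seq_len(J)
    site_ids[(m - 1L) * J + seq_len(J)] <-
      paste("chr1", "+", "L", a, ends, sep = ":")
    depth <- stats::rnbinom(n_cells, mu = depth_mean,
                            size = depth_dispersion)
    depth[stats::runif(n_cells) < module_silencing_rate] <- 0L
    counts <- matrix(0L, J, n_cells)
    for (cl in seq_len(n_clusters)) {
      idx <- which(labels == cl)
      if (length(idx) == 0L) next
      counts[, idx] <- rmultinom_vec(depth[idx], module_probs[m, , cl])
      truth[(m - 1L) * J + seq_len(J), idx] <- module_probs[m, , cl]
    }
    nz <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(nz)) {
      chrom <- c(chrom, rep("chr1", nrow(nz)))
      jstart <- c(jstart, rep(a, nrow(nz)))
      jend <- c(jend, ends[nz[, 1L]])
      cell_v <- c(cell_v, cells[nz[, 2L]])
      count_v <- c(count_v, counts[nz])
    }
  }
  tab <- new_junction_counts(data.frame(
    chrom = chrom, start = jstart, end = jend,
    strand = rep("+", length(chrom)),
    cell_id = cell_v, count = count_v, stringsAsFactors = FALSE))
  rownames(truth) <- site_ids
  colnames(truth) <- cells
  structure(list(junctions = tab, labels = labels, truth = truth,
                 module_probs = module_probs,
                 config = list(n_cells = n_cells, n_clusters = n_clusters,
                               cluster_proportions = cluster_proportions,
                               n_modules = n_modules,
                               junctions_per_module = J,
                               informative_fraction = informative_fraction,
                               polarization = polarization,
                               depth_mean = depth_mean,
                               depth_dispersion = depth_dispersion,
                               module_silencing_rate = module_silencing_rate,
                               seed = seed)),
            class = "splice_sim")
}

# multinomial draws with per-observation sizes, via the conditional
# binomial decomposition (exact)
rmultinom_vec <- function(sizes, prob) {
  J <- length(prob)
  n <- length(sizes)
  out <- matrix(0L, J, n)
  remaining <- as.integer(sizes)
  prem <- 1
  for (j in seq_len(J - 1L)) {
    if (prem <= 0) break                 # all mass already allocated
    pj <- min(max(prob[j] / prem, 0), 1)
    out[j, ] <- stats::rbinom(n, remaining, pj)
    remaining <- remaining - out[j, ]
    prem <- prem - prob[j]
  }
  out[J, ] <- remaining
  out
}

#' @export
print.splice_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("splice_sim: %d cells, %d clusters, %d modules x %d ",
                     "junctions (polarization %.2f)\n"),
              cfg$n_cells, cfg$n_clusters, cfg$n_modules,
              cfg$junctions_per_module, cfg$polarization))
  invisible(x)
}

#' Write a simulated dataset as a junction-file fixture
#'
#' One `.junc` file per cell in the requested dialect, a truth-labels TSV
#' (`cell_id`, `cluster`) and the true probability matrix TSV. The files
#' round-trip through [read_junctions()] with exact count recovery.
#'
#' @param sim a `splice_sim` object.
#' @param out_dir output directory (created if needed).
#' @param dialect coordinate dialect for the `.junc` files.
#' @return Invisible list of written paths (`junc_files`, `labels`,
#'   `truth`).
#' @export
write_sim_fixture <- function(sim, out_dir,
                              dialect = c("bed-intron", "anchor-bed")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- sim$junctions
  files <- character(0)
  for (cell in unique(tab$cell_id)) {
    sub <- tab[tab$cell_id == cell, , drop = FALSE]
    conv <- convert_coords(sub$start, sub$end, from = dialect,
                           reverse = TRUE)
    out <- data.frame(chrom = sub$chrom, start = conv$start,
                      end = conv$end,
                      name = sprintf("j%06d", seq_len(nrow(sub))),
                      count = sub$count, strand = sub$strand)
    f <- file.path(out_dir, paste0(cell, ".junc"))
    utils::write.table(out, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  lab_path <- file.path(out_dir, "truth_labels.tsv")
  utils::write.table(data.frame(cell_id = names(sim$labels),
                                cluster = unname(sim$labels)),
                     lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth_probabilities.tsv")
  write_as_matrix(sim$truth, truth_path)
  invisible(list(junc_files = files, labels = lab_path,
                 truth = truth_path))
}
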