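#' Cluster single cells by their alternative-splicing landscape
#'
#' The central fit: from per-cell junction counts it (1) groups junctions
#' sharing a 5' or 3' splice site into AS modules and converts counts to
#' per-cell event probabilities with a per-(module, cell) depth filter,
#' (2) filters sites and cells for coverage, (3) completes the missing
#' entries by iterative weighted kNN imputation, (4) stacks the completed
#' probabilities over the binary missingness indicator, reduces by PCA and
#' clusters the cells by spectral clustering on a kNN graph, selecting the
#' number of clusters by the elbow method when not given, and (5) computes
#' a 2D embedding for plotting.
#'
#' @param x input data: a `junction_counts` table (see
#'   [read_junctions()]), a directory containing `.junc` files, a
#'   character vector of `.junc` paths, or a `splice_sim` object.
#' @param dialect coordinate dialect when reading files.
#' @param min_module_reads per-(module, cell) depth filter: a module needs
#'   strictly more than this many summed junction reads in a cell to be
#'   quantified there (default 20).
#' @param min_cells_per_site,min_sites_per_cell coverage filters
#'   (defaults 10 and 1000; scale `min_sites_per_cell` to the size of the
#'   dataset — see [coverage_density()]).
#' @param k imputation neighbours (default 10).
#' @param iterations imputation rounds (default 3).
#' @param tol imputation early-stop tolerance (default 0).
#' @param n_pcs principal components kept (default 20, capped at the data
#'   dimension).
#' @param n_clusters number of clusters, or `"auto"` for elbow selection.
#' @param graph_k kNN parameter of the spectral graph (default 10).
#' @param k_min,k_max elbow-search range when `n_clusters = "auto"`.
#' @param seed seed for all randomized stages (k-means restarts, elbow).
#' @return A `spliceclust` object: list with `labels` (named integer
#'   vector), `k_clusters`, `X` (filtered raw probability matrix), `R`
#'   (indicator), `imputation` (the [knn_impute()] result), `coords` (PCA
#'   cell coordinates), `embedding` (N x 2), `modules`, `elbow` (NULL when
#'   k was given), `params`. Methods: `print`, `summary`, `plot`,
#'   `labels`.
#' @examples
#' sim <- simulate_splicing(n_cells = 60, n_modules = 40, seed = 1)
#' fit <- spliceclust(sim, min_sites_per_cell = 20, n_clusters = 3)
#' table(labels(fit), sim$labels)
#' @export
spliceclust <- function(x, dialect = c("bed-intron", "anchor-bed"),
                        min_module_reads = 20, min_cells_per_site = 10,
                        min_sites_per_cell = 1000,
                        k = 10, iterations = 3, tol = 0,
                        n_pcs = 20, n_clusters = "auto", graph_k = 10,
                        k_min = 2, k_max = 12, seed = 1) {
  dialect <- match.arg(dialect)
  tab <- if (inherits(x, "splice_sim")) x$junctions
    else if (inherits(x, "junction_counts")) x
    else if (is.character(x) && length(x) == 1L && dir.exists(x))
      read_junctions(list.files(x, pattern = "\\.junc$",
                                full.names = TRUE), dialect = dialect)
    else if (is.character(x)) read_junctions(x, dialect = dialect)
    else stop("unsupported input type for spliceclust()")
  if (nrow(tab) == 0L) stop("no junction records in input")

  modules <- build_as_modules(tab)
  if (nrow(modules) == 0L) stop("no AS modules with >= 2 junctions found")
  X0 <- as_probabilities(tab, modules, min_module_reads = min_module_reads)
  X <- filter_as_matrix(X0, min_cells_per_site = min_cells_per_site,
                        min_sites_per_cell = min_sites_per_cell)
  R <- missing_indicator(X)
  imp <- knn_impute(X, k = k, iterations = iterations, tol = tol)
  D <- feature_matrix(imp$Z, R)
  npc <- min(n_pcs, min(dim(D)) - 1L)
  coords <- reduce_pca(D, n_components = npc)

  elbow <- NULL
  if (identical(n_clusters, "auto")) {
    elbow <- select_k_elbow(coords, k_min = k_min, k_max = k_max,
                            graph_k = graph_k, seed = seed)
    n_clusters <- elbow$k
  }
  cl <- spectral_cluster(coords, n_clusters, graph_k = graph_k,
                         seed = seed)
  emb <- embed_cells(coords)
  structure(list(labels = cl$labels, k_clusters = cl$k_clusters,
                 X = X, R = R, imputation = imp, coords = coords,
                 embedding = emb, modules = modules, elbow = elbow,
                 clustering = cl,
                 params = list(dialect = dialect,
                               min_module_reads = min_module_reads,
                               min_cells_per_site = min_cells_per_site,
                               min_sites_per_cell = min_sites_per_cell,
                               k = k, iterations = iterations, tol = tol,
                               n_pcs = npc, graph_k = graph_k,
                               seed = seed)),
            class = "spliceclust")
}

#' @export
print.spliceclust <- function(x, ...) {
  cat(sprintf("spliceclust fit: %d cells, %d AS sites, %d clusters\n",
              ncol(x$X), nrow(x$X), x$k_clusters))
  cat(sprintf("  missingness before imputation: %.1f%%\n",
              100 * mean(x$R)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
summary.spliceclust <- function(object, ...) {
  dens <- coverage_density(object$X)
  cat(sprintf("spliceclust fit of %d cells on %d AS sites\n",
              ncol(object$X), nrow(object$X)))
  cat(sprintf("  matrix missingness: %.1f%% (indicator mean)\n",
              100 * mean(object$R)))
  cat(sprintf("  imputation: k = %d, %d iteration(s), mean |change| %s\n",
              object$imputation$k, object$imputation$iterations_run,
              paste(signif(object$imputation$per_iteration_change, 3),
                    collapse = " -> ")))
  cat(sprintf("  PCA components: %d; spectral graph k = %d\n",
              object$params$n_pcs, object$params$graph_k))
  if (!is.null(object$elbow))
    cat(sprintf("  elbow-selected k = %d (confident: %s)\n",
                object$elbow$k, object$elbow$confident))
  cat(sprintf("  clusters: %d; sizes: %s\n", object$k_clusters,
              paste(table(object$labels), collapse = ", ")))
  cat(sprintf("  median observed sites per cell: %d\n",
              as.integer(stats::median(dens$cell_coverage))))
  invisible(object)
}

#' Extract cluster labels from a fit
#' @param object a `spliceclust` fit.
#' @param ... unused.
#' @return Named integer vector of cluster labels (1-based).
#' @export
labels.spliceclust <- function(object, ...) object$labels

#' Plot the 2D embedding coloured by cluster
#' @param x a `spliceclust` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spliceclust <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(x$k_clusters, 2L), "Dark 3")
  graphics::plot(x$embedding, col = cols[x$labels], pch = 19,
                 xlab = "dim 1", ylab = "dim 2",
                 main = "splicing-landscape clustering", ...)
  graphics::legend("topright", legend = sort(unique(x$labels)),
                   col = cols[sort(unique(x$labels))], pch = 19,
                   title = "cluster", bty = "n")
  invisible(x)
}
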