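#' Stack imputed probabilities over the missingness indicator
#'
#' The clustering features are the completed probability matrix with the
#' binary indicator of originally missing entries appended below it, giving
#' a 2M x N matrix: the splicing pattern and the dropout pattern both carry
#' cluster signal. Indicator rows keep their 0/1 scale, commensurate with
#' probabilities in [0,1].
#'
#' @param Z completed M x N probability matrix.
#' @param R M x N binary indicator from [missing_indicator()].
#' @return 2M x N matrix; indicator rows are suffixed `"|na"`.
#' @export
feature_matrix <- function(Z, R) {
  if (!identical(dim(Z), dim(R)) ||
      !identical(rownames(Z), rownames(R)) ||
      !identical(colnames(Z), colnames(R)))
    stop("feature_matrix: Z and R must share shape and dimnames")
  D <- rbind(Z, R)
  rownames(D) <- c(rownames(Z), paste0(rownames(R), "|na"))
  D
}

#' PCA reduction of the feature matrix
#'
#' Cells (columns of D) are the observations. Components are centred, not
#' scaled. Signs are fixed by making the largest-magnitude loading of each
#' component positive, so results are fully deterministic.
#'
#' @param D feature matrix (rows = features, columns = cells).
#' @param n_components number of components to keep (default 20).
#' @return N x n_components matrix of cell coordinates, with the explained
#'   variance per component in attribute `"explained_variance"`.
#' @export
reduce_pca <- function(D, n_components = 20) {
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components >= min(dim(D)))
    stop("reduce_pca: n_components must be in [1, min(2M, N) - 1]")
  pc <- stats::prcomp(t(D), center = TRUE, scale. = FALSE,
                      rank. = n_components)
  rot <- pc$rotation
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, `*`)
  attr(coords, "explained_variance") <-
    pc$sdev[seq_len(n_components)]^2
  coords
}

#' Build the cell-cell spectral graph
#'
#' Affinities are Gaussian in the Euclidean distance,
#' \eqn{w_{ij} = \exp(-2 d(v_i, v_j) / \sigma^2)} with a single global
#' \eqn{\sigma^2}, the variance of all pairwise distances. The graph is
#' polarized by k-nearest neighbours: the adjacency sums the two
#' one-directional kNN indicators, so entries are 0, 1 (one-way) or 2
#' (mutual). The normalized Laplacian is
#' \eqn{L = I - Deg^{-1/2} A Deg^{-1/2}} with degrees taken from A, which
#' keeps the eigenvalues of L inside [0, 2].
#'
#' @param coords N x p cell coordinates (rows = cells).
#' @param graph_k neighbours per cell for the kNN polarization (default 10).
#' @return List with `W` (dense affinity), `A` (kNN adjacency), `degree`,
#'   and `L` (normalized Laplacian).
#' @export
spectral_graph <- function(coords, graph_k = 10) {
  n <- nrow(coords)
  if (graph_k >= n) stop("spectral_graph: graph_k must be < number of cells")
  D <- as.matrix(stats::dist(coords))
  ut <- D[upper.tri(D)]
  s2 <- stats::var(ut)
  W <- if (!is.finite(s2) || s2 <= 0) matrix(1, n, n)
       else exp(-2 * D / s2)
  diag(W) <- 1
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(graph_k)]        # ties broken by cell index
    A[i, nb] <- A[i, nb] + 1
  }
  A <- A + t(A)                             # A_ij = 1(j in kNN(i)) + 1(i in kNN(j))
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (dinv %o% dinv) * A
  dimnames(W) <- dimnames(A) <- dimnames(L) <-
    list(rownames(coords), rownames(coords))
  names(deg) <- rownames(coords)
  list(W = W, A = A, degree = deg, L = L)
}

#' Spectral clustering of cells
#'
#' Computes the eigenvectors of the normalized Laplacian belonging to the
#' `k_clusters` smallest eigenvalues and clusters their rows with k-means
#' (multiple seeded restarts). If the graph has more connected components
#' than requested clusters a warning is issued (the zero eigenvalue then has
#' higher multiplicity than k).
#'
#' @param coords N x p cell coordinates.
#' @param k_clusters number of clusters (2 <= k_clusters <= N).
#' @param graph_k kNN polarization parameter (default 10).
#' @param seed RNG seed for the k-means restarts.
#' @return A `cell_clustering` object: list with `labels` (named integer
#'   vector, values 1..k), `k_clusters`, `graph` (the [spectral_graph()]),
#'   `eigenvalues`.
#' @export
spectral_cluster <- function(coords, k_clusters, graph_k = 10, seed = 1) {
  n <- nrow(coords)
  if (k_clusters < 1L || k_clusters > n)
    stop("spectral_cluster: k_clusters must be in [1, N]")
  if (k_clusters == n) {
    labels <- seq_len(n)
    names(labels) <- rownames(coords)
    return(structure(list(labels = labels, k_clusters = n,
                          graph = NULL, eigenvalues = NULL),
                     class = "cell_clustering"))
  }
  g <- spectral_graph(coords, graph_k = graph_k)
  eg <- eigen(g$L, symmetric = TRUE)
  ev <- rev(eg$values)                      # ascending
  n_zero <- sum(ev < 1e-10)
  if (n_zero > k_clusters)
    warning(sprintf(paste0("graph has %d connected components but only %d ",
                           "clusters requested"), n_zero, k_clusters))
  U <- eg$vectors[, rev(seq_len(ncol(eg$vectors)))[seq_len(k_clusters)],
                  drop = FALSE]
  km <- kmeans_restarts(U, k_clusters, nstart = 20, seed = seed)
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(coords)
  structure(list(labels = labels, k_clusters = as.integer(k_clusters),
                 graph = g, eigenvalues = ev),
            class = "cell_clustering")
}

#' @export
print.cell_clustering <- function(x, ...) {
  cat(sprintf("cell_clustering: %d cells in %d clusters\n",
              length(x$labels), x$k_clusters))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Choose the number of clusters by the elbow method
#'
#' Runs k-means on the cell coordinates for each candidate k and records
#' the within-cluster sum of squares (WCSS). The elbow is the k maximizing
#' the (discrete) second difference of the WCSS curve, i.e. the sharpest
#' bend; for well-separated clusters the curve drops to the noise floor at
#' the true k. The full curve is returned so the choice can be overridden.
#'
#' @param coords N x p cell coordinates.
#' @param k_min,k_max candidate range (defaults 2 and 12).
#' @param graph_k kept for interface compatibility with
#'   [spectral_cluster()]; the WCSS curve itself does not use the graph.
#' @param seed RNG seed.
#' @return List with `k` (selected), `wcss` (named numeric vector over the
#'   candidate range) and `confident` (FALSE when the curve shows no clear
#'   knee or is non-monotone).
#' @export
select_k_elbow <- function(coords, k_min = 2, k_max = 12, graph_k = 10,
                           seed = 1) {
  n <- nrow(coords)
  if (k_max >= n) k_max <- n - 1L
  if (k_max < k_min) stop("select_k_elbow: empty candidate range")
  ks <- seq.int(k_min, k_max)
  wcss <- vapply(ks, function(k) {
    kmeans_restarts(coords, k, nstart = 20, seed = seed + k)$tot.withinss
  }, numeric(1))
  names(wcss) <- ks
  confident <- TRUE
  if (any(diff(wcss) > 0)) {
    warning("WCSS curve is not non-increasing; falling back to k_min")
    return(list(k = as.integer(k_min), wcss = wcss, confident = FALSE))
  }
  if (length(ks) < 3L) {
    k <- ks[1L]
    confident <- FALSE
  } else {
    sec <- wcss[seq_len(length(ks) - 2L)] -
           2 * wcss[seq.int(2L, length(ks) - 1L)] +
           wcss[seq.int(3L, length(ks))]
    k <- ks[which.max(sec) + 1L]
    if (max(sec) <= 1e-8 * max(wcss[1], 1)) confident <- FALSE
  }
  list(k = as.integer(k), wcss = wcss, confident = confident)
}

# Seeded k-means with deterministic restarts. Exact duplicate rows (e.g.
# eigenvectors of disconnected identical cliques) would make random center
# draws fail, so centers are drawn from the distinct rows; when there are
# no more distinct rows than clusters, each distinct row is its own center.
kmeans_restarts <- function(x, k, nstart = 20, seed = 1) {
  set.seed(seed)
  key <- do.call(paste, c(as.data.frame(x), sep = "\r"))
  ukey <- unique(key)
  if (length(ukey) <= k) {
    cl <- match(key, ukey)
    return(list(cluster = cl, tot.withinss = 0))
  }
  uidx <- which(!duplicated(key))
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- x[uidx[sample.int(length(uidx), k)], , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Two-dimensional embedding for visualisation
#'
#' Classical multidimensional scaling of the Euclidean distances between
#' the PCA cell coordinates. Deterministic; used for plotting only, never
#' for clustering.
#'
#' @param coords N x p cell coordinates.
#' @param seed kept for interface stability; the embedding is
#'   deterministic and does not consume randomness.
#' @return N x 2 coordinate matrix.
#' @export
embed_cells <- function(coords, seed = 1) {
  n <- nrow(coords)
  if (n < 3L) {
    out <- cbind(coords[, 1L], if (ncol(coords) > 1L) coords[, 2L]
                               else rep(0, n))
  } else {
    out <- stats::cmdscale(stats::dist(coords), k = 2L)
    if (ncol(out) < 2L) out <- cbind(out, 0)
  }
  flip <- vapply(seq_len(2L), function(j) {
    v <- out[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  out <- sweep(out[, 1:2, drop = FALSE], 2L, flip, `*`)
  dimnames(out) <- list(rownames(coords), c("dim1", "dim2"))
  out
}
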