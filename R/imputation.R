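#' Mean initialization of missing probabilities
#'
#' Each missing entry is replaced by the mean of the observed values at the
#' same AS site (row). Every row must carry at least one observed value,
#' which [filter_as_matrix()] guarantees.
#'
#' @param X probability matrix with NA for missing entries.
#' @return Completed matrix; observed entries unchanged.
#' @export
mean_impute <- function(X) {
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0L))
    stop("mean_impute: some sites have no observed values; ",
         "run filter_as_matrix() first")
  rmean <- rowSums(X, na.rm = TRUE) / rowSums(obs)
  idx <- which(!obs)
  X[idx] <- rmean[((idx - 1L) %% nrow(X)) + 1L]
  X
}

#' Iterative weighted k-nearest-neighbour imputation
#'
#' Starting from [mean_impute()], each iteration recomputes pairwise
#' Euclidean distances between cell columns of the current completed
#' matrix, finds each cell's `k` nearest neighbour cells (self excluded,
#' ties broken by cell index), forms Gaussian weights
#' \eqn{w_i = \exp(-d(n, n_i) / (2\sigma^2))} with \eqn{\sigma^2} the
#' variance of that cell's k neighbour distances, normalizes them to sum to
#' one, and replaces only the originally missing entries with the weighted
#' average of the neighbours' values at that site. As in standard kNN
#' imputation the average is taken over the neighbours that actually
#' carry an observed value at the site (weights renormalized over them);
#' only when none of the k neighbours is observed there does the update
#' fall back to the neighbours' current estimates, which the next round
#' then refines. When all k neighbour distances are identical the
#' Gaussian kernel degenerates and uniform weights 1/k are used (its
#' limit). Iteration stops after `iterations` rounds, or earlier when the
#' mean absolute change over imputed entries drops to `tol` or below
#' (`tol = 0` runs the fixed number of rounds).
#'
#' Imputed values are convex combinations of values in [0,1], so the result
#' needs no clamping; observed entries are returned bit-identical.
#'
#' @param X probability matrix with NA for missing entries, already passed
#'   through [filter_as_matrix()].
#' @param k number of neighbour cells (default 10).
#' @param iterations number of refinement rounds (default 3).
#' @param tol early-stopping threshold on the mean absolute change over
#'   imputed entries (default 0: never stop early).
#' @return A `knn_imputation` object: list with `Z` (completed matrix),
#'   `k`, `iterations_run`, `per_iteration_change`, `converged`.
#' @export
knn_impute <- function(X, k = 10, iterations = 3, tol = 0) {
  n <- ncol(X)
  if (k >= n) stop("knn_impute: k must be smaller than the number of cells")
  miss <- is.na(X)
  Z <- mean_impute(X)
  change <- numeric(0)
  it_run <- 0L
  any_missing <- any(miss)
  for (it in seq_len(iterations)) {
    if (!any_missing) break
    D <- as.matrix(stats::dist(t(Z)))
    if (any(!is.finite(D))) stop("knn_impute: non-finite cell distance")
    Znew <- Z
    for (j in seq_len(n)) {
      mj <- which(miss[, j])
      if (length(mj) == 0L) next
      d <- D[, j]
      d[j] <- Inf
      nb <- order(d)[seq_len(k)]            # ties broken by cell index
      dn <- d[nb]
      s2 <- stats::var(dn)
      # shifted exponent: w_i / sum(w) is invariant under subtracting the
      # minimum distance, and the shift prevents the kernel underflowing
      # to an all-zero weight vector when s2 is tiny
      w <- if (!is.finite(s2) || s2 <= 0) rep(1 / k, k)
           else exp(-(dn - dn[1L]) / (2 * s2))
      w <- w / sum(w)
      nb_obs <- !miss[mj, nb, drop = FALSE]       # observed donors
      W <- matrix(w, length(mj), k, byrow = TRUE)
      Wd <- W * nb_obs
      rs <- rowSums(Wd)
      has_donor <- rs > 0
      est <- numeric(length(mj))
      if (any(has_donor))
        est[has_donor] <- rowSums((Wd / rs)[has_donor, , drop = FALSE] *
                                  Z[mj[has_donor], nb, drop = FALSE])
      if (any(!has_donor))
        est[!has_donor] <- as.vector(
          Z[mj[!has_donor], nb, drop = FALSE] %*% w)
      Znew[mj, j] <- est
    }
    delta <- mean(abs(Znew[miss] - Z[miss]))
    change <- c(change, delta)
    Z <- Znew
    it_run <- it
    if (delta <= tol) break
  }
  structure(list(Z = Z, k = k, iterations_run = it_run,
                 per_iteration_change = change,
                 converged = (length(change) > 0 &&
                              change[length(change)] <= tol) ||
                             !any_missing),
            class = "knn_imputation")
}

#' @export
print.knn_imputation <- function(x, ...) {
  cat(sprintf("knn_imputation: %d x %d matrix, k = %d, %d iteration(s)\n",
              nrow(x$Z), ncol(x$Z), x$k, x$iterations_run))
  if (length(x$per_iteration_change))
    cat("mean |change| per iteration:",
        paste(signif(x$per_iteration_change, 4), collapse = ", "), "\n")
  invisible(x)
}
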