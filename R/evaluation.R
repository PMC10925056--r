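#' Normalized entropy of a clustering against reference labels
#'
#' For clusters q with sizes \eqn{n_q} and contingency counts
#' \eqn{n_q^j} against l reference categories, the per-cluster entropy is
#' \eqn{H_q = -\sum_j (n_q^j/n_q) \log(n_q^j/n_q)}, the overall entropy the
#' cluster-size-weighted sum \eqn{H = \sum_q (n_q/n) H_q}, and the
#' normalized entropy \eqn{\tilde H = H / \log l}:
#' \deqn{\tilde H = -\frac{1}{n \log l} \sum_q \sum_j
#'   n_q^j \log \frac{n_q^j}{n_q}}
#' Natural logarithm throughout; \eqn{0 \log 0 \equiv 0}. \eqn{\tilde H}
#' is 0 exactly when every cluster is pure and 1 in the maximal-disorder
#' case (e.g. one cluster, uniform reference).
#'
#' @param labels cluster labels (any atomic type), one per cell.
#' @param reference reference category labels, same cells in same order.
#' @return An `entropy_report`: list with `normalized`, `overall` (H),
#'   `h_max` (log l), `per_cluster_entropy`, `counts` (contingency matrix),
#'   `n`, `l`.
#' @export
normalized_entropy <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("labels and reference must cover the same cells")
  counts <- table(cluster = as.character(labels),
                  category = as.character(reference))
  l <- ncol(counts)
  if (l < 2L) stop("normalized entropy needs >= 2 reference categories ",
                   "(H_max = log l would be 0)")
  n <- sum(counts)
  nq <- rowSums(counts)
  frac <- counts / nq
  terms <- counts * log(frac)
  terms[counts == 0] <- 0
  Hq <- -rowSums(terms) / nq
  H <- sum(nq / n * Hq)
  hmax <- log(l)
  structure(list(normalized = H / hmax, overall = H, h_max = hmax,
                 per_cluster_entropy = Hq, counts = unclass(counts),
                 n = n, l = l),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf(
    "entropy_report: normalized entropy %.4f (n = %d cells, l = %d categories)\n",
    x$normalized, x$n, x$l))
  invisible(x)
}

#' Null distribution of entropy under partial label scrambling
#'
#' Repeatedly replaces a random fraction of the reference labels by draws
#' uniform over the existing categories (a redrawn label may coincide with
#' the original) and recomputes the normalized entropy of `labels` against
#' the scrambled reference.
#'
#' @param labels cluster labels.
#' @param reference reference category labels.
#' @param fraction fraction of reference labels scrambled per repetition
#'   (default 0.25).
#' @param reps number of repetitions (default 10000).
#' @param seed RNG seed.
#' @return List with `values` (normalized entropies, length `reps`),
#'   `observed` (unscrambled entropy), `fraction`, `seed`.
#' @export
scramble_null <- function(labels, reference, fraction = 0.25, reps = 10000,
                          seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  cats <- unique(as.character(reference))
  n <- length(reference)
  n_scramble <- round(fraction * n)
  observed <- normalized_entropy(labels, reference)$normalized
  set.seed(seed)
  values <- vapply(seq_len(reps), function(r) {
    ref <- as.character(reference)
    if (n_scramble > 0L) {
      idx <- sample.int(n, n_scramble)
      ref[idx] <- sample(cats, n_scramble, replace = TRUE)
    }
    normalized_entropy(labels, ref)$normalized
  }, numeric(1))
  list(values = values, observed = observed, fraction = fraction,
       seed = seed)
}

#' Mask observed entries for an imputation benchmark
#'
#' Uniformly samples `round(fraction * n_observed)` observed entries and
#' sets them missing, returning their positions and true values for
#' scoring. A draw that leaves a site (row) or cell (column) with no
#' observed entry is repaired by un-masking one entry of the starved
#' row/column and masking a replacement elsewhere, up to `max_retries`
#' repair rounds; if the mask cannot be repaired an error is raised.
#'
#' @param X probability matrix with NA for missing.
#' @param fraction fraction of observed entries to mask, in (0, 1).
#' @param seed RNG seed.
#' @param max_retries repair-round limit (default 100).
#' @return List with `masked` (matrix) and `heldout` (data.frame row,
#'   col, value).
#' @export
forced_dropout <- function(X, fraction, seed = 1, max_retries = 100) {
  stopifnot(fraction > 0, fraction < 1)
  obs <- which(!is.na(X))
  n_mask <- round(fraction * length(obs))
  set.seed(seed)
  mask <- sample(obs, n_mask)
  masked_flag <- logical(length(X))
  masked_flag[mask] <- TRUE
  repair_mask(X, masked_flag, max_retries)
}

# repair a dropout mask so no row or column loses its last observation,
# keeping the masked count fixed; returns the masked matrix and held-out set
repair_mask <- function(X, masked_flag, max_retries = 100) {
  nr <- nrow(X)
  for (try in seq_len(max_retries)) {
    Xm <- X
    Xm[masked_flag] <- NA_real_
    bad_rows <- which(rowSums(!is.na(Xm)) == 0L)
    bad_cols <- which(colSums(!is.na(Xm)) == 0L)
    if (length(bad_rows) == 0L && length(bad_cols) == 0L) break
    if (try == max_retries)
      stop("forced_dropout: could not repair mask within retry limit")
    freed <- integer(0)
    for (r in bad_rows) {
      cand <- which(masked_flag & ((seq_along(masked_flag) - 1L) %% nr) + 1L == r)
      pick <- cand[sample.int(length(cand), 1L)]
      masked_flag[pick] <- FALSE
      freed <- c(freed, pick)
    }
    for (cc in bad_cols) {
      cand <- which(masked_flag &
                    ((seq_along(masked_flag) - 1L) %/% nr) + 1L == cc)
      if (length(cand) == 0L) next
      pick <- cand[sample.int(length(cand), 1L)]
      masked_flag[pick] <- FALSE
      freed <- c(freed, pick)
    }
    # re-mask replacements among entries that are observed, unmasked, and
    # whose row/col keeps at least 2 observations
    Xm <- X
    Xm[masked_flag] <- NA_real_
    robs <- rowSums(!is.na(Xm))
    cobs <- colSums(!is.na(Xm))
    cand <- which(!is.na(Xm))
    ri <- ((cand - 1L) %% nr) + 1L
    ci <- ((cand - 1L) %/% nr) + 1L
    cand <- cand[robs[ri] >= 2L & cobs[ci] >= 2L & !(cand %in% freed)]
    need <- length(freed)
    if (length(cand) < need)
      stop("forced_dropout: could not repair mask within retry limit")
    masked_flag[cand[sample.int(length(cand), need)]] <- TRUE
  }
  mask_idx <- which(masked_flag)
  Xm <- X
  Xm[mask_idx] <- NA_real_
  heldout <- data.frame(row = ((mask_idx - 1L) %% nr) + 1L,
                        col = ((mask_idx - 1L) %/% nr) + 1L,
                        value = X[mask_idx])
  list(masked = Xm, heldout = heldout)
}

#' Imputation accuracy benchmark under forced dropout
#'
#' For each dropout fraction, masks that share of the observed entries,
#' re-imputes with the default pipeline and records the absolute deviation
#' of every imputed entry from its held-out truth. The masks are nested —
#' a single random permutation of the observed entries is drawn and
#' fraction f masks its first round(f n) entries — so that larger
#' fractions remove strictly more information, mirroring a gradually
#' increased dropout percentage and making the degradation across
#' fractions a paired comparison. The whole protocol is repeated `reps`
#' times with independent seeded permutations and the deviations pooled,
#' so the summary statistics (in particular the medians, which sit on a
#' flat part of the error distribution) are stable against the draw of
#' the mask. Two-sided Welch t-tests compare the pooled deviation
#' distributions between fractions.
#'
#' @param X probability matrix (filtered).
#' @param fractions dropout fractions (default `c(0.1, 0.3, 0.9)`).
#' @param seed RNG seed.
#' @param k,iterations imputation parameters (defaults 10 and 3).
#' @param reps number of repetitions pooled (default 10).
#' @return List with per-fraction `deviations` (list of numeric vectors),
#'   `summary` (data.frame: fraction, n, mean, median,
#'   frac_within_0.2), and `t_tests` (data.frame of pairwise p-values);
#'   `seed`.
#' @export
imputation_benchmark <- function(X, fractions = c(0.1, 0.3, 0.9), seed = 1,
                                 k = 10, iterations = 3, reps = 10) {
  stopifnot(all(fractions > 0), all(fractions < 1), reps >= 1)
  devs <- rep(list(numeric(0)), length(fractions))
  names(devs) <- as.character(fractions)
  obs <- which(!is.na(X))
  for (r in seq_len(reps)) {
    set.seed(seed + r - 1L)
    perm <- sample(obs)
    for (i in seq_along(fractions)) {
      masked_flag <- logical(length(X))
      masked_flag[perm[seq_len(round(fractions[i] * length(obs)))]] <- TRUE
      fd <- repair_mask(X, masked_flag)
      imp <- knn_impute(fd$masked, k = k, iterations = iterations)
      pred <- imp$Z[cbind(fd$heldout$row, fd$heldout$col)]
      devs[[i]] <- c(devs[[i]], abs(pred - fd$heldout$value))
    }
  }
  summ <- data.frame(
    fraction = fractions,
    n = vapply(devs, length, integer(1)),
    mean = vapply(devs, mean, numeric(1)),
    median = vapply(devs, stats::median, numeric(1)),
    frac_within_0.2 = vapply(devs, function(d) mean(d <= 0.2), numeric(1)))
  tt <- NULL
  if (length(fractions) >= 2L) {
    pairs <- utils::combn(seq_along(fractions), 2L)
    tt <- data.frame(
      fraction_a = fractions[pairs[1L, ]],
      fraction_b = fractions[pairs[2L, ]],
      p_value = apply(pairs, 2L, function(pr)
        stats::t.test(devs[[pr[1L]]], devs[[pr[2L]]])$p.value))
  }
  list(deviations = devs, summary = summ, t_tests = tt, seed = seed)
}

#' Clustering robustness protocols
#'
#' Perturbs the probability matrix and reruns imputation + clustering,
#' scoring each perturbed run by the normalized entropy of its labels
#' against the labels of the unperturbed baseline run. Three protocols:
#' `"value-dropout"` masks a fraction of observed values;
#' `"site-deletion"` removes a fraction of whole AS modules (all sites
#' sharing a module prefix in the site id); `"cell-subsample"` keeps a
#' fraction of the cells, and entropy is computed on the shared cells.
#'
#' @param X filtered probability matrix.
#' @param mode one of `"value-dropout"`, `"site-deletion"`,
#'   `"cell-subsample"`.
#' @param grid perturbation fractions in (0, 1] (for dropout/deletion the
#'   fraction removed; for subsampling the fraction kept).
#' @param seed RNG seed.
#' @param k_clusters number of clusters.
#' @param k,iterations,n_pcs,graph_k pipeline parameters.
#' @return List with `baseline` labels, `results` data.frame (setting,
#'   entropy, n_cells), and per-setting labels; `seed`.
#' @export
robustness_suite <- function(X, mode = c("value-dropout", "site-deletion",
                                         "cell-subsample"),
                             grid, seed = 1, k_clusters = 3, k = 10,
                             iterations = 3, n_pcs = 20, graph_k = 10) {
  mode <- match.arg(mode)
  stopifnot(all(grid >= 0), all(grid <= 1))
  if (mode == "cell-subsample" && any(grid <= 0))
    stop("cell-subsample fractions must be positive")
  base_lab <- cluster_matrix(X, k_clusters, k, iterations, n_pcs, graph_k,
                             seed)
  res <- data.frame(setting = grid, entropy = NA_real_,
                    n_cells = NA_integer_)
  labs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    f <- grid[i]
    s <- seed + i
    if (mode == "value-dropout") {
      Xp <- if (f > 0 && f < 1) forced_dropout(X, f, seed = s)$masked
            else X
      Xp <- Xp[rowSums(!is.na(Xp)) > 0L, , drop = FALSE]
    } else if (mode == "site-deletion") {
      mods <- sub(":[0-9]+$", "", rownames(X))   # site_id minus partner
      um <- unique(mods)
      set.seed(s)
      drop <- sample(um, round(f * length(um)))
      Xp <- X[!(mods %in% drop), , drop = FALSE]
      if (nrow(Xp) < 2L) stop("site-deletion removed nearly all sites")
    } else {
      set.seed(s)
      keep <- sort(sample.int(ncol(X), round(f * ncol(X))))
      Xp <- X[, keep, drop = FALSE]
      Xp <- Xp[rowSums(!is.na(Xp)) > 0L, , drop = FALSE]
    }
    lab <- cluster_matrix(Xp, k_clusters, k, iterations, n_pcs, graph_k,
                          seed)
    shared <- intersect(names(lab), names(base_lab))
    res$entropy[i] <- normalized_entropy(lab[shared],
                                         base_lab[shared])$normalized
    res$n_cells[i] <- length(shared)
    labs[[i]] <- lab
  }
  list(baseline = base_lab, results = res, labels = labs, mode = mode,
       seed = seed)
}

# impute + assemble + reduce + cluster a probability matrix; helper shared
# by the robustness protocols and the main fit
cluster_matrix <- function(X, k_clusters, k = 10, iterations = 3,
                           n_pcs = 20, graph_k = 10, seed = 1) {
  R <- missing_indicator(X)
  imp <- knn_impute(X, k = k, iterations = iterations)
  D <- feature_matrix(imp$Z, R)
  npc <- min(n_pcs, min(dim(D)) - 1L)
  coords <- reduce_pca(D, n_components = npc)
  spectral_cluster(coords, k_clusters, graph_k = graph_k, seed = seed)$labels
}

#' Shuffle one feature block within each cell
#'
#' Randomly permutes, independently within each column, either the
#' indicator block or the probability block of a matrix — the negative
#' control showing that each block's row structure (not just its column
#' sums, which shuffling preserves) carries the cluster signal.
#'
#' @param M matrix to shuffle (the block itself).
#' @param seed RNG seed.
#' @return Matrix with each column independently permuted across rows.
#' @export
shuffle_within_cells <- function(M, seed = 1) {
  set.seed(seed)
  out <- apply(M, 2L, function(col) col[sample.int(length(col))])
  dimnames(out) <- dimnames(M)
  out
}
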