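#' Group junctions into alternative-splicing modules
#'
#' Junctions sharing the same 5' or 3' splice site are grouped into an AS
#' module. Grouping is done within (chrom, strand): junctions sharing their
#' left coordinate form a shared-left module, junctions sharing their right
#' coordinate a shared-right module, so one junction can belong to up to two
#' modules. On the + strand the shared-left anchor is the 5' splice site and
#' shared-right the 3' site; on the - strand the labels swap; for
#' unknown-strand junctions the neutral left/right tags stand on their own.
#' Modules with a single member are uninformative and dropped.
#'
#' @param tab a `junction_counts` table (see [read_junctions()]).
#' @return A data.frame with one row per (module, member junction):
#'   `module_id`, `site_id`, `chrom`, `strand`, `side` ("L" or "R"),
#'   `anchor`, `start`, `end`. `site_id` is stable across runs.
#' @export
build_as_modules <- function(tab) {
  jx <- unique(data.frame(chrom = tab$chrom, start = tab$start,
                          end = tab$end, strand = tab$strand,
                          stringsAsFactors = FALSE))
  out <- list()
  for (side in c("L", "R")) {
    anchor <- if (side == "L") jx$start else jx$end
    grp <- paste(jx$chrom, jx$strand, side, anchor, sep = ":")
    keep <- grp %in% names(which(table(grp) >= 2L))
    if (!any(keep)) next
    g <- jx[keep, , drop = FALSE]
    a <- anchor[keep]
    partner <- if (side == "L") g$end else g$start
    out[[side]] <- data.frame(
      module_id = paste(g$chrom, g$strand, side, a, sep = ":"),
      site_id = paste(g$chrom, g$strand, side, a, partner, sep = ":"),
      chrom = g$chrom, strand = g$strand, side = side,
      anchor = a, start = g$start, end = g$end,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(module_id = character(), site_id = character(),
                      chrom = character(), strand = character(),
                      side = character(), anchor = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$strand, res$side, res$anchor,
                   res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-cell alternative-splicing probabilities
#'
#' For each cell and module, the probability of each member junction is its
#' read count divided by the summed read count over all member junctions in
#' that cell (the shared-left form uses the left anchor's module, the
#' shared-right form the right anchor's). Modules with ultralow depth in a
#' cell — summed member reads not exceeding `min_module_reads` — are
#' unreliable and their entries are set missing (NA) in that cell. The
#' comparison is strict: a module needs more than `min_module_reads` reads
#' to be quantified.
#'
#' @param tab a `junction_counts` table.
#' @param modules module membership table from [build_as_modules()].
#' @param min_module_reads depth threshold (default 20).
#' @return An M x N numeric matrix (rows = `site_id`, columns = cell) with
#'   entries in [0,1] or NA. Within a (module, cell) the observed entries
#'   sum to 1.
#' @export
as_probabilities <- function(tab, modules, min_module_reads = 20) {
  cells <- sort(unique(tab$cell_id))
  if (nrow(modules) == 0L || length(cells) == 0L) {
    return(matrix(numeric(), 0L, length(cells),
                  dimnames = list(character(), cells)))
  }
  jkey <- paste(tab$chrom, tab$start, tab$end, tab$strand, sep = ":")
  mkey <- paste(modules$chrom, modules$start, modules$end, modules$strand,
                sep = ":")
  if (!all(mkey %in% jkey))
    stop("module references a junction absent from the table")
  ukey <- sort(unique(jkey))
  cnt <- matrix(0, length(ukey), length(cells),
                dimnames = list(ukey, cells))
  cnt[cbind(match(jkey, ukey), match(tab$cell_id, cells))] <- tab$count

  member_counts <- cnt[match(mkey, ukey), , drop = FALSE]
  rownames(member_counts) <- modules$site_id
  # per-(module, cell) depth
  modsum <- rowsum(member_counts, modules$module_id, reorder = FALSE)
  depth <- modsum[match(modules$module_id, rownames(modsum)), , drop = FALSE]
  X <- member_counts / depth
  X[depth <= min_module_reads] <- NA_real_
  rownames(X) <- modules$site_id
  X
}

#' Filter the probability matrix for coverage
#'
#' Alternately removes AS sites observed in fewer than `min_cells_per_site`
#' cells and cells with fewer than `min_sites_per_cell` observed sites until
#' both criteria hold simultaneously (a fixed point). Row and column order
#' is preserved. Both thresholds are adjustable; [coverage_density()] helps
#' choose them for a given dataset.
#'
#' @param X probability matrix from [as_probabilities()].
#' @param min_cells_per_site minimum observed cells per site (default 10).
#' @param min_sites_per_cell minimum observed sites per cell (default 1000).
#' @return The filtered matrix.
#' @export
filter_as_matrix <- function(X, min_cells_per_site = 10,
                             min_sites_per_cell = 1000) {
  repeat {
    obs_site <- rowSums(!is.na(X))
    X <- X[obs_site >= min_cells_per_site, , drop = FALSE]
    obs_cell <- colSums(!is.na(X))
    X <- X[, obs_cell >= min_sites_per_cell, drop = FALSE]
    if (nrow(X) == 0L || ncol(X) == 0L)
      stop("coverage filtering removed all sites or cells; relax ",
           "min_cells_per_site / min_sites_per_cell (see coverage_density())")
    if (all(rowSums(!is.na(X)) >= min_cells_per_site) &&
        all(colSums(!is.na(X)) >= min_sites_per_cell)) break
  }
  X
}

#' Binary missingness indicator
#'
#' @param X probability matrix with NA for missing entries.
#' @return Same-shape matrix: 1 where `X` is missing, 0 where observed.
#' @export
missing_indicator <- function(X) {
  R <- matrix(as.numeric(is.na(X)), nrow(X), ncol(X),
              dimnames = dimnames(X))
  R
}

#' Coverage density summary
#'
#' Per-site observed-cell counts, per-cell observed-site counts, and the
#' overall missingness fraction — the reference for choosing the
#' [filter_as_matrix()] thresholds on a new dataset.
#'
#' @param X probability matrix.
#' @param path optional TSV output path for the two marginals.
#' @return A list with `site_coverage` (named integer vector),
#'   `cell_coverage` (named integer vector) and `missingness` (fraction).
#' @export
coverage_density <- function(X, path = NULL) {
  site_cov <- rowSums(!is.na(X))
  cell_cov <- colSums(!is.na(X))
  miss <- if (length(X)) mean(is.na(X)) else NA_real_
  if (!is.null(path)) {
    long <- rbind(
      data.frame(axis = "site", id = rownames(X), observed = site_cov,
                 stringsAsFactors = FALSE),
      data.frame(axis = "cell", id = colnames(X), observed = cell_cov,
                 stringsAsFactors = FALSE))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(site_coverage = site_cov, cell_coverage = cell_cov,
       missingness = miss)
}

#' Write a probability or indicator matrix as TSV
#'
#' Rows are site ids, columns cell ids, missing entries written as `NA`.
#' @param X matrix to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_as_matrix <- function(X, path) {
  df <- data.frame(site_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
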