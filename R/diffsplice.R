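#' Categorize AS probabilities as present or absent
#'
#' Single-cell AS probabilities are highly polarized, so differential
#' splicing is cast as a classification problem: an event with probability
#' strictly above `present_thr` is present in the cell, strictly below
#' `absent_thr` absent. Values in `[absent_thr, present_thr]` are
#' indeterminate and excluded from contingency tables; missing values stay
#' missing.
#'
#' @param X raw (unimputed) probability matrix, or a numeric vector.
#' @param present_thr presence threshold (default 0.6, strict).
#' @param absent_thr absence threshold (default 0.4, strict).
#' @return Character array of the same shape with values `"present"`,
#'   `"absent"`, `"indeterminate"`, or NA for missing.
#' @export
categorize_events <- function(X, present_thr = 0.6, absent_thr = 0.4) {
  stopifnot(present_thr > absent_thr)
  out <- ifelse(is.na(X), NA_character_,
         ifelse(X > present_thr, "present",
         ifelse(X < absent_thr, "absent", "indeterminate")))
  if (is.matrix(X)) dimnames(out) <- dimnames(X)
  out
}

#' Differential splicing between two cell groups
#'
#' For every AS site, cells of the two groups are categorized as
#' present/absent from the raw (unimputed) probabilities and collected in a
#' 2x2 contingency table; a two-sided Fisher's exact test asks whether the
#' event is preferentially enriched in one group. Sites with `p < alpha`
#' are flagged as differentially spliced. Raw-data summaries (mean and
#' median probability difference, per-group detection probability) are
#' computed exclusively from observed, unimputed entries — imputed values
#' never enter the differential statistics. Sites with an empty table (no
#' categorizable cell in either group) are skipped.
#'
#' @param X_raw raw probability matrix (NA = missing). Never pass an
#'   imputed matrix here.
#' @param labels named cluster labels covering the columns of `X_raw`.
#' @param group_a,group_b cluster labels of the two groups to compare.
#' @param present_thr,absent_thr categorization thresholds (0.6 / 0.4).
#' @param alpha significance threshold on the Fisher p-value (default
#'   0.01; events with `p < alpha` are flagged).
#' @param adjust apply Benjamini-Hochberg adjustment before flagging
#'   (default FALSE: the raw p-values are thresholded).
#' @return data.frame with one row per testable site: `site_id`,
#'   `p_value`, (optionally `p_adjusted`), `flagged`, the four table
#'   counts, `mean_diff`, `median_diff` (group A minus group B),
#'   `detection_a`, `detection_b`.
#' @export
diff_splicing <- function(X_raw, labels, group_a, group_b,
                          present_thr = 0.6, absent_thr = 0.4,
                          alpha = 0.01, adjust = FALSE) {
  if (is.null(names(labels)))
    names(labels) <- colnames(X_raw)
  ca <- names(labels)[labels %in% group_a]
  cb <- names(labels)[labels %in% group_b]
  ca <- intersect(ca, colnames(X_raw))
  cb <- intersect(cb, colnames(X_raw))
  if (length(ca) == 0L || length(cb) == 0L)
    stop("both groups must contain cells present in the matrix")
  if (length(intersect(ca, cb)) > 0L) stop("groups must be disjoint")
  Xa <- X_raw[, ca, drop = FALSE]
  Xb <- X_raw[, cb, drop = FALSE]
  Ca <- categorize_events(Xa, present_thr, absent_thr)
  Cb <- categorize_events(Xb, present_thr, absent_thr)
  rows <- lapply(seq_len(nrow(X_raw)), function(i) {
    a <- sum(Ca[i, ] == "present", na.rm = TRUE)
    b <- sum(Cb[i, ] == "present", na.rm = TRUE)
    c_ <- sum(Ca[i, ] == "absent", na.rm = TRUE)
    d <- sum(Cb[i, ] == "absent", na.rm = TRUE)
    if (a + b + c_ + d == 0L) return(NULL)
    p <- stats::fisher.test(matrix(c(a, c_, b, d), 2L))$p.value
    va <- Xa[i, !is.na(Xa[i, ])]
    vb <- Xb[i, !is.na(Xb[i, ])]
    data.frame(site_id = rownames(X_raw)[i], p_value = p,
               present_a = a, present_b = b, absent_a = c_, absent_b = d,
               mean_diff = mean(va) - mean(vb),
               median_diff = stats::median(va) - stats::median(vb),
               detection_a = length(va) / length(ca),
               detection_b = length(vb) / length(cb),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(site_id = character(), p_value = numeric()))
  if (adjust) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$flagged <- res$p_adjusted < alpha
  } else {
    res$flagged <- res$p_value < alpha
  }
  rownames(res) <- NULL
  res
}

#' Rank differentially spliced events
#'
#' Flagged events ranked by increasing p-value; with `direction_aware` the
#' ranking is done separately for events up in group A (positive mean
#' difference) and down (negative), interleaving is left to the caller.
#' Ties in p-value are broken by `site_id` for determinism.
#'
#' @param results output of [diff_splicing()].
#' @param n_top number of events to keep (per direction when
#'   `direction_aware`).
#' @param direction_aware split by sign of `mean_diff` (default TRUE).
#' @return The ranked subset of `results`, with a `direction` column when
#'   direction-aware.
#' @export
top_events <- function(results, n_top, direction_aware = TRUE) {
  fl <- results[results$flagged, , drop = FALSE]
  if (nrow(fl) == 0L) return(fl)
  pick <- function(df) {
    df <- df[order(df$p_value, df$site_id), , drop = FALSE]
    utils::head(df, n_top)
  }
  if (!direction_aware) return(pick(fl))
  up <- pick(fl[fl$mean_diff > 0, , drop = FALSE])
  dn <- pick(fl[fl$mean_diff <= 0, , drop = FALSE])
  if (nrow(up)) up$direction <- "up"
  if (nrow(dn)) dn$direction <- "down"
  out <- rbind(up, dn)
  rownames(out) <- NULL
  out
}

#' Map AS sites to genes
#'
#' Each junction is assigned to the overlapping gene containing the
#' largest fraction of the junction span (strand-matched when the junction
#' strand is known); ties are broken by the smallest distance between the
#' junction midpoint and the gene midpoint. A junction overlapping no gene
#' is assigned the nearest gene within `window` bases, else none.
#' Chromosome naming is reconciled across the `chr` prefix.
#'
#' @param sites data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (e.g. the module table of [build_as_modules()], or parsed site ids).
#' @param annotation path to a GTF/GFF file, or a GRanges of genes with a
#'   `gene_id`-like metadata column.
#' @param window search window for non-overlapping junctions (default
#'   5000).
#' @return Character vector of gene identifiers (NA where unassigned),
#'   one per row of `sites`.
#' @export
map_junctions_to_genes <- function(sites, annotation, window = 5000) {
  for (p in c("GenomicRanges", "IRanges", "S4Vectors"))
    if (!requireNamespace(p, quietly = TRUE))
      stop("package '", p, "' is required for gene mapping")
  genes <- if (is.character(annotation)) read_gene_ranges(annotation)
           else annotation
  gchr <- as.character(GenomicRanges::seqnames(genes))
  schr <- sites$chrom
  if (!any(schr %in% gchr)) {          # reconcile chr prefix
    if (all(grepl("^chr", gchr)) && !all(grepl("^chr", schr)))
      schr <- paste0("chr", schr)
    else if (!all(grepl("^chr", gchr)) && all(grepl("^chr", schr)))
      schr <- sub("^chr", "", schr)
  }
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) ids <- S4Vectors::mcols(genes)[[1L]]
  gstrand <- as.character(GenomicRanges::strand(genes))
  out <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    onchr <- which(gchr == schr[i])
    if (sites$strand[i] %in% c("+", "-"))
      onchr <- onchr[gstrand[onchr] %in% c(sites$strand[i], "*")]
    if (length(onchr) == 0L) next
    gs <- GenomicRanges::start(genes)[onchr]
    ge <- GenomicRanges::end(genes)[onchr]
    js <- sites$start[i]; je <- sites$end[i]
    ov_lo <- pmax(gs, js); ov_hi <- pmin(ge, je)
    ov <- pmax(0, ov_hi - ov_lo + 1) / (je - js + 1)
    if (any(ov > 0)) {
      best <- which(ov == max(ov))
      if (length(best) > 1L) {
        mid_d <- abs((gs[best] + ge[best]) / 2 - (js + je) / 2)
        best <- best[which.min(mid_d)]
      }
      out[i] <- ids[onchr[best]]
    } else {
      dist <- pmax(gs - je, js - ge)   # gap between intervals
      j <- which.min(dist)
      if (dist[j] <= window) out[i] <- ids[onchr[j]]
    }
  }
  out
}

read_gene_ranges <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("package 'rtracklayer' is required to read GTF/GFF annotation")
  gr <- rtracklayer::import(path)
  ty <- S4Vectors::mcols(gr)$type
  if (!is.null(ty) && any(ty == "gene")) gr <- gr[ty == "gene"]
  gr
}

#' Parse site ids back into genomic coordinates
#'
#' Site ids have the form `chrom:strand:side:anchor:partner`; this returns
#' the underlying junction interval of each site.
#'
#' @param site_ids character vector of site ids.
#' @return data.frame with `chrom`, `strand`, `side`, `anchor`, `start`,
#'   `end`.
#' @export
parse_site_ids <- function(site_ids) {
  parts <- strsplit(site_ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) stop("malformed site id: ", site_ids[bad][1L])
  chrom <- vapply(parts, `[[`, "", 1L)
  strand <- vapply(parts, `[[`, "", 2L)
  side <- vapply(parts, `[[`, "", 3L)
  anchor <- as.integer(vapply(parts, `[[`, "", 4L))
  partner <- as.integer(vapply(parts, `[[`, "", 5L))
  data.frame(chrom = chrom, strand = strand, side = side, anchor = anchor,
             start = ifelse(side == "L", anchor, partner),
             end = ifelse(side == "L", partner, anchor),
             stringsAsFactors = FALSE)
}
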