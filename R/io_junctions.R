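#' Read per-cell splice-junction count files
#'
#' Reads one BED6-like `.junc` file per cell (tab-separated:
#' chrom, start, end, name, count, strand) and merges them into a single
#' junction-count table. Coordinates are converted from the declared dialect
#' to the internal convention: 1-based inclusive over the intron, i.e.
#' `start` is the first intronic base and `end` the last intronic base.
#'
#' Two dialects are accepted. `"bed-intron"` (the default, matching common
#' junction-caller output) treats the BED interval as 0-based half-open over
#' the intron, so internal start = start + 1, internal end = end.
#' `"anchor-bed"` treats the interval as spanning the flanking anchors, with
#' the intron strictly inside: internal start = start + 2, internal end =
#' end - 1.
#'
#' Records with zero counts are dropped; duplicate junction keys within one
#' cell have their counts summed. Cell identity is the file basename
#' (extension stripped) unless a two-column `manifest` (path, cell_id) is
#' supplied.
#'
#' @param paths character vector of `.junc` file paths.
#' @param dialect coordinate dialect, `"bed-intron"` or `"anchor-bed"`.
#' @param manifest optional data.frame with columns `path` and `cell_id`.
#' @return A `junction_counts` data.frame with columns `chrom`, `start`,
#'   `end`, `strand`, `cell_id`, `count`, sorted by
#'   (chrom, start, end, strand, cell_id).
#' @seealso [write_junctions()], [extract_junctions()], [build_as_modules()]
#' @export
read_junctions <- function(paths, dialect = c("bed-intron", "anchor-bed"),
                           manifest = NULL) {
  dialect <- match.arg(dialect)
  if (length(paths) == 0L) {
    return(new_junction_counts(data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), cell_id = character(), count = integer(),
      stringsAsFactors = FALSE)))
  }
  ids <- if (!is.null(manifest)) {
    stopifnot(all(c("path", "cell_id") %in% names(manifest)))
    m <- match(normalizePath(paths, mustWork = FALSE),
               normalizePath(manifest$path, mustWork = FALSE))
    if (anyNA(m)) stop("manifest does not cover all input paths")
    as.character(manifest$cell_id[m])
  } else {
    sub("\\.[^.]*$", "", basename(paths))
  }
  pieces <- mapply(read_one_junc, paths, ids,
                   MoreArgs = list(dialect = dialect), SIMPLIFY = FALSE)
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL
  new_junction_counts(tab)
}

read_one_junc <- function(path, cell_id, dialect) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      cell_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)[1L]
    stop(sprintf("malformed line %d in %s: expected >= 5 tab-separated fields",
                 bad, path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  count <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(start) || anyNA(end) || anyNA(count)) {
    bad <- which(is.na(start) | is.na(end) | is.na(count))[1L]
    stop(sprintf("malformed line %d in %s: non-numeric coordinate or count",
                 bad, path))
  }
  strand <- ifelse(nf >= 6L, vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  conv <- convert_coords(start, end, from = dialect)
  if (any(conv$start > conv$end)) {
    bad <- which(conv$start > conv$end)[1L]
    stop(sprintf("line %d in %s: intron start >= end after dialect conversion",
                 bad, path))
  }
  tab <- data.frame(chrom = chrom, start = conv$start, end = conv$end,
                    strand = strand, cell_id = cell_id,
                    count = as.integer(round(count)),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$count > 0L, , drop = FALSE]
  collapse_duplicates(tab)
}

# dialect <-> internal (1-based inclusive intron) conversion
convert_coords <- function(start, end, from, reverse = FALSE) {
  if (from == "bed-intron") {
    if (reverse) list(start = start - 1L, end = end)
    else list(start = start + 1L, end = end)
  } else if (from == "anchor-bed") {
    if (reverse) list(start = start - 2L, end = end + 1L)
    else list(start = start + 2L, end = end - 1L)
  } else stop("unknown coordinate dialect: ", from)
}

collapse_duplicates <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  key <- paste(tab$chrom, tab$start, tab$end, tab$strand, tab$cell_id,
               sep = "\r")
  if (!anyDuplicated(key)) return(tab)
  agg <- rowsum(tab$count, key)
  first <- tab[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[match(paste(first$chrom, first$start,
                                            first$end, first$strand,
                                            first$cell_id, sep = "\r"),
                                      rownames(agg))])
  first
}

new_junction_counts <- function(tab) {
  ord <- order(tab$chrom, tab$start, tab$end, tab$strand, tab$cell_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("junction_counts", "data.frame")
  tab
}

#' Write a junction-count table to TSV
#'
#' Deterministic ordering (chrom, start, end, strand, cell_id); coordinates
#' are written back in the requested dialect so that
#' `read_junctions(write_junctions(x))` round-trips exactly.
#'
#' @param tab a `junction_counts` table.
#' @param path output file path.
#' @param dialect coordinate dialect used on disk.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(tab, path,
                            dialect = c("bed-intron", "anchor-bed")) {
  dialect <- match.arg(dialect)
  conv <- convert_coords(tab$start, tab$end, from = dialect, reverse = TRUE)
  out <- data.frame(chrom = tab$chrom, start = conv$start, end = conv$end,
                    strand = tab$strand, cell_id = tab$cell_id,
                    count = tab$count, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Extract splice junctions from an alignment file
#'
#' Counts split reads whose skip (CIGAR `N`) operations evidence intron
#' excision. A read contributes to a junction only if the aligned blocks
#' flanking the skip are each at least `min_overhang` bases long. Strand is
#' taken from the `XS` tag when present, otherwise reported unknown (`*`).
#'
#' @param path BAM file (or SAM, converted on the fly), coordinate-sorted.
#' @param cell_id cell identifier to assign to all extracted junctions.
#' @param min_overhang minimum flanking aligned-block length (default 6).
#' @return A `junction_counts` table (possibly empty if no split reads).
#' @export
extract_junctions <- function(path, cell_id, min_overhang = 6L) {
  for (p in c("Rsamtools", "GenomicAlignments", "GenomicRanges", "S4Vectors"))
    if (!requireNamespace(p, quietly = TRUE))
      stop("package '", p, "' is required for alignment extraction")
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(tag = "XS")
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  empty <- new_junction_counts(data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), cell_id = character(), count = integer(),
    stringsAsFactors = FALSE))
  if (length(gal) == 0L) return(empty)
  has_skip <- grepl("N", GenomicAlignments::cigar(gal), fixed = TRUE)
  gal <- gal[has_skip]
  if (length(gal) == 0L) return(empty)
  blocks <- GenomicAlignments::grglist(gal)  # aligned blocks per read
  xs <- S4Vectors::mcols(gal)$XS

  recs <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (length(b) < 2L) next
    w <- GenomicRanges::width(b)
    s <- GenomicRanges::start(b)
    e <- GenomicRanges::end(b)
    for (j in seq_len(length(b) - 1L)) {
      if (w[j] < min_overhang || w[j + 1L] < min_overhang) next
      strand <- if (!is.null(xs) && !is.na(xs[i]) &&
                    xs[i] %in% c("+", "-")) xs[i] else "*"
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(b)[j]),
        start = e[j] + 1L, end = s[j + 1L] - 1L,
        strand = strand, cell_id = cell_id, count = 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) return(empty)
  new_junction_counts(collapse_duplicates(do.call(rbind, recs)))
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d records, %d junctions, %d cells\n",
              nrow(x),
              length(unique(paste(x$chrom, x$start, x$end, x$strand))),
              length(unique(x$cell_id))))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
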