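# Genomic intervals use the BED convention throughout: 0-based, half-open
# [start, end). Overlap machinery is backed by GenomicRanges (1-based closed
# internally; converted at the boundary).

#' Sorted set of genomic peaks
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `region_id` (unique; generated when absent)
#'   and `stat` (a per-region statistic such as a differential-binding log2
#'   fold change).
#' @param chrom_lengths Optional named vector of chromosome lengths; peaks
#'   exceeding a declared length are an error.
#' @return A `peak_set` data frame sorted by `(chrom, start)`.
#' @export
peak_set <- function(df, chrom_lengths = NULL) {
  req <- c("chrom", "start", "end")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("peaks missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("peaks must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$chrom]
    if (anyNA(len)) {
      stop("peaks on undeclared chromosome(s): ",
           paste(unique(df$chrom[is.na(len)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(df$end > len)) {
      stop("peak(s) exceed chromosome bounds: ",
           paste(utils::head(which(df$end > len), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(df$region_id)) {
    df$region_id <- sprintf("region_%05d", seq_len(nrow(df)))
  }
  df$region_id <- as.character(df$region_id)
  if (anyDuplicated(df$region_id)) {
    stop("region_id must be unique", call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  keep <- intersect(c("chrom", "start", "end", "region_id", "stat", "strand"),
                    names(df))
  df <- df[keep]
  attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- c("peak_set", "data.frame")
  df
}

peaks_to_granges <- function(peaks, seqlevels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    region_id = peaks$region_id
  )
}

#' Flag intervals of one peak set overlapping another
#'
#' @param a,b `peak_set` objects (plain data frames are coerced, with
#'   auto-sorting).
#' @param min_overlap Minimum number of shared bases (default 1). Half-open
#'   intervals that merely abut do not overlap.
#' @return Logical vector along the rows of `a`, named by `region_id`.
#' @export
intervals_overlap <- function(a, b, min_overlap = 1L) {
  if (!inherits(a, "peak_set")) {
    warning("coercing and sorting unsorted peak input", call. = FALSE)
    a <- peak_set(a)
  }
  if (!inherits(b, "peak_set")) {
    warning("coercing and sorting unsorted peak input", call. = FALSE)
    b <- peak_set(b)
  }
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  lv <- union(a$chrom, b$chrom)
  hits <- GenomicRanges::countOverlaps(peaks_to_granges(a, lv),
                                       peaks_to_granges(b, lv),
                                       minoverlap = min_overlap)
  stats::setNames(hits > 0L, a$region_id)
}

#' Transcription start site table
#'
#' @param df Data frame with columns `gene`, `chrom`, `pos` (TSS
#'   coordinate), `strand`, and `signature` (signature label or `NA`).
#' @param one_based If `TRUE` (default) `pos` is a 1-based coordinate and is
#'   converted to the internal 0-based convention.
#' @return A `tss_table` data frame with 0-based `pos`.
#' @export
tss_table <- function(df, one_based = TRUE) {
  req <- c("gene", "chrom", "pos")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("TSS table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos) - as.integer(one_based)
  if (any(df$pos < 0)) stop("TSS position out of range", call. = FALSE)
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$signature)) df$signature <- NA_character_
  df$signature <- as.character(df$signature)
  rownames(df) <- NULL
  class(df) <- c("tss_table", "data.frame")
  df
}

#' Assign peaks to genes by TSS windows
#'
#' A peak is assigned to a gene when it overlaps the window
#' `[tss - half_width, tss + half_width]` (inclusive of the TSS base; stored
#' half-open as `[tss - half_width, tss + half_width + 1)`) by at least one
#' base. Multi-assignment is allowed: a peak inside several genes' windows
#' yields several rows.
#'
#' @param peaks A `peak_set`.
#' @param tss A [tss_table()].
#' @param half_width Window half-width in bp (default 50000; 0 keeps only
#'   peaks covering the TSS base itself).
#' @return Data frame `region_id`, `gene`, `signature` (one row per
#'   assignment).
#' @export
tss_window_assign <- function(peaks, tss, half_width = 50000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(tss, "tss_table"))
  if (half_width < 0) stop("half_width must be >= 0", call. = FALSE)
  lv <- union(peaks$chrom, tss$chrom)
  win <- GenomicRanges::GRanges(
    seqnames = factor(tss$chrom, levels = lv),
    ranges = IRanges::IRanges(start = pmax(0, tss$pos - half_width) + 1L,
                              end = tss$pos + half_width + 1L)
  )
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(peaks, lv), win,
                                      minoverlap = 1L)
  out <- data.frame(
    region_id = peaks$region_id[S4Vectors::queryHits(hits)],
    gene = tss$gene[S4Vectors::subjectHits(hits)],
    signature = tss$signature[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build signature-specific region sets from TF peaks
#'
#' For each signature, collects the TF peaks assigned (by TSS window) to
#' that signature's genes, optionally excluding peaks cobound by a partner
#' TF — the "single-bound" region sets used to test global binding shifts
#' per signature. Empty resulting sets are dropped with a warning.
#'
#' @param tf_peaks `peak_set` of the TF of interest.
#' @param partner_peaks `peak_set` of the co-binding partner.
#' @param tss A [tss_table()] with signature labels.
#' @param half_width TSS window half-width (default 50000).
#' @param exclude_cobound If `TRUE` (default) remove cobound peaks from the
#'   sets; `FALSE` keeps plain window assignment.
#' @return Named list of region-id vectors, one per signature, with
#'   attribute `cobound` (the per-peak co-binding flags).
#' @export
build_signature_region_sets <- function(tf_peaks, partner_peaks, tss,
                                        half_width = 50000,
                                        exclude_cobound = TRUE) {
  stopifnot(inherits(tf_peaks, "peak_set"), inherits(tss, "tss_table"))
  cobound <- intervals_overlap(tf_peaks, partner_peaks)
  assign <- tss_window_assign(tf_peaks, tss, half_width)
  assign <- assign[!is.na(assign$signature), , drop = FALSE]
  sets <- lapply(split(assign$region_id, assign$signature), unique)
  if (exclude_cobound) {
    cb_ids <- names(cobound)[cobound]
    sets <- lapply(sets, setdiff, y = cb_ids)
  }
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    warning("empty region set(s) dropped: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  sets <- sets[lengths(sets) > 0L]
  attr(sets, "cobound") <- cobound
  sets
}

#' Plain differential-binding statistic from a region count matrix
#'
#' A simple substitute for a fitted differential-binding model, used as the
#' default GSEA ranking statistic: samples are library-size normalized
#' (scaled to the mean total count), averaged per condition, and compared as
#' `log2((mean_A + pc) / (mean_B + pc))`.
#'
#' @param counts Region x sample count matrix.
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels; the statistic is the first level versus the second.
#' @param pseudocount Pseudocount on normalized counts (default 0.5).
#' @return Named per-region statistic (log2 units).
#' @export
simple_region_logfc <- function(counts, condition, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition must have one entry per sample", call. = FALSE)
  }
  if (nlevels(droplevels(condition)) != 2L) {
    stop("exactly two conditions required", call. = FALSE)
  }
  condition <- droplevels(condition)
  depth <- colSums(counts)
  if (any(depth == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[depth == 0], collapse = ", "), call. = FALSE)
  }
  norm <- sweep(counts, 2L, depth / mean(depth), "/")
  ma <- rowMeans(norm[, condition == levels(condition)[1L], drop = FALSE])
  mb <- rowMeans(norm[, condition == levels(condition)[2L], drop = FALSE])
  stat <- log2((ma + pseudocount) / (mb + pseudocount))
  names(stat) <- rownames(counts)
  stat
}

#' Read / write peaks as BED
#'
#' BED files are 0-based half-open; the name column carries `region_id`. The
#' per-region statistic is written as a separate TSV (`region_id`, `stat`)
#' to avoid BED score quantization.
#'
#' @param path BED file path.
#' @param stats_path Optional TSV of per-region statistics.
#' @param chrom_lengths Optional named chromosome lengths for validation.
#' @return `read_peaks_bed` returns a `peak_set`.
#' @export
read_peaks_bed <- function(path, stats_path = NULL, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- gr$name
  if (!is.null(nm) && !anyNA(nm)) df$region_id <- as.character(nm)
  ps <- peak_set(df, chrom_lengths)
  if (!is.null(stats_path)) {
    st <- utils::read.delim(stats_path, stringsAsFactors = FALSE)
    ps$stat <- st$stat[match(ps$region_id, st$region_id)]
  }
  ps
}

#' @rdname read_peaks_bed
#' @param peaks A `peak_set`.
#' @export
write_peaks_bed <- function(peaks, path, stats_path = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  bed <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE,
                                        trim = TRUE),
                    format(peaks$end, scientific = FALSE, trim = TRUE),
                    peaks$region_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(stats_path) && !is.null(peaks$stat)) {
    utils::write.table(
      data.frame(region_id = peaks$region_id, stat = peaks$stat),
      stats_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
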