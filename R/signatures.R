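# Signature scoring on a genes x cells expression matrix (dense matrix or
# Matrix sparse class). Cells in columns, genes in rows, as in
# SingleCellExperiment conventions.

match_signature <- function(expr, signature, what = "signature") {
  if (length(signature) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  present <- intersect(unique(as.character(signature)), rownames(expr))
  dropped <- setdiff(unique(as.character(signature)), present)
  if (length(dropped)) {
    warning(length(dropped), " ", what, " gene(s) absent from matrix, ",
            "dropped: ", paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...", call. = FALSE)
  }
  if (length(present) == 0L) {
    stop("no ", what, " genes present in the matrix", call. = FALSE)
  }
  present
}

#' Percentage of signature genes expressed per cell
#'
#' A gene counts as expressed in a cell when its raw count is non-zero; the
#' per-cell value is `100 * (# expressed signature genes) / |signature|`
#' (after dropping signature genes absent from the matrix, with a warning).
#'
#' @param expr Raw count matrix, genes x cells.
#' @param signature Character vector of gene ids.
#' @return Named numeric vector (per cell) of percentages in `[0, 100]`.
#' @export
percent_expressing_per_cell <- function(expr, signature) {
  sig <- match_signature(expr, signature)
  sub <- expr[sig, , drop = FALSE]
  100 * Matrix::colSums(sub > 0) / length(sig)
}

#' Summarize per-cell values by cluster and genotype
#'
#' Box-plot style summary per group: median, quartiles (linear-interpolation
#' quantiles, R type 7), and whisker bounds at the most extreme data points
#' within 1.5 times the interquartile range of the quartiles.
#'
#' @param values Named per-cell numeric vector (names = cell ids).
#' @param annotation Data frame with columns `cell_id`, `cluster`, and
#'   (optionally) `genotype`.
#' @param by Annotation columns to group by.
#' @return Data frame with one row per non-empty group: grouping columns,
#'   `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`. Empty groups
#'   (unused factor levels) are omitted with a warning.
#' @export
aggregate_by_cluster <- function(values, annotation,
                                 by = intersect(c("cluster", "genotype"),
                                                names(annotation))) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (!"cell_id" %in% names(annotation)) {
    stop("annotation must have a 'cell_id' column", call. = FALSE)
  }
  if (length(by) == 0L) stop("no grouping columns", call. = FALSE)
  ann <- annotation[match(names(values), annotation$cell_id), , drop = FALSE]
  if (anyNA(ann$cell_id)) {
    stop("cells missing from annotation", call. = FALSE)
  }
  key <- interaction(ann[by], drop = FALSE, sep = "\r")
  empty <- setdiff(levels(key), unique(as.character(key)))
  if (length(empty)) {
    warning(length(empty), " empty group(s) omitted", call. = FALSE)
  }
  groups <- split(values, key, drop = TRUE)
  summ <- t(vapply(groups, function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3L] - qs[1L]
    lo <- min(v[v >= qs[1L] - 1.5 * iqr])
    hi <- max(v[v <= qs[3L] + 1.5 * iqr])
    c(length(v), qs[2L], qs[1L], qs[3L], lo, hi)
  }, numeric(6L)))
  keys <- do.call(rbind, strsplit(rownames(summ), "\r", fixed = TRUE))
  out <- data.frame(keys, summ, stringsAsFactors = FALSE)
  names(out) <- c(by, "n", "median", "q1", "q3", "whisker_lo", "whisker_hi")
  out$n <- as.integer(out$n)
  rownames(out) <- NULL
  attr(out, "quantile_type") <- 7L
  out
}

normalize_expression <- function(expr, scale_factor = 1e4) {
  depth <- Matrix::colSums(expr)
  sf <- ifelse(depth > 0, depth / scale_factor, 1)
  list(depth = depth, sf = sf)
}

#' Mean z-score signature score per cell
#'
#' Scores each cell as the mean, over signature genes, of the gene's
#' z-scored expression across cells. Raw counts are normalized internally to
#' counts-per-`scale_factor` followed by `log1p`; already-normalized input
#' is used as is. Genes with zero variance contribute 0.
#'
#' @param expr Genes x cells matrix (raw counts or normalized values).
#' @param signature Character vector of gene ids.
#' @param normalized `TRUE` if `expr` is already normalized, `FALSE` for raw
#'   counts, or `NULL` to auto-detect (integer-valued non-negative matrices
#'   are treated as raw).
#' @param scale_factor Depth target for internal normalization (default
#'   1e4).
#' @return Named per-cell numeric score with attribute `normalized_internally`.
#' @export
signature_mean_score <- function(expr, signature, normalized = NULL,
                                 scale_factor = 1e4) {
  sig <- match_signature(expr, signature)
  vals <- if (methods::is(expr, "sparseMatrix")) expr@x else expr
  if (is.null(normalized)) {
    normalized <- !(all(vals >= 0) && all(vals == round(vals)))
  }
  sub <- as.matrix(expr[sig, , drop = FALSE])
  if (!normalized) {
    nf <- normalize_expression(expr, scale_factor)
    sub <- log1p(sweep(sub, 2L, nf$sf, "/"))
  }
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  score <- colMeans(z)
  attr(score, "normalized_internally") <- !normalized
  score
}

#' Neutrophil and monocyte lineage scores per cell
#'
#' Convenience wrapper computing [signature_mean_score()] for a neutrophil
#' and a monocyte marker set jointly, e.g. for 2-D contour summaries of
#' lineage priming in early progenitors.
#'
#' @param expr Genes x cells matrix.
#' @param neutrophil_markers,monocyte_markers Marker gene sets.
#' @inheritParams signature_mean_score
#' @return Data frame `cell_id`, `neutrophil`, `monocyte`.
#' @export
lineage_scores <- function(expr, neutrophil_markers, monocyte_markers,
                           normalized = NULL, scale_factor = 1e4) {
  neu <- signature_mean_score(expr, neutrophil_markers, normalized,
                              scale_factor)
  mono <- signature_mean_score(expr, monocyte_markers, normalized,
                               scale_factor)
  data.frame(cell_id = colnames(expr), neutrophil = as.numeric(neu),
             monocyte = as.numeric(mono), stringsAsFactors = FALSE)
}

#' Binned signature trajectory along pseudotime
#'
#' Averages per-cell scores in equal-width pseudotime bins, separately per
#' genotype, over the pooled pseudotime range of all scored cells with
#' non-missing pseudotime. Empty bins are reported as `NA`.
#'
#' @param scores Named per-cell numeric vector.
#' @param annotation Data frame with `cell_id`, `genotype`, `pseudotime`.
#' @param n_bins Number of equal-width bins (default 50).
#' @return Data frame `bin`, `mid` (bin center), `genotype`, `mean_score`,
#'   `n_cells` covering the full bin x genotype grid.
#' @export
pseudotime_profile <- function(scores, annotation, n_bins = 50L) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  req <- c("cell_id", "genotype", "pseudotime")
  if (!all(req %in% names(annotation))) {
    stop("annotation needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  ann <- annotation[match(names(scores), annotation$cell_id), , drop = FALSE]
  keep <- is.finite(ann$pseudotime)
  if (!any(keep)) stop("no cells with pseudotime", call. = FALSE)
  pt <- ann$pseudotime[keep]
  sc <- scores[keep]
  gt <- as.character(ann$genotype[keep])
  breaks <- seq(min(pt), max(pt), length.out = n_bins + 1L)
  bin <- if (n_bins == 1L) rep(1L, length(pt)) else {
    findInterval(pt, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  genotypes <- sort(unique(gt))
  grid <- expand.grid(bin = seq_len(n_bins), genotype = genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(bin, gt, sep = "\r")
  means <- tapply(sc, key, mean)
  ns <- tapply(sc, key, length)
  gkey <- paste(grid$bin, grid$genotype, sep = "\r")
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  n_cells <- as.integer(ns[gkey])
  n_cells[is.na(n_cells)] <- 0L
  out <- data.frame(
    bin = grid$bin,
    mid = mids[grid$bin],
    genotype = grid$genotype,
    mean_score = as.numeric(means[gkey]),
    n_cells = n_cells,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
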