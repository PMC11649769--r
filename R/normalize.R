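#' NTC-anchored per-sample size factors
#'
#' Computes one positive scale factor per sample from the non-targeting
#' controls: `factor_s = stat(NTC counts in s) / geometric mean of the stats
#' across samples`. Dividing sample `s` by `factor_s` equalizes the NTC
#' summary statistic across samples, anchoring normalization on the controls
#' rather than on total library size.
#'
#' @param counts A [screen_counts()] object.
#' @param library A [screen_library()].
#' @param stat Summary of NTC counts per sample: `"median"` (robust default)
#'   or `"total"`.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
ntc_size_factors <- function(counts, library, stat = c("median", "total")) {
  stopifnot(inherits(counts, "screen_counts"), inherits(library, "screen_library"))
  stat <- match.arg(stat)
  ntc <- intersect(library$shrna_id[library$role == "ntc"],
                   rownames(counts$counts))
  if (length(ntc) < 1L) stop("no NTC shRNAs found in counts", call. = FALSE)
  m <- counts$counts[ntc, , drop = FALSE]
  if (any(colSums(m) == 0)) {
    stop("all NTC counts are zero in sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  }
  s <- if (stat == "median") apply(m, 2L, stats::median) else colSums(m)
  if (any(s == 0)) {
    stop("NTC ", stat, " is zero in sample(s): ",
         paste(colnames(m)[s == 0], collapse = ", "), call. = FALSE)
  }
  s / geometric_mean(s)
}

#' Per-shRNA log2 fold changes of final versus input samples
#'
#' Pairs every final sample with an input sample of the same cell line
#' (replicate-matched input when present, otherwise the line's single input)
#' and computes `log2((c_final / f_final + pc) / (c_input / f_input + pc))`
#' per shRNA, where `f` are size factors and `pc` a pseudocount applied after
#' size-factor scaling.
#'
#' @param counts A [screen_counts()] object.
#' @param factors Named per-sample size factors, e.g. from
#'   [ntc_size_factors()].
#' @param pseudocount Pseudocount added to scaled counts (default 0.5).
#' @return A `fc_matrix`: list with `logfc` (shRNA x column matrix, one
#'   column per final sample named `<cellline>__r<k>`), `samples` (data frame
#'   column/cell_line/replicate), `qn = FALSE`, and `pseudocount`.
#' @export
shrna_log_fold_change <- function(counts, factors, pseudocount = 0.5) {
  stopifnot(inherits(counts, "screen_counts"))
  meta <- counts$meta
  if (!all(meta$sample_id %in% names(factors))) {
    stop("size factors missing for sample(s): ",
         paste(setdiff(meta$sample_id, names(factors)), collapse = ", "),
         call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  finals <- meta[meta$timepoint == "final", , drop = FALSE]
  if (nrow(finals) == 0L) stop("no final samples present", call. = FALSE)
  cols <- list()
  samples <- list()
  for (i in seq_len(nrow(finals))) {
    fin <- finals[i, ]
    inputs <- meta[meta$timepoint == "input" &
                     meta$cell_line == fin$cell_line, , drop = FALSE]
    inp <- inputs[inputs$replicate == fin$replicate, , drop = FALSE]
    if (nrow(inp) == 0L && nrow(inputs) == 1L) inp <- inputs
    if (nrow(inp) != 1L) {
      stop("final sample '", fin$sample_id,
           "' has no unambiguous input sample", call. = FALSE)
    }
    cf <- counts$counts[, fin$sample_id] / factors[[fin$sample_id]]
    ci <- counts$counts[, inp$sample_id] / factors[[inp$sample_id]]
    cname <- sprintf("%s__r%d", fin$cell_line, fin$replicate)
    cols[[cname]] <- log2((cf + pseudocount) / (ci + pseudocount))
    samples[[cname]] <- data.frame(column = cname, cell_line = fin$cell_line,
                                   replicate = fin$replicate,
                                   stringsAsFactors = FALSE)
  }
  logfc <- do.call(cbind, cols)
  rownames(logfc) <- rownames(counts$counts)
  structure(list(logfc = logfc, samples = do.call(rbind, samples),
                 qn = FALSE, pseudocount = pseudocount),
            class = "fc_matrix")
}

#' Quantile-normalize a fold-change matrix
#'
#' Replaces each column's values by the mean of the order statistics across
#' columns (the reference distribution), assigned by within-column rank, so
#' that afterwards the sorted values of every column are identical. A
#' single-column matrix passes through unchanged.
#'
#' Tied values: with `ties = "split"` (the default) tied entries receive
#' distinct consecutive reference values in row order, so every output
#' column is exactly a permutation of the reference and the operation is
#' exactly idempotent. With `ties = "average"` tied entries all receive the
#' mean of the reference values over their tied rank range; this keeps equal
#' inputs equal but places averaged values outside the reference, so a
#' second pass can shift them (not idempotent on tied data).
#'
#' @param fc A `fc_matrix` from [shrna_log_fold_change()].
#' @param ties Tie policy, `"split"` or `"average"` (see Details).
#' @return The `fc_matrix` with normalized `logfc` and `qn = TRUE`.
#' @export
quantile_normalize <- function(fc, ties = c("split", "average")) {
  stopifnot(inherits(fc, "fc_matrix"))
  ties <- match.arg(ties)
  x <- fc$logfc
  if (any(!is.finite(x))) {
    stop("fold-change matrix contains non-finite values", call. = FALSE)
  }
  if (ncol(x) > 1L) {
    ref <- rowMeans(apply(x, 2L, sort))
    for (j in seq_len(ncol(x))) {
      o <- order(x[, j])
      if (ties == "split") {
        x[o, j] <- ref
      } else {
        xs <- x[o, j]
        grp <- cumsum(c(TRUE, xs[-1L] != xs[-length(xs)]))
        gm <- vapply(split(seq_along(xs), grp),
                     function(idx) mean(ref[idx]), numeric(1L))
        x[o, j] <- gm[grp]
      }
    }
    fc$logfc <- x
  }
  fc$qn <- TRUE
  fc
}

#' Restrict a fold-change matrix to one cell line
#'
#' @param fc A `fc_matrix`.
#' @param cell_line Cell-line label to keep.
#' @return The `fc_matrix` with only that line's replicate columns.
#' @export
fc_subset <- function(fc, cell_line) {
  stopifnot(inherits(fc, "fc_matrix"))
  keep <- fc$samples$cell_line == cell_line
  if (!any(keep)) {
    stop("no columns for cell line '", cell_line, "'", call. = FALSE)
  }
  fc$logfc <- fc$logfc[, fc$samples$column[keep], drop = FALSE]
  fc$samples <- fc$samples[keep, , drop = FALSE]
  fc
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix:", nrow(x$logfc), "shRNAs x", ncol(x$logfc), "columns;",
      "qn =", x$qn, "\n")
  invisible(x)
}
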