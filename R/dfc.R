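#' Per-shRNA differential fold changes between two cell lines
#'
#' For every shRNA, the difference of replicate-mean quantile-normalized
#' log2 fold changes between two cell lines:
#' `DFC = mean qn-logFC(line A) - mean qn-logFC(line B)`. Negative values
#' mean stronger depletion (preferential growth inhibition) in line A.
#' Replicate averaging precedes the subtraction, and the table is
#' antisymmetric under swapping the two lines.
#'
#' @param fc_a,fc_b Quantile-normalized single-line `fc_matrix` objects (use
#'   [fc_subset()] on a jointly normalized matrix); must cover an identical
#'   shRNA universe.
#' @param library A [screen_library()] supplying gene and role per shRNA.
#' @return A `dfc_table` data frame: `shrna_id`, `gene`, `role`, `dfc`, with
#'   attribute `comparison` `"A_vs_B"`.
#' @export
per_shrna_dfc <- function(fc_a, fc_b, library) {
  stopifnot(inherits(fc_a, "fc_matrix"), inherits(fc_b, "fc_matrix"),
            inherits(library, "screen_library"))
  if (!isTRUE(fc_a$qn) || !isTRUE(fc_b$qn)) {
    stop("both fold-change matrices must be quantile-normalized", call. = FALSE)
  }
  for (fc in list(fc_a, fc_b)) {
    if (length(unique(fc$samples$cell_line)) != 1L) {
      stop("each fc matrix must hold a single cell line; use fc_subset()",
           call. = FALSE)
    }
  }
  a_ids <- rownames(fc_a$logfc)
  b_ids <- rownames(fc_b$logfc)
  miss <- c(setdiff(a_ids, b_ids), setdiff(b_ids, a_ids))
  if (length(miss)) {
    stop("shRNA universes differ; missing: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ...", call. = FALSE)
  }
  dfc <- rowMeans(fc_a$logfc) - rowMeans(fc_b$logfc)[a_ids]
  lib <- library[match(a_ids, library$shrna_id), , drop = FALSE]
  if (anyNA(lib$shrna_id)) {
    stop("shRNAs absent from library", call. = FALSE)
  }
  line_a <- unique(fc_a$samples$cell_line)
  line_b <- unique(fc_b$samples$cell_line)
  out <- data.frame(shrna_id = a_ids, gene = lib$gene, role = lib$role,
                    dfc = unname(dfc), stringsAsFactors = FALSE)
  attr(out, "comparison") <- paste0(line_a, "_vs_", line_b)
  attr(out, "line_a") <- line_a
  attr(out, "line_b") <- line_b
  class(out) <- c("dfc_table", "data.frame")
  out
}

#' Empirical NTC-based DFC cutoff
#'
#' The q-th quantile of the non-targeting controls' differential fold
#' changes, used as the empirical threshold beyond which a target shRNA's
#' DFC is considered to show preferential depletion. The linear-interpolation
#' quantile convention (R type 7) is used and recorded on the result.
#'
#' @param dfc A `dfc_table` from [per_shrna_dfc()].
#' @param q Lower-tail quantile (default 0.05).
#' @return Numeric cutoff (log2 units) with attribute `quantile_type`.
#' @export
ntc_dfc_cutoff <- function(dfc, q = 0.05) {
  stopifnot(inherits(dfc, "dfc_table"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  ntc <- dfc$dfc[dfc$role == "ntc"]
  if (length(ntc) < 10L) {
    stop("need >= 10 NTC rows for the empirical cutoff (have ",
         length(ntc), ")", call. = FALSE)
  }
  cutoff <- unname(stats::quantile(ntc, probs = q, type = 7))
  attr(cutoff, "quantile_type") <- 7L
  attr(cutoff, "q") <- q
  cutoff
}

#' Classify genes with preferential growth inhibition
#'
#' A gene is classified as preferentially growth-inhibiting in line A of the
#' comparison when it is essential in line A and at least `min_support` of
#' its shRNAs have a DFC below the empirical NTC cutoff.
#'
#' @param dfc A `dfc_table` (line A minus line B).
#' @param cutoff The NTC cutoff from [ntc_dfc_cutoff()].
#' @param essential_calls_a A `gene_essentiality` data frame for line A with
#'   the `essential` column filled (see [call_essential_genes()]).
#' @param min_support Minimum shRNAs beyond the cutoff (default 3).
#' @return A `preferential_calls` data frame: `gene`, `comparison`,
#'   `essential_a`, `n_below_cutoff`, `classified`, `cutoff`.
#' @export
classify_preferential_genes <- function(dfc, cutoff, essential_calls_a,
                                        min_support = 3L) {
  stopifnot(inherits(dfc, "dfc_table"),
            inherits(essential_calls_a, "gene_essentiality"))
  if (!"essential" %in% names(essential_calls_a)) {
    stop("essential calls lack an 'essential' column; run ",
         "call_essential_genes() first", call. = FALSE)
  }
  tgt <- dfc[dfc$role == "target", , drop = FALSE]
  n_below <- tapply(tgt$dfc < cutoff, tgt$gene, sum)
  genes <- names(n_below)
  ess <- genes %in% essential_calls_a$gene[essential_calls_a$essential]
  out <- data.frame(
    gene = genes,
    comparison = attr(dfc, "comparison"),
    essential_a = ess,
    n_below_cutoff = as.integer(n_below),
    classified = ess & as.integer(n_below) >= min_support,
    cutoff = as.numeric(cutoff),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("preferential_calls", "data.frame")
  out
}

#' Genes classified preferential in multiple comparisons
#'
#' @param calls Named list of `preferential_calls` data frames (one per
#'   comparison).
#' @return Data frame of genes classified in at least two comparisons, with
#'   a comma-separated `comparisons` provenance column and `n_comparisons`.
#' @export
cross_line_intersection <- function(calls) {
  if (length(calls) < 2L) {
    stop("need >= 2 comparisons", call. = FALSE)
  }
  hits <- lapply(calls, function(x) {
    stopifnot(inherits(x, "preferential_calls"))
    x[x$classified, c("gene", "comparison"), drop = FALSE]
  })
  all_hits <- do.call(rbind, hits)
  if (nrow(all_hits) == 0L) {
    return(data.frame(gene = character(0), comparisons = character(0),
                      n_comparisons = integer(0), stringsAsFactors = FALSE))
  }
  by_gene <- split(all_hits$comparison, all_hits$gene)
  shared <- by_gene[lengths(by_gene) >= 2L]
  out <- data.frame(
    gene = names(shared),
    comparisons = vapply(shared, function(z) paste(sort(unique(z)),
                                                   collapse = ","),
                         character(1L)),
    n_comparisons = lengths(shared),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
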