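#' Per-shRNA depletion p-values against the NTC empirical null
#'
#' Scores every shRNA's mean quantile-normalized log2 fold change for one
#' cell line against the empirical distribution of the non-targeting
#' controls: `p_i = (#\{NTC j : x_j <= x_i\} + 1) / (N_ntc + 1)` for the
#' depletion direction (`>=` for enrichment). Normalized ranks `r = rank/N`
#' are computed over all target (non-control) shRNAs ordered by p, with ties
#' broken by mean logFC (ascending) and then id, so ranks are reproducible.
#'
#' @param fc A quantile-normalized `fc_matrix` (see [quantile_normalize()]).
#' @param library A [screen_library()].
#' @param cell_line Cell line to score; may be omitted when `fc` holds a
#'   single line.
#' @param alpha Significance threshold used for the support flag and for
#'   alpha-RRA selection (default 0.25).
#' @param direction `"depletion"` (dropout screens) or `"enrichment"`.
#' @return A `shrna_stats` data frame with columns `shrna_id`, `gene`,
#'   `role`, `mean_logfc`, `p`, `r` (normalized rank, `NA` for controls) and
#'   `support` (`p < alpha` and depleted).
#' @export
shrna_null_pvalues <- function(fc, library, cell_line = NULL, alpha = 0.25,
                               direction = c("depletion", "enrichment")) {
  stopifnot(inherits(fc, "fc_matrix"), inherits(library, "screen_library"))
  direction <- match.arg(direction)
  if (!isTRUE(fc$qn)) {
    stop("fold changes must be quantile-normalized first", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  lines <- unique(fc$samples$cell_line)
  if (is.null(cell_line)) {
    if (length(lines) != 1L) {
      stop("fc holds multiple cell lines; specify 'cell_line'", call. = FALSE)
    }
    cell_line <- lines
  }
  fc <- fc_subset(fc, cell_line)
  x <- rowMeans(fc$logfc)
  lib <- library[match(names(x), library$shrna_id), , drop = FALSE]
  if (anyNA(lib$shrna_id)) {
    stop("fold-change rows absent from library", call. = FALSE)
  }
  ntc <- x[lib$role == "ntc"]
  if (length(ntc) < 10L) {
    stop("need >= 10 NTC shRNAs for the empirical null (have ",
         length(ntc), ")", call. = FALSE)
  }
  n_ntc <- length(ntc)
  ntc_sorted <- sort(ntc)
  p <- if (direction == "depletion") {
    (findInterval(x, ntc_sorted) + 1) / (n_ntc + 1)
  } else {
    (n_ntc - findInterval(x, ntc_sorted, left.open = TRUE) + 1) / (n_ntc + 1)
  }
  out <- data.frame(shrna_id = names(x), gene = lib$gene, role = lib$role,
                    mean_logfc = unname(x), p = unname(p), r = NA_real_,
                    stringsAsFactors = FALSE)
  tgt <- which(out$role == "target")
  o <- tgt[order(out$p[tgt], out$mean_logfc[tgt], out$shrna_id[tgt])]
  out$r[o] <- seq_along(o) / length(o)
  out$support <- out$p < alpha &
    (if (direction == "depletion") out$mean_logfc < 0 else out$mean_logfc > 0)
  attr(out, "cell_line") <- cell_line
  attr(out, "alpha") <- alpha
  attr(out, "direction") <- direction
  class(out) <- c("shrna_stats", "data.frame")
  out
}

#' Alpha-RRA gene score from shRNA normalized ranks
#'
#' The robust rank aggregation score of a gene with `n` shRNAs whose
#' normalized ranks are `r_1 <= ... <= r_n`: with `j` shRNAs selected
#' (p-value below `alpha`), `rho = min_{k=1..j} BetaCDF(r_k; k, n - k + 1)`,
#' the tail probability of the k-th order statistic of `n` uniforms; if no
#' shRNA is selected, `rho = 1`. Smaller `rho` means more consistently
#' top-ranked shRNAs.
#'
#' @param r Normalized ranks in (0, 1] (any order).
#' @param selected Logical vector marking selected shRNAs (p < alpha); the
#'   selected shRNAs are always the lowest-ranked ones because ranks are
#'   monotone in p.
#' @return The score `rho` in (0, 1].
#' @examples
#' alpha_rra_score(c(0.01, 0.02, 0.5, 0.7, 0.9),
#'                 selected = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
alpha_rra_score <- function(r, selected) {
  stopifnot(length(r) == length(selected))
  if (any(r <= 0 | r > 1)) stop("ranks must lie in (0, 1]", call. = FALSE)
  n <- length(r)
  j <- sum(selected)
  if (j == 0L) return(1)
  rs <- sort(r)
  k <- seq_len(j)
  min(stats::pbeta(rs[k], k, n - k + 1))
}

# vectorized rho for a stack of genes of equal size: rmat is an
# n_genes x size matrix of ranks, j the per-gene number of selected shRNAs
rho_matrix <- function(rmat, j) {
  size <- ncol(rmat)
  o <- order(row(rmat), rmat)
  rs <- matrix(rmat[o], nrow(rmat), size, byrow = TRUE)
  rho <- rep(1, nrow(rmat))
  for (k in seq_len(size)) {
    bk <- stats::pbeta(rs[, k], k, size - k + 1)
    use <- j >= k
    rho[use] <- pmin(rho[use], bk[use])
  }
  rho
}

#' Gene-level essentiality by alpha-RRA with permutation FDR
#'
#' Aggregates per-shRNA NTC-null statistics to gene level: observed `rho` per
#' target gene via [alpha_rra_score()], then a permutation null obtained by
#' randomly permuting shRNA-to-gene assignments (preserving per-gene shRNA
#' counts; null distributions pooled across genes of equal size),
#' `p_perm = (#\{null rho <= observed\} + 1) / (n_null + 1)`, and
#' Benjamini-Hochberg FDR across target genes. Killing pseudo-genes and NTCs
#' are excluded by role.
#'
#' @param stats A `shrna_stats` data frame from [shrna_null_pvalues()].
#' @param alpha Selection threshold for alpha-RRA (default: the alpha stored
#'   in `stats`).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return A `gene_essentiality` data frame: `gene`, `n_shrna`, `rho`,
#'   `p_perm`, `fdr`, `n_support`, `mean_logfc` (and, after
#'   [call_essential_genes()], `essential`).
#' @export
rra_permutation_fdr <- function(stats, alpha = NULL, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(stats, "shrna_stats"))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  alpha <- alpha %||% attr(stats, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  tgt <- stats[stats$role == "target", , drop = FALSE]
  sel <- tgt$p < alpha
  genes <- split(seq_len(nrow(tgt)), tgt$gene)
  sizes <- lengths(genes)

  obs <- vapply(genes, function(idx) {
    alpha_rra_score(tgt$r[idx], sel[idx])
  }, numeric(1L))

  # genes grouped by shRNA count: a permuted vector is cut into contiguous
  # blocks per size class and reshaped into one matrix per class
  by_size <- split(seq_along(genes), sizes)
  n_sh <- nrow(tgt)
  pools <- with_seed(seed, {
    acc <- lapply(by_size, function(gi) {
      matrix(NA_real_, nrow = length(gi), ncol = n_perm)
    })
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n_sh)
      rp <- tgt$r[idx]
      sp <- sel[idx]
      offset <- 0L
      for (s in seq_along(by_size)) {
        size <- as.integer(names(by_size)[s])
        g <- length(by_size[[s]])
        take <- offset + seq_len(g * size)
        rmat <- matrix(rp[take], nrow = g, ncol = size, byrow = TRUE)
        jvec <- rowSums(matrix(sp[take], nrow = g, ncol = size, byrow = TRUE))
        acc[[s]][, p] <- rho_matrix(rmat, jvec)
        offset <- offset + g * size
      }
    }
    lapply(acc, function(m) sort(as.numeric(m)))
  })

  p_perm <- numeric(length(genes))
  for (s in seq_along(by_size)) {
    pool <- pools[[s]]
    which_genes <- by_size[[s]]
    p_perm[which_genes] <-
      (findInterval(obs[which_genes], pool) + 1) / (length(pool) + 1)
  }

  out <- data.frame(
    gene = names(genes),
    n_shrna = as.integer(sizes),
    rho = unname(obs),
    p_perm = p_perm,
    fdr = stats::p.adjust(p_perm, method = "BH"),
    n_support = vapply(genes, function(idx) sum(tgt$support[idx]), integer(1L)),
    mean_logfc = vapply(genes, function(idx) mean(tgt$mean_logfc[idx]),
                        numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "cell_line") <- attr(stats, "cell_line")
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  class(out) <- c("gene_essentiality", "data.frame")
  out
}

#' Call essential genes from aggregated screen statistics
#'
#' A gene is called essential when (a) its knockdown reduces growth
#' (gene-level mean logFC < 0), (b) it is significant in the permutation test
#' (FDR below `fdr_threshold`), and (c) at least `min_support` of its shRNAs
#' individually show significant depletion against the NTC null.
#'
#' @param results A `gene_essentiality` data frame from
#'   [rra_permutation_fdr()].
#' @param fdr_threshold Gene-level FDR cutoff (default 0.01).
#' @param min_support Minimum number of supporting shRNAs (default 3).
#' @return The input with a logical `essential` column filled in.
#' @export
call_essential_genes <- function(results, fdr_threshold = 0.01,
                                 min_support = 3L) {
  stopifnot(inherits(results, "gene_essentiality"))
  results$essential <- results$fdr < fdr_threshold &
    results$n_support >= min_support &
    results$mean_logfc < 0
  results
}

#' Overlap classes of essential-gene sets across cell lines
#'
#' Partitions the union of per-line essential gene sets into exclusive
#' intersection classes (the counts behind an upset plot).
#'
#' @param calls Named list (one element per cell line) of either
#'   `gene_essentiality` data frames with an `essential` column or plain
#'   character vectors of essential genes.
#' @return Data frame with one row per non-empty class: one logical column
#'   per line, a `lines` label (e.g. `"A&B"`), and `n_genes`; classes
#'   partition the union.
#' @export
essentiality_overlap <- function(calls) {
  if (length(calls) < 2L || is.null(names(calls))) {
    stop("'calls' must be a named list of >= 2 cell lines", call. = FALSE)
  }
  sets <- lapply(calls, function(x) {
    if (is.data.frame(x)) {
      if (!"essential" %in% names(x)) {
        stop("data frame lacks an 'essential' column; run ",
             "call_essential_genes() first", call. = FALSE)
      }
      x$gene[x$essential]
    } else {
      as.character(x)
    }
  })
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L) {
    out <- data.frame(lines = character(0), n_genes = integer(0))
    attr(out, "n_union") <- 0L
    return(out)
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  pattern <- apply(member, 1L, function(z) {
    paste(names(sets)[z], collapse = "&")
  })
  tab <- table(pattern)
  out <- data.frame(lines = names(tab), n_genes = as.integer(tab),
                    stringsAsFactors = FALSE)
  for (ln in names(sets)) {
    out[[ln]] <- vapply(strsplit(out$lines, "&", fixed = TRUE),
                        function(z) ln %in% z, logical(1L))
  }
  out <- out[order(-out$n_genes), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_union") <- length(universe)
  out
}

#' Write gene-level essentiality results as TSV
#'
#' @param results A `gene_essentiality` data frame.
#' @param path Output path.
#' @export
write_essentiality <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
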