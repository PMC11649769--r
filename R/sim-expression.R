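#' Generate a signature-structured single-cell expression fixture
#'
#' Simulates a sparse genes x cells count matrix emulating an HSPC
#' single-cell experiment with a neutrophil differentiation trajectory:
#' cells belong to clusters along the trajectory (plus a monocyte-progenitor
#' cluster off it), carry a genotype label, and trajectory cells carry a
#' pseudotime in `[0, 1]`. Four gene signatures (stem/growth, monocytic,
#' pro-survival, neutrophil) follow cluster-level baseline trends, and
#' configurable genotype effects plant over/under-expression of signature
#' genes. Counts are Poisson draws around per-group expected profiles scaled
#' to a common library size, with optional extra dropout.
#'
#' Defaults mirror the emulated study qualitatively: the pro-survival
#' signature (and the neutrophil signature) are overexpressed and the
#' monocytic signature underexpressed in the PU.1-low genotype along the
#' trajectory; the third signature has 346 genes.
#'
#' @param n_cells Total number of cells (default 4000; a desk-scale stand-in
#'   for the ~10,000-cell experiment).
#' @param n_genes Gene universe size (default 2500).
#' @param cluster_props Named cluster proportions (default C1/C2/C3 on the
#'   trajectory plus C5 off it).
#' @param genotypes Character vector of genotype labels, assigned to cells
#'   with equal probability (default `c("WT", "URE")`).
#' @param signature_sizes Named signature sizes; must sum to at most
#'   `n_genes`.
#' @param effects Data frame of planted genotype effects with columns
#'   `signature`, `genotype`, `log2fc` (applied in every cluster). Use
#'   `NULL` for no effect.
#' @param cluster_profile Optional signature x cluster matrix of baseline
#'   log2 shifts; a built-in trend (stem high early, neutrophil rising along
#'   the trajectory, monocytic in C5) is used when `NULL`.
#' @param library_size Expected counts per cell (default 5000).
#' @param dropout_rate Extra Bernoulli dropout applied to all entries
#'   (default 0; the Poisson model already yields zeros).
#' @param n_markers Number of top trend genes exported as neutrophil /
#'   monocyte lineage marker sets.
#' @param seed RNG seed.
#' @return An `expression_fixture` list: `counts` (sparse dgCMatrix, genes x
#'   cells), `annotation` (`cell_id`, `cluster`, `genotype`, `pseudotime`;
#'   pseudotime is `NA` off the trajectory), and `signatures` (named list of
#'   gene sets including `neutrophil` / `monocyte` marker sets).
#' @export
generate_expression_fixture <- function(n_cells = 4000L,
                                        n_genes = 2500L,
                                        cluster_props = c(C1 = 0.3, C2 = 0.25,
                                                          C3 = 0.25, C5 = 0.2),
                                        genotypes = c("WT", "URE"),
                                        signature_sizes = c(signature1 = 600L,
                                                            signature2 = 500L,
                                                            signature3 = 346L,
                                                            signature4 = 473L),
                                        effects = data.frame(
                                          signature = c("signature3",
                                                        "signature4",
                                                        "signature2"),
                                          genotype = "URE",
                                          log2fc = c(1, 1, -1),
                                          stringsAsFactors = FALSE
                                        ),
                                        cluster_profile = NULL,
                                        library_size = 5000,
                                        dropout_rate = 0,
                                        n_markers = 50L,
                                        seed = 1L) {
  if (sum(signature_sizes) > n_genes) {
    stop("signatures larger than the gene universe (",
         sum(signature_sizes), " > ", n_genes, ")", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("dropout_rate must be in [0, 1]", call. = FALSE)
  }
  clusters <- names(cluster_props)
  trajectory <- intersect(c("C1", "C2", "C3"), clusters)
  if (is.null(cluster_profile)) {
    cluster_profile <- matrix(0, nrow = length(signature_sizes),
                              ncol = length(clusters),
                              dimnames = list(names(signature_sizes),
                                              clusters))
    put <- function(sig, cl, v) {
      cl <- intersect(cl, clusters)
      if (length(cl) && sig %in% rownames(cluster_profile)) {
        cluster_profile[sig, cl] <<- v
      }
    }
    put("signature1", "C1", 1.0); put("signature1", "C2", 0.5)
    put("signature4", "C2", 0.7); put("signature4", "C3", 1.5)
    put("signature2", "C5", 1.5); put("signature2", "C1", 0.3)
    put("signature3", c("C1", "C2", "C3"), 0.3)
  }

  genes <- sprintf("gene%05d", seq_len(n_genes))
  sig_genes <- split(
    genes[seq_len(sum(signature_sizes))],
    rep(names(signature_sizes), times = signature_sizes)
  )[names(signature_sizes)]
  sig_of_gene <- rep(NA_character_, n_genes)
  for (nm in names(sig_genes)) {
    sig_of_gene[match(sig_genes[[nm]], genes)] <- nm
  }

  with_seed(seed, {
    cluster <- sample(clusters, n_cells, replace = TRUE,
                      prob = cluster_props / sum(cluster_props))
    genotype <- sample(genotypes, n_cells, replace = TRUE)
    pseudotime <- rep(NA_real_, n_cells)
    for (i in seq_along(trajectory)) {
      idx <- cluster == trajectory[i]
      lo <- (i - 1) / length(trajectory)
      hi <- i / length(trajectory)
      pseudotime[idx] <- stats::runif(sum(idx), lo, hi)
    }

    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)

    counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
    for (cl in clusters) {
      shift_cl <- rep(0, n_genes)
      for (nm in names(sig_genes)) {
        shift_cl[sig_of_gene == nm] <- cluster_profile[nm, cl]
      }
      for (gt in genotypes) {
        cells <- which(cluster == cl & genotype == gt)
        if (!length(cells)) next
        shift <- shift_cl
        if (!is.null(effects) && nrow(effects)) {
          eff <- effects[effects$genotype == gt, , drop = FALSE]
          for (k in seq_len(nrow(eff))) {
            in_sig <- !is.na(sig_of_gene) & sig_of_gene == eff$signature[k]
            shift[in_sig] <- shift[in_sig] + eff$log2fc[k]
          }
        }
        mu <- base * 2^shift
        lambda <- mu / sum(mu) * library_size
        counts[, cells] <- stats::rpois(n_genes * length(cells),
                                        lambda = rep(lambda, length(cells)))
      }
    }
    if (dropout_rate > 0) {
      keep <- stats::runif(length(counts)) >= dropout_rate
      counts <- counts * keep
    }
    dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(n_cells)))

    sigs <- sig_genes
    if ("signature4" %in% names(sig_genes)) {
      sigs$neutrophil <- utils::head(sig_genes$signature4, n_markers)
    }
    if ("signature2" %in% names(sig_genes)) {
      sigs$monocyte <- utils::head(sig_genes$signature2, n_markers)
    }
    structure(
      list(
        counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                             "CsparseMatrix"),
        annotation = data.frame(cell_id = colnames(counts), cluster = cluster,
                                genotype = genotype, pseudotime = pseudotime,
                                stringsAsFactors = FALSE),
        signatures = sigs
      ),
      class = "expression_fixture"
    )
  })
}

#' Write / read an expression fixture as MTX triplet
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, and `annotation.tsv`
#' under a directory (the plain-text exchange format for sparse single-cell
#' matrices), and reads them back.
#'
#' @param fixture An `expression_fixture` (or any list with `counts` and
#'   `annotation`).
#' @param dir Directory path.
#' @return `read_expression_mtx` returns a list with `counts` and
#'   `annotation`.
#' @export
write_expression_mtx <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(fixture$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(fixture$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(fixture$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(fixture$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  ann_path <- file.path(dir, "annotation.tsv")
  ann <- if (file.exists(ann_path)) {
    utils::read.delim(ann_path, stringsAsFactors = FALSE)
  }
  list(counts = m, annotation = ann)
}
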