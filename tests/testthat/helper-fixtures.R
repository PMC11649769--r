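# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# A small screen simulated end to end: config -> library -> truth -> counts.
small_screen <- function(seed = 1L, ...) {
  cfg <- sim_config(n_target_genes = 30L, n_essential = 6L, n_ntc = 15L,
                    n_killing = 10L, barcodes_per_killing_gene = 5L,
                    depth = 5e4, replicates_per_line = 2L,
                    cell_lines = c("wt", "mut"), seed = seed, ...)
  lib <- generate_library(cfg)
  truth <- generate_screen_truth(lib, cfg)
  counts <- simulate_screen_counts(lib, truth, cfg)
  list(cfg = cfg, lib = lib, truth = truth, counts = counts)
}

# Build an fc_matrix by hand from a named list of per-column logFC vectors.
manual_fc <- function(cols, cell_line = "wt", qn = TRUE) {
  m <- do.call(cbind, cols)
  samples <- data.frame(column = colnames(m),
                        cell_line = rep_len(cell_line, ncol(m)),
                        replicate = seq_len(ncol(m)),
                        stringsAsFactors = FALSE)
  samples$column <- colnames(m)
  structure(list(logfc = m, samples = samples, qn = qn, pseudocount = 0.5),
            class = "fc_matrix")
}

# Minimal library data frame for hand-built statistics.
manual_library <- function(ids, genes, roles) {
  screen_library(data.frame(shrna_id = ids,
                            barcode = make_random_barcodes(length(ids)),
                            gene = genes, role = roles,
                            stringsAsFactors = FALSE))
}

make_random_barcodes <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = "")
  }, character(1L))
}

# Hand-built gene_essentiality rows for classifier tests.
manual_essentiality <- function(gene, fdr, n_support, mean_logfc) {
  out <- data.frame(gene = gene, n_shrna = 5L, rho = 0.5, p_perm = fdr,
                    fdr = fdr, n_support = n_support,
                    mean_logfc = mean_logfc, stringsAsFactors = FALSE)
  class(out) <- c("gene_essentiality", "data.frame")
  out
}

# Random peak data frame on a small genome (possibly overlapping intervals).
random_peaks <- function(n, seed, chroms = c("chr1", "chr2"),
                         chrom_len = 1e6, max_width = 5000) {
  withr::with_seed(seed, {
    chrom <- sample(chroms, n, replace = TRUE)
    start <- sample.int(chrom_len - max_width, n)
    width <- sample.int(max_width, n)
    peak_set(data.frame(chrom = chrom, start = start, end = start + width,
                        region_id = sprintf("p%04d_%d", seq_len(n), seed)))
  })
}
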