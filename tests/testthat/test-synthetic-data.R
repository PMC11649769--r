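test_that("generate_library reproduces the configured design", {
  lib <- generate_library(sim_config())
  expect_s3_class(lib, "screen_library")
  expect_equal(nrow(lib), 344 * 5 + 30 + 45)
  expect_equal(sum(lib$role == "target"), 344 * 5)
  expect_equal(length(unique(lib$gene[lib$role == "target"])), 344)
  expect_equal(sum(lib$role == "killing"), 30)
  expect_equal(length(unique(lib$gene[lib$role == "killing"])), 3)
  expect_true(all(table(lib$gene[lib$role == "killing"]) == 10))
  expect_equal(sum(lib$role == "ntc"), 45)
  expect_false(anyDuplicated(lib$shrna_id) > 0)
  expect_false(anyDuplicated(lib$barcode) > 0)

  tiny <- generate_library(sim_config(n_target_genes = 0, n_killing = 0,
                                      n_ntc = 1))
  expect_equal(nrow(tiny), 1)
  expect_equal(tiny$role, "ntc")

  two <- generate_library(sim_config(n_target_genes = 2, shrnas_per_gene = 3,
                                     n_killing = 0, n_ntc = 1))
  expect_true(all(table(two$gene[two$role == "target"]) == 3))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(generations = 0.5), "generations")
  expect_error(sim_config(essential_effect = 0.1), "\\[-1, 0\\]")
  expect_error(sim_config(essential_effect = -1.5), "\\[-1, 0\\]")
  expect_error(sim_config(killing_effect = -0.5), "killing_effect")
  expect_error(sim_config(n_target_genes = 0, n_killing = 0, n_ntc = 0),
               "non-empty")
  expect_error(sim_config(n_effective = 6), "n_effective")
  expect_error(sim_config(reference_line = "nope"), "reference_line")
})

test_that("screen truth satisfies its invariants", {
  scr <- small_screen(seed = 3, n_preferential = 2)
  truth <- scr$truth
  lib <- scr$lib
  f <- truth$fitness
  expect_true(all(f[lib$shrna_id[lib$role == "ntc"], ] == 0))
  expect_true(all(f[lib$shrna_id[lib$role == "killing"], ] <= -0.8))
  expect_true(all(f >= -1 & f <= 0))
  # essential flag <=> >= 3 shRNAs at or below the effect threshold
  for (ln in colnames(truth$essential)) {
    for (g in rownames(truth$essential)) {
      ids <- lib$shrna_id[lib$role == "target" & lib$gene == g]
      expect_identical(unname(truth$essential[g, ln]),
                       sum(f[ids, ln] <= truth$threshold) >= 3)
    }
  }
  expect_true(all(truth$preferential$line != scr$cfg$reference_line))
  expect_true(all(truth$essential[truth$preferential$gene,
                                  scr$cfg$reference_line]))
})

test_that("simulated counts keep the multinomial and determinism contracts", {
  scr <- small_screen(seed = 5)
  expect_true(all(colSums(scr$counts$counts) == scr$cfg$depth))
  again <- simulate_screen_counts(scr$lib, scr$truth, scr$cfg)
  expect_identical(scr$counts$counts, again$counts)
  other <- simulate_screen_counts(scr$lib, scr$truth, scr$cfg, seed = 999)
  expect_false(identical(scr$counts$counts, other$counts))
})

test_that("neutral dynamics leave proportions unchanged on average", {
  cfg <- sim_config(n_target_genes = 20, n_essential = 0, n_killing = 0,
                    n_ntc = 10, cell_lines = "wt", replicates_per_line = 1,
                    depth = 2e5, abundance_sigma = 0, replicate_sigma = 0,
                    seed = 2)
  lib <- generate_library(cfg)
  truth <- generate_screen_truth(lib, cfg)
  sc <- simulate_screen_counts(lib, truth, cfg)
  lfc <- log2((sc$counts[, "wt__final__r1"] + 0.5) /
                (sc$counts[, "wt__input__r1"] + 0.5))
  se <- sd(lfc) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc)), 3 * se + 1e-3)
})

test_that("growth model matches 2^(G f) depletion for strong effects", {
  # killing clones at f = -1 over G = 10 doublings: logFC vs neutral ~ -10
  cfg <- sim_config(n_target_genes = 20, n_essential = 0, n_killing = 5,
                    barcodes_per_killing_gene = 5, n_ntc = 10,
                    cell_lines = "wt", replicates_per_line = 1,
                    depth = 2e6, generations = 10, killing_effect = -1,
                    abundance_sigma = 0, replicate_sigma = 0, seed = 8)
  lib <- generate_library(cfg)
  truth <- generate_screen_truth(lib, cfg)
  sc <- simulate_screen_counts(lib, truth, cfg)
  lfc <- log2((sc$counts[, "wt__final__r1"] + 0.5) /
                (sc$counts[, "wt__input__r1"] + 0.5))
  drop <- mean(lfc[lib$role == "killing"]) - mean(lfc[lib$role == "ntc"])
  expect_lt(abs(drop - (-10)), 0.5)
})

test_that("Monte-Carlo mean logFC converges to G*f relative to neutral", {
  cfg <- sim_config(n_target_genes = 10, n_essential = 1, n_effective = 5,
                    shrnas_per_gene = 5, essential_effect = -0.5,
                    effect_sd = 0, n_killing = 0, n_ntc = 10,
                    cell_lines = "wt", replicates_per_line = 1,
                    depth = 1e5, generations = 4,
                    abundance_sigma = 0, replicate_sigma = 0, seed = 4)
  lib <- generate_library(cfg)
  truth <- generate_screen_truth(lib, cfg)
  ess <- rownames(truth$fitness)[truth$fitness[, "wt"] == -0.5]
  reps <- vapply(1:200, function(i) {
    sc <- simulate_screen_counts(lib, truth, cfg, seed = 10000 + i)
    lfc <- log2((sc$counts[, "wt__final__r1"] + 0.5) /
                  (sc$counts[, "wt__input__r1"] + 0.5))
    mean(lfc[ess]) - mean(lfc[lib$role == "ntc"])
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 4 * (-0.5)), 3 * se)
})

test_that("simulate_screen_counts validates its inputs", {
  scr <- small_screen()
  broken <- scr$truth
  broken$fitness <- broken$fitness[-1, , drop = FALSE]
  expect_error(simulate_screen_counts(scr$lib, broken, scr$cfg),
               "missing fitness")
  broken2 <- scr$truth
  colnames(broken2$fitness) <- c("x", "y")
  expect_error(simulate_screen_counts(scr$lib, broken2, scr$cfg),
               "missing cell line")
})

test_that("expression fixture plants recoverable genotype effects", {
  fx <- generate_expression_fixture(
    n_cells = 400, n_genes = 400,
    signature_sizes = c(signature1 = 40, signature2 = 40, signature3 = 50,
                        signature4 = 40),
    effects = data.frame(signature = "signature3", genotype = "URE",
                         log2fc = 1, stringsAsFactors = FALSE),
    seed = 21
  )
  expect_true(all(fx$counts@x >= 0))
  sc <- signature_mean_score(fx$counts, fx$signatures$signature3)
  ure <- sc[fx$annotation$genotype == "URE"]
  wt <- sc[fx$annotation$genotype == "WT"]
  expect_gt(mean(ure), mean(wt))
  expect_lt(wilcox.test(ure, wt, alternative = "greater")$p.value, 0.01)

  # effect size 0: no systematic genotype difference
  fx0 <- generate_expression_fixture(
    n_cells = 400, n_genes = 400,
    signature_sizes = c(signature1 = 40, signature2 = 40, signature3 = 50,
                        signature4 = 40),
    effects = NULL, seed = 22
  )
  sc0 <- signature_mean_score(fx0$counts, fx0$signatures$signature3)
  p0 <- wilcox.test(sc0[fx0$annotation$genotype == "URE"],
                    sc0[fx0$annotation$genotype == "WT"])$p.value
  expect_gt(p0, 0.001)
})

test_that("expression fixture boundaries and determinism", {
  expect_error(
    generate_expression_fixture(n_genes = 100,
                                signature_sizes = c(signature1 = 200)),
    "larger than the gene universe"
  )
  fx <- generate_expression_fixture(n_cells = 50, n_genes = 60,
                                    signature_sizes = c(signature3 = 10),
                                    effects = NULL, dropout_rate = 1,
                                    seed = 1)
  expect_equal(sum(fx$counts), 0)
  expect_true(all(percent_expressing_per_cell(fx$counts,
                                              fx$signatures$signature3) == 0))
  a <- generate_expression_fixture(n_cells = 80, n_genes = 100,
                                   signature_sizes = c(signature3 = 10),
                                   seed = 7)
  b <- generate_expression_fixture(n_cells = 80, n_genes = 100,
                                   signature_sizes = c(signature3 = 10),
                                   seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  # trajectory cells have pseudotime, off-trajectory cells do not
  expect_true(all(is.finite(
    a$annotation$pseudotime[a$annotation$cluster %in% c("C1", "C2", "C3")])))
  expect_true(all(is.na(
    a$annotation$pseudotime[a$annotation$cluster == "C5"])))
})

test_that("genomic fixture honors co-binding boundaries", {
  fx0 <- generate_genomic_fixture(n_genes_per_signature = 5,
                                  n_background_genes = 2,
                                  n_background_peaks = 10,
                                  cobound_fraction = 0, seed = 3)
  expect_false(any(intervals_overlap(fx0$tf_peaks, fx0$partner_peaks)))

  fx1 <- generate_genomic_fixture(n_genes_per_signature = 5,
                                  n_background_genes = 2,
                                  n_background_peaks = 10,
                                  cobound_fraction = 1, seed = 3)
  expect_warning(
    sets <- build_signature_region_sets(fx1$tf_peaks, fx1$partner_peaks,
                                        fx1$tss),
    "empty region set"
  )
  expect_length(sets, 0)

  a <- generate_genomic_fixture(n_genes_per_signature = 5,
                                n_background_genes = 2,
                                n_background_peaks = 10, seed = 9)
  b <- generate_genomic_fixture(n_genes_per_signature = 5,
                                n_background_genes = 2,
                                n_background_peaks = 10, seed = 9)
  expect_identical(a$tf_peaks, b$tf_peaks)
  expect_identical(a$truth, b$truth)
})

test_that("peaks exceeding chromosome bounds are an error", {
  expect_error(
    peak_set(data.frame(chrom = "chr1", start = 900, end = 1200),
             chrom_lengths = c(chr1 = 1000)),
    "exceed chromosome bounds"
  )
  expect_error(
    peak_set(data.frame(chrom = "chrX", start = 0, end = 10),
             chrom_lengths = c(chr1 = 1000)),
    "undeclared chromosome"
  )
})
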