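#' Configuration for the pooled-screen simulator
#'
#' Describes a pooled shRNA dropout screen: library composition, growth and
#' sequencing parameters, and the planted fitness-effect model. Defaults
#' reproduce the screen design of the study the package accompanies: a
#' signature-focused library of 344 target genes with five shRNAs each,
#' 30 killing-control shRNAs grouped into 3 pseudo-genes of 10 barcodes,
#' 45 non-targeting controls (NTCs), three cell lines screened in triplicate,
#' and 10 population doublings between the input and final harvests.
#'
#' Fitness effects `f` are dimensionless per-shRNA growth penalties on the
#' scale where 0 is neutral and -1 means no growth: a clone with effect `f`
#' multiplies its abundance by `2^(G * (1 + f))` over `generations = G`
#' doublings, i.e. its expected log2 fold change versus a neutral clone is
#' `G * f`.
#'
#' @param n_target_genes Number of target genes in the library.
#' @param shrnas_per_gene shRNAs designed per target gene.
#' @param n_killing Total killing-control shRNAs (positive controls against
#'   universally growth-essential genes).
#' @param barcodes_per_killing_gene Killing shRNAs are grouped into
#'   pseudo-genes of this size (the last group may be smaller).
#' @param n_ntc Number of non-targeting control shRNAs.
#' @param cell_lines Character vector of cell-line labels.
#' @param replicates_per_line Screen replicates per cell line; each replicate
#'   contributes a replicate-matched input and a final sample.
#' @param depth Sequencing depth (reads) per sample; every simulated sample is
#'   a multinomial draw of exactly this many reads.
#' @param generations Population doublings between input and final harvest.
#' @param frac_essential Fraction of target genes planted as growth-essential
#'   (shared across cell lines); ignored when `n_essential` is given.
#' @param n_essential Number of planted essential genes, overrides
#'   `frac_essential`.
#' @param essential_effect Fitness effect carried by the effective shRNAs of a
#'   planted essential gene (in `[-1, 0]`).
#' @param effect_sd Standard deviation of per-shRNA jitter added to
#'   `essential_effect` (results clamped to `[-1, 0]`).
#' @param n_effective Number of the gene's shRNAs that actually carry the
#'   effect (default 4 of 5: one shRNA per gene is a dud, so the >=3/5
#'   support rule is exercised).
#' @param essential_threshold Effect threshold below which a shRNA counts as
#'   effective when deriving the ground-truth essential flag.
#' @param killing_effect Fitness effect of killing-control shRNAs (must be
#'   <= -0.8).
#' @param n_preferential Number of planted essential genes given an extra
#'   line-specific depletion (differential essentiality).
#' @param delta Extra fitness effect added to the effective shRNAs of a
#'   preferential gene in its assigned non-reference line (total effect is
#'   clamped at -1).
#' @param reference_line Cell line against which differential effects are
#'   defined (no `delta` is ever planted in this line).
#' @param abundance_sigma Log-normal sigma (natural-log scale) of initial
#'   clone abundances; models uneven library representation.
#' @param replicate_sigma Per-sample, per-clone log-normal overdispersion in
#'   log2 units applied to abundances before the multinomial draw; models
#'   replicate-level biological/PCR noise. Set to 0 for a pure multinomial
#'   sequencing model.
#' @param seed Integer seed; together with the config it fully determines all
#'   simulator outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_target_genes = 10, n_essential = 3, depth = 1e4)
#' lib <- generate_library(cfg)
#' @export
sim_config <- function(n_target_genes = 344L,
                       shrnas_per_gene = 5L,
                       n_killing = 30L,
                       barcodes_per_killing_gene = 10L,
                       n_ntc = 45L,
                       cell_lines = c("hoxwt", "hoxure", "ureaml"),
                       replicates_per_line = 3L,
                       depth = 1e6,
                       generations = 10,
                       frac_essential = 0.5,
                       n_essential = NULL,
                       essential_effect = -0.6,
                       effect_sd = 0,
                       n_effective = min(4L, shrnas_per_gene),
                       essential_threshold = -0.3,
                       killing_effect = -0.9,
                       n_preferential = 0L,
                       delta = -1,
                       reference_line = cell_lines[[1L]],
                       abundance_sigma = 1,
                       replicate_sigma = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_target_genes = as.integer(n_target_genes),
    shrnas_per_gene = as.integer(shrnas_per_gene),
    n_killing = as.integer(n_killing),
    barcodes_per_killing_gene = as.integer(barcodes_per_killing_gene),
    n_ntc = as.integer(n_ntc),
    cell_lines = as.character(cell_lines),
    replicates_per_line = as.integer(replicates_per_line),
    depth = as.numeric(depth),
    generations = as.numeric(generations),
    frac_essential = as.numeric(frac_essential),
    n_essential = if (is.null(n_essential)) {
      as.integer(round(frac_essential * n_target_genes))
    } else as.integer(n_essential),
    essential_effect = as.numeric(essential_effect),
    effect_sd = as.numeric(effect_sd),
    n_effective = as.integer(n_effective),
    essential_threshold = as.numeric(essential_threshold),
    killing_effect = as.numeric(killing_effect),
    n_preferential = as.integer(n_preferential),
    delta = as.numeric(delta),
    reference_line = as.character(reference_line),
    abundance_sigma = as.numeric(abundance_sigma),
    replicate_sigma = as.numeric(replicate_sigma),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(...) stop("invalid sim_config: ", ..., call. = FALSE)
  with(cfg, {
    if (n_target_genes < 0L || n_killing < 0L || n_ntc < 0L) {
      fail("library counts must be non-negative")
    }
    if (n_target_genes + n_killing + n_ntc < 1L) fail("library must be non-empty")
    if (shrnas_per_gene < 1L) fail("shrnas_per_gene must be >= 1")
    if (n_killing > 0L && barcodes_per_killing_gene < 1L) {
      fail("barcodes_per_killing_gene must be >= 1")
    }
    if (length(cell_lines) < 1L || anyDuplicated(cell_lines)) {
      fail("cell_lines must be a non-empty set of unique labels")
    }
    if (replicates_per_line < 1L) fail("replicates_per_line must be >= 1")
    if (!is.finite(depth) || depth < 1) fail("depth must be positive")
    if (generations < 1) fail("generations must be >= 1")
    for (f in c("essential_effect", "killing_effect")) {
      v <- cfg[[f]]
      if (v < -1 || v > 0) fail(f, " must lie in [-1, 0]")
    }
    if (killing_effect > -0.8) fail("killing_effect must be <= -0.8")
    if (delta > 0) fail("delta must be <= 0")
    if (n_effective < 1L || n_effective > shrnas_per_gene) {
      fail("n_effective must be in 1..shrnas_per_gene")
    }
    if (n_essential < 0L || n_essential > n_target_genes) {
      fail("n_essential must be in 0..n_target_genes")
    }
    if (n_preferential < 0L || n_preferential > n_essential) {
      fail("n_preferential must be in 0..n_essential")
    }
    if (n_preferential > 0L && length(cell_lines) < 2L) {
      fail("preferential effects need >= 2 cell lines")
    }
    if (!reference_line %in% cell_lines) {
      fail("reference_line must be one of cell_lines")
    }
    if (abundance_sigma < 0 || replicate_sigma < 0) {
      fail("dispersion parameters must be >= 0")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_target_genes, "genes x", x$shrnas_per_gene, "shRNAs;",
      x$n_killing, "killing;", x$n_ntc, "NTC;",
      length(x$cell_lines), "lines x", x$replicates_per_line, "replicates;",
      "G =", x$generations, "depth =", format(x$depth, big.mark = ","),
      "seed =", x$seed, "\n")
  invisible(x)
}
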