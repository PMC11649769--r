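#' Generate a synthetic screen library
#'
#' Builds the shRNA annotation for a simulated pooled dropout screen: target
#' genes with a fixed number of shRNAs each, killing controls grouped into
#' pseudo-genes, and non-targeting controls. Barcodes encode the record index
#' in base 4, so ids and barcodes are unique by construction and the library
#' is fully deterministic.
#'
#' @param config A [sim_config()].
#' @return A [screen_library()].
#' @examples
#' lib <- generate_library(sim_config())
#' nrow(lib)  # 344*5 + 30 + 45 = 1795
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  genes <- sprintf("g%04d", seq_len(config$n_target_genes))
  target <- if (config$n_target_genes > 0L) {
    data.frame(
      shrna_id = paste0(rep(genes, each = config$shrnas_per_gene), "_sh",
                        rep(seq_len(config$shrnas_per_gene),
                            times = config$n_target_genes)),
      gene = rep(genes, each = config$shrnas_per_gene),
      role = "target", stringsAsFactors = FALSE
    )
  }
  killing <- if (config$n_killing > 0L) {
    grp <- (seq_len(config$n_killing) - 1L) %/% config$barcodes_per_killing_gene + 1L
    idx <- stats::ave(seq_len(config$n_killing), grp, FUN = seq_along)
    kg <- sprintf("killctrl%d", grp)
    data.frame(
      shrna_id = sprintf("%s_sh%02d", kg, idx),
      gene = kg, role = "killing", stringsAsFactors = FALSE
    )
  }
  ntc <- if (config$n_ntc > 0L) {
    data.frame(
      shrna_id = sprintf("ntc_%03d", seq_len(config$n_ntc)),
      gene = "NTC", role = "ntc", stringsAsFactors = FALSE
    )
  }
  df <- rbind(target, killing, ntc)
  df$barcode <- make_barcodes(nrow(df))
  screen_library(df[, c("shrna_id", "barcode", "gene", "role")])
}

#' Plant ground-truth fitness effects for a simulated screen
#'
#' Draws the per-shRNA, per-cell-line fitness effects that define the
#' simulated truth: a shared set of essential genes whose effective shRNAs
#' carry `essential_effect`, killing controls at `killing_effect` everywhere,
#' NTCs at 0 everywhere, and a subset of essential genes given an extra
#' line-specific `delta` in one non-reference line (preferential genes,
#' assigned to non-reference lines in rotation). All effects are clamped to
#' `[-1, 0]`.
#'
#' @param library A [screen_library()].
#' @param config A [sim_config()]; `config$seed` determines the draw.
#' @return An object of class `screen_truth`: list with `fitness` (shRNA x
#'   cell-line matrix), `essential` (target gene x cell-line logical matrix,
#'   TRUE when >= 3 shRNAs have effect <= `essential_threshold`),
#'   `preferential` (data frame gene/line), and `threshold`.
#' @export
generate_screen_truth <- function(library, config) {
  stopifnot(inherits(library, "screen_library"), inherits(config, "sim_config"))
  lines <- config$cell_lines
  fitness <- matrix(0, nrow = nrow(library), ncol = length(lines),
                    dimnames = list(library$shrna_id, lines))
  fitness[library$role == "killing", ] <- config$killing_effect

  target_genes <- unique(library$gene[library$role == "target"])
  pref <- data.frame(gene = character(0), line = character(0),
                     stringsAsFactors = FALSE)
  with_seed(config$seed + 1L, {
    ess_genes <- sample(target_genes, config$n_essential)
    for (g in ess_genes) {
      ids <- library$shrna_id[library$role == "target" & library$gene == g]
      eff <- sample(ids, min(config$n_effective, length(ids)))
      f <- config$essential_effect +
        stats::rnorm(length(eff), 0, config$effect_sd)
      fitness[eff, ] <- pmin(0, pmax(-1, f))
    }
    if (config$n_preferential > 0L) {
      nonref <- setdiff(lines, config$reference_line)
      pg <- sample(ess_genes, config$n_preferential)
      pl <- nonref[(seq_along(pg) - 1L) %% length(nonref) + 1L]
      for (i in seq_along(pg)) {
        ids <- library$shrna_id[library$role == "target" &
                                  library$gene == pg[i]]
        eff <- ids[fitness[ids, pl[i]] < 0]  # the effective shRNAs
        fitness[eff, pl[i]] <- pmax(-1, fitness[eff, pl[i]] + config$delta)
      }
      pref <- data.frame(gene = pg, line = pl, stringsAsFactors = FALSE)
    }
  })

  ess <- matrix(FALSE, nrow = length(target_genes), ncol = length(lines),
                dimnames = list(target_genes, lines))
  for (g in target_genes) {
    ids <- library$shrna_id[library$role == "target" & library$gene == g]
    ess[g, ] <- colSums(fitness[ids, , drop = FALSE] <=
                          config$essential_threshold) >= 3L
  }
  structure(list(fitness = fitness, essential = ess, preferential = pref,
                 threshold = config$essential_threshold),
            class = "screen_truth")
}

#' Simulate barcode counts for a pooled dropout screen
#'
#' For each cell line and replicate, draws a replicate-matched input sample
#' and a final sample of exactly `depth` reads. Initial clone abundances are
#' log-normal (`abundance_sigma`, shared by all samples, mimicking uneven
#' library representation); the final abundance of clone i with fitness
#' effect f is scaled by `2^(G * (1 + f))` and renormalized, so the expected
#' log2 fold change of clone i relative to a neutral clone is `G * f`.
#' Optionally, per-sample log-normal overdispersion (`replicate_sigma`, log2
#' units) perturbs abundances before each multinomial draw, modeling
#' replicate-level biological and amplification noise.
#'
#' @param library A [screen_library()].
#' @param truth A `screen_truth` from [generate_screen_truth()]; must cover
#'   every shRNA and cell line.
#' @param config A [sim_config()].
#' @param seed Optional seed override (default `config$seed + 2`), useful for
#'   Monte-Carlo replication.
#' @return A [screen_counts()] object; sample ids follow
#'   `<cellline>__<timepoint>__r<k>` and every column sums exactly to
#'   `config$depth`.
#' @export
simulate_screen_counts <- function(library, truth, config, seed = NULL) {
  stopifnot(inherits(library, "screen_library"),
            inherits(truth, "screen_truth"),
            inherits(config, "sim_config"))
  if (config$depth < 1) stop("sequencing depth must be positive", call. = FALSE)
  missing_sh <- setdiff(library$shrna_id, rownames(truth$fitness))
  if (length(missing_sh)) {
    stop("truth is missing fitness for shRNA(s): ",
         paste(utils::head(missing_sh, 5L), collapse = ", "), call. = FALSE)
  }
  missing_ln <- setdiff(config$cell_lines, colnames(truth$fitness))
  if (length(missing_ln)) {
    stop("truth is missing cell line(s): ",
         paste(missing_ln, collapse = ", "), call. = FALSE)
  }
  n <- nrow(library)
  ids <- library$shrna_id
  lines <- config$cell_lines
  reps <- config$replicates_per_line
  s_ln <- config$replicate_sigma * log(2)  # log2 sigma -> natural-log sigma

  with_seed(seed %||% (config$seed + 2L), {
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sigma)
    names(abundance) <- ids
    cols <- list()
    meta <- list()
    for (ln in lines) {
      growth <- 2^(config$generations * (1 + truth$fitness[ids, ln]))
      final_ab <- abundance * growth
      for (r in seq_len(reps)) {
        for (tp in c("input", "final")) {
          base <- if (tp == "input") abundance else final_ab
          if (s_ln > 0) base <- base * stats::rlnorm(n, 0, s_ln)
          sid <- sprintf("%s__%s__r%d", ln, tp, r)
          cols[[sid]] <- stats::rmultinom(1L, size = config$depth,
                                          prob = base / sum(base))[, 1L]
          meta[[sid]] <- data.frame(sample_id = sid, cell_line = ln,
                                    timepoint = tp, replicate = r,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- ids
    screen_counts(counts, do.call(rbind, meta), library)
  })
}
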