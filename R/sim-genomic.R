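#' Generate a genomic fixture with planted co-binding and binding shifts
#'
#' Builds TF ("tf") and partner TF peak sets, a TSS table assigning genes to
#' signatures, and per-region differential-binding statistics with known
#' ground truth. Genes are laid out on a regular grid (spacing larger than
#' twice the TSS window), each gene gets `peaks_per_gene` TF peaks inside
#' its +/- 45 kb neighbourhood, and background TF peaks sit midway between
#' gene slots, outside every window. A configurable fraction of TF peaks is
#' cobound (an identical partner peak is planted); statistics are standard
#' normal, and signature-proximal, non-cobound peaks of `signal_signature`
#' receive a positive location `shift` with probability `signal_fraction`.
#'
#' @param n_genes_per_signature Genes per signature (four signatures).
#' @param n_background_genes Genes without signature membership.
#' @param peaks_per_gene TF peaks planted in each gene's neighbourhood.
#' @param n_background_peaks TF peaks outside all TSS windows.
#' @param cobound_fraction Probability that a TF peak is cobound by the
#'   partner.
#' @param signal_signature Signature whose single-bound proximal peaks carry
#'   the shift (default `"signature3"`; `NA` for a fully null fixture).
#' @param signal_fraction Fraction of eligible peaks that receive the shift.
#' @param shift Location shift added to the statistic of signal peaks.
#' @param stat_sd Standard deviation of the null statistic.
#' @param peak_width Width of every peak in bp.
#' @param gene_spacing Distance between consecutive TSS slots (must exceed
#'   `2 * half_width + peak_width`).
#' @param half_width TSS window half-width the fixture is designed for.
#' @param seed RNG seed.
#' @return A `genomic_fixture` list: `tf_peaks` (a `peak_set` with `stat`),
#'   `partner_peaks`, `tss` (a [tss_table()]), `chrom_lengths`, and `truth`
#'   (cobound flags, the planted peak-to-gene map, shifted region ids).
#' @export
generate_genomic_fixture <- function(n_genes_per_signature = 40L,
                                     n_background_genes = 40L,
                                     peaks_per_gene = 3L,
                                     n_background_peaks = 200L,
                                     cobound_fraction = 0.5,
                                     signal_signature = "signature3",
                                     signal_fraction = 1,
                                     shift = 1,
                                     stat_sd = 1,
                                     peak_width = 400L,
                                     gene_spacing = 200000L,
                                     half_width = 50000L,
                                     seed = 1L) {
  if (cobound_fraction < 0 || cobound_fraction > 1 ||
      signal_fraction < 0 || signal_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (gene_spacing <= 2 * half_width + peak_width) {
    stop("gene_spacing must exceed 2 * half_width + peak_width", call. = FALSE)
  }
  signatures <- paste0("signature", 1:4)
  n_genes <- 4L * n_genes_per_signature + n_background_genes
  sig_of_gene <- c(rep(signatures, each = n_genes_per_signature),
                   rep(NA_character_, n_background_genes))

  chroms <- c("chr1", "chr2")
  slot <- seq_len(n_genes)
  chrom_of_slot <- chroms[(slot - 1L) %% 2L + 1L]
  slot_on_chrom <- stats::ave(slot, chrom_of_slot, FUN = seq_along)
  tss_pos <- 2L * half_width + (slot_on_chrom - 1L) * gene_spacing
  chrom_lengths <- vapply(chroms, function(ch) {
    max(tss_pos[chrom_of_slot == ch]) + 2 * half_width + gene_spacing
  }, numeric(1L))

  genes <- sprintf("tgene%04d", seq_len(n_genes))
  tss <- data.frame(gene = genes,
                    chrom = chrom_of_slot,
                    pos = tss_pos + 1L,  # 1-based on disk convention
                    strand = "+",
                    signature = sig_of_gene,
                    stringsAsFactors = FALSE)

  with_seed(seed, {
    offsets <- seq(-45000, 45000, length.out = peaks_per_gene)
    tf <- list()
    map <- list()
    for (i in seq_len(n_genes)) {
      jitter <- stats::runif(peaks_per_gene, -5000, 5000)
      centers <- tss_pos[i] + offsets + jitter
      starts <- pmax(0, round(centers - peak_width / 2))
      tf[[i]] <- data.frame(chrom = chrom_of_slot[i], start = starts,
                            end = starts + peak_width,
                            gene = genes[i], stringsAsFactors = FALSE)
    }
    bg_slot <- sample(slot, n_background_peaks, replace = TRUE)
    bg_center <- tss_pos[bg_slot] + gene_spacing / 2 +
      stats::runif(n_background_peaks, -20000, 20000)
    bg <- data.frame(chrom = chrom_of_slot[bg_slot],
                     start = round(bg_center - peak_width / 2),
                     end = round(bg_center - peak_width / 2) + peak_width,
                     gene = NA_character_, stringsAsFactors = FALSE)
    all_tf <- rbind(do.call(rbind, tf), bg)
    all_tf$region_id <- sprintf("tf_%05d", seq_len(nrow(all_tf)))

    cobound <- stats::runif(nrow(all_tf)) < cobound_fraction
    partner <- all_tf[cobound, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(partner) == 0L) {
      # a partner set must be non-empty for overlap machinery; park one peak
      # far outside every TSS window and gene slot
      partner <- data.frame(chrom = chroms[1L], start = 0,
                            end = peak_width, stringsAsFactors = FALSE)
    }
    partner$region_id <- sprintf("partner_%05d", seq_len(nrow(partner)))

    stat <- stats::rnorm(nrow(all_tf), 0, stat_sd)
    eligible <- !cobound & !is.na(all_tf$gene) &
      !is.na(signal_signature) &
      all_tf$gene %in% tss$gene[!is.na(tss$signature) &
                                  tss$signature == signal_signature]
    shifted <- eligible & stats::runif(nrow(all_tf)) < signal_fraction
    stat[shifted] <- stat[shifted] + shift
    all_tf$stat <- stat

    tf_peaks <- peak_set(all_tf[, c("chrom", "start", "end", "region_id",
                                    "stat")], chrom_lengths)
    partner_peaks <- peak_set(partner, chrom_lengths)
    structure(
      list(
        tf_peaks = tf_peaks,
        partner_peaks = partner_peaks,
        tss = tss_table(tss, one_based = TRUE),
        chrom_lengths = chrom_lengths,
        truth = list(
          cobound = stats::setNames(cobound, all_tf$region_id),
          peak_gene = stats::setNames(all_tf$gene, all_tf$region_id),
          shifted = all_tf$region_id[shifted]
        )
      ),
      class = "genomic_fixture"
    )
  })
}
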