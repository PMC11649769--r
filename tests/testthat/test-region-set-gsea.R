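# Quadratic brute-force oracles, deliberately naive.
overlap_oracle <- function(a, b, min_overlap = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

assign_oracle <- function(peaks, tss, half_width) {
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(tss))) {
      ws <- max(0, tss$pos[j] - half_width)
      we <- tss$pos[j] + half_width + 1  # half-open window end
      if (peaks$chrom[i] == tss$chrom[j] &&
          min(peaks$end[i], we) - max(peaks$start[i], ws) >= 1) {
        hits[[length(hits) + 1L]] <- data.frame(
          region_id = peaks$region_id[i], gene = tss$gene[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(region_id = character(0), gene = character(0))
}

test_that("interval overlap follows the half-open convention", {
  a <- peak_set(data.frame(chrom = "chr1", start = c(100, 300),
                           end = c(200, 400), region_id = c("a1", "a2")))
  b <- peak_set(data.frame(chrom = "chr1", start = c(150, 200),
                           end = c(250, 300), region_id = c("b1", "b2")))
  fl <- intervals_overlap(a, b)
  expect_true(fl[["a1"]])     # [100,200) vs [150,250)
  expect_false(fl[["a2"]])    # [300,400) abuts [200,300)
  # min_overlap raises the bar
  expect_false(intervals_overlap(a, b, min_overlap = 51)[["a1"]])
  expect_true(intervals_overlap(a, b, min_overlap = 50)[["a1"]])
  # different chromosome never overlaps
  b2 <- peak_set(data.frame(chrom = "chr2", start = 100, end = 200))
  expect_false(any(intervals_overlap(a, b2)))
  expect_error(intervals_overlap(a, b, min_overlap = 0), "min_overlap")
})

test_that("interval overlap matches the quadratic oracle on random fixtures", {
  for (seed in 1:3) {
    a <- random_peaks(500, seed)
    b <- random_peaks(500, seed + 100)
    expect_identical(unname(intervals_overlap(a, b)), overlap_oracle(a, b))
    expect_identical(unname(intervals_overlap(a, b, min_overlap = 1000)),
                     overlap_oracle(a, b, min_overlap = 1000))
  }
})

test_that("TSS windows assign peaks by any-overlap of the +/- window", {
  tss <- tss_table(data.frame(gene = "geneX", chrom = "chr1", pos = 100000,
                              signature = "signature1"), one_based = TRUE)
  mk <- function(s, e) peak_set(data.frame(chrom = "chr1", start = s, end = e,
                                           region_id = "p1"))
  # window covers bases [49999, 150000) in 0-based coordinates
  expect_equal(nrow(tss_window_assign(mk(149000, 149500), tss)), 1)
  expect_equal(nrow(tss_window_assign(mk(150001, 150100), tss)), 0)
  expect_equal(nrow(tss_window_assign(mk(150000, 150100), tss)), 0)
  expect_equal(nrow(tss_window_assign(mk(149999, 150100), tss)), 1)
  # half_width 0 keeps only peaks covering the TSS base (0-based 99999)
  expect_equal(nrow(tss_window_assign(mk(99999, 100000), tss, half_width = 0)),
               1)
  expect_equal(nrow(tss_window_assign(mk(100000, 100100), tss,
                                      half_width = 0)), 0)
  expect_error(tss_window_assign(mk(1, 2), tss, half_width = -1),
               "half_width")
})

test_that("TSS assignment matches the quadratic oracle and multi-assigns", {
  withr::with_seed(31, {
    tss <- tss_table(data.frame(
      gene = sprintf("g%03d", 1:40),
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      pos = sample.int(9e5, 40) + 1,
      signature = sample(c("signature1", NA), 40, replace = TRUE),
      stringsAsFactors = FALSE
    ), one_based = FALSE)
  })
  peaks <- random_peaks(300, 77)
  for (hw in c(0, 5000, 50000)) {
    got <- tss_window_assign(peaks, tss, half_width = hw)
    want <- assign_oracle(peaks, tss, hw)
    key <- function(d) sort(paste(d$region_id, d$gene))
    expect_identical(key(got), key(want))
  }
  # multi-assignment yields one row per (peak, gene) pair
  tss2 <- tss_table(data.frame(gene = c("gA", "gB"), chrom = "chr1",
                               pos = c(1000, 2000)), one_based = FALSE)
  wide <- peak_set(data.frame(chrom = "chr1", start = 500, end = 2500,
                              region_id = "big"))
  expect_equal(nrow(tss_window_assign(wide, tss2, half_width = 100)), 2)
})

test_that("signature region sets exclude cobound peaks and match planted truth", {
  fx <- generate_genomic_fixture(n_genes_per_signature = 10,
                                 n_background_genes = 5,
                                 n_background_peaks = 30,
                                 cobound_fraction = 0.4, seed = 19)
  sets <- build_signature_region_sets(fx$tf_peaks, fx$partner_peaks, fx$tss)
  truth_assign <- !is.na(fx$truth$peak_gene)
  for (sig in names(sets)) {
    genes_sig <- fx$tss$gene[!is.na(fx$tss$signature) &
                               fx$tss$signature == sig]
    want <- names(fx$truth$peak_gene)[truth_assign &
                                        fx$truth$peak_gene %in% genes_sig &
                                        !fx$truth$cobound]
    expect_setequal(sets[[sig]], want)
  }
  # exclude_cobound = FALSE keeps plain window assignment
  sets_all <- build_signature_region_sets(fx$tf_peaks, fx$partner_peaks,
                                          fx$tss, exclude_cobound = FALSE)
  for (sig in names(sets_all)) {
    genes_sig <- fx$tss$gene[!is.na(fx$tss$signature) &
                               fx$tss$signature == sig]
    want <- names(fx$truth$peak_gene)[truth_assign &
                                        fx$truth$peak_gene %in% genes_sig]
    expect_setequal(sets_all[[sig]], want)
  }
})

test_that("simple region logFC normalizes library size before the ratio", {
  m <- rbind(r1 = c(20, 20, 10, 10), r2 = c(5, 5, 5, 5),
             r3 = c(10, 10, 20, 20))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  cond <- factor(c("A", "A", "B", "B"), levels = c("A", "B"))
  # equal depths: raw-scale ratio with pseudocount
  expect_equal(unname(simple_region_logfc(m, cond)["r1"]),
               log2(20.5 / 10.5))
  expect_equal(unname(simple_region_logfc(m, cond)["r2"]), 0)
  # identical samples in both conditions -> 0
  m0 <- cbind(a = c(3, 7), b = c(3, 7))
  expect_true(all(simple_region_logfc(m0, c("A", "B")) == 0))
  # uniform depth change in one sample is normalized away (up to pseudocount)
  m2 <- m
  m2[, "b1"] <- m2[, "b1"] * 2
  expect_equal(simple_region_logfc(m2, cond), simple_region_logfc(m, cond),
               tolerance = 0.05)
  expect_error(simple_region_logfc(cbind(a = c(0, 0), b = c(1, 2)),
                                   c("A", "B")), "zero library size")
  expect_error(simple_region_logfc(m, c("A", "A", "A", "A")), "two conditions")
})

test_that("running-sum ES matches hand-computed values", {
  stats <- setNames(c(3, 2, 1, -1, -2), paste0("r", 1:5))
  rs <- gsea_running_sum(stats, c("r1", "r2"))
  expect_equal(as.numeric(rs[1:2]), c(0.6, 1.0))
  expect_equal(attr(rs, "es"), 1.0)
  expect_equal(attr(gsea_running_sum(stats, c("r4", "r5")), "es"), -1.0)
  expect_equal(attr(gsea_running_sum(stats, names(stats)), "es"), 1.0)
})

test_that("preranked ES equals the explicit running-sum oracle", {
  withr::with_seed(8, {
    for (i in 1:30) {
      n <- sample(50:200, 1)
      stats <- setNames(rnorm(n), sprintf("r%04d", seq_len(n)))
      k <- sample(2:20, 1)
      set <- sample(names(stats), k)
      for (w in c(0, 1)) {
        res <- preranked_gsea(stats, list(s = set), weight = w,
                              n_perm = 100, seed = i)
        expect_equal(res$es, attr(gsea_running_sum(stats, set, weight = w),
                                  "es"))
      }
    }
  })
})

test_that("preranked GSEA output respects sign and threshold contracts", {
  withr::with_seed(4, {
    stats <- setNames(rnorm(500), sprintf("r%03d", 1:500))
  })
  up <- names(sort(stats, decreasing = TRUE))[1:25]
  dn <- names(sort(stats))[1:25]
  res <- preranked_gsea(stats, list(up = up, dn = dn, rnd = sample(names(stats), 25)),
                        n_perm = 500, seed = 2)
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_gt(res$nes[res$set == "up"], 0)
  expect_lt(res$nes[res$set == "dn"], 0)
  expect_lt(res$fdr[res$set == "up"], 0.05)
  # determinism
  res2 <- preranked_gsea(stats, list(up = up, dn = dn), n_perm = 100, seed = 9)
  res3 <- preranked_gsea(stats, list(up = up, dn = dn), n_perm = 100, seed = 9)
  expect_identical(res2, res3)
  # input validation
  expect_error(preranked_gsea(stats, list(s = character(0))), "empty")
  expect_error(preranked_gsea(stats, list(s = c(names(stats)[1], "zzz"))),
               "outside the universe")
  expect_error(preranked_gsea(c(stats, bad = NA), list(s = "r001")), "finite")
})

test_that("null statistics keep the false-positive rate controlled", {
  withr::with_seed(14, {
    stats <- setNames(rnorm(400), sprintf("r%03d", 1:400))
    sets <- lapply(1:100, function(i) sample(names(stats), 20))
    names(sets) <- paste0("s", 1:100)
  })
  res <- preranked_gsea(stats, sets, n_perm = 200, seed = 6)
  expect_lte(mean(res$fdr < 0.05), 0.1)
})

test_that("BED round trip preserves peaks and statistics", {
  fx <- generate_genomic_fixture(n_genes_per_signature = 3,
                                 n_background_genes = 2,
                                 n_background_peaks = 5, seed = 23)
  bed <- withr::local_tempfile(fileext = ".bed")
  stsv <- withr::local_tempfile(fileext = ".tsv")
  write_peaks_bed(fx$tf_peaks, bed, stsv)
  back <- read_peaks_bed(bed, stsv, chrom_lengths = fx$chrom_lengths)
  expect_equal(back$chrom, fx$tf_peaks$chrom)
  expect_equal(back$start, fx$tf_peaks$start)
  expect_equal(back$end, fx$tf_peaks$end)
  expect_equal(back$region_id, fx$tf_peaks$region_id)
  expect_equal(back$stat, fx$tf_peaks$stat)
})

test_that("rnd set in duplicated-name regression stays valid", {
  # sets may share members across signatures (duplicate regions allowed)
  stats <- setNames(seq(5, -5, length.out = 11), paste0("r", 1:11))
  sets <- list(a = c("r1", "r2", "r3"), b = c("r2", "r3", "r4"))
  res <- preranked_gsea(stats, sets, n_perm = 100, seed = 1)
  expect_equal(nrow(res), 2)
  expect_true(all(res$es > 0))
})
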