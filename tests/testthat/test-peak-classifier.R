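test_that("p300-only partition matches a brute-force distance oracle", {
  # 10 p300 peaks, 4 of them within 1 kb of an H3K27ac peak
  k27 <- gr("c", c(10000, 50000, 90000), c(10500, 50500, 90500))
  p300 <- gr("c",
             c(9000, 10900, 50900, 91400,          # within 1 kb of a k27ac
               20000, 30000, 40000, 60000, 70000, 121000),
             c(9200, 11100, 51100, 91600,
               20200, 30200, 40200, 60200, 70200, 121200))
  part <- p300_only_peaks(p300, k27, k27ac_flank = 1000)
  # oracle: gap between spans < 1 kb means shared
  gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2) - 1)
  shared_oracle <- vapply(seq_along(p300), function(i) {
    any(vapply(seq_along(k27), function(j) {
      gap(BiocGenerics::start(p300)[i], BiocGenerics::end(p300)[i],
          BiocGenerics::start(k27)[j], BiocGenerics::end(k27)[j]) <= 1000
    }, logical(1)))
  }, logical(1))
  expect_equal(length(part$p300_only), 6L)
  expect_equal(sum(shared_oracle), length(part$p300_shared))

  # degenerate inputs
  none <- p300_only_peaks(p300, GenomicRanges::GRanges())
  expect_equal(length(none$p300_only), length(p300))
  all_shared <- p300_only_peaks(p300, p300)
  expect_equal(length(all_shared$p300_only), 0L)
})

test_that("p300 partition is exhaustive and shrinks with larger flank", {
  set.seed(21)
  for (rep_i in 1:5) {
    n <- 50
    p300 <- gr("c", s <- sample(1e6, n), s + 300)
    k27 <- gr("c", s2 <- sample(1e6, 40), s2 + 400)
    sizes_only <- vapply(c(0, 500, 1000, 2000, 5000), function(fl) {
      part <- p300_only_peaks(p300, k27, fl)
      expect_equal(length(part$p300_only) + length(part$p300_shared), n)
      length(part$p300_only)
    }, numeric(1))
    expect_true(all(diff(sizes_only) <= 0))
  }
})

test_that("feature annotation follows the midpoint and priority rules", {
  gm <- toy_gene_models(n_plus = 1, n_minus = 1)
  # '+' gene at 20000: exons [20000,20999],[23000,23999],[26000,29999]
  # '-' gene at 70000: transcription-order first intron is [74000,75999]
  peaks <- gr("chrT",
              c(19600,  # 300 bp upstream of '+' TSS (promoter)
                21400,  # intron 1 of '+' gene
                74500,  # first intron in transcription order of '-' gene
                71500,  # other intron of '-' gene
                23300,  # exon 2 of '+' gene
                29100,  # inside last exon but within 1 kb of '+' TES: exon
                500000),# desert
              c(19700, 21500, 74600, 71600, 23400, 29200, 500100))
  lab <- annotate_feature(peaks, gm)
  expect_equal(lab, c("promoter", "first intron", "first intron",
                      "other intron", "exon", "exon", "distal intergenic"))
})

test_that("midpoint in intron 3 of a 7-exon gene is 'other intron'", {
  # explicit exon/intron enumeration oracle
  ex_starts <- 1000 + 0:6 * 2000          # exons of width 1000 every 2000
  exons <- gr("cI", ex_starts, ex_starts + 999)
  genes <- gr("cI", 1000, 13999, "+", gene_id = "g7")
  exl <- methods::as(GenomicRanges::GRangesList(list(g7 = exons)), "GRangesList")
  gm <- gene_models(genes, exl)
  intron3 <- c(ex_starts[3] + 1000, ex_starts[4] - 1)  # oracle bounds
  mid <- floor(mean(intron3))
  expect_equal(annotate_feature(gr("cI", mid, mid), gm), "other intron")
  # and intron 1 for contrast
  expect_equal(annotate_feature(gr("cI", 2500, 2500), gm), "first intron")
})

test_that("feature distribution sums to one and recovers planted fractions", {
  gm <- toy_gene_models(n_plus = 10, n_minus = 10)
  # plant 30% of 2000 peak midpoints in first introns (known by grid
  # construction), the rest in deep intergenic space
  set.seed(22)
  n <- 2000; n_fi <- 600
  g <- gm$genes
  strands <- as.character(BiocGenerics::strand(g))
  fi_lo <- ifelse(strands == "+", BiocGenerics::start(g) + 1000,
                  BiocGenerics::start(g) + 4000)
  fi_hi <- fi_lo + 1999
  pick <- sample(length(g), n_fi, replace = TRUE)
  fi_pos <- round(stats::runif(n_fi, fi_lo[pick], fi_hi[pick]))
  inter_pos <- round(stats::runif(n - n_fi, 2e6, 3e6))
  peaks <- gr("chrT", c(fi_pos, inter_pos), c(fi_pos, inter_pos))
  fd <- feature_distribution(peaks, gm)
  expect_equal(sum(fd$proportion), 1, tolerance = 1e-12)
  expect_equal(fd$proportion[fd$feature == "first intron"], 0.3,
               tolerance = 0.02)
  expect_equal(fd$proportion[fd$feature == "distal intergenic"], 0.7,
               tolerance = 0.02)
  expect_warning(feature_distribution(GenomicRanges::GRanges(), gm), "empty")
})

test_that("signal matrix averages coverage per bin like a per-bp oracle", {
  sites <- gr("cS", c(50000, 120000), c(50400, 120400))
  flat <- gr("cS", 1, 2e5); flat$score <- 2
  sm <- signal_matrix(sites, flat, flank = 5000, n_bins = 20)
  expect_equal(dim(sm$values), c(2L, 20L))
  expect_true(all(abs(sm$values - 2) < 1e-12))

  # spike exactly at each site center peaks the central bin
  ctr <- BiocGenerics::start(midpoints(sites))
  spike <- gr("cS", ctr, ctr); spike$score <- 1000
  sp <- signal_matrix(sites, spike, flank = 5000, n_bins = 100)
  expect_equal(which.max(sp$profile), 51L)

  # random step function vs per-bp averaging
  set.seed(23)
  seg_start <- seq(1, 99001, by = 1000)
  segs <- gr("cB", seg_start, seg_start + 999)
  segs$score <- stats::runif(length(segs), 0, 10)
  site <- gr("cB", 40000, 40000)
  got <- signal_matrix(site, segs, flank = 5000, n_bins = 25)
  bp <- numeric(1e5)
  for (i in seq_along(segs)) {
    bp[seq(BiocGenerics::start(segs)[i], BiocGenerics::end(segs)[i])] <-
      segs$score[i]
  }
  win <- bp[(40000 - 5000):(40000 + 5000 - 1)]
  oracle <- colMeans(matrix(win, nrow = 400))
  expect_equal(as.numeric(got$values), oracle, tolerance = 1e-9)
})

test_that("signal matrix truncates windows at chromosome ends", {
  sizes <- c(cE = 6000)
  cov <- gr("cE", 1, 6000); cov$score <- 3
  sm <- signal_matrix(gr("cE", 4000, 4001), cov, flank = 5000, n_bins = 10,
                      chrom_sizes = sizes)
  # window [-1000, 8999): first bin precedes the chromosome, bin 8 keeps
  # only its single available bp, bins 9-10 are fully past the end
  expect_true(all(abs(sm$values[1, 2:8] - 3) < 1e-12))
  expect_equal(sm$values[1, c(1, 9, 10)], c(0, 0, 0))
})
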