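test_that("read_bed preserves BED coordinates and strand, rejects bad lines", {
  p <- write_lines_tmp(c("chr1\t100\t200",
                         "chr1\t500\t900"))
  x <- read_bed(p)
  expect_equal(BiocGenerics::start(x), c(101, 501))
  expect_equal(BiocGenerics::end(x), c(200, 900))

  p6 <- write_lines_tmp("chr1\t100\t200\tpk1\t0\t-")
  x6 <- read_bed(p6)
  expect_equal(as.character(BiocGenerics::strand(x6)), "-")
  expect_equal(x6$name, "pk1")

  expect_error(read_bed(write_lines_tmp("chr1\t200\t100")), "line 1")
  expect_error(read_bed(write_lines_tmp(c("chr1\t1\t2", "chr1\t5"))), "line 2")
  expect_error(read_bed(write_lines_tmp("chr1\tx\t100")), "line 1")
})

test_that("read_bed/write_bed round trip is byte-identical", {
  bed6 <- c("chr1\t100\t200\ta\t1\t+",
            "chr2\t0\t5000\tb\t2.5\t-",
            "chr2\t7000\t7100\tc\t0\t.")
  p <- write_lines_tmp(bed6)
  out <- tempfile()
  write_bed(read_bed(p), out)
  expect_identical(readLines(out), bed6)

  bed3 <- c("chr1\t100\t200", "chr1\t100000000\t100000050")
  p3 <- write_lines_tmp(bed3)
  write_bed(read_bed(p3), out)
  expect_identical(readLines(out), bed3)
})

test_that("read_gtf_genes converts coordinates and derives strand-aware TSS/TES", {
  gtf <- c(
    'chrG\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id "gp"; gene_name "GP";',
    'chrG\tsrc\texon\t1\t40\t.\t+\t.\tgene_id "gp";',
    'chrG\tsrc\texon\t60\t100\t.\t+\t.\tgene_id "gp";',
    'chrG\tsrc\tgene\t201\t300\t.\t-\t.\tgene_id "gm";',
    'chrG\tsrc\texon\t201\t300\t.\t-\t.\tgene_id "gm";')
  gm <- read_gtf_genes(write_lines_tmp(gtf))
  gp <- gm$genes["gp"]
  expect_equal(BiocGenerics::start(gp), 1)
  expect_equal(BiocGenerics::end(gp), 100)
  expect_equal(gp$tss, 1)   # 0-based 0
  expect_equal(gp$tes, 100) # 0-based 99
  gmi <- gm$genes["gm"]
  expect_equal(gmi$tss, 300)
  expect_equal(gmi$tes, 201)
})

test_that("genes with only exon records are synthesized from the exon envelope", {
  gtf <- c(
    'chrG\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "ge";',
    'chrG\tsrc\texon\t901\t1000\t.\t+\t.\tgene_id "ge";')
  gm <- read_gtf_genes(write_lines_tmp(gtf))
  # oracle: min/max over the exon records
  expect_equal(BiocGenerics::start(gm$genes["ge"]), 501)
  expect_equal(BiocGenerics::end(gm$genes["ge"]), 1000)
  expect_equal(length(gm$exons[["ge"]]), 2L)
})

test_that("read_gtf_genes rejects records without gene_id or strand", {
  bad_strand <- 'chrG\tsrc\tgene\t1\t100\t.\t.\t.\tgene_id "gs";'
  expect_error(read_gtf_genes(write_lines_tmp(bad_strand)), "strand")
  no_id <- "chrG\tsrc\tgene\t1\t100\t.\t+\t.\tfoo \"bar\";"
  expect_error(read_gtf_genes(write_lines_tmp(no_id)), "gene_id")
})

test_that("GTF -> promoter/terminator windows agree with hand computation", {
  gtf <- c(
    'chrG\tsrc\tgene\t10001\t20000\t.\t+\t.\tgene_id "gp";',
    'chrG\tsrc\tgene\t50001\t60000\t.\t-\t.\tgene_id "gm";')
  gm <- read_gtf_genes(write_lines_tmp(gtf))
  prom <- promoter_windows(gm, 1000)
  expect_equal(BiocGenerics::start(prom["gp"]), 9001)
  expect_equal(BiocGenerics::end(prom["gp"]), 11001)
  expect_equal(BiocGenerics::start(prom["gm"]), 59000)
  expect_equal(BiocGenerics::end(prom["gm"]), 61000)
  term <- terminator_windows(gm, 5000)
  expect_equal(BiocGenerics::start(term["gp"]), 15000)
  expect_equal(BiocGenerics::end(term["gp"]), 25000)
  expect_equal(BiocGenerics::start(term["gm"]), 45001)
  expect_equal(BiocGenerics::end(term["gm"]), 55001)
})

test_that("read_bedpe canonicalizes anchors and flags trans records", {
  p <- write_lines_tmp(c(
    "chr1\t10000\t15000\tchr1\t90000\t95000",
    "chr1\t90000\t95000\tchr1\t10000\t15000",
    "chr2\t100\t200\tchr1\t300\t400"))
  lp <- read_bedpe(p)
  expect_equal(lp$start1[1], 10000)
  expect_equal(lp$start1[2], 10000)  # reversed input swapped
  expect_equal(lp$chrom1[3], "chr1") # trans record canonical by chrom
  expect_equal(lp$trans, c(FALSE, FALSE, TRUE))
  expect_error(read_bedpe(write_lines_tmp("chr1\t1\t2\tchr1\t3")), "line 1")
})

test_that("extend_intervals clamps to chromosome bounds and preserves order", {
  sizes <- c(chr1 = 1e6)
  x <- gr("chr1", c(5001, 301), c(5200, 400))
  ext <- extend_intervals(x, 1000, sizes)
  # +/-1kb extension of chr1:5000-5200 (BED) is chr1:4000-6200
  expect_equal(BiocGenerics::start(ext), c(4001, 1))
  expect_equal(BiocGenerics::end(ext), c(6200, 1400))
  expect_identical(extend_intervals(x, 0, sizes), x)
  small <- c(chr1 = 10000)
  expect_equal(BiocGenerics::end(extend_intervals(gr("chr1", 9500, 9900),
                                                  1000, small)), 10000)
  expect_error(extend_intervals(gr("chrX", 1, 10), 10, sizes), "chrX")
})

test_that("interval overlap equals the per-bp intersection oracle", {
  expect_false(interval_overlaps(gr("c", 1, 10), gr("c", 11, 20)))
  expect_true(interval_overlaps(gr("c", 1, 10), gr("c", 10, 20)))
  expect_false(interval_overlaps(gr("c1", 1, 10), gr("c2", 1, 10)))
  set.seed(11)
  n <- 1000
  s1 <- sample(200, n, TRUE); e1 <- s1 + sample(0:30, n, TRUE)
  s2 <- sample(200, n, TRUE); e2 <- s2 + sample(0:30, n, TRUE)
  chr1 <- sample(c("a", "b"), n, TRUE); chr2 <- sample(c("a", "b"), n, TRUE)
  got <- interval_overlaps(gr(chr1, s1, e1), gr(chr2, s2, e2))
  oracle <- vapply(seq_len(n), function(i) {
    chr1[i] == chr2[i] &&
      length(intersect(seq(s1[i], e1[i]), seq(s2[i], e2[i]))) > 0
  }, logical(1))
  expect_identical(got, oracle)
})

test_that("any_overlap equals the quadratic all-pairs oracle", {
  q <- gr("c", c(1, 5), c(2, 9))
  expect_identical(any_overlap(q, GenomicRanges::GRanges()), c(FALSE, FALSE))
  expect_identical(any_overlap(q, q), c(TRUE, TRUE))
  set.seed(12)
  n <- 200
  qs <- sample(5000, n, TRUE); qe <- qs + sample(0:200, n, TRUE)
  ss <- sample(5000, n, TRUE); se <- ss + sample(0:200, n, TRUE)
  qc <- sample(c("a", "b"), n, TRUE); sc <- sample(c("a", "b"), n, TRUE)
  got <- any_overlap(gr(qc, qs, qe), gr(sc, ss, se))
  oracle <- vapply(seq_len(n), function(i) {
    any(qc[i] == sc & qs[i] <= se & ss <= qe[i])
  }, logical(1))
  expect_identical(got, oracle)
})
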