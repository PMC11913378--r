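test_that("TAD boundary windows are centered on the domain edges", {
  tads <- read_bed(write_lines_tmp("chr1\t100000\t500000"))
  bw <- tad_boundary_windows(tads, flank = 5000)
  # BED terms: left 95000-105000, right 495000-505000
  expect_equal(BiocGenerics::start(bw$left) - 1, 95000)
  expect_equal(BiocGenerics::end(bw$left), 105000)
  expect_equal(BiocGenerics::start(bw$right) - 1, 495000)
  expect_equal(BiocGenerics::end(bw$right), 505000)
  expect_equal(BiocGenerics::width(bw$left), 10000)

  expect_error(tad_boundary_windows(tads, flank = 0))
  short <- gr("chr1", 1000, 9000)
  expect_warning(out <- tad_boundary_windows(c(tads, short), 5000), "skipped")
  expect_equal(out$kept, 1L)
})

test_that("merge_loops collapses near-duplicates and matches a union-find oracle", {
  one <- data.frame(chrom1 = "c", start1 = 10000, end1 = 15000,
                    chrom2 = "c", start2 = 90000, end2 = 95000,
                    name = "l", score = NA_real_, trans = FALSE)
  four_phases <- lapply(1:4, function(i) {
    x <- one; x$start1 <- x$start1 + i * 100; x$end1 <- x$end1 + i * 100; x
  })
  m <- merge_loops(four_phases, tolerance = 1000)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_merged, 4L)

  far <- one; far$start1 <- far$start1 + 30000; far$end1 <- far$end1 + 30000
  expect_equal(nrow(merge_loops(list(one, far), tolerance = 1000)), 2L)

  set.seed(31)
  n <- 200
  c1 <- sample(2e5, n); c2 <- c1 + 1e5 + sample(5e4, n)
  df <- data.frame(chrom1 = "c", start1 = c1 - 2500, end1 = c1 + 2500,
                   chrom2 = "c", start2 = c2 - 2500, end2 = c2 + 2500,
                   name = sprintf("l%03d", 1:n), score = NA_real_,
                   trans = FALSE)
  tol <- 4000
  got <- merge_loops(df, tol)
  # oracle: BFS connected components of the tolerance graph
  adj <- abs(outer(c1, c1, "-")) <= tol & abs(outer(c2, c2, "-")) <= tol
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  expect_equal(nrow(got), length(unique(comp)))
  expect_equal(sort(got$n_merged), sort(as.integer(table(comp))))
  # idempotence
  again <- merge_loops(got[names(df)], tol)
  expect_equal(again[names(df)], got[names(df)])
})

test_that("anchor labels follow the overlap and exclusion rules", {
  gm <- toy_gene_models(n_plus = 1, n_minus = 0)  # '+' gene at 20000-29999
  p300 <- gr("chrT", 21500, 21700)                # inside intron 1
  k27me3 <- gr("chrT", 150000, 155000)            # desert block
  anchors <- gr("chrT",
                c(19500, 21400, 300000, 151000, 25000),
                c(20500, 21800, 301000, 152000, 25500))
  lab <- annotate_anchor(anchors, gm, p300, k27me3)
  # over the TSS: promoter + gene body + exclusion label 'gene'
  expect_true(lab$promoter[1] && lab$gene_body[1] && lab$gene[1])
  # over the p300-only peak inside the gene: no 'gene' label
  expect_true(lab$p300_only[2] && lab$gene_body[2])
  expect_false(lab$gene[2])
  # open desert
  expect_true(lab$intergenic[3])
  expect_false(any(unlist(lab[3, c("promoter", "terminator", "gene_body",
                                   "gene", "p300_only", "H3K27me3")])))
  # over the H3K27me3 block: not intergenic by exclusion
  expect_true(lab$H3K27me3[4])
  expect_false(lab$intergenic[4])
  # plain gene body
  expect_true(lab$gene[5] && lab$gene_body[5])
})

test_that("interaction classification is symmetric and precedence-ordered", {
  mk <- function(...) {
    base <- data.frame(p300_only = FALSE, H3K27me3 = FALSE, promoter = FALSE,
                       terminator = FALSE, gene_body = FALSE, gene = FALSE,
                       intergenic = FALSE)
    base[names(list(...))] <- unlist(list(...))
    base
  }
  expect_equal(classify_interaction(mk(p300_only = TRUE), mk(H3K27me3 = TRUE)),
               "p300only-H3K27me3")
  expect_equal(classify_interaction(mk(H3K27me3 = TRUE), mk(p300_only = TRUE)),
               "p300only-H3K27me3")
  expect_equal(
    classify_interaction(mk(promoter = TRUE, gene_body = TRUE),
                         mk(terminator = TRUE, gene_body = TRUE),
                         interaction_precedence("genes")),
    "PT")
  # the repressive class wins even when both anchors also carry gene labels
  expect_equal(
    classify_interaction(mk(p300_only = TRUE, gene_body = TRUE),
                         mk(H3K27me3 = TRUE, gene_body = TRUE)),
    "p300only-H3K27me3")
  expect_equal(classify_interaction(mk(), mk()), "other")

  set.seed(32)
  cols <- c("p300_only", "H3K27me3", "promoter", "terminator", "gene_body",
            "gene", "intergenic")
  rnd <- function(n) {
    as.data.frame(matrix(sample(c(TRUE, FALSE), n * length(cols), TRUE),
                         ncol = length(cols), dimnames = list(NULL, cols)))
  }
  a <- rnd(300); b <- rnd(300)
  for (mode in c("chromatin", "genes")) {
    prec <- interaction_precedence(mode)
    expect_identical(classify_interaction(a, b, prec),
                     classify_interaction(b, a, prec))
  }
})

test_that("category counts are exhaustive, normalized and order-invariant", {
  cats <- c(rep("p300only-H3K27me3", 8), rep("gene-gene", 52),
            rep("intergenic-intergenic", 40))
  tab <- count_interaction_categories(cats)
  expect_equal(sum(tab$n), 100L)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$fraction[tab$category == "p300only-H3K27me3"], 0.08)
  set.seed(33)
  tab2 <- count_interaction_categories(sample(cats))
  expect_equal(tab2, tab)
  one <- count_interaction_categories("PT")
  expect_equal(one$fraction, 1)
})
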