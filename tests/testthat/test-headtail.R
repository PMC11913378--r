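test_that("a head-to-tail toy pair is found and the strand rule enforced", {
  tads <- read_bed(write_lines_tmp("chr1\t100000\t500000"))
  mk_gm <- function(strand_b) {
    genes <- gr("chr1", c(50000, 497000), c(98000, 540000),
                c("+", strand_b), gene_id = c("upA", "dnB"))
    gene_models(genes)
  }
  pairs <- detect_head_to_tail(tads, mk_gm("+"))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$upstream_gene, "upA")
  expect_equal(pairs$downstream_gene, "dnB")
  expect_equal(pairs$boundary_side_up, "left")
  expect_equal(pairs$upstream_element, "terminator")
  # same geometry with the downstream gene flipped: no pair
  expect_equal(nrow(detect_head_to_tail(tads, mk_gm("-"))), 0L)
})

test_that("detection equals the brute-force oracle on a synthetic genome", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_genome(cfg)
  pairs <- detect_head_to_tail(sim$tads, sim$gm,
                               chrom_sizes = sim$chrom_sizes)
  got <- sort(paste(pairs$tad, pairs$upstream_gene, pairs$downstream_gene,
                    pairs$boundary_side_up))
  expect_equal(got, headtail_oracle(sim$tads, sim$gm))
  # exactly the planted pairs, nothing else
  expect_setequal(paste(pairs$upstream_gene, pairs$downstream_gene),
                  paste(sim$truth$pairs$upstream_gene,
                        sim$truth$pairs$downstream_gene))
})

test_that("mirroring the genome yields the mirror-image pair set", {
  L <- 4e6
  cfg <- small_sim_config(seed = 13)
  sim <- simulate_genome(cfg)
  pairs <- detect_head_to_tail(sim$tads, sim$gm)
  mirror_gr <- function(x) {
    s <- BiocGenerics::start(x); e <- BiocGenerics::end(x)
    GenomicRanges::ranges(x) <- IRanges::IRanges(L - e + 1, L - s + 1)
    str <- as.character(BiocGenerics::strand(x))
    flip <- c("+" = "-", "-" = "+", "*" = "*")
    BiocGenerics::strand(x) <- unname(flip[str])
    x
  }
  g2 <- mirror_gr(sim$gm$genes)
  gm2 <- gene_models(GenomicRanges::granges(g2, use.mcols = TRUE))
  pairs2 <- detect_head_to_tail(mirror_gr(sim$tads), gm2)
  expect_equal(nrow(pairs2), nrow(pairs))
  expect_setequal(paste(pairs2$upstream_gene, pairs2$downstream_gene),
                  paste(pairs$upstream_gene, pairs$downstream_gene))
  # boundary sides swap under the mirror
  key <- function(p) p[order(p$upstream_gene), ]
  expect_equal(key(pairs2)$boundary_side_up,
               ifelse(key(pairs)$boundary_side_up == "left", "right", "left"))
})

test_that("detection is invariant to gene input order", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_genome(cfg)
  pairs <- detect_head_to_tail(sim$tads, sim$gm)
  set.seed(1)
  perm <- sample(length(sim$gm$genes))
  gm_perm <- gene_models(sim$gm$genes[perm], sim$gm$exons[perm])
  pairs_perm <- detect_head_to_tail(sim$tads, gm_perm)
  expect_equal(pairs_perm, pairs)
})

test_that("oncogene pair summary reports counts and fractions per role", {
  pairs <- data.frame(
    upstream_gene = sprintf("u%02d", 1:10),
    downstream_gene = sprintf("d%02d", 1:10))
  onc <- c("u01", "u02", "x99")
  tsg <- c("d05")
  tab <- oncogene_pair_summary(pairs, onc, tsg)
  up_onc <- tab[tab$role == "upstream_3prime" & tab$class == "oncogene", ]
  expect_equal(up_onc$n_pairs, 2L)
  expect_equal(up_onc$fraction_of_pairs, 0.2)
  expect_equal(up_onc$fraction_of_list, 2 / 3)
  dn_tsg <- tab[tab$role == "downstream_promoter" & tab$class == "tsg", ]
  expect_equal(dn_tsg$n_pairs, 1L)
  # disjoint lists: all zero
  tab0 <- oncogene_pair_summary(pairs, c("zz1"), c("zz2"))
  expect_true(all(tab0$n_pairs[tab0$class != "neither"] == 0))
  expect_equal(nrow(oncogene_pair_summary(pairs[0, ], onc, tsg)), 0L)
})

test_that("promoter mutation counting deduplicates samples and respects the window", {
  gm <- toy_gene_models(n_plus = 2, n_minus = 0)  # genes at 20000, 70000
  pairs <- data.frame(upstream_gene = "tg01", downstream_gene = "tg02")
  # '+' gene tg02 at 70000: promoter window covers 69000-71000
  muts <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s3"),
    chrom = "chrT",
    pos = c(70010, 70020, 70030,  # s1: three hits in one promoter
            68999,                # s2: 1 bp outside the +/-1 kb window
            71000))               # s3: on the boundary, inside
  res <- promoter_mutation_summary(muts, pairs, gm)
  expect_equal(res$per_gene$n_samples[res$per_gene$gene_id == "tg02"], 2L)
  expect_equal(res$fraction, 2 / 3)
  expect_true(res$incidence["tg02", "s1"])
  expect_false(res$incidence["tg02", "s2"])
})

test_that("uniform mutations hit promoters at the binomial rate", {
  gm <- toy_gene_models(n_plus = 6, n_minus = 6, spacing = 80000)
  pairs <- data.frame(upstream_gene = rep("none", 12),
                      downstream_gene = gm$genes$gene_id)
  L <- 1e6
  n_samples <- 400
  set.seed(19)
  muts <- data.frame(sample_id = sprintf("s%03d", seq_len(n_samples)),
                     chrom = "chrT", pos = sample.int(L, n_samples, TRUE))
  res <- promoter_mutation_summary(muts, pairs, gm)
  p <- 12 * 2001 / L  # total promoter bp over genome length
  se <- sqrt(p * (1 - p) / n_samples)
  expect_lt(abs(res$fraction - p), 1.96 * se + 1e-9)
})
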