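#' Simulation configuration
#'
#' All synthetic-data generators are pure functions of this configuration:
#' the same config yields byte-identical outputs. Defaults describe a
#' compact two-chromosome genome whose planted structure mirrors the real
#' inputs the pipeline targets (ChIP-seq peak sets with controlled
#' co-occurrence, TAD tilings carrying head-to-tail gene pairs,
#' distance-decay contact matrices with planted loop pixels, log-normal
#' expression with an H3K27me3 repression shift, and qPCR Ct tables with
#' planted fold changes).
#'
#' @param seed Integer seed; every generator derives its RNG state from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 10 Mb).
#' @param bin_size Contact-matrix bin size in bp (default 25000).
#' @param n_tads Number of TADs tiled across the genome (default 300).
#' @param tad_width_range,tad_gap_range TAD geometry in bp.
#' @param planted_pairs Number of TADs carrying a head-to-tail boundary
#'   gene pair (default 12).
#' @param n_filler_genes Genes placed inside TAD interiors, away from
#'   boundary windows (default 200).
#' @param planted_gene_width,filler_gene_width Gene length ranges in bp.
#' @param boundary_flank,promoter_flank,terminator_flank Window half-widths
#'   in bp matching the analysis defaults.
#' @param n_p300,n_k27ac Peak counts; `frac_p300_shared` is the fraction of
#'   p300 peaks placed within 1 kb of an H3K27ac peak (the rest are placed
#'   at least 2 kb away and form the true p300-only set).
#' @param peak_width Peak width range in bp.
#' @param n_h3k27me3_genes Genes covered by an H3K27me3 block.
#' @param n_boundary_class_tads TADs whose boundary pair is planted as the
#'   repressive p300only-H3K27me3 class.
#' @param n_pg_tads,n_pp_tads TADs planted as promoter-genebody and
#'   promoter-promoter boundary pairs (gene-label universe), populating the
#'   boundary-type expression comparison.
#' @param n_loops Loops generated by [simulate_loops()];
#'   `loop_class_props` gives the planted interaction-class proportions
#'   (chromatin-mode labels; must sum to 1). The repressive class default
#'   is 8.33%.
#' @param anchor_width Loop anchor width in bp.
#' @param loop_span_range Anchor center distance range in bp.
#' @param alpha,base_count Contact distance-decay `lambda(d) = base_count *
#'   (d+1)^-alpha` (d in bins).
#' @param tad_factor Multiplier on intra-TAD pixels.
#' @param loop_enrichment Multiplier on planted loop pixels (default 5).
#' @param n_apa_loops,apa_distance_bins Planted APA pixel count and anchor
#'   distance range in bins.
#' @param expr_mu,expr_sigma log2(TPM+1) normal parameters;
#'   `k27me3_shift` is subtracted from marked genes (log2 units).
#' @param fold_map Named vector of planted qPCR fold changes;
#'   `ct_sigma` Gaussian Ct noise, `n_replicates` replicates,
#'   `reference_gene`/`control_sample`/`treated_sample` labels, `ref_ct`
#'   baseline Ct of the reference gene.
#' @param n_mut_samples,promoter_mut_rate,background_muts_per_sample Mutation
#'   table shape: per-sample probability of one planted promoter mutation in
#'   a target gene, plus uniform background mutations.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 10e6, bin_size = 25000,
                       n_tads = 300,
                       tad_width_range = c(35e3, 50e3),
                       tad_gap_range = c(16e3, 20e3),
                       planted_pairs = 12,
                       n_filler_genes = 200,
                       planted_gene_width = c(5000, 6500),
                       filler_gene_width = c(5e3, 10e3),
                       boundary_flank = 5000, promoter_flank = 1000,
                       terminator_flank = 5000,
                       n_p300 = 200, frac_p300_shared = 0.4, n_k27ac = 250,
                       peak_width = c(400, 1500),
                       n_h3k27me3_genes = 60,
                       n_boundary_class_tads = 5,
                       n_pg_tads = 8, n_pp_tads = 8,
                       n_loops = 400,
                       loop_class_props = c(
                         "p300only-H3K27me3" = 0.0833,
                         "H3K27me3-H3K27me3" = 0.06,
                         "p300only-p300only" = 0.06,
                         "p300only-gene" = 0.10,
                         "gene-gene" = 0.28,
                         "gene-intergenic" = 0.18,
                         "intergenic-intergenic" = 0.2367),
                       anchor_width = 8000,
                       loop_span_range = c(100e3, 3e6),
                       alpha = 1, base_count = 1000, tad_factor = 1.6,
                       loop_enrichment = 5,
                       n_apa_loops = 50, apa_distance_bins = c(100, 300),
                       expr_mu = 3, expr_sigma = 1.2, k27me3_shift = 1,
                       fold_map = c(Tfrc = 4, Slc4a1 = 0.5, Epb42 = 1),
                       ct_sigma = 0.05, n_replicates = 3,
                       reference_gene = "Actb", control_sample = "control",
                       treated_sample = "treated", ref_ct = 20,
                       n_mut_samples = 1000, promoter_mut_rate = 0.01,
                       background_muts_per_sample = 1) {
  stopifnot(seed == floor(seed), n_chroms >= 1, chrom_length > 0,
            planted_pairs >= 0, n_filler_genes >= 0,
            frac_p300_shared >= 0, frac_p300_shared <= 1,
            alpha > 0, loop_enrichment >= 1, ct_sigma >= 0,
            all(loop_class_props >= 0),
            abs(sum(loop_class_props) - 1) < 1e-8,
            all(fold_map > 0))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "-", x$n_chroms, "x",
      format_coord(x$chrom_length), "bp,", x$n_tads, "TADs,",
      x$planted_pairs, "planted head-to-tail pairs\n")
  invisible(x)
}

# all generator seeds derive from the config seed with fixed offsets,
# kept below 2^31
sim_seed <- function(config, offset) {
  as.integer((abs(config$seed) + offset * 97L) %% .Machine$integer.max)
}

#' Simulate genome: chromosomes, TAD tiling, gene models
#'
#' Tiles each chromosome with non-overlapping TADs, plants head-to-tail
#' boundary gene pairs in `planted_pairs` TADs (TES and TSS placed inside
#' opposite boundary windows with 0-4 kb jitter, on a common random
#' strand), and fills TAD interiors with multi-exon genes on both strands
#' kept clear of the boundary windows.
#'
#' @param config A [sim_config()].
#' @return List: `chrom_sizes`, `gm` ([gene_models]), `tads` (`GRanges`),
#'   and `truth` (planted pair table, planted/boundary-class TAD indices).
#' @export
simulate_genome <- function(config) {
  set.seed(sim_seed(config, 1L))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                           paste0("chr", seq_len(config$n_chroms)))
  per_chrom <- diff(round(seq(0, config$n_tads, length.out = config$n_chroms + 1)))
  tad_chrom <- character(0); tad_start <- numeric(0); tad_end <- numeric(0)
  for (ci in seq_len(config$n_chroms)) {
    pos <- 30001
    for (t in seq_len(per_chrom[ci])) {
      w <- round(stats::runif(1, config$tad_width_range[1], config$tad_width_range[2]))
      if (pos + w > config$chrom_length - 30000) {
        stop("infeasible TAD packing: reduce n_tads or enlarge chrom_length")
      }
      tad_chrom <- c(tad_chrom, names(sizes)[ci])
      tad_start <- c(tad_start, pos)
      tad_end <- c(tad_end, pos + w - 1)
      pos <- pos + w +
        round(stats::runif(1, config$tad_gap_range[1], config$tad_gap_range[2]))
    }
  }
  tads <- GenomicRanges::GRanges(tad_chrom, IRanges::IRanges(tad_start, tad_end))
  n_tads <- length(tads)
  # planted and boundary-class TADs: pairwise non-adjacent so planted gene
  # bodies and boundary marks cannot collide across neighbouring TADs
  n_special <- config$planted_pairs + config$n_boundary_class_tads +
    config$n_pg_tads + config$n_pp_tads
  if (n_special > 0) {
    if (n_special * 2 + 2 > n_tads) stop("too many planted TADs for n_tads")
    repeat {
      special <- sort(sample(2:(n_tads - 1), n_special))
      if (n_special < 2 || min(diff(special)) >= 2) break
    }
    pick <- sample(n_special)
    take <- function(n, used) special[pick[seq_len(n) + used]]
    planted_tads <- sort(take(config$planted_pairs, 0L))
    boundary_tads <- sort(take(config$n_boundary_class_tads,
                               config$planted_pairs))
    pg_tads <- sort(take(config$n_pg_tads,
                         config$planted_pairs + config$n_boundary_class_tads))
    pp_tads <- sort(take(config$n_pp_tads,
                         config$planted_pairs + config$n_boundary_class_tads +
                           config$n_pg_tads))
  } else {
    planted_tads <- boundary_tads <- pg_tads <- pp_tads <- integer(0)
  }
  g_chrom <- character(0); g_start <- numeric(0); g_end <- numeric(0)
  g_strand <- character(0); g_id <- character(0)
  pairs <- list()
  glen <- function(r) round(stats::runif(1, r[1], r[2]))
  for (k in seq_along(planted_tads)) {
    t <- planted_tads[k]
    s1 <- tad_start[t]; e1 <- tad_end[t]
    chrom <- tad_chrom[t]
    strand <- sample(c("+", "-"), 1)
    jit <- function() sample(-4000:4000, 1)
    lenU <- glen(config$planted_gene_width)
    lenD <- glen(config$planted_gene_width)
    if (strand == "+") {
      tesU <- s1 + jit(); gU <- c(tesU - lenU + 1, tesU)
      tssD <- e1 + jit(); gD <- c(tssD, tssD + lenD - 1)
      side_up <- "left"; side_down <- "right"
    } else {
      tesU <- e1 + jit(); gU <- c(tesU, tesU + lenU - 1)
      tssD <- s1 + jit(); gD <- c(tssD - lenD + 1, tssD)
      side_up <- "right"; side_down <- "left"
    }
    idU <- sprintf("HT%02dU", k); idD <- sprintf("HT%02dD", k)
    g_chrom <- c(g_chrom, chrom, chrom)
    g_start <- c(g_start, gU[1], gD[1])
    g_end <- c(g_end, gU[2], gD[2])
    g_strand <- c(g_strand, strand, strand)
    g_id <- c(g_id, idU, idD)
    pairs[[k]] <- data.frame(tad = t, upstream_gene = idU,
                             downstream_gene = idD, strand = strand,
                             boundary_side_up = side_up,
                             boundary_side_down = side_down,
                             stringsAsFactors = FALSE)
  }
  # promoter-genebody boundary TADs: a '+' gene with its TSS in the left
  # window, and a '-' gene whose body crosses the right window with TSS and
  # TES both kept clear of it; opposite strands rule out spurious
  # head-to-tail pairs
  for (k in seq_along(pg_tads)) {
    t <- pg_tads[k]
    s1 <- tad_start[t]; e1 <- tad_end[t]; chrom <- tad_chrom[t]
    tssP <- s1 + sample(-4000:4000, 1)
    lenP <- glen(config$filler_gene_width)
    g_chrom <- c(g_chrom, chrom, chrom)
    g_start <- c(g_start, tssP, e1 - 18000)
    g_end <- c(g_end, tssP + lenP - 1, e1 + 8000)
    g_strand <- c(g_strand, "+", "-")
    g_id <- c(g_id, sprintf("PG%02dP", k), sprintf("PG%02dB", k))
  }
  # promoter-promoter boundary TADs: opposite-strand genes pointing into
  # the TAD, one TSS in each boundary window
  for (k in seq_along(pp_tads)) {
    t <- pp_tads[k]
    s1 <- tad_start[t]; e1 <- tad_end[t]; chrom <- tad_chrom[t]
    tssL <- s1 + sample(-4000:4000, 1)
    tssR <- e1 + sample(-4000:4000, 1)
    lenL <- glen(config$filler_gene_width)
    lenR <- glen(config$filler_gene_width)
    g_chrom <- c(g_chrom, chrom, chrom)
    g_start <- c(g_start, tssL, tssR - lenR + 1)
    g_end <- c(g_end, tssL + lenL - 1, tssR)
    g_strand <- c(g_strand, "+", "-")
    g_id <- c(g_id, sprintf("PP%02dL", k), sprintf("PP%02dR", k))
  }
  if (config$n_filler_genes > 0) {
    eligible <- setdiff(seq_len(n_tads), c(pg_tads, pp_tads))
    host <- sample(eligible, min(config$n_filler_genes, length(eligible)))
    for (k in seq_along(host)) {
      t <- host[k]
      len <- glen(config$filler_gene_width)
      lo <- tad_start[t] + 11000
      hi <- tad_end[t] - 11000 - len
      if (hi <= lo) next
      s <- round(stats::runif(1, lo, hi))
      g_chrom <- c(g_chrom, tad_chrom[t])
      g_start <- c(g_start, s)
      g_end <- c(g_end, s + len - 1)
      g_strand <- c(g_strand, sample(c("+", "-"), 1))
      g_id <- c(g_id, sprintf("gene%04d", k))
    }
  }
  if (length(g_id)) {
    genes <- GenomicRanges::GRanges(g_chrom, IRanges::IRanges(g_start, g_end),
                                    strand = g_strand, gene_id = g_id)
    exons <- methods::as(GenomicRanges::GRangesList(lapply(seq_along(genes), function(i) {
      make_exon_set(g_chrom[i], g_start[i], g_end[i],
                    sample(2:5, 1))
    })), "GRangesList")
    names(exons) <- g_id
    gm <- gene_models(genes, exons)
  } else {
    gm <- gene_models(GenomicRanges::GRanges(gene_id = character()))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(tad = integer(), upstream_gene = character(),
               downstream_gene = character(), strand = character(),
               boundary_side_up = character(), boundary_side_down = character())
  list(chrom_sizes = sizes, gm = gm, tads = tads,
       truth = list(pairs = pairs, planted_tads = planted_tads,
                    boundary_class_tads = boundary_tads,
                    pg_tads = pg_tads, pp_tads = pp_tads))
}

# multi-exon structure: alternate exon/intron blocks cut on a 200 bp grid,
# span endpoints always exonic
make_exon_set <- function(chrom, start, end, n_exons) {
  len <- end - start + 1
  n_blocks <- 2L * n_exons - 1L
  grid <- seq(start + 400, end - 400, by = 200)
  if (length(grid) < n_blocks - 1L) {
    return(GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end)))
  }
  cuts <- sort(sample(grid, n_blocks - 1L))
  bounds <- c(start, cuts, end + 1)
  s <- bounds[seq_len(n_blocks)]
  e <- bounds[-1L] - 1
  keep <- seq(1L, n_blocks, by = 2L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s[keep], e[keep]))
}

#' Simulate ChIP-seq peak sets with controlled co-occurrence
#'
#' H3K27ac peaks are placed first; the configured fraction of p300 peaks
#' is planted within 1 kb of an H3K27ac peak (true shared set) and the
#' remainder at least 2 kb away from every H3K27ac peak (true p300-only
#' set). H3K27me3 blocks cover a random gene subset (span +/- 500 bp). For
#' each boundary-class TAD, one extra p300-only peak is planted in the
#' left boundary window and one extra H3K27me3 block in the right window.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @return List: `p300`, `h3k27ac`, `h3k27me3` (`GRanges`) and `truth`
#'   (true p300-only/shared sets, marked gene ids, boundary blocks).
#' @export
simulate_peaks <- function(config, sim) {
  set.seed(sim_seed(config, 2L))
  sizes <- sim$chrom_sizes
  rand_peaks <- function(n) {
    chrom <- sample(names(sizes), n, replace = TRUE)
    w <- round(stats::runif(n, config$peak_width[1], config$peak_width[2]))
    s <- round(stats::runif(n, 30000, unname(sizes[chrom]) - 30000))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1))
  }
  pw <- function(n = 1) round(stats::runif(n, config$peak_width[1], config$peak_width[2]))
  # batched rejection sampling against an exclusion set
  sample_clear <- function(n, reject) {
    out <- NULL
    while (is.null(out) || length(out) < n) {
      cand <- rand_peaks(max(2L * n, 50L))
      cand <- cand[!reject(cand)]
      out <- if (is.null(out)) cand else
        suppressWarnings(c(out, cand))
    }
    out[seq_len(n)]
  }
  # keep H3K27ac clear of boundary-class windows so the plants there stay
  # p300-only
  avoid <- GenomicRanges::GRanges()
  if (length(sim$truth$boundary_class_tads)) {
    bc <- sim$tads[sim$truth$boundary_class_tads]
    edges <- c(BiocGenerics::start(bc), BiocGenerics::end(bc))
    avoid <- GenomicRanges::GRanges(
      rep(as.character(GenomicRanges::seqnames(bc)), 2),
      IRanges::IRanges(edges - 9000, edges + 9000))
  }
  k27ac <- sample_clear(config$n_k27ac, function(x) any_overlap(x, avoid))
  n_shared <- round(config$frac_p300_shared * config$n_p300)
  n_bc <- length(sim$truth$boundary_class_tads)
  n_only_free <- config$n_p300 - n_shared - n_bc
  if (n_only_free < 0) stop("n_p300 too small for the planted sets")
  host <- k27ac[sample(length(k27ac), n_shared, replace = TRUE)]
  sh_s <- BiocGenerics::start(host) + sample(-800:800, n_shared, replace = TRUE)
  shared <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(host)),
    IRanges::IRanges(sh_s, sh_s + pw(n_shared) - 1))
  only <- sample_clear(n_only_free, function(x)
    any_overlap(extend_intervals(x, 2000, sizes), k27ac))
  if (n_bc > 0) {
    bc <- sim$tads[sim$truth$boundary_class_tads]
    ctr <- BiocGenerics::start(bc) + sample(-3000:3000, n_bc, replace = TRUE)
    w <- pw(n_bc)
    only <- suppressWarnings(c(only, GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(bc)),
      IRanges::IRanges(ctr - floor(w / 2), ctr + ceiling(w / 2) - 1))))
  }
  gene_ids <- sim$gm$genes$gene_id
  marked <- sort(sample(gene_ids, min(config$n_h3k27me3_genes, length(gene_ids))))
  k27me3 <- extend_intervals(sim$gm$genes[marked], 500, sizes)
  S4Vectors::mcols(k27me3) <- NULL
  bc_blocks <- GenomicRanges::GRanges()
  if (n_bc > 0) {
    bc <- sim$tads[sim$truth$boundary_class_tads]
    ctr <- BiocGenerics::end(bc) + vapply(seq_len(n_bc), function(i)
      sample(-3000:3000, 1), integer(1))
    bc_blocks <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(bc)),
      IRanges::IRanges(ctr - 1500, ctr + 1500))
  }
  name_peaks <- function(gr, prefix) {
    if (length(gr)) gr$name <- sprintf("%s_%04d", prefix, seq_along(gr))
    gr
  }
  p300 <- name_peaks(c(shared, only), "p300")
  truth_only <- p300[seq_len(length(only)) + length(shared)]
  truth_shared <- p300[seq_len(length(shared))]
  list(p300 = p300,
       h3k27ac = name_peaks(k27ac, "k27ac"),
       h3k27me3 = name_peaks(c(k27me3, bc_blocks), "k27me3"),
       truth = list(p300_only = truth_only, p300_shared = truth_shared,
                    h3k27me3_genes = marked, boundary_blocks = bc_blocks))
}

#' Simulate chromatin loops with planted interaction classes
#'
#' Draws anchors from construction pools guaranteed to carry exactly the
#' intended chromatin labels (p300-only peak, H3K27me3 block, unmarked
#' gene, clean intergenic space) and pairs them per the configured class
#' proportions.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param peaks Output of [simulate_peaks()].
#' @return List: `loops` (loop `data.frame`) and `truth`
#'   (`data.frame(name, class)`).
#' @export
simulate_loops <- function(config, sim, peaks) {
  set.seed(sim_seed(config, 3L))
  sizes <- sim$chrom_sizes
  g <- sim$gm$genes
  k27me3 <- peaks$h3k27me3
  p300_only <- peaks$truth$p300_only
  near <- function(x, subject, margin) {
    if (length(x) == 0L || length(subject) == 0L) return(rep(FALSE, length(x)))
    any_overlap(extend_intervals(x, margin, sizes), subject)
  }
  half <- floor(config$anchor_width / 2)
  # pools: element centers whose anchor_width neighbourhood carries only
  # the intended labels
  p300_pool <- p300_only[!near(p300_only, k27me3, half + 1000)]
  marked <- g[g$gene_id %in% peaks$truth$h3k27me3_genes]
  k27me3_pool <- marked[!near(marked, p300_only, half + 1000)]
  unmarked <- g[!g$gene_id %in% peaks$truth$h3k27me3_genes &
                  BiocGenerics::width(g) >= 4000]
  gene_pool <- unmarked[!near(unmarked, p300_only, half + 1000) &
                          !near(unmarked, k27me3, half + 1000)]
  n_inter <- 300L
  all_genes_gr <- GenomicRanges::granges(g)
  inter_pool <- NULL
  guard <- 0L
  while ((is.null(inter_pool) || length(inter_pool) < n_inter) && guard < 50L) {
    guard <- guard + 1L
    chrom <- sample(names(sizes), 2L * n_inter, replace = TRUE)
    s <- round(stats::runif(2L * n_inter, 30000, unname(sizes[chrom]) - 30000))
    cand <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(s, s + config$anchor_width - 1))
    keep <- !(near(cand, all_genes_gr, 1000) | near(cand, p300_only, 2000) |
                near(cand, k27me3, 2000) | near(cand, peaks$h3k27ac, 2000))
    cand <- cand[keep]
    inter_pool <- if (is.null(inter_pool)) cand else
      suppressWarnings(c(inter_pool, cand))
  }
  if (is.null(inter_pool)) inter_pool <- GenomicRanges::GRanges()
  if (length(inter_pool) > n_inter) inter_pool <- inter_pool[seq_len(n_inter)]
  anchor_at <- function(gr_el, label) {
    ctr <- floor((BiocGenerics::start(gr_el) + BiocGenerics::end(gr_el)) / 2)
    if (label == "gene") {
      # keep the anchor inside the gene span so the gene_body label holds
      s <- pmax(BiocGenerics::start(gr_el), ctr - half)
      e <- pmin(BiocGenerics::end(gr_el), ctr + half)
    } else {
      s <- ctr - half
      e <- ctr + half
    }
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr_el)),
                           IRanges::IRanges(s, e))
  }
  pool_of <- list(p300_only = list(gr = p300_pool, label = "p300"),
                  H3K27me3 = list(gr = k27me3_pool, label = "k27me3"),
                  gene = list(gr = gene_pool, label = "gene"),
                  intergenic = list(gr = inter_pool, label = "intergenic"))
  class_labels <- list(
    "p300only-H3K27me3" = c("p300_only", "H3K27me3"),
    "H3K27me3-H3K27me3" = c("H3K27me3", "H3K27me3"),
    "p300only-p300only" = c("p300_only", "p300_only"),
    "p300only-gene" = c("p300_only", "gene"),
    "p300only-intergenic" = c("p300_only", "intergenic"),
    "H3K27me3-gene" = c("H3K27me3", "gene"),
    "H3K27me3-intergenic" = c("H3K27me3", "intergenic"),
    "gene-gene" = c("gene", "gene"),
    "gene-intergenic" = c("gene", "intergenic"),
    "intergenic-intergenic" = c("intergenic", "intergenic"))
  props <- config$loop_class_props
  if (!all(names(props) %in% names(class_labels))) {
    stop("unknown loop class in loop_class_props")
  }
  counts <- floor(props * config$n_loops)
  rem <- config$n_loops - sum(counts)
  if (rem > 0) {
    extra <- order(props * config$n_loops - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rows <- list()
  truth <- list()
  for (cls in names(counts)) {
    lab <- class_labels[[cls]]
    pa <- pool_of[[lab[1L]]]$gr
    pb <- pool_of[[lab[2L]]]$gr
    if (length(pa) == 0L || length(pb) == 0L) {
      stop("empty anchor pool for class ", cls)
    }
    for (k in seq_len(counts[[cls]])) {
      ok <- FALSE
      for (try in seq_len(400L)) {
        ea <- pa[sample(length(pa), 1)]
        chrom <- as.character(GenomicRanges::seqnames(ea))
        pb_c <- pb[as.character(GenomicRanges::seqnames(pb)) == chrom]
        if (length(pb_c) == 0L) next
        eb <- pb_c[sample(length(pb_c), 1)]
        d <- abs(floor((BiocGenerics::start(ea) + BiocGenerics::end(ea)) / 2) -
                   floor((BiocGenerics::start(eb) + BiocGenerics::end(eb)) / 2))
        if (d < config$loop_span_range[1] || d > config$loop_span_range[2]) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place a loop of class ", cls)
      a1 <- anchor_at(ea, pool_of[[lab[1L]]]$label)
      a2 <- anchor_at(eb, pool_of[[lab[2L]]]$label)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = as.character(GenomicRanges::seqnames(a1)),
        start1 = BiocGenerics::start(a1) - 1, end1 = BiocGenerics::end(a1),
        chrom2 = as.character(GenomicRanges::seqnames(a2)),
        start2 = BiocGenerics::start(a2) - 1, end2 = BiocGenerics::end(a2),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- cls
    }
  }
  loops <- do.call(rbind, rows)
  loops$name <- sprintf("loop%05d", seq_len(nrow(loops)))
  loops$score <- NA_real_
  loops <- canonicalize_loops(loops)
  list(loops = loops,
       truth = data.frame(name = loops$name, class = unlist(truth),
                          stringsAsFactors = FALSE))
}

#' Simulate a distance-decay contact matrix with planted structure
#'
#' Expected counts follow `lambda(d) = base_count * (d+1)^-alpha` (d =
#' bin distance), multiplied by `tad_factor` for intra-TAD pixels and by
#' `loop_enrichment` at planted pixels; observed counts are Poisson draws.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name.
#' @param tads Optional TAD `GRanges` (only this chromosome's TADs are
#'   used).
#' @param pixels Optional `data.frame(i, j)` of 0-based planted loop bins.
#' @param seed_offset Offset distinguishing independent draws (default 4).
#' @return A RAW [contact_matrix()].
#' @export
simulate_contacts <- function(config, chrom, tads = NULL, pixels = NULL,
                              seed_offset = 4L) {
  set.seed(sim_seed(config, seed_offset))
  n <- as.integer(config$chrom_length %/% config$bin_size)
  d <- abs(outer(seq_len(n) - 1L, seq_len(n) - 1L, "-"))
  lambda <- config$base_count * (d + 1)^(-config$alpha)
  if (!is.null(tads)) {
    tads <- tads[as.character(GenomicRanges::seqnames(tads)) == chrom]
    for (t in seq_along(tads)) {
      b0 <- floor((BiocGenerics::start(tads)[t] - 1) / config$bin_size) + 1L
      b1 <- floor((BiocGenerics::end(tads)[t] - 1) / config$bin_size) + 1L
      b1 <- min(b1, n)
      lambda[b0:b1, b0:b1] <- lambda[b0:b1, b0:b1] * config$tad_factor
    }
  }
  if (!is.null(pixels) && nrow(pixels)) {
    idx <- cbind(pixels$i + 1L, pixels$j + 1L)
    lambda[idx] <- lambda[idx] * config$loop_enrichment
    lambda[idx[, c(2L, 1L), drop = FALSE]] <- lambda[idx]
  }
  up <- upper.tri(lambda, diag = TRUE)
  m <- matrix(0, n, n)
  m[up] <- stats::rpois(sum(up), lambda[up])
  m <- m + t(m) - diag(diag(m))
  contact_matrix(chrom, config$bin_size, m, "RAW")
}

#' Sample loop pixels for aggregate peak analysis
#'
#' Draws `n` bin pairs at the configured APA distances, respecting the
#' window-6 diagonal guard and matrix edges, and returns both the pixel
#' table (for planting into [simulate_contacts()]) and the matching loop
#' records (anchors = the bin intervals).
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name.
#' @param n Number of pixels (default `config$n_apa_loops`).
#' @param seed_offset Offset distinguishing independent draws (default 5;
#'   use another value for control pixel sets).
#' @return List: `pixels` (`data.frame(i, j)`, 0-based bins) and `loops`
#'   (loop `data.frame`).
#' @export
sample_pixel_loops <- function(config, chrom, n = config$n_apa_loops,
                               seed_offset = 5L) {
  set.seed(sim_seed(config, seed_offset))
  nb <- as.integer(config$chrom_length %/% config$bin_size)
  w <- 6L
  dmin <- max(config$apa_distance_bins[1], 2L * w + 1L)
  dmax <- min(config$apa_distance_bins[2], nb - 2L * w - 2L)
  i <- integer(n); j <- integer(n)
  for (k in seq_len(n)) {
    d <- sample(dmin:dmax, 1)
    i[k] <- sample(w:(nb - 1L - w - d), 1)
    j[k] <- i[k] + d
  }
  bs <- config$bin_size
  loops <- data.frame(chrom1 = chrom, start1 = i * bs, end1 = (i + 1) * bs,
                      chrom2 = chrom, start2 = j * bs, end2 = (j + 1) * bs,
                      name = sprintf("px%04d", seq_len(n)), score = NA_real_,
                      stringsAsFactors = FALSE)
  loops <- canonicalize_loops(loops)
  list(pixels = data.frame(i = i, j = j), loops = loops)
}

#' Simulate gene expression with an H3K27me3 repression shift
#'
#' log2(TPM+1) is drawn from Normal(`expr_mu`, `expr_sigma`); genes in
#' `marked_genes` are shifted down by `k27me3_shift` log2 units. TPM is
#' recovered by the inverse transform (floored at 0).
#'
#' @param config A [sim_config()].
#' @param gene_ids Character vector of gene identifiers.
#' @param marked_genes Subset of `gene_ids` carrying the repressive mark.
#' @return `data.frame` with `gene_id` and `TPM`.
#' @export
simulate_expression <- function(config, gene_ids, marked_genes = character()) {
  set.seed(sim_seed(config, 6L))
  x <- stats::rnorm(length(gene_ids), config$expr_mu, config$expr_sigma)
  x <- x - config$k27me3_shift * (gene_ids %in% marked_genes)
  data.frame(gene_id = gene_ids, TPM = pmax(0, 2^x - 1),
             stringsAsFactors = FALSE)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' The reference gene sits at `ref_ct`; each target gene gets a baseline
#' delta-Ct (uniform in 2-6 cycles) in the control sample and is shifted
#' by `-log2(fold)` in the treated sample. Gaussian noise of sd
#' `ct_sigma` is added per well.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with `sample`, `gene`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(config) {
  set.seed(sim_seed(config, 7L))
  genes <- names(config$fold_map)
  base_dct <- stats::setNames(stats::runif(length(genes), 2, 6), genes)
  rows <- list()
  for (smp in c(config$control_sample, config$treated_sample)) {
    for (gene in c(config$reference_gene, genes)) {
      for (rep_i in seq_len(config$n_replicates)) {
        ct <- if (gene == config$reference_gene) config$ref_ct else {
          shift <- if (smp == config$treated_sample)
            -log2(config$fold_map[[gene]]) else 0
          config$ref_ct + base_dct[[gene]] + shift
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, gene = gene, replicate = rep_i,
          ct = ct + stats::rnorm(1, 0, config$ct_sigma),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a MAF-like mutation table
#'
#' Each sample carries `background_muts_per_sample` mutations at uniform
#' random genome positions and, with probability `promoter_mut_rate`, one
#' planted mutation inside the promoter window of a random target gene.
#'
#' @param config A [sim_config()].
#' @param gm A [gene_models] object.
#' @param target_genes Gene ids whose promoters receive planted mutations.
#' @param chrom_sizes Named chromosome lengths.
#' @return `data.frame` with `sample_id`, `chrom`, `pos` (1-based).
#' @export
simulate_mutations <- function(config, gm, target_genes, chrom_sizes) {
  set.seed(sim_seed(config, 8L))
  prom <- promoter_windows(gm, config$promoter_flank)
  prom <- prom[names(prom) %in% target_genes]
  rows <- list()
  for (s in seq_len(config$n_mut_samples)) {
    sid <- sprintf("S%04d", s)
    for (b in seq_len(config$background_muts_per_sample)) {
      chrom <- sample(names(chrom_sizes), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = chrom,
        pos = sample.int(chrom_sizes[[chrom]], 1), stringsAsFactors = FALSE)
    }
    if (length(prom) && stats::runif(1) < config$promoter_mut_rate) {
      p <- prom[sample(length(prom), 1)]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = as.character(GenomicRanges::seqnames(p)),
        pos = sample(BiocGenerics::start(p):BiocGenerics::end(p), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate and write every synthetic input with ground truth
#'
#' Runs all generators in a fixed order and writes the full input set of
#' the pipeline to `outdir`: chrom.sizes, genes.gtf, tads.bed, three peak
#' BEDs, loops.bedpe, one triplet contact matrix per chromosome (planted
#' APA pixels on the first chromosome), expression.tsv, ct.tsv,
#' mutations.tsv, oncogene/TSG lists and ground_truth.json.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with all in-memory objects, the ground truth
#'   and the written file paths.
#' @export
simulate_all <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  peaks <- simulate_peaks(config, sim)
  loops <- simulate_loops(config, sim, peaks)
  apa_px <- sample_pixel_loops(config, names(sim$chrom_sizes)[1L])
  contacts <- lapply(seq_along(sim$chrom_sizes), function(ci) {
    simulate_contacts(config, names(sim$chrom_sizes)[ci], tads = sim$tads,
                      pixels = if (ci == 1L) apa_px$pixels else NULL,
                      seed_offset = 4L + 10L * ci)
  })
  names(contacts) <- names(sim$chrom_sizes)
  gene_ids <- sim$gm$genes$gene_id
  expr <- simulate_expression(config, gene_ids, peaks$truth$h3k27me3_genes)
  ct <- simulate_ct_table(config)
  set.seed(sim_seed(config, 9L))
  fillers <- setdiff(gene_ids, c(sim$truth$pairs$upstream_gene,
                                 sim$truth$pairs$downstream_gene))
  n_onc_up <- min(3L, nrow(sim$truth$pairs))
  oncogenes <- sort(c(sample(fillers, min(30L, length(fillers))),
                      if (n_onc_up) sample(sim$truth$pairs$upstream_gene, n_onc_up)))
  tsgs <- sort(sample(setdiff(fillers, oncogenes),
                      min(20L, length(setdiff(fillers, oncogenes)))))
  mut_targets <- setdiff(sim$truth$pairs$downstream_gene, oncogenes)
  muts <- simulate_mutations(config, sim$gm, mut_targets, sim$chrom_sizes)
  paths <- list(
    chrom_sizes = file.path(outdir, "chrom.sizes"),
    genes = file.path(outdir, "genes.gtf"),
    tads = file.path(outdir, "tads.bed"),
    p300 = file.path(outdir, "peaks_p300.bed"),
    h3k27ac = file.path(outdir, "peaks_h3k27ac.bed"),
    h3k27me3 = file.path(outdir, "peaks_h3k27me3.bed"),
    loops = file.path(outdir, "loops.bedpe"),
    expression = file.path(outdir, "expression.tsv"),
    ct = file.path(outdir, "ct.tsv"),
    mutations = file.path(outdir, "mutations.tsv"),
    oncogenes = file.path(outdir, "oncogenes.tsv"),
    tsgs = file.path(outdir, "tsgs.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json"))
  write_chrom_sizes(sim$chrom_sizes, paths$chrom_sizes)
  write_gtf_genes(sim$gm, paths$genes)
  write_bed(sim$tads, paths$tads)
  write_bed(peaks$p300, paths$p300)
  write_bed(peaks$h3k27ac, paths$h3k27ac)
  write_bed(peaks$h3k27me3, paths$h3k27me3)
  write_bedpe(loops$loops, paths$loops)
  for (chrom in names(contacts)) {
    paths[[paste0("contacts_", chrom)]] <-
      file.path(outdir, paste0("contacts_", chrom, ".tsv"))
    write_contacts(contacts[[chrom]], paths[[paste0("contacts_", chrom)]])
  }
  write_tsv(expr, paths$expression)
  write_tsv(ct, paths$ct)
  write_tsv(muts, paths$mutations)
  writeLines(oncogenes, paths$oncogenes)
  writeLines(tsgs, paths$tsgs)
  truth <- list(
    planted_pairs = sim$truth$pairs,
    planted_tads = sim$truth$planted_tads,
    boundary_class_tads = sim$truth$boundary_class_tads,
    p300_only_names = peaks$truth$p300_only$name,
    h3k27me3_genes = peaks$truth$h3k27me3_genes,
    loop_classes = loops$truth,
    apa_pixels = apa_px$pixels,
    expression_shift = config$k27me3_shift,
    qpcr_folds = as.list(config$fold_map),
    oncogenes = oncogenes, tsgs = tsgs,
    mutation_target_genes = mut_targets)
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(list(config = config, genome = sim, peaks = peaks, loops = loops,
                 apa = apa_px, contacts = contacts, expression = expr,
                 ct = ct, mutations = muts, oncogenes = oncogenes,
                 tsgs = tsgs, truth = truth, paths = paths))
}
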