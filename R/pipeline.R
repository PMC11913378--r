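#' Run the full pipeline on a freshly simulated genome
#'
#' Generates every synthetic input under the given seed, runs all analysis
#' stages in dependency order (p300-only partition, feature distribution,
#' loop and TAD-boundary classification in both label universes, virtual
#' 4C, APA on planted vs control pixels, head-to-tail screening with
#' oncogene and promoter-mutation summaries, expression group comparisons,
#' qPCR quantification), writes every stage output plus a summary JSON to
#' `outdir`, and finishes with an md5 manifest of all written files. Two
#' runs with the same seed produce byte-identical manifests.
#'
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @param config Optional [sim_config()]; default `sim_config(seed = seed)`.
#' @return Invisibly, a list with the `manifest` data.frame, the `summary`
#'   list and all stage results.
#' @export
reproduce_synthetic <- function(seed = 1, outdir, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_all(config, file.path(outdir, "inputs"))
  gm <- sim$genome$gm
  sizes <- sim$genome$chrom_sizes
  out <- function(name) file.path(outdir, name)

  # p300-only partition
  part <- p300_only_peaks(sim$peaks$p300, sim$peaks$h3k27ac,
                          k27ac_flank = 1000, chrom_sizes = sizes)
  write_bed(part$p300_only, out("p300_only.bed"))
  write_bed(part$p300_shared, out("p300_shared.bed"))
  featdist <- feature_distribution(part$p300_only, gm)
  write_tsv(featdist, out("p300_only_features.tsv"))

  # interaction categories: loops and TAD boundaries
  loops_cls <- classify_loops(sim$loops$loops, gm, part$p300_only,
                              sim$peaks$h3k27me3, mode = "chromatin")
  write_bedpe(loops_cls, out("loops_classified.bedpe"),
              extra_cols = "category")
  loop_counts <- count_interaction_categories(loops_cls$category)
  write_tsv(loop_counts, out("loop_category_counts.tsv"))
  tad_cls <- classify_tad_boundaries(sim$genome$tads, gm, part$p300_only,
                                     sim$peaks$h3k27me3, mode = "chromatin",
                                     chrom_sizes = sizes)
  write_tsv(count_interaction_categories(tad_cls$category),
            out("tad_boundary_category_counts.tsv"))
  tad_gene_cls <- classify_tad_boundaries(sim$genome$tads, gm,
                                          GenomicRanges::GRanges(),
                                          GenomicRanges::GRanges(),
                                          mode = "genes", chrom_sizes = sizes)
  write_tsv(count_interaction_categories(tad_gene_cls$category),
            out("tad_boundary_gene_category_counts.tsv"))

  # Hi-C: virtual 4C from the first planted pixel, APA planted vs control
  chrom1 <- names(sim$contacts)[1L]
  m_norm <- vc_sqrt_normalize(sim$contacts[[chrom1]])
  v4c_anchor <- loop_anchors(sim$apa$loops[1L, ], 1)
  v4c <- virtual_4c(m_norm, v4c_anchor)
  write_tsv(v4c, out("virtual4c_profile.tsv"))
  apa_planted <- apa(m_norm, sim$apa$loops, window = 6)
  ctrl <- sample_pixel_loops(config, chrom1, seed_offset = 15L)
  apa_control <- apa(m_norm, ctrl$loops, window = 6)
  write_tsv(as.data.frame(apa_planted$aggregate), out("apa_aggregate.tsv"))

  # head-to-tail screen
  pairs <- detect_head_to_tail(sim$genome$tads, gm, chrom_sizes = sizes)
  write_tsv(pairs, out("head_to_tail_pairs.tsv"))
  onco <- oncogene_pair_summary(pairs, sim$oncogenes, sim$tsgs)
  write_tsv(onco, out("oncogene_pair_summary.tsv"))
  mut <- promoter_mutation_summary(sim$mutations, pairs, gm,
                                   oncogenes = sim$oncogenes)
  write_tsv(mut$per_gene, out("promoter_mutation_counts.tsv"))

  # expression comparisons
  expr <- read_expression(sim$paths$expression)
  grp <- loop_gene_groups(sim$loops$loops, gm, part$p300_only,
                          sim$peaks$h3k27me3, expr)
  write_tsv(grp, out("loop_gene_groups.tsv"))
  wtest <- if (length(unique(grp$group)) == 2L) {
    rank_sum_test(grp$log_expr[grp$group == "H3K27me3"],
                  grp$log_expr[grp$group == "non-H3K27me3"])
  } else list(statistic = NA_real_, p_value = NA_real_)
  btypes <- boundary_type_expression(sim$genome$tads, gm, expr,
                                     chrom_sizes = sizes)
  write_tsv(btypes, out("boundary_type_expression.tsv"))
  kw <- if (length(unique(btypes$category)) >= 2L) {
    kruskal_wallis(split(btypes$log_expr, btypes$category))
  } else list(statistic = NA_real_, p_value = NA_real_)

  # qPCR
  dct <- delta_ct(sim$ct, config$reference_gene)
  dd <- ddct(dct, config$control_sample)
  write_tsv(dd, out("qpcr_ddct.tsv"))

  headline <- "p300only-H3K27me3"
  frac_of <- function(counts, cls) {
    f <- counts$fraction[counts$category == cls]
    if (length(f)) f else 0
  }
  truth_only <- sort(sim$peaks$truth$p300_only$name)
  summary <- list(
    seed = config$seed,
    n_p300_only = length(part$p300_only),
    p300_only_exact = identical(sort(part$p300_only$name), truth_only),
    loop_headline_fraction = frac_of(loop_counts, headline),
    tad_boundary_headline_fraction =
      frac_of(count_interaction_categories(tad_cls$category), headline),
    n_head_to_tail_pairs = nrow(pairs),
    head_to_tail_exact = setequal(
      paste(pairs$upstream_gene, pairs$downstream_gene),
      paste(sim$truth$planted_pairs$upstream_gene,
            sim$truth$planted_pairs$downstream_gene)),
    apa_p2ll_planted = apa_planted$score_p2ll,
    apa_p2ll_control = apa_control$score_p2ll,
    expression_group_shift =
      stats::median(grp$log_expr[grp$group == "non-H3K27me3"]) -
      stats::median(grp$log_expr[grp$group == "H3K27me3"]),
    wilcoxon_p = wtest$p_value,
    kruskal_wallis_p = kw$p_value,
    promoter_mutation_fraction = mut$fraction,
    qpcr_folds = stats::setNames(
      as.list(dd$fold[dd$sample == config$treated_sample]),
      dd$gene[dd$sample == config$treated_sample]))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, out("manifest.tsv"))
  invisible(list(manifest = manifest, summary = summary, pairs = pairs,
                 loop_counts = loop_counts, apa_planted = apa_planted,
                 apa_control = apa_control, part = part, sim = sim))
}
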