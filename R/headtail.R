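#' Detect head-to-tail TAD boundary gene pairs
#'
#' A head-to-tail pair is two genes on the same strand at opposite
#' boundaries of one TAD, arranged so that the upstream gene (in
#' transcription order) presents its 3' region to one boundary window and
#' the downstream gene its promoter to the other. The upstream 3' element
#' may be either the terminator window (TES +/- `terminator_flank`) or the
#' 3' half of the gene body; which one matched is recorded per pair.
#'
#' @param tads TAD `GRanges`.
#' @param gm A [gene_models] object.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @param terminator_flank Terminator half-width in bp (default 5000).
#' @param boundary_flank TAD boundary window half-width in bp (default
#'   5000).
#' @param chrom_sizes Optional chromosome lengths.
#' @return `data.frame`: one row per (TAD, upstream gene, downstream gene)
#'   with `tad` (index into the input TAD set), TAD coordinates, gene ids,
#'   strand, `upstream_element` (`"terminator"` or `"gene_body"`) and the
#'   boundary side (`"left"`/`"right"`) each gene anchors; sorted by TAD
#'   then gene ids.
#' @export
detect_head_to_tail <- function(tads, gm, promoter_flank = 1000,
                                terminator_flank = 5000,
                                boundary_flank = 5000, chrom_sizes = NULL) {
  bw <- tad_boundary_windows(tads, boundary_flank, chrom_sizes)
  g <- gm$genes
  prom <- promoter_windows(gm, promoter_flank)
  term <- terminator_windows(gm, terminator_flank)
  tail3 <- gene_body_3prime_half(gm)
  hits <- function(windows, side_gr) {
    ov <- GenomicRanges::findOverlaps(windows, side_gr, ignore.strand = TRUE)
    split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  }
  prom_l <- hits(prom, bw$left);  prom_r <- hits(prom, bw$right)
  term_l <- hits(term, bw$left);  term_r <- hits(term, bw$right)
  tail_l <- hits(tail3, bw$left); tail_r <- hits(tail3, bw$right)
  strand_of <- as.character(BiocGenerics::strand(g))
  tss <- g$tss
  rows <- list()
  get <- function(lst, t) {
    i <- lst[[as.character(t)]]
    if (is.null(i)) integer(0) else i
  }
  for (t in seq_along(bw$tads)) {
    for (side_up in c("left", "right")) {
      side_down <- if (side_up == "left") "right" else "left"
      up_term <- get(if (side_up == "left") term_l else term_r, t)
      up_tail <- get(if (side_up == "left") tail_l else tail_r, t)
      ups <- union(up_term, up_tail)
      downs <- get(if (side_down == "left") prom_l else prom_r, t)
      if (!length(ups) || !length(downs)) next
      for (u in ups) {
        for (d in downs) {
          if (u == d || strand_of[u] != strand_of[d]) next
          upstream_first <- if (strand_of[u] == "+") tss[u] < tss[d]
                            else tss[u] > tss[d]
          if (!upstream_first) next
          rows[[length(rows) + 1L]] <- data.frame(
            tad = bw$kept[t],
            chrom = as.character(GenomicRanges::seqnames(bw$tads))[t],
            tad_start = BiocGenerics::start(bw$tads)[t] - 1,
            tad_end = BiocGenerics::end(bw$tads)[t],
            upstream_gene = g$gene_id[u], downstream_gene = g$gene_id[d],
            strand = strand_of[u],
            upstream_element = if (u %in% up_term) "terminator" else "gene_body",
            boundary_side_up = side_up, boundary_side_down = side_down,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tad = integer(), chrom = character(),
                      tad_start = numeric(), tad_end = numeric(),
                      upstream_gene = character(), downstream_gene = character(),
                      strand = character(), upstream_element = character(),
                      boundary_side_up = character(),
                      boundary_side_down = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tad, out$upstream_gene, out$downstream_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Oncogene / tumour-suppressor composition of head-to-tail pairs
#'
#' Cross-references the 3'-anchored (upstream) and promoter-anchored
#' (downstream) genes of each pair against oncogene and tumour-suppressor
#' lists.
#'
#' @param pairs `data.frame` from [detect_head_to_tail()].
#' @param oncogenes,tsgs Character vectors of gene identifiers.
#' @return `data.frame` with one row per role x class: `n_pairs`,
#'   `fraction_of_pairs` (denominator = number of pairs), `n_genes`
#'   (distinct genes of that class in that role) and `fraction_of_list`
#'   (distinct genes / list size; NA for class "neither").
#' @export
oncogene_pair_summary <- function(pairs, oncogenes, tsgs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(role = character(), class = character(),
                      n_pairs = integer(), fraction_of_pairs = numeric(),
                      n_genes = integer(), fraction_of_list = numeric()))
  }
  classify <- function(genes) {
    ifelse(genes %in% oncogenes, "oncogene",
           ifelse(genes %in% tsgs, "tsg", "neither"))
  }
  one_role <- function(role, genes) {
    cls <- classify(genes)
    do.call(rbind, lapply(c("oncogene", "tsg", "neither"), function(k) {
      sel <- cls == k
      list_size <- switch(k, oncogene = length(unique(oncogenes)),
                          tsg = length(unique(tsgs)), NA_integer_)
      data.frame(role = role, class = k, n_pairs = sum(sel),
                 fraction_of_pairs = sum(sel) / length(genes),
                 n_genes = length(unique(genes[sel])),
                 fraction_of_list = length(unique(genes[sel])) / list_size,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one_role("upstream_3prime", pairs$upstream_gene),
               one_role("downstream_promoter", pairs$downstream_gene))
  rownames(out) <- NULL
  out
}

#' Promoter mutation burden of promoter-anchored non-oncogenes
#'
#' Counts, per promoter-anchored (downstream) non-oncogene, the distinct
#' samples carrying at least one mutation inside the gene's promoter
#' window; a sample counts once per gene regardless of how many mutations
#' it has there. The overall fraction is the number of distinct samples
#' with at least one hit in any target promoter over the total number of
#' distinct samples in the mutation table.
#'
#' @param mutations `data.frame` with `sample_id`, `chrom`, `pos` (1-based).
#' @param pairs `data.frame` from [detect_head_to_tail()].
#' @param gm A [gene_models] object.
#' @param oncogenes Character vector; these genes are excluded from the
#'   target set.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @return List with `per_gene` (`gene_id`, `n_samples`), `fraction`,
#'   `n_samples_total`, and `incidence` (gene x sample logical matrix,
#'   oncoplot-ready).
#' @export
promoter_mutation_summary <- function(mutations, pairs, gm,
                                      oncogenes = character(),
                                      promoter_flank = 1000) {
  targets <- setdiff(unique(pairs$downstream_gene), oncogenes)
  total <- length(unique(mutations$sample_id))
  prom <- promoter_windows(gm, promoter_flank)
  prom <- prom[names(prom) %in% targets]
  mut_gr <- GenomicRanges::GRanges(mutations$chrom,
                                   IRanges::IRanges(mutations$pos, mutations$pos))
  ov <- GenomicRanges::findOverlaps(mut_gr, prom, ignore.strand = TRUE)
  hit_gene <- names(prom)[S4Vectors::subjectHits(ov)]
  hit_sample <- mutations$sample_id[S4Vectors::queryHits(ov)]
  pairs_hit <- unique(data.frame(gene = hit_gene, sample = hit_sample,
                                 stringsAsFactors = FALSE))
  per_gene <- data.frame(
    gene_id = targets,
    n_samples = as.integer(table(factor(pairs_hit$gene, levels = targets))),
    stringsAsFactors = FALSE)
  samples <- sort(unique(mutations$sample_id))
  incidence <- matrix(FALSE, nrow = length(targets), ncol = length(samples),
                      dimnames = list(targets, samples))
  if (nrow(pairs_hit)) {
    incidence[cbind(pairs_hit$gene, pairs_hit$sample)] <- TRUE
  }
  list(per_gene = per_gene,
       fraction = if (total > 0) length(unique(pairs_hit$sample)) / total else NA_real_,
       n_samples_total = total,
       incidence = incidence)
}
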