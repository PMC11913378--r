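#' Split genes looped to p300-only anchors by H3K27me3 status
#'
#' Collects genes whose span overlaps a loop anchor whose partner anchor
#' carries a p300-only peak, then splits them by overlap of the gene span
#' with H3K27me3 peaks. A gene appearing in several qualifying loops is
#' counted once; genes without an expression record are skipped with a
#' message.
#'
#' @param loops Loop `data.frame`.
#' @param gm A [gene_models] object.
#' @param p300_only,h3k27me3 Peak `GRanges`.
#' @param expression `data.frame` from [read_expression()].
#' @return `data.frame` with `gene_id`, `group` (`"H3K27me3"` /
#'   `"non-H3K27me3"`) and `log_expr`.
#' @export
loop_gene_groups <- function(loops, gm, p300_only, h3k27me3, expression) {
  a1 <- loop_anchors(loops, 1)
  a2 <- loop_anchors(loops, 2)
  p1 <- any_overlap(a1, p300_only)
  p2 <- any_overlap(a2, p300_only)
  genes_at <- function(anchors) {
    ov <- GenomicRanges::findOverlaps(gm$genes, anchors, ignore.strand = TRUE)
    gm$genes$gene_id[unique(S4Vectors::queryHits(ov))]
  }
  ids <- unique(c(genes_at(a2[p1]), genes_at(a1[p2])))
  if (length(ids) == 0L) {
    return(data.frame(gene_id = character(), group = character(),
                      log_expr = numeric()))
  }
  marked <- gm$genes$gene_id[any_overlap(gm$genes, h3k27me3)]
  grp <- ifelse(ids %in% marked, "H3K27me3", "non-H3K27me3")
  le <- expression$log_expr[match(ids, expression$gene_id)]
  if (anyNA(le)) {
    message(sum(is.na(le)), " gene(s) without expression record skipped")
  }
  keep <- !is.na(le)
  data.frame(gene_id = ids[keep], group = grp[keep], log_expr = le[keep],
             stringsAsFactors = FALSE)
}

#' Expression at TAD boundaries by boundary-pair type
#'
#' Classifies each TAD's boundary pair in the gene-label universe
#' (PP/PT/PG/...), keeps the requested categories, and attaches the
#' expression of genes overlapping either boundary window, deduplicated
#' per (gene, category).
#'
#' @inheritParams classify_tad_boundaries
#' @param expression `data.frame` from [read_expression()].
#' @param categories Categories to keep (default PT, PG, PP).
#' @return `data.frame` with `category`, `gene_id`, `log_expr`.
#' @export
boundary_type_expression <- function(tads, gm, expression,
                                     categories = c("PT", "PG", "PP"),
                                     boundary_flank = 5000,
                                     promoter_flank = 1000,
                                     terminator_flank = 5000,
                                     chrom_sizes = NULL) {
  bw <- tad_boundary_windows(tads, boundary_flank, chrom_sizes)
  empty <- GenomicRanges::GRanges()
  l1 <- annotate_anchor(bw$left, gm, empty, empty, promoter_flank, terminator_flank)
  l2 <- annotate_anchor(bw$right, gm, empty, empty, promoter_flank, terminator_flank)
  cat_of <- classify_interaction(l1, l2, interaction_precedence("genes"))
  rows <- list()
  for (t in which(cat_of %in% categories)) {
    win <- c(bw$left[t], bw$right[t])
    ids <- gm$genes$gene_id[any_overlap(gm$genes, win)]
    if (length(ids)) {
      rows[[length(rows) + 1L]] <- data.frame(category = cat_of[t],
                                              gene_id = ids,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(category = character(), gene_id = character(),
                      log_expr = numeric()))
  }
  out <- unique(do.call(rbind, rows))
  out$log_expr <- expression$log_expr[match(out$gene_id, expression$gene_id)]
  out <- out[!is.na(out$log_expr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF of a sample (the representation behind ECDF
#' comparison plots of expression groups).
#'
#' @param values Numeric vector, length >= 1.
#' @return A function of class `ecdf`.
#' @export
expression_ecdf <- function(values) {
  if (length(values) == 0L) stop("ECDF of an empty sample")
  stats::ecdf(values)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration for small tie-free samples, tie-corrected normal
#' approximation otherwise (the behaviour of [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors (each n >= 1).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (Mann-Whitney U for `a`), `p_value`,
#'   `method`.
#' @export
rank_sum_test <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `statistic` (tie-corrected H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("need >= 2 non-empty groups")
  }
  ht <- stats::kruskal.test(groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
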