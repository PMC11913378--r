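#' Partition p300 peaks into p300-only and p300/H3K27ac-shared sets
#'
#' H3K27ac peaks are first extended by `k27ac_flank` bp on each side; p300
#' peaks overlapping none of the extended set are the "p300-only" peaks, a
#' candidate repressive p300 class; the remainder are shared with H3K27ac.
#' The two outputs are a disjoint partition of the input p300 set.
#'
#' @param p300 `GRanges` of p300 ChIP-seq peaks.
#' @param h3k27ac `GRanges` of H3K27ac peaks.
#' @param k27ac_flank Extension applied to H3K27ac peaks in bp (default
#'   1000).
#' @param chrom_sizes Optional chromosome lengths for clamping the
#'   extension.
#' @return `list(p300_only = GRanges, p300_shared = GRanges)`.
#' @export
p300_only_peaks <- function(p300, h3k27ac, k27ac_flank = 1000,
                            chrom_sizes = NULL) {
  ext <- extend_intervals(h3k27ac, k27ac_flank, chrom_sizes)
  shared <- any_overlap(p300, ext)
  list(p300_only = p300[!shared], p300_shared = p300[shared])
}

#' Assign a genomic feature label to each peak
#'
#' Assignment uses the peak midpoint. Candidate labels, in priority order:
#' `promoter` (TSS +/- `promoter_flank`), `first intron` (the intron after
#' exon 1 in transcription order), `other intron`, `exon`, `3'-end` (within
#' `tes_flank` of a TES), `distal intergenic`.
#'
#' @param peaks `GRanges`.
#' @param gm A [gene_models] object.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @param tes_flank 3'-end half-width in bp (default 1000).
#' @return Character vector of labels, one per peak.
#' @export
annotate_feature <- function(peaks, gm, promoter_flank = 1000,
                             tes_flank = 1000) {
  if (length(peaks) == 0L) return(character(0))
  pts <- midpoints(peaks)
  introns <- gene_introns(gm)
  lab <- rep("distal intergenic", length(peaks))
  hit <- function(subject) any_overlap(pts, subject)
  # lowest priority first; later assignments overwrite
  lab[hit(point_windows(gm, gm$genes$tes, tes_flank))] <- "3'-end"
  lab[hit(unlist(gm$exons))] <- "exon"
  lab[hit(introns$other)] <- "other intron"
  lab[hit(introns$first)] <- "first intron"
  lab[hit(promoter_windows(gm, promoter_flank))] <- "promoter"
  lab
}

# introns per gene, split into first (transcription order) vs other
gene_introns <- function(gm) {
  spans <- methods::as(GenomicRanges::split(
    GenomicRanges::granges(gm$genes), gm$genes$gene_id), "GRangesList")
  intr <- GenomicRanges::psetdiff(unlist(range(spans)),
                                  gm$exons[names(spans)])
  flat <- unlist(intr)
  if (length(flat) == 0L) {
    return(list(first = GenomicRanges::GRanges(), other = GenomicRanges::GRanges()))
  }
  len <- lengths(intr)
  gid <- rep(names(intr), len)
  strand_of <- as.character(BiocGenerics::strand(gm$genes))[
    match(gid, gm$genes$gene_id)]
  # within each gene, psetdiff output is sorted by start; in transcription
  # order the first intron is the first block on '+' and the last on '-'
  pos <- sequence(len)
  n_of_gene <- rep(len, len)
  is_first <- ifelse(strand_of == "+", pos == 1L, pos == n_of_gene)
  list(first = flat[is_first], other = flat[!is_first])
}

#' Feature distribution of a peak set
#'
#' Counts and proportions of [annotate_feature()] labels, the input of a
#' genome-distribution pie chart.
#'
#' @inheritParams annotate_feature
#' @return `data.frame` with `feature`, `n`, `proportion` (sums to 1 for
#'   non-empty input).
#' @export
feature_distribution <- function(peaks, gm, promoter_flank = 1000,
                                 tes_flank = 1000) {
  if (length(peaks) == 0L) {
    warning("empty peak set")
    return(data.frame(feature = character(), n = integer(),
                      proportion = numeric()))
  }
  lab <- annotate_feature(peaks, gm, promoter_flank, tes_flank)
  levels <- c("promoter", "first intron", "other intron", "exon",
              "3'-end", "distal intergenic")
  n <- table(factor(lab, levels = levels))
  data.frame(feature = levels, n = as.integer(n),
             proportion = as.numeric(n) / length(peaks))
}

#' Binned signal matrix around site centers
#'
#' For each site, the window of `flank` bp on either side of the site
#' midpoint is tiled into `n_bins` bins and the length-weighted mean of the
#' coverage track over each bin is computed (absent coverage counts as 0).
#' Column means of the matrix give the aggregate binding profile.
#'
#' @param sites `GRanges` of anchor sites (e.g. p300-only peaks).
#' @param coverage `GRanges` with a numeric `score`, non-overlapping within
#'   a chromosome (a bedGraph track).
#' @param flank Window half-width in bp (default 5000).
#' @param n_bins Number of bins; `2 * flank` must be divisible by it.
#' @param chrom_sizes Optional chromosome lengths; windows running past a
#'   chromosome end have their truncated bins averaged over the available
#'   bp only.
#' @return A `signal_matrix` object: list with `values` (sites x bins
#'   matrix), `profile` (column means), `sites`, `flank`, `n_bins`.
#' @export
signal_matrix <- function(sites, coverage, flank = 5000, n_bins = 100,
                          chrom_sizes = NULL) {
  stopifnot(n_bins >= 1, flank > 0)
  if ((2 * flank) %% n_bins != 0) {
    stop("2*flank must be divisible by n_bins")
  }
  bw <- (2 * flank) / n_bins
  mid <- BiocGenerics::start(midpoints(sites))
  chrom <- as.character(GenomicRanges::seqnames(sites))
  # all site x bin windows at once
  bin_start <- rep(mid - flank, each = n_bins) +
    rep.int(seq_len(n_bins) - 1L, length(sites)) * bw
  bin_end <- bin_start + bw - 1
  bin_chrom <- rep(chrom, each = n_bins)
  cs <- pmax(1, bin_start)
  ce <- bin_end
  if (!is.null(chrom_sizes)) {
    if (!all(chrom %in% names(chrom_sizes))) {
      stop("site chromosome absent from chrom_sizes")
    }
    ce <- pmin(ce, unname(chrom_sizes[bin_chrom]))
  }
  avail <- pmax(0, ce - cs + 1)
  vals <- numeric(length(cs))
  ok <- avail > 0
  if (any(ok) && length(coverage)) {
    bins <- GenomicRanges::GRanges(bin_chrom[ok], IRanges::IRanges(cs[ok], ce[ok]))
    ov <- GenomicRanges::findOverlaps(bins, coverage, ignore.strand = TRUE)
    w <- BiocGenerics::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(ov)], coverage[S4Vectors::subjectHits(ov)]))
    tot <- numeric(length(bins))
    contrib <- w * coverage$score[S4Vectors::subjectHits(ov)]
    agg <- rowsum(contrib, S4Vectors::queryHits(ov))
    tot[as.integer(rownames(agg))] <- agg[, 1L]
    vals[ok] <- tot / avail[ok]
  }
  values <- matrix(vals, nrow = length(sites), ncol = n_bins, byrow = TRUE)
  structure(list(sites = sites, flank = flank, n_bins = n_bins,
                 values = values, profile = colMeans(values)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$values), "sites x", x$n_bins,
      "bins (flank", x$flank, "bp)\n")
  invisible(x)
}
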