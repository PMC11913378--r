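#' Extend intervals on both sides, clamping to chromosome bounds
#'
#' The "slop"-style operation used, e.g., to build the extended H3K27ac
#' region (+/- 1 kb around each peak) before p300-only partitioning.
#'
#' @param gr `GRanges` to extend.
#' @param flank Extension in bp on each side (>= 0).
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   given, every chromosome present in `gr` must be named and intervals
#'   are clamped to `[1, length]`. Without it only the lower bound is
#'   clamped.
#' @return `GRanges` in the input order.
#' @export
extend_intervals <- function(gr, flank, chrom_sizes = NULL) {
  stopifnot(flank >= 0)
  if (length(gr) == 0L) return(gr)
  s <- BiocGenerics::start(gr) - flank
  e <- BiocGenerics::end(gr) + flank
  if (!is.null(chrom_sizes)) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chrom %in% names(chrom_sizes))) {
      stop("chromosome absent from chrom_sizes: ",
           setdiff(chrom, names(chrom_sizes))[1L])
    }
    e <- pmin(e, unname(chrom_sizes[chrom]))
  }
  GenomicRanges::ranges(gr) <- IRanges::IRanges(pmax(1, s), e)
  gr
}

#' Do two interval sets overlap element-wise?
#'
#' True iff the pair shares at least 1 bp on the same chromosome; strand is
#' ignored everywhere in the package's overlap algebra.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b)) &
    BiocGenerics::start(a) <= BiocGenerics::end(b) &
    BiocGenerics::start(b) <= BiocGenerics::end(a)
}

#' Which query intervals overlap any subject interval?
#'
#' @param query,subject `GRanges`.
#' @return Logical mask over `query`.
#' @export
any_overlap <- function(query, subject) {
  if (length(query) == 0L) return(logical(0))
  if (length(subject) == 0L) return(rep(FALSE, length(query)))
  IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

#' Interval midpoints as 1 bp points
#' @param gr `GRanges`.
#' @return `GRanges` of 1 bp midpoints (floor of the center).
#' @export
midpoints <- function(gr) {
  mid <- floor((BiocGenerics::start(gr) + BiocGenerics::end(gr)) / 2)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr), IRanges::IRanges(mid, mid))
}
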