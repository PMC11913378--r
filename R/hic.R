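#' Binned Hi-C contact matrix
#'
#' Symmetric per-chromosome count matrix at a fixed bin size. Bin `b`
#' (0-based) covers bp `[b*bin_size, (b+1)*bin_size)`.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param counts Symmetric non-negative numeric matrix.
#' @param norm Normalization state: `"RAW"`, `"VC"` or `"VC_SQRT"`.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(chrom, bin_size, counts, norm = "RAW") {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0), norm %in% c("RAW", "VC", "VC_SQRT"))
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8))) {
    stop("contact matrix must be symmetric")
  }
  structure(list(chrom = chrom, bin_size = bin_size,
                 n_bins = nrow(counts), counts = counts, norm = norm),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", x$n_bins, "bins of", x$bin_size,
      "bp,", x$norm, "normalized, total", sum(x$counts), "\n")
  invisible(x)
}

#' Load a contact matrix from triplet text
#'
#' Format: a header line `#chrom=<name> bin_size=<bp> n_bins=<n>` followed
#' by tab-separated `i j count` triplets (0-based bin indices, upper or
#' lower triangle). Each triplet is mirrored to keep the matrix symmetric.
#'
#' @param path Triplet text file.
#' @return A [contact_matrix()] (norm `"RAW"`).
#' @export
load_contacts <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^#chrom=", lines[1L])) {
    stop("missing contact-matrix header '#chrom=... bin_size=... n_bins=...'")
  }
  hdr <- strsplit(sub("^#", "", lines[1L]), " ", fixed = TRUE)[[1L]]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  chrom <- vals[["chrom"]]
  bin_size <- as.numeric(vals[["bin_size"]])
  n_bins <- as.integer(vals[["n_bins"]])
  m <- matrix(0, n_bins, n_bins)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) != 3L)) stop("malformed triplet line")
    i <- as.integer(vapply(f, `[[`, "", 1L))
    j <- as.integer(vapply(f, `[[`, "", 2L))
    v <- as.numeric(vapply(f, `[[`, "", 3L))
    if (any(is.na(i) | is.na(j) | is.na(v))) stop("malformed triplet line")
    if (any(i < 0 | j < 0 | i >= n_bins | j >= n_bins)) {
      stop("bin index out of range")
    }
    if (any(v < 0)) stop("negative count")
    m[cbind(i + 1L, j + 1L)] <- m[cbind(i + 1L, j + 1L)] + v
    off <- i != j
    m[cbind(j + 1L, i + 1L)[off, , drop = FALSE]] <-
      m[cbind(j + 1L, i + 1L)[off, , drop = FALSE]] + v[off]
  }
  contact_matrix(chrom, bin_size, m, "RAW")
}

#' Write a contact matrix as triplet text (upper triangle, nonzero cells)
#' @param m A [contact_matrix()].
#' @param path Output path.
#' @export
write_contacts <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  hdr <- sprintf("#chrom=%s bin_size=%s n_bins=%d",
                 m$chrom, format_coord(m$bin_size), m$n_bins)
  writeLines(c(hdr, paste(idx[, 1L] - 1L, idx[, 2L] - 1L,
                          format_coord(m$counts[idx]), sep = "\t")), path)
  invisible(path)
}

#' VC_SQRT matrix balancing
#'
#' Vanilla-coverage square-root normalization: with row sums `r`, each cell
#' becomes `c_ij / (sqrt(r_i) * sqrt(r_j))` (rows with zero sum are left as
#' zeros), then the matrix is rescaled by one scalar so its grand sum
#' equals the input grand sum. Symmetry is preserved; the operation is not
#' idempotent.
#'
#' @param m A RAW [contact_matrix()].
#' @return Normalized `contact_matrix` with `norm = "VC_SQRT"`.
#' @export
vc_sqrt_normalize <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$norm != "RAW") stop("matrix is already normalized")
  r <- rowSums(m$counts)
  s <- sqrt(r)
  inv <- ifelse(s > 0, 1 / s, 0)
  norm <- m$counts * outer(inv, inv)
  tot <- sum(norm)
  if (tot > 0) norm <- norm * (sum(m$counts) / tot)
  out <- m
  out$counts <- norm
  out$norm <- "VC_SQRT"
  out
}

#' Virtual 4C profile from one anchor
#'
#' Extracts the contact-matrix row(s) of the bins covered by the anchor
#' (averaged when the anchor spans several bins): the one-anchor
#' interaction profile over the viewpoint region.
#'
#' @param m A [contact_matrix()] (any normalization state).
#' @param anchor Single-interval `GRanges` on `m$chrom`.
#' @param region Optional single-interval `GRanges` restricting the
#'   reported bins; default is the whole chromosome.
#' @return `data.frame` with `bin` (0-based), `start`, `end` (bp, BED
#'   convention) and `value`.
#' @export
virtual_4c <- function(m, anchor, region = NULL) {
  stopifnot(inherits(m, "contact_matrix"), length(anchor) == 1L)
  if (as.character(GenomicRanges::seqnames(anchor)) != m$chrom) {
    stop("anchor is not on matrix chromosome ", m$chrom)
  }
  bins <- bp_to_bin(m, BiocGenerics::start(anchor), BiocGenerics::end(anchor))
  if (bins[1L] < 0L || bins[2L] >= m$n_bins) stop("anchor outside matrix")
  rows <- m$counts[(bins[1L]:bins[2L]) + 1L, , drop = FALSE]
  value <- colMeans(rows)
  keep <- seq_len(m$n_bins) - 1L
  if (!is.null(region)) {
    stopifnot(length(region) == 1L)
    if (as.character(GenomicRanges::seqnames(region)) != m$chrom) {
      stop("region is not on matrix chromosome ", m$chrom)
    }
    rb <- bp_to_bin(m, BiocGenerics::start(region), BiocGenerics::end(region))
    keep <- keep[keep >= max(0L, rb[1L]) & keep <= min(m$n_bins - 1L, rb[2L])]
  }
  data.frame(bin = keep, start = keep * m$bin_size,
             end = (keep + 1) * m$bin_size, value = value[keep + 1L])
}

# first and last 0-based bins covered by a 1-based closed interval
bp_to_bin <- function(m, start1, end1) {
  c(floor((start1 - 1) / m$bin_size), floor((end1 - 1) / m$bin_size))
}

#' Aggregate peak analysis (APA)
#'
#' For every cis loop whose anchor-midpoint bins `(i, j)` satisfy the
#' diagonal guard `j - i > 2*window` and whose `(2*window+1)^2`
#' neighbourhood fits inside the matrix, the submatrix centered on `(i, j)`
#' is extracted; the aggregate is the element-wise mean over the loops
#' used. The P2LL score is the center pixel divided by the mean of the
#' `ceiling(window/2)`-sized lower-left corner submatrix (largest anchor-1
#' coordinates, smallest anchor-2 coordinates).
#'
#' @param m A normalized [contact_matrix()] (typically VC_SQRT).
#' @param loops Loop `data.frame`; loops on other chromosomes are ignored,
#'   guarded or edge-clipped loops are skipped and counted.
#' @param window Window half-width in bins (default 6, giving a 13 x 13
#'   aggregate).
#' @return An `apa_result`: list with `aggregate`, `window`, `resolution`,
#'   `n_loops_used`, `n_skipped`, `score_p2ll`.
#' @export
apa <- function(m, loops, window = 6) {
  stopifnot(inherits(m, "contact_matrix"), window >= 1)
  if (m$norm == "RAW") stop("normalize the matrix first (see vc_sqrt_normalize)")
  cis <- loops[!loops$trans & loops$chrom1 == m$chrom, , drop = FALSE]
  w <- as.integer(window)
  size <- 2L * w + 1L
  agg <- matrix(0, size, size)
  used <- 0L
  skipped <- nrow(loops) - nrow(cis)
  for (k in seq_len(nrow(cis))) {
    i <- floor(((cis$start1[k] + cis$end1[k]) / 2) / m$bin_size)
    j <- floor(((cis$start2[k] + cis$end2[k]) / 2) / m$bin_size)
    if (j < i) { tmp <- i; i <- j; j <- tmp }
    if (j - i <= 2L * w || i - w < 0L || j + w > m$n_bins - 1L) {
      skipped <- skipped + 1L
      next
    }
    agg <- agg + m$counts[(i - w):(i + w) + 1L, (j - w):(j + w) + 1L]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loops")
  agg <- agg / used
  cs <- as.integer(ceiling(w / 2))
  center <- agg[w + 1L, w + 1L]
  corner <- agg[(size - cs + 1L):size, 1L:cs]
  structure(list(aggregate = agg, window = w, resolution = m$bin_size,
                 n_loops_used = used, n_skipped = skipped,
                 score_p2ll = center / mean(corner)),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat("APA:", nrow(x$aggregate), "x", ncol(x$aggregate), "aggregate at",
      x$resolution, "bp;", x$n_loops_used, "loops used,", x$n_skipped,
      "skipped; P2LL =", signif(x$score_p2ll, 4), "\n")
  invisible(x)
}
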