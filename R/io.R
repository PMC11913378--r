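#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED6 peak, TAD or region files into a [GenomicRanges::GRanges]
#' object. BED coordinates (0-based half-open) are converted to the 1-based
#' closed convention used throughout the package; [write_bed()] inverts the
#' conversion so a read/write round trip is byte-identical on the first six
#' columns.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A `GRanges`; columns 4-6, when present, populate `name`, `score`
#'   and the strand (`"."` becomes `"*"`).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("malformed BED line ", which(ncols < 3L)[1L], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | !nzchar(chrom))
  if (length(bad)) stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": requires 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  n_min <- min(ncols)
  if (n_min >= 4L) gr$name <- vapply(fields, `[[`, "", 4L)
  if (n_min >= 5L) {
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (n_min >= 6L) {
    s <- vapply(fields, `[[`, "", 6L)
    if (!all(s %in% c("+", "-", "."))) {
      stop("malformed BED line ", which(!s %in% c("+", "-", "."))[1L], ": bad strand")
    }
    s[s == "."] <- "*"
    BiocGenerics::strand(gr) <- s
  }
  gr
}

#' Write intervals to BED
#'
#' @param gr A `GRanges`. Writes BED6 when `name` metadata is present
#'   (missing scores become 0), BED3 otherwise.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- format_coord(BiocGenerics::start(gr) - 1)
  end0 <- format_coord(BiocGenerics::end(gr))
  if (!is.null(gr$name)) {
    score <- if (is.null(gr$score)) rep(0, length(gr)) else gr$score
    s <- as.character(BiocGenerics::strand(gr))
    s[s == "*"] <- "."
    out <- paste(chrom, start0, end0, gr$name, score, s, sep = "\t")
  } else {
    out <- paste(chrom, start0, end0, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(tab$length, tab$chrom)
}

#' Write a chrom.sizes file
#' @param sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), format_coord(sizes), sep = "\t"), path)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' Anchor pairs are canonicalized so that anchor 1 is not after anchor 2
#' (ordered by chromosome then start). Trans (different-chromosome) records
#' are kept and flagged in the `trans` column.
#'
#' @param path BEDPE file with >= 6 columns
#'   `chrom1 start1 end1 chrom2 start2 end2`, optionally followed by
#'   `name` and `score`.
#' @return A loop `data.frame` with BED-convention (0-based half-open)
#'   anchor coordinates, plus `name`, `score`, `trans` columns.
#' @export
read_bedpe <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_loops())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6L)) {
    stop("malformed BEDPE line ", which(ncols < 6L)[1L], ": fewer than 6 columns")
  }
  get <- function(k) vapply(fields, `[[`, "", k)
  num <- function(k) suppressWarnings(as.numeric(get(k)))
  df <- data.frame(chrom1 = get(1), start1 = num(2), end1 = num(3),
                   chrom2 = get(4), start2 = num(5), end2 = num(6),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start1) | is.na(df$end1) | is.na(df$start2) | is.na(df$end2) |
                 df$start1 >= df$end1 | df$start2 >= df$end2 | df$start1 < 0 | df$start2 < 0)
  if (length(bad)) stop("malformed BEDPE line ", bad[1L])
  df$name <- if (min(ncols) >= 7L) get(7) else paste0("loop", seq_len(nrow(df)))
  df$score <- if (min(ncols) >= 8L) num(8) else NA_real_
  canonicalize_loops(df)
}

canonicalize_loops <- function(df) {
  swap <- (df$chrom1 > df$chrom2) | (df$chrom1 == df$chrom2 & df$start1 > df$start2)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <- df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  df$trans <- df$chrom1 != df$chrom2
  rownames(df) <- NULL
  df
}

empty_loops <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             name = character(), score = numeric(), trans = logical(),
             stringsAsFactors = FALSE)
}

#' Write loops to BEDPE
#' @param loops Loop `data.frame` as returned by [read_bedpe()].
#' @param path Output path.
#' @param extra_cols Character vector of additional metadata columns to
#'   append after the score column (e.g. `"category"`).
#' @export
write_bedpe <- function(loops, path, extra_cols = character()) {
  cols <- c(format_loop_cols(loops), lapply(extra_cols, function(k) loops[[k]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_loop_cols <- function(loops) {
  list(loops$chrom1, format_coord(loops$start1), format_coord(loops$end1),
       loops$chrom2, format_coord(loops$start2), format_coord(loops$end2),
       loops$name, ifelse(is.na(loops$score), ".", as.character(loops$score)))
}

#' Anchor intervals of a loop set
#' @param loops Loop `data.frame`.
#' @param which 1 or 2: which anchor.
#' @return A `GRanges` of anchor intervals.
#' @export
loop_anchors <- function(loops, which = 1) {
  stopifnot(which %in% c(1, 2))
  chrom <- loops[[paste0("chrom", which)]]
  s <- loops[[paste0("start", which)]]
  e <- loops[[paste0("end", which)]]
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e))
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, value). Records are expected
#'   to be non-overlapping within a chromosome.
#' @return A `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  gr <- read_bed(path)
  if (is.null(gr$name)) stop("bedGraph requires 4 columns")
  gr$score <- suppressWarnings(as.numeric(gr$name))
  if (anyNA(gr$score)) stop("non-numeric bedGraph value")
  gr$name <- NULL
  gr
}

#' Write a bedGraph coverage track
#' @param gr `GRanges` with `score`.
#' @param path Output path.
#' @export
write_bedgraph <- function(gr, path) {
  writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                   format_coord(BiocGenerics::start(gr) - 1),
                   format_coord(BiocGenerics::end(gr)),
                   gr$score, sep = "\t"), path)
  invisible(path)
}

#' Read a gene quantification table
#'
#' Accepts ENCODE-style TSVs; the identifier and TPM columns are
#' configurable.
#'
#' @param path TSV with a header line.
#' @param gene_col,tpm_col Column names holding gene identifier and TPM.
#' @return `data.frame` with `gene_id`, `tpm` and `log_expr` = log2(TPM+1).
#' @export
read_expression <- function(path, gene_col = "gene_id", tpm_col = "TPM") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c(gene_col, tpm_col) %in% names(tab))) {
    stop("expression table must contain columns '", gene_col, "' and '", tpm_col, "'")
  }
  tpm <- as.numeric(tab[[tpm_col]])
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0")
  data.frame(gene_id = as.character(tab[[gene_col]]), tpm = tpm,
             log_expr = log2(tpm + 1), stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table
#' @param path TSV with header `sample`, `gene`, `replicate`, `ct`.
#' @return `data.frame` with those columns.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    stop("Ct table must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$ct <= 0)) stop("Ct values must be > 0")
  if (anyDuplicated(tab[c("sample", "gene", "replicate")])) {
    stop("replicate indices must be unique within (sample, gene)")
  }
  tab[need]
}

#' Read a one-per-line gene list (optionally TSV with a header)
#' @param path File whose first column holds gene identifiers.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  x <- as.character(tab[[1L]])
  x[!x %in% c("gene", "gene_id", "gene_name", "symbol")]
}

#' Read a MAF-like mutation table
#' @param path TSV with header `sample_id`, `chrom`, `pos` (1-based).
#' @return `data.frame` with those columns.
#' @export
read_mutations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos")
  if (!all(need %in% names(tab))) {
    stop("mutation table must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$pos < 1)) stop("mutation positions are 1-based and must be >= 1")
  tab[need]
}

#' Write a tab-separated table with header
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
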