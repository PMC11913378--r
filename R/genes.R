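#' Gene models: spans, exons, TSS/TES
#'
#' Container for gene annotations used throughout the pipeline. `genes` is a
#' `GRanges` of gene spans carrying `gene_id`, `gene_name`, `tss` and `tes`
#' metadata (1-based bp; the TSS is the strand-aware 5' end, the TES the 3'
#' end). `exons` is a `GRangesList` of per-gene exon intervals, indexed by
#' `gene_id`.
#'
#' @param genes `GRanges` of gene spans with `gene_id` metadata and strand
#'   `+` or `-`; `gene_name`, `tss`, `tes` are derived when absent.
#' @param exons `GRangesList` keyed by `gene_id`; genes without exon records
#'   get their full span as a single exon.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(methods::is(genes, "GRanges"), !is.null(genes$gene_id))
  s <- as.character(BiocGenerics::strand(genes))
  if (!all(s %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  genes$tss <- ifelse(s == "+", BiocGenerics::start(genes), BiocGenerics::end(genes))
  genes$tes <- ifelse(s == "+", BiocGenerics::end(genes), BiocGenerics::start(genes))
  names(genes) <- genes$gene_id
  if (is.null(exons)) {
    exons <- methods::as(GenomicRanges::split(
      GenomicRanges::granges(genes), genes$gene_id), "GRangesList")
  }
  missing <- setdiff(genes$gene_id, names(exons))
  if (length(missing)) {
    extra <- methods::as(GenomicRanges::split(
      GenomicRanges::granges(genes[missing]), missing), "GRangesList")
    exons <- c(exons, extra)
  }
  exons <- exons[genes$gene_id]
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models with", length(x$genes), "genes on",
      length(unique(as.character(GenomicRanges::seqnames(x$genes)))),
      "chromosome(s)\n")
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' Read gene models from a GTF file
#'
#' GTF 1-based closed coordinates are kept (the package's native
#' convention). One gene model is produced per `gene_id`: exon records are
#' merged per gene, and genes without a `gene` feature line are synthesized
#' from the envelope of their exons.
#'
#' @param path GTF file with `gene` and/or `exon` features carrying
#'   `gene_id` attributes.
#' @return A [gene_models] object.
#' @export
read_gtf_genes <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("gene", "exon")]
  if (length(gr) == 0L) {
    return(gene_models(GenomicRanges::GRanges(gene_id = character(),
                                              gene_name = character())))
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) stop("GTF record without gene_id")
  if (any(as.character(BiocGenerics::strand(gr)) == "*")) {
    stop("GTF gene/exon records must have strand '+' or '-'")
  }
  exon_gr <- gr[gr$type == "exon"]
  exons <- if (length(exon_gr)) {
    methods::as(GenomicRanges::reduce(
      GenomicRanges::split(exon_gr, exon_gr$gene_id)), "GRangesList")
  } else NULL
  gene_name_of <- function(ids) {
    if (is.null(gr$gene_name)) return(ids)
    nm <- gr$gene_name[match(ids, gr$gene_id)]
    ifelse(is.na(nm), ids, nm)
  }
  gene_gr <- gr[gr$type == "gene"]
  gene_ids <- gene_gr$gene_id
  spans <- GenomicRanges::granges(gene_gr)
  # genes present only as exon lines: synthesize the span from the envelope
  missing <- setdiff(unique(gr$gene_id), gene_ids)
  if (length(missing)) {
    env <- unlist(range(exons[missing]))
    str <- as.character(BiocGenerics::strand(exon_gr))
    BiocGenerics::strand(env) <- str[match(names(env), exon_gr$gene_id)]
    spans <- c(spans, GenomicRanges::granges(env))
    gene_ids <- c(gene_ids, names(env))
  }
  spans$gene_id <- gene_ids
  spans$gene_name <- gene_name_of(gene_ids)
  gene_models(spans, exons)
}

#' Write gene models to GTF
#' @param gm A [gene_models] object.
#' @param path Output path.
#' @export
write_gtf_genes <- function(gm, path) {
  g <- gm$genes
  attr_str <- function(id, name) {
    sprintf('gene_id "%s"; gene_name "%s";', id, name)
  }
  gene_lines <- paste(as.character(GenomicRanges::seqnames(g)), "tadloops", "gene",
                      BiocGenerics::start(g), BiocGenerics::end(g), ".",
                      as.character(BiocGenerics::strand(g)), ".",
                      attr_str(g$gene_id, g$gene_name), sep = "\t")
  ex <- unlist(gm$exons)
  ex_id <- rep(names(gm$exons), lengths(gm$exons))
  ex_name <- g$gene_name[match(ex_id, g$gene_id)]
  ex_strand <- as.character(BiocGenerics::strand(g))[match(ex_id, g$gene_id)]
  exon_lines <- paste(as.character(GenomicRanges::seqnames(ex)), "tadloops", "exon",
                      BiocGenerics::start(ex), BiocGenerics::end(ex), ".",
                      ex_strand, ".", attr_str(ex_id, ex_name), sep = "\t")
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}

#' Strand-aware promoter windows (TSS +/- flank)
#'
#' The promoter is the window of `flank` bp on either side of the
#' transcription start site.
#'
#' @param gm A [gene_models] object.
#' @param flank Half-width in bp (default 1000).
#' @return `GRanges` named by gene_id, clamped at position 1.
#' @export
promoter_windows <- function(gm, flank = 1000) {
  point_windows(gm, gm$genes$tss, flank)
}

#' Strand-aware terminator windows (TES +/- flank)
#'
#' The terminator is the window of `flank` bp on either side of the 3' end
#' of the annotated transcript.
#'
#' @inheritParams promoter_windows
#' @param flank Half-width in bp (default 5000).
#' @export
terminator_windows <- function(gm, flank = 5000) {
  point_windows(gm, gm$genes$tes, flank)
}

point_windows <- function(gm, at, flank) {
  stopifnot(flank >= 0)
  g <- gm$genes
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                               IRanges::IRanges(pmax(1, at - flank), at + flank),
                               strand = BiocGenerics::strand(g),
                               gene_id = g$gene_id)
  names(gr) <- g$gene_id
  gr
}

#' 3'-half of each gene body
#'
#' The half of the gene span nearest the TES, used as an alternative
#' "3' region" element in head-to-tail screening.
#'
#' @param gm A [gene_models] object.
#' @return `GRanges` named by gene_id.
#' @export
gene_body_3prime_half <- function(gm) {
  g <- gm$genes
  mid <- floor((BiocGenerics::start(g) + BiocGenerics::end(g)) / 2)
  plus <- as.character(BiocGenerics::strand(g)) == "+"
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(ifelse(plus, mid, BiocGenerics::start(g)),
                     ifelse(plus, BiocGenerics::end(g), mid)),
    strand = BiocGenerics::strand(g), gene_id = g$gene_id)
  names(gr) <- g$gene_id
  gr
}
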