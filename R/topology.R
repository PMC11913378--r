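#' TAD boundary windows
#'
#' For every TAD, the window of `flank` bp around each domain edge (the
#' region used for all boundary-level analyses). TADs shorter than
#' `2 * flank` are skipped with a warning.
#'
#' @param tads `GRanges` of TAD intervals.
#' @param flank Half-width of the boundary window in bp (default 5000,
#'   must be >= 1).
#' @param chrom_sizes Optional chromosome lengths for clamping.
#' @return List with `left` and `right` boundary `GRanges` (parallel to the
#'   kept TADs), `tads` (the kept TADs) and `kept` (indices into the
#'   input).
#' @export
tad_boundary_windows <- function(tads, flank = 5000, chrom_sizes = NULL) {
  stopifnot(flank >= 1)
  keep <- BiocGenerics::width(tads) > 2 * flank
  if (!all(keep)) {
    warning(sum(!keep), " TAD(s) shorter than 2*flank skipped")
  }
  tads <- tads[keep]
  chrom <- as.character(GenomicRanges::seqnames(tads))
  clamp <- function(s, e) {
    s <- pmax(1, s)
    if (!is.null(chrom_sizes)) e <- pmin(e, unname(chrom_sizes[chrom]))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
  }
  # domain edges in BED terms are start0 = start-1 and end0 = end; the
  # window [edge-flank, edge+flank) then maps to these 1-based bounds
  left <- clamp(BiocGenerics::start(tads) - flank,
                BiocGenerics::start(tads) + flank - 1)
  right <- clamp(BiocGenerics::end(tads) - flank + 1,
                 BiocGenerics::end(tads) + flank)
  list(left = left, right = right, tads = tads, kept = which(keep))
}

#' Merge loop sets collapsing near-duplicate loops
#'
#' Loops from several call sets (e.g. cell-cycle phases) are collapsed when
#' both anchor centers lie within `tolerance` bp of each other; connected
#' groups under this relation are represented by their first loop in sorted
#' order (chrom1, start1, chrom2, start2). Idempotent.
#'
#' @param loop_sets A loop `data.frame` or list of them.
#' @param tolerance Anchor center distance in bp (>= 0); a sensible default
#'   is one matrix bin.
#' @return Merged loop `data.frame` with an `n_merged` column, sorted.
#' @export
merge_loops <- function(loop_sets, tolerance) {
  stopifnot(tolerance >= 0)
  if (is.data.frame(loop_sets)) loop_sets <- list(loop_sets)
  df <- do.call(rbind, loop_sets)
  if (is.null(df) || nrow(df) == 0L) return(empty_loops())
  df <- df[order(df$chrom1, df$start1, df$chrom2, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  c1 <- (df$start1 + df$end1) / 2
  c2 <- (df$start2 + df$end2) / 2
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (df$chrom1[i] == df$chrom1[j] && df$chrom2[i] == df$chrom2[j] &&
          abs(c1[i] - c1[j]) <= tolerance && abs(c2[i] - c2[j]) <= tolerance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  reps <- sort(unique(comp))
  out <- df[reps, , drop = FALSE]
  out$n_merged <- as.integer(table(factor(comp, levels = reps)))
  rownames(out) <- NULL
  out
}

#' Label a set of anchors by overlapping chromatin and gene elements
#'
#' Each anchor interval receives the labels of the elements it overlaps:
#' `p300_only` and `H3K27me3` peaks, strand-aware `promoter` (TSS +/-
#' `promoter_flank`) and `terminator` (TES +/- `terminator_flank`) windows,
#' and `gene_body` (full gene span). Two exclusion labels are derived:
#' `gene` marks anchors on a gene free of both chromatin marks, and
#' `intergenic` marks anchors free of genes and both marks.
#'
#' @param anchors `GRanges` of anchor intervals (loop anchors or TAD
#'   boundary windows).
#' @param gm A [gene_models] object.
#' @param p300_only,h3k27me3 Peak `GRanges`.
#' @param promoter_flank,terminator_flank Window half-widths in bp.
#' @return `data.frame` of logical label columns, one row per anchor.
#' @export
annotate_anchor <- function(anchors, gm, p300_only, h3k27me3,
                            promoter_flank = 1000, terminator_flank = 5000) {
  p300 <- any_overlap(anchors, p300_only)
  k27me3 <- any_overlap(anchors, h3k27me3)
  prom <- any_overlap(anchors, promoter_windows(gm, promoter_flank))
  term <- any_overlap(anchors, terminator_windows(gm, terminator_flank))
  body <- any_overlap(anchors, gm$genes)
  data.frame(p300_only = p300, H3K27me3 = k27me3, promoter = prom,
             terminator = term, gene_body = body,
             gene = body & !k27me3 & !p300,
             intergenic = !body & !k27me3 & !p300)
}

#' Interaction category precedence tables
#'
#' Two label universes are used, selected by `mode`: `"chromatin"`
#' classifies anchors by {p300_only, H3K27me3, gene, intergenic} with the
#' repressive p300only-H3K27me3 class first so it is never absorbed by a
#' broader class; `"genes"` classifies by {promoter, terminator, gene_body}
#' into PP/PT/PG/TT/TG/GG. Pairs matching no rule are `"other"`.
#'
#' @param mode `"chromatin"` or `"genes"`.
#' @return `data.frame` with columns `a`, `b`, `category`, in match order.
#' @export
interaction_precedence <- function(mode = c("chromatin", "genes")) {
  mode <- match.arg(mode)
  if (mode == "chromatin") {
    rules <- rbind(
      c("p300_only",  "H3K27me3",   "p300only-H3K27me3"),
      c("H3K27me3",   "H3K27me3",   "H3K27me3-H3K27me3"),
      c("p300_only",  "p300_only",  "p300only-p300only"),
      c("p300_only",  "gene",       "p300only-gene"),
      c("p300_only",  "intergenic", "p300only-intergenic"),
      c("H3K27me3",   "gene",       "H3K27me3-gene"),
      c("H3K27me3",   "intergenic", "H3K27me3-intergenic"),
      c("gene",       "gene",       "gene-gene"),
      c("gene",       "intergenic", "gene-intergenic"),
      c("intergenic", "intergenic", "intergenic-intergenic"))
  } else {
    rules <- rbind(
      c("promoter",   "promoter",   "PP"),
      c("promoter",   "terminator", "PT"),
      c("promoter",   "gene_body",  "PG"),
      c("terminator", "terminator", "TT"),
      c("terminator", "gene_body",  "TG"),
      c("gene_body",  "gene_body",  "GG"))
  }
  data.frame(a = rules[, 1L], b = rules[, 2L], category = rules[, 3L],
             stringsAsFactors = FALSE)
}

#' Classify anchor-pair interactions
#'
#' Returns, per interaction, the category of the first precedence rule
#' matched in either anchor orientation; symmetric in anchor order.
#'
#' @param labels1,labels2 Label `data.frame`s from [annotate_anchor()],
#'   row-parallel to the interactions.
#' @param precedence Precedence table from [interaction_precedence()] (or a
#'   custom one with columns `a`, `b`, `category`).
#' @return Character vector of category names (`"other"` when unmatched).
#' @export
classify_interaction <- function(labels1, labels2,
                                 precedence = interaction_precedence("chromatin")) {
  stopifnot(nrow(labels1) == nrow(labels2))
  out <- rep("other", nrow(labels1))
  undecided <- rep(TRUE, nrow(labels1))
  for (k in seq_len(nrow(precedence))) {
    a <- precedence$a[k]
    b <- precedence$b[k]
    hit <- (labels1[[a]] & labels2[[b]]) | (labels1[[b]] & labels2[[a]])
    take <- undecided & hit
    out[take] <- precedence$category[k]
    undecided <- undecided & !take
  }
  out
}

#' Tabulate interaction categories
#'
#' @param categories Character vector from [classify_interaction()].
#' @return `data.frame` with `category`, `n`, `fraction` (fractions sum to
#'   1), sorted by decreasing count.
#' @export
count_interaction_categories <- function(categories) {
  n <- sort(table(categories), decreasing = TRUE)
  data.frame(category = names(n), n = as.integer(n),
             fraction = as.numeric(n) / length(categories),
             stringsAsFactors = FALSE)
}

#' Classify the boundary-pair interaction of every TAD
#'
#' The two boundary windows of one TAD form one interaction (the corner
#' loop); each is labelled with [annotate_anchor()] and the pair is
#' classified under the chosen mode.
#'
#' @inheritParams annotate_anchor
#' @param tads TAD `GRanges`.
#' @param boundary_flank Boundary window half-width in bp (default 5000).
#' @param mode Label universe, see [interaction_precedence()].
#' @param chrom_sizes Optional chromosome lengths.
#' @return `data.frame` with TAD coordinates and `category`.
#' @export
classify_tad_boundaries <- function(tads, gm, p300_only, h3k27me3,
                                    boundary_flank = 5000,
                                    promoter_flank = 1000,
                                    terminator_flank = 5000,
                                    mode = c("chromatin", "genes"),
                                    chrom_sizes = NULL) {
  mode <- match.arg(mode)
  bw <- tad_boundary_windows(tads, boundary_flank, chrom_sizes)
  l1 <- annotate_anchor(bw$left, gm, p300_only, h3k27me3,
                        promoter_flank, terminator_flank)
  l2 <- annotate_anchor(bw$right, gm, p300_only, h3k27me3,
                        promoter_flank, terminator_flank)
  data.frame(chrom = as.character(GenomicRanges::seqnames(bw$tads)),
             start = BiocGenerics::start(bw$tads) - 1,
             end = BiocGenerics::end(bw$tads),
             category = classify_interaction(l1, l2, interaction_precedence(mode)),
             stringsAsFactors = FALSE)
}

#' Classify a loop set
#'
#' @inheritParams classify_tad_boundaries
#' @param loops Loop `data.frame` ([read_bedpe()] layout). Trans loops are
#'   classified like cis ones (each anchor independently).
#' @return The loop `data.frame` with a `category` column appended.
#' @export
classify_loops <- function(loops, gm, p300_only, h3k27me3,
                           promoter_flank = 1000, terminator_flank = 5000,
                           mode = c("chromatin", "genes")) {
  mode <- match.arg(mode)
  l1 <- annotate_anchor(loop_anchors(loops, 1), gm, p300_only, h3k27me3,
                        promoter_flank, terminator_flank)
  l2 <- annotate_anchor(loop_anchors(loops, 2), gm, p300_only, h3k27me3,
                        promoter_flank, terminator_flank)
  loops$category <- classify_interaction(l1, l2, interaction_precedence(mode))
  loops
}
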