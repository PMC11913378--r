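# shared fixture builders; oracles used in tests are written inline with
# plain arithmetic so they stay independent of the package's overlap stack

gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

# a toy gene on a fixed exon grid; exon layout relative to `at`:
# exon1 [0, 999], exon2 [3000, 3999], exon3 [6000, 9999] (1-based widths)
toy_gene <- function(id, chrom, at, strand) {
  span <- gr(chrom, at, at + 9999, strand, gene_id = id)
  exons <- gr(chrom, at + c(0, 3000, 6000), at + c(999, 3999, 9999))
  list(span = span, exons = exons)
}

toy_gene_models <- function(n_plus = 3, n_minus = 3, chrom = "chrT",
                            spacing = 50000) {
  ids <- sprintf("tg%02d", seq_len(n_plus + n_minus))
  strands <- c(rep("+", n_plus), rep("-", n_minus))
  parts <- lapply(seq_along(ids), function(i) {
    toy_gene(ids[i], chrom, 20000 + (i - 1) * spacing, strands[i])
  })
  genes <- do.call(c, lapply(parts, `[[`, "span"))
  exons <- methods::as(GenomicRanges::GRangesList(lapply(parts, `[[`, "exons")),
                      "GRangesList")
  names(exons) <- ids
  gene_models(genes, exons)
}

small_sim_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 1, chrom_length = 4e6, n_tads = 50,
         planted_pairs = 4, n_boundary_class_tads = 2, n_pg_tads = 2,
         n_pp_tads = 2, n_filler_genes = 30, n_p300 = 60, n_k27ac = 80,
         n_h3k27me3_genes = 12, n_loops = 80),
    list(...))
  do.call(sim_config, args)
}

write_lines_tmp <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}

# independent brute-force oracle: plain-arithmetic enumeration over every
# TAD x ordered gene pair, using BED-style numbers extracted up front
headtail_oracle <- function(tads, gm, promoter_flank = 1000,
                            terminator_flank = 5000, boundary_flank = 5000) {
  td <- data.frame(chrom = as.character(GenomicRanges::seqnames(tads)),
                   s = BiocGenerics::start(tads) - 1,
                   e = BiocGenerics::end(tads))
  g <- gm$genes
  gd <- data.frame(id = g$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(g)),
                   s = BiocGenerics::start(g) - 1, e = BiocGenerics::end(g),
                   strand = as.character(BiocGenerics::strand(g)))
  gd$tss0 <- ifelse(gd$strand == "+", gd$s, gd$e - 1)
  gd$tes0 <- ifelse(gd$strand == "+", gd$e - 1, gd$s)
  ov <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1  # half-open
  out <- list()
  for (t in seq_len(nrow(td))) {
    if (td$e[t] - td$s[t] <= 2 * boundary_flank) next
    win <- list(left = c(td$s[t] - boundary_flank, td$s[t] + boundary_flank),
                right = c(td$e[t] - boundary_flank, td$e[t] + boundary_flank))
    gi <- gd[gd$chrom == td$chrom[t], , drop = FALSE]
    # every anchoring element lies within span +/- 5 kb, and windows within
    # edge +/- 5 kb, so genes farther than 30 kb from the TAD cannot match
    gi <- gi[gi$e >= td$s[t] - 30000 & gi$s <= td$e[t] + 30000, , drop = FALSE]
    for (u in seq_len(nrow(gi))) for (d in seq_len(nrow(gi))) {
      if (u == d || gi$strand[u] != gi$strand[d]) next
      if (gi$strand[u] == "+" && gi$tss0[u] >= gi$tss0[d]) next
      if (gi$strand[u] == "-" && gi$tss0[u] <= gi$tss0[d]) next
      # the 3' half uses the 1-based midpoint floor((start1+end1)/2),
      # written here in 0-based half-open terms
      mid1 <- floor((gi$s[u] + gi$e[u] + 1) / 2)
      half3 <- if (gi$strand[u] == "+") c(mid1 - 1, gi$e[u])
               else c(gi$s[u], mid1)
      for (w_up in c("left", "right")) {
        w_dn <- setdiff(c("left", "right"), w_up)
        wu <- win[[w_up]]; wd <- win[[w_dn]]
        up_hit <- ov(gi$tes0[u] - terminator_flank,
                     gi$tes0[u] + terminator_flank + 1, wu[1], wu[2]) ||
          ov(half3[1], half3[2], wu[1], wu[2])
        dn_hit <- ov(gi$tss0[d] - promoter_flank,
                     gi$tss0[d] + promoter_flank + 1, wd[1], wd[2])
        if (up_hit && dn_hit) {
          out[[length(out) + 1L]] <- paste(t, gi$id[u], gi$id[d], w_up)
        }
      }
    }
  }
  sort(unlist(out))
}
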