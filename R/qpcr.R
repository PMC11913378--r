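#' Per-replicate delta-Ct against a reference gene
#'
#' For every (sample, gene, replicate), dCt = Ct(gene) - Ct(reference
#' gene of the same sample and replicate). Replicates lacking a reference
#' measurement are dropped with a warning.
#'
#' @param ct `data.frame` with `sample`, `gene`, `replicate`, `ct`
#'   ([read_ct_table()] layout).
#' @param reference_gene Internal control gene (e.g. actin).
#' @return `data.frame` with `sample`, `gene`, `replicate`, `dct`
#'   (reference rows excluded).
#' @export
delta_ct <- function(ct, reference_gene) {
  ref <- ct[ct$gene == reference_gene, c("sample", "replicate", "ct")]
  if (nrow(ref) == 0L) stop("no Ct records for reference gene ", reference_gene)
  names(ref)[3L] <- "ref_ct"
  tgt <- ct[ct$gene != reference_gene, , drop = FALSE]
  merged <- merge(tgt, ref, by = c("sample", "replicate"), all.x = TRUE,
                  sort = FALSE)
  if (anyNA(merged$ref_ct)) {
    warning(sum(is.na(merged$ref_ct)),
            " replicate(s) without reference Ct dropped")
    merged <- merged[!is.na(merged$ref_ct), , drop = FALSE]
  }
  out <- data.frame(sample = merged$sample, gene = merged$gene,
                    replicate = merged$replicate,
                    dct = merged$ct - merged$ref_ct,
                    stringsAsFactors = FALSE)
  out[order(out$sample, out$gene, out$replicate), , drop = FALSE]
}

#' Summarize delta-Ct by sample and gene
#' @param dct `data.frame` from [delta_ct()].
#' @return `data.frame` with `sample`, `gene`, `n`, `mean_dct`, `sd_dct`,
#'   and `rel_expr` = 2^-mean_dct (the 2^-dCt quantification).
#' @export
summarize_dct <- function(dct) {
  key <- interaction(dct$sample, dct$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(dct, key), function(d) {
    data.frame(sample = d$sample[1L], gene = d$gene[1L], n = nrow(d),
               mean_dct = mean(d$dct), sd_dct = stats::sd(d$dct),
               stringsAsFactors = FALSE)
  }))
  agg$rel_expr <- 2^(-agg$mean_dct)
  agg <- agg[order(agg$sample, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Relative expression by the 2^-dCt method
#' @param dct Numeric delta-Ct values.
#' @return 2^(-dct), exactly.
#' @export
relative_expression <- function(dct) 2^(-dct)

#' Delta-delta-Ct relative quantification
#'
#' Per gene, ddCt of each treated replicate is its dCt minus the mean
#' control dCt of that gene; fold change = 2^-ddCt and log2 fold change =
#' -ddCt, exactly. Error is reported both as the sd of per-replicate folds
#' and as the sd propagated from ddCt (`ln2 * fold * sd_ddct`).
#'
#' @param dct `data.frame` from [delta_ct()] covering control and treated
#'   samples.
#' @param control_sample Name of the control (calibrator) sample.
#' @return `data.frame` with `sample`, `gene`, `n`, `ddct`, `sd_ddct`,
#'   `log2fc`, `fold`, `sd_fold`, `sd_fold_prop`.
#' @export
ddct <- function(dct, control_sample) {
  ctl <- dct[dct$sample == control_sample, , drop = FALSE]
  if (nrow(ctl) == 0L) stop("no dCt records for control sample ", control_sample)
  ctl_mean <- tapply(ctl$dct, ctl$gene, mean)
  base <- ctl_mean[dct$gene]
  if (anyNA(base)) {
    warning("gene(s) without control dCt dropped: ",
            paste(unique(dct$gene[is.na(base)]), collapse = ", "))
  }
  d <- dct[!is.na(base), , drop = FALSE]
  d$ddct_rep <- d$dct - ctl_mean[d$gene]
  key <- interaction(d$sample, d$gene, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(x) {
    dd <- mean(x$ddct_rep)
    folds <- 2^(-x$ddct_rep)
    data.frame(sample = x$sample[1L], gene = x$gene[1L], n = nrow(x),
               ddct = dd, sd_ddct = stats::sd(x$ddct_rep),
               log2fc = -dd, fold = 2^(-dd),
               sd_fold = stats::sd(folds),
               sd_fold_prop = log(2) * 2^(-dd) * stats::sd(x$ddct_rep),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unpaired t-test between replicate groups
#'
#' Welch's unequal-variance test by default (Student's available via
#' `var_equal`), one- or two-tailed.
#'
#' @param a,b Numeric vectors of folds or dCt values (each n >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @export
replicate_test <- function(a, b, alternative = "two.sided",
                           var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = ht$method)
}
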