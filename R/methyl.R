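## ---------------------------------------------------------------------------
## Gene-level methylation summarisation, response association, and
## correlation mapping of signature genes.
## ---------------------------------------------------------------------------

#' Median-based gene-level methylation summary
#'
#' Collapses probe-level beta values to one row per gene using the per-gene,
#' per-sample median (even probe counts use the mean-of-middle convention of
#' [stats::median()]).  Probes without a gene mapping are dropped and their
#' count recorded.
#'
#' @param probes probes x samples beta matrix.
#' @param map data.frame with columns `probe_id` and `gene`.
#' @return genes x samples matrix with attribute `n_unmapped`.
#' @export
summarize_gene_methylation <- function(probes, map) {
  if (!all(c("probe_id", "gene") %in% names(map)))
    stopf("`map` needs columns probe_id and gene")
  map <- map[!is.na(map$gene) & nzchar(map$gene), , drop = FALSE]
  if (!nrow(map)) stopf("empty probe-to-gene mapping")
  keep <- rownames(probes) %in% map$probe_id
  n_unmapped <- sum(!keep)
  probes <- probes[keep, , drop = FALSE]
  gene_of <- setNames(map$gene, map$probe_id)[rownames(probes)]
  groups <- split(seq_len(nrow(probes)), gene_of)
  out <- t(vapply(groups, function(ix)
    apply(probes[ix, , drop = FALSE], 2, median),
    numeric(ncol(probes))))
  colnames(out) <- colnames(probes)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Methylation-response rank-regression scan with a direction tally
#'
#' Runs [rank_regression_scan()] (no covariates by default) on gene-level
#' methylation against growth response and tallies the direction of the
#' significant genes: a negative sign means hypermethylation at lower
#' response rates.  For small cohorts (n <= 8) the scan reports exact
#' permutation p-values.
#'
#' @param meth genes x samples beta matrix.
#' @param response named response vector.
#' @param alpha significance threshold (default 0.01).
#' @param covariates optional covariates.
#' @return list with `table` (AssociationTable) and `tally`
#'   (`n_sig`, `n_neg`, `n_pos`, `neg_share`).
#' @export
methylation_response_scan <- function(meth, response, alpha = 0.01,
                                      covariates = NULL) {
  common <- intersect(colnames(meth), names(response))
  n <- sum(!is.na(response[common]))
  if (n < 4) stopf("methylation scan needs at least 4 samples (got %d)", n)
  tab <- rank_regression_scan(meth, response, covariates = covariates,
                              alpha = alpha, min_n = 4)
  sig <- tab[tab$flagged & !tab$degenerate, ]
  n_neg <- sum(sig$sign == "-")
  n_pos <- sum(sig$sign == "+")
  list(table = tab,
       tally = list(n_sig = nrow(sig), n_neg = n_neg, n_pos = n_pos,
                    neg_share = if (nrow(sig)) n_neg / nrow(sig) else NA_real_))
}

#' Map signature genes to methylation-response correlations
#'
#' Computes the Spearman correlation of each signature gene's methylation
#' with growth response and classifies genes as correlated when
#' `|r| > r_threshold` (default 0.3), recording the sign.  Signature genes
#' absent from the methylation matrix are reported as unmapped.
#'
#' @param signature a `signature` object or a character gene vector.
#' @param meth genes x samples beta matrix.
#' @param response named response vector.
#' @param r_threshold absolute-correlation threshold.
#' @return list with `table` (gene, r, correlated, direction) and
#'   `unmapped`.
#' @export
map_signature_methylation <- function(signature, meth, response,
                                      r_threshold = 0.3) {
  genes <- if (inherits(signature, "signature")) signature$genes
           else unique(as.character(signature))
  common <- intersect(colnames(meth), names(response))
  resp <- response[common]
  keep <- !is.na(resp)
  resp <- resp[keep]; common <- common[keep]
  mapped <- intersect(genes, rownames(meth))
  unmapped <- setdiff(genes, mapped)
  r <- vapply(mapped, function(g)
    suppressWarnings(cor(meth[g, common], resp, method = "spearman")), 0)
  r[is.na(r)] <- 0
  tab <- data.frame(
    gene = mapped, r = unname(r),
    correlated = abs(r) > r_threshold,
    direction = ifelse(r >= 0, "+", "-"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, unmapped = unmapped)
}
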