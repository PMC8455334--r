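## ---------------------------------------------------------------------------
## Cross-condition comparison of network cores and selection of the shared
## classification gene set per treatment year.
## ---------------------------------------------------------------------------

#' Hypergeometric overlap test between two gene cores
#'
#' Tests whether the observed overlap between two gene sets drawn from a
#' common universe is larger than expected by chance: the p-value is the
#' upper tail `P(X >= |A intersect B|)` of the hypergeometric distribution
#' with population `universe`, `|A|` successes and `|B|` draws.
#'
#' @param coreA,coreB character gene sets.
#' @param universe universe size (count), at least `|A union B|`.
#' @return list with `shared` (the intersection) and `p`.
#' @export
core_overlap_test <- function(coreA, coreB, universe) {
  coreA <- unique(as.character(coreA))
  coreB <- unique(as.character(coreB))
  assert_count(universe, "universe", min = 1)
  if (universe < length(union(coreA, coreB)))
    stopf("universe (%d) smaller than |A union B| (%d)",
          universe, length(union(coreA, coreB)))
  shared <- intersect(coreA, coreB)
  k <- length(shared)
  p <- phyper(k - 1, length(coreA), universe - length(coreA),
              length(coreB), lower.tail = FALSE)
  list(shared = shared, p = min(1, p))
}

#' Select the shared classification signature for one treatment year
#'
#' From the genes shared between the two condition cores, keeps those
#' significantly associated with height velocity by rank regression in
#' either condition (`p < alpha`, default 0.05).  Genes absent from both
#' association tables are excluded with a logged reason; an empty result is
#' allowed (with a warning) and the pipeline continues.
#'
#' @param shared character vector: genes in both condition cores.
#' @param assoc_ghd,assoc_ts AssociationTable data.frames with `feature_id`
#'   and `p`.
#' @param alpha selection threshold.
#' @param year treatment year (1-5), recorded in the signature.
#' @param overlap_p optional overlap p-value to record.
#' @return object of class `signature`: `year`, `genes`, `provenance`
#'   (per-gene p-values and core flags), `overlap_p`, `excluded`.
#' @export
select_signature <- function(shared, assoc_ghd, assoc_ts, alpha = 0.05,
                             year = NA_integer_, overlap_p = NA_real_) {
  assert_prob(alpha, "alpha")
  shared <- unique(as.character(shared))
  p_ghd <- setNames(assoc_ghd$p, assoc_ghd$feature_id)[shared]
  p_ts <- setNames(assoc_ts$p, assoc_ts$feature_id)[shared]
  absent <- shared[is.na(p_ghd) & is.na(p_ts)]
  keep <- !is.na(p_ghd) | !is.na(p_ts)
  sel <- shared[keep &
                  ((!is.na(p_ghd) & p_ghd < alpha) |
                     (!is.na(p_ts) & p_ts < alpha))]
  if (!length(sel))
    warnf("empty signature for year %s (no shared gene below alpha = %g)",
          year, alpha)
  prov <- data.frame(
    gene = shared,
    p_ghd = unname(p_ghd), p_ts = unname(p_ts),
    selected = shared %in% sel,
    stringsAsFactors = FALSE)
  structure(list(year = year, genes = sel, provenance = prov,
                 overlap_p = overlap_p, excluded = absent),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature (year %s): %d genes, overlap p = %s\n",
              x$year, length(x$genes), format(x$overlap_p, digits = 4)))
  invisible(x)
}

#' Pairwise overlap summary across yearly condition cores
#'
#' Computes shared gene counts and hypergeometric overlap p-values between
#' every pair of cores (across years and conditions), flagging pairs below
#' `alpha`.
#'
#' @param cores named list of gene sets (names like `GHD_y1`).
#' @param universe universe size for the hypergeometric test.
#' @param alpha flag threshold (default 0.01).
#' @return list with `overlap` (count matrix), `p` (p-value matrix),
#'   `flagged` (logical matrix).
#' @export
yearwise_overlap_summary <- function(cores, universe, alpha = 0.01) {
  if (length(cores) < 1) stopf("need at least one core")
  nm <- names(cores) %||% sprintf("core%d", seq_along(cores))
  k <- length(cores)
  ov <- matrix(0L, k, k, dimnames = list(nm, nm))
  pv <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { ov[i, j] <- length(unique(cores[[i]])); pv[i, j] <- NA; next }
    res <- core_overlap_test(cores[[i]], cores[[j]], universe)
    ov[i, j] <- length(res$shared)
    pv[i, j] <- res$p
  }
  list(overlap = ov, p = pv, flagged = !is.na(pv) & pv < alpha)
}
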