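## ---------------------------------------------------------------------------
## Association scans: covariate elimination, rank regression, Kruskal-Wallis
## genetic models, LD-block Bonferroni, Benjamini-Hochberg FDR, variance
## filtering.
## ---------------------------------------------------------------------------

## build a full-rank covariate design (intercept + expanded indicators),
## erroring with the aliased column names if rank-deficient
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && !ncol(covariates)))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    stopf("covariates have %d rows but data have %d samples", nrow(covariates), n)
  if (any(!complete.cases(covariates)))
    stopf("covariates must be complete for all samples")
  for (nm in names(covariates))
    if (is.character(covariates[[nm]]) || is.logical(covariates[[nm]]))
      covariates[[nm]] <- factor(covariates[[nm]])
  ## constant columns carry no information beyond the intercept
  keep <- vapply(covariates, function(x) length(unique(x)) > 1, TRUE)
  covariates <- covariates[, keep, drop = FALSE]
  if (!ncol(covariates))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  mm <- model.matrix(~ ., data = covariates)
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_d$pivot[seq(qr_d$rank + 1L, ncol(mm))]]
    stopf("covariate design is rank deficient; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }
  mm
}

#' Residualize a matrix (or vector) on clinical covariates
#'
#' Fits, per gene, an ordinary least-squares model with the covariates as
#' predictors (intercept always included; nominal covariates expanded to
#' indicators) and returns only the residuals.  For a single nominal factor
#' this is exactly mean-centring within each factor level.
#'
#' @param mat numeric genes x samples matrix, or a numeric vector (one
#'   feature, e.g. the response).
#' @param covariates data.frame of per-sample covariates aligned with the
#'   columns of `mat` (or `NULL` for intercept-only, i.e. mean-centring).
#' @return residual matrix (or vector) of the same shape.
#' @export
residualize_covariates <- function(mat, covariates = NULL) {
  vec <- is.null(dim(mat))
  m <- if (vec) matrix(mat, nrow = 1) else mat
  mm <- covariate_design(covariates, ncol(m))
  qr_d <- qr(mm)
  res <- t(qr.resid(qr_d, t(m)))
  dimnames(res) <- dimnames(m)
  if (vec) drop(res) else res
}

## midranks of a numeric vector
midrank <- function(x) rank(x, ties.method = "average")

## exact permutation p-value of the Spearman statistic for small n:
## two-sided P(|rho_perm| >= |rho_obs|) over all n! permutations
exact_spearman_p <- function(rx, ry, perms = NULL) {
  n <- length(rx)
  if (is.null(perms)) perms <- all_permutations(n)
  cx <- rx - mean(rx)
  if (sum(cx^2) == 0) return(1)
  y <- ry
  cy <- matrix(y[perms], nrow(perms), n)
  cy <- cy - rowMeans(cy)
  denom <- sqrt(sum(cx^2) * rowSums(cy^2))
  rho <- as.numeric(cy %*% cx) / denom
  obs <- sum(cx * (y - mean(y))) / sqrt(sum(cx^2) * sum((y - mean(y))^2))
  mean(abs(rho) >= abs(obs) - 1e-12)
}

## all permutations of 1..n as a matrix (n! rows); n <= 8 in practice
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.integer(block)
    r <- r + nrow(sub)
  }
  out
}

#' Rank-regression association scan of expression against growth response
#'
#' Covariates are eliminated from *both* the expression matrix and the
#' response by OLS residualization; the per-gene test is then a linear
#' regression on midrank-transformed residuals, with a two-sided p-value
#' from the nested-model F statistic with one numerator degree of freedom
#' (equivalently the t test of the slope).  The sign column carries the
#' direction of the association.  For `n <= exact_max_n` samples with no
#' covariates, the p-value comes from the exact permutation distribution of
#' the Spearman statistic instead of the F approximation.
#'
#' @param mat genes x samples matrix.
#' @param response named (or column-aligned) response vector; samples with
#'   missing response are dropped.
#' @param covariates optional covariate data.frame aligned with `mat`
#'   columns.
#' @param alpha flag threshold (default 0.01).
#' @param exact_max_n largest sample size at which the exact permutation
#'   p-value is used (only without covariates).
#' @param min_n smallest admissible sample size (default 8; small-cohort
#'   callers such as the methylation scan relax this to 4, where the exact
#'   permutation path applies).
#' @return An AssociationTable `data.frame` with columns `feature_id`,
#'   `statistic` (signed rank-regression t), `sign`, `p`, `p_adj` (BH),
#'   `method`, `model`, `flagged`, `degenerate`.
#' @export
rank_regression_scan <- function(mat, response, covariates = NULL,
                                 alpha = 0.01, exact_max_n = 8, min_n = 8) {
  if (!is.null(names(response)) && !is.null(colnames(mat))) {
    common <- intersect(colnames(mat), names(response))
    mat <- mat[, common, drop = FALSE]
    response <- response[common]
    if (!is.null(covariates)) covariates <- covariates[
      match(common, colnames(mat)), , drop = FALSE]
  }
  ok <- !is.na(response)
  mat <- mat[, ok, drop = FALSE]
  response <- response[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- length(response)
  if (n < max(min_n, 4))
    stopf("rank regression needs at least %d samples (got %d)",
          max(min_n, 4), n)

  q_cov <- 0L
  if (!is.null(covariates)) {
    design <- covariate_design(covariates, n)
    q_cov <- ncol(design) - 1L   # eliminated model df beyond the intercept
    qr_d <- qr(design)
    mat <- t(qr.resid(qr_d, t(mat)))
    response <- drop(qr.resid(qr_d, matrix(response, ncol = 1)))
  }
  if (n - 2 - q_cov < 1)
    stopf("not enough residual degrees of freedom (n = %d, covariate df = %d)",
          n, q_cov)
  ry <- midrank(response)
  rx <- t(apply(mat, 1, midrank))
  cy <- ry - mean(ry)
  sy <- sum(cy^2)
  cx <- rx - rowMeans(rx)
  sx <- rowSums(cx^2)
  degenerate <- sx == 0 | sy == 0
  r <- as.numeric(cx %*% cy) / sqrt(pmax(sx, 1e-300) * max(sy, 1e-300))
  r[degenerate] <- 0
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  ## nested-model F test (1 numerator df): the null model is the eliminated
  ## covariates alone, so their model df are removed from the denominator
  df2 <- n - 2 - q_cov
  tstat <- r * sqrt(df2 / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = df2)
  if (n <= exact_max_n && is.null(covariates)) {
    perms <- all_permutations(n)
    for (i in which(!degenerate))
      p[i] <- exact_spearman_p(rx[i, ], ry, perms)
  }
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  data.frame(
    feature_id = rownames(mat) %||% sprintf("g%d", seq_len(nrow(mat))),
    statistic = tstat,
    sign = ifelse(r >= 0, "+", "-"),
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    method = "rank_regression",
    model = "none",
    flagged = p < alpha,
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis genetic association scan
#'
#' Applies the Kruskal-Wallis rank-sum test per marker under one of three
#' genetic models: genotypic (AA, AB, BB), dominant (AA vs AB+BB), or
#' recessive (AA+AB vs BB).  Missing calls are dropped per marker.  For
#' non-pseudoautosomal X markers in single-X samples the grouping uses the
#' two homozygote categories only (heterozygote calls there are a validation
#' error upstream, see [validate_genotypes()]).  Markers whose grouping
#' collapses to fewer than two non-empty groups are skipped with the reason
#' recorded.
#'
#' @param gt a `genotype_matrix`.
#' @param response named response vector (names = sample ids).
#' @param model genetic model.
#' @return AssociationTable data.frame (statistic = tie-corrected H, p from
#'   the chi-squared approximation) with a `skipped` attribute naming
#'   markers that could not be tested.
#' @export
kruskal_wallis_genetic <- function(gt, response,
                                   model = c("genotypic", "dominant", "recessive")) {
  model <- match.arg(model)
  samples <- intersect(colnames(gt$calls), names(response))
  if (!length(samples)) stopf("no samples shared between genotypes and response")
  resp <- response[samples]
  calls <- gt$calls[, samples, drop = FALSE]
  out <- vector("list", nrow(calls))
  skipped <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    keep <- cl != "missing" & !is.na(resp)
    cl <- cl[keep]; y <- resp[keep]
    grp <- switch(model,
      genotypic = cl,
      dominant = ifelse(cl == "AA", "AA", "AB+BB"),
      recessive = ifelse(cl == "BB", "BB", "AA+AB"))
    tab <- table(grp)
    if (length(tab[tab > 0]) < 2) {
      skipped <- c(skipped, sprintf("%s: single group under %s model",
                                    rownames(calls)[i], model))
      next
    }
    kw <- kruskal.test(y, factor(grp))
    h <- unname(kw$statistic)
    pv <- kw$p.value
    if (!is.finite(h)) { h <- 0; pv <- 1 }   # all responses tied
    out[[i]] <- data.frame(
      feature_id = rownames(calls)[i],
      statistic = h,
      sign = "+",
      p = pv,
      method = "kruskal_wallis",
      model = model,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(feature_id = character(0), statistic = numeric(0),
                      sign = character(0), p = numeric(0),
                      method = character(0), model = character(0))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res <- res[c("feature_id", "statistic", "sign", "p", "p_adj", "method", "model")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' LD-block Bonferroni adjustment
#'
#' Adds two Bonferroni-adjusted columns: `p_adj_gene` multiplies the raw p
#' by the number of LD blocks in the marker's gene, and `p_adj_genome`
#' multiplies by the total number of LD blocks in the panel (e.g. 768 in the
#' GHD panel, 563 in TS).  Both are clipped at 1.
#'
#' @param table AssociationTable with `feature_id`.
#' @param gene_blocks named integer: LD blocks in the marker's gene, per
#'   marker.
#' @param total_blocks total number of LD blocks.
#' @return the table with `p_adj_gene` and `p_adj_genome` columns.
#' @export
adjust_ld_bonferroni <- function(table, gene_blocks, total_blocks) {
  assert_count(total_blocks, "total_blocks")
  gb <- gene_blocks[table$feature_id]
  if (any(is.na(gb)))
    stopf("missing LD-block annotation for markers: %s",
          paste(head(table$feature_id[is.na(gb)], 5), collapse = ", "))
  if (any(gb < 1)) stopf("per-gene LD-block counts must be >= 1")
  table$p_adj_gene <- pmin(1, table$p * gb)
  table$p_adj_genome <- pmin(1, table$p * total_blocks)
  table
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param table AssociationTable with a `p` column.
#' @return the table with `p_adj` replaced by BH step-up adjusted values.
#' @export
adjust_fdr_bh <- function(table) {
  if (!nrow(table)) return(table)
  table$p_adj <- p.adjust(table$p, method = "BH")
  table
}

#' Variance filtering with an optional projection-score mode
#'
#' In fixed-count mode the `n_keep` highest-variance genes are retained.  In
#' projection-score mode a grid of candidate subset sizes is swept (genes
#' ranked by variance); for each subset the variance captured by the leading
#' `n_pc` principal components is compared with the same statistic after
#' independently permuting each gene row (a null baseline that preserves
#' per-gene variance but destroys inter-gene correlation).  The score rises
#' while added genes carry shared structure and plateaus once they are
#' noise; the retained subset is the plateau onset - the smallest size whose
#' marginal score gain per added gene falls below 10% of its average gain
#' (falling back to the score maximum when no plateau is found).
#'
#' @param mat genes x samples matrix.
#' @param n_keep number of genes to keep (fixed-count mode).
#' @param method `"count"` or `"projection"`.
#' @param n_pc leading components used by the projection score.
#' @param grid_size number of candidate sizes swept in projection mode.
#' @param seed seed for the permutation baseline.
#' @return the filtered matrix, with attribute `projection_score` in
#'   projection mode.
#' @export
variance_filter <- function(mat, n_keep = NULL,
                            method = c("count", "projection"),
                            n_pc = 2, grid_size = 12, seed = 1) {
  method <- match.arg(method)
  v <- apply(mat, 1, var)
  ord <- order(v, decreasing = TRUE)
  if (method == "count") {
    if (is.null(n_keep)) stopf("`n_keep` required in count mode")
    assert_count(n_keep, "n_keep")
    if (n_keep > nrow(mat)) stopf("n_keep exceeds gene count")
    return(mat[sort(ord[seq_len(n_keep)]), , drop = FALSE])
  }
  top_var <- function(m) {
    m <- m - rowMeans(m)
    d <- svd(m, nu = 0, nv = 0)$d
    sum(d[seq_len(min(n_pc, length(d)))]^2)
  }
  sizes <- unique(round(exp(seq(log(max(n_pc + 2, 5)),
                                log(nrow(mat)), length.out = grid_size))))
  scores <- with_seed(child_seed(seed, 61), vapply(sizes, function(k) {
    sub <- mat[ord[seq_len(k)], , drop = FALSE]
    null <- t(apply(sub, 1, sample))
    top_var(sub) - top_var(null)
  }, 0))
  best <- sizes[which.max(scores)]
  for (i in seq(2, length(sizes))) {
    gain <- (scores[i] - scores[i - 1]) / (sizes[i] - sizes[i - 1])
    if (is.finite(gain) && gain < 0.1 * scores[i] / sizes[i]) {
      best <- sizes[i]
      break
    }
  }
  out <- mat[sort(ord[seq_len(best)]), , drop = FALSE]
  attr(out, "projection_score") <- data.frame(size = sizes, score = scores)
  out
}
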