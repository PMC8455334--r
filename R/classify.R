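## ---------------------------------------------------------------------------
## Response-quartile labelling, SMOTE rebalancing, random-forest OOB
## classification, Boruta-style shadow-feature confirmation, PLS-DA and DAPC
## ordinations, and the clinical-vs-combined feature comparison.
## ---------------------------------------------------------------------------

#' Label low/mid/high response quartiles
#'
#' Samples are ranked ascending on the response; the `floor(n/4)` smallest
#' become `low`, the `floor(n/4)` largest `high`, the rest `mid`.  Ties at a
#' quartile boundary are broken by sample id, so the labelling is
#' deterministic; an all-equal response triggers a warning but still yields
#' the deterministic id-ordered split.
#'
#' @param response named numeric vector (names = sample ids); must be finite.
#' @param endpoint free-text descriptor recorded with the labels (e.g.
#'   `"hv_y1"` or `"cm_5y"`).
#' @return object of class `response_classes`: named factor with levels
#'   `low`, `mid`, `high`, plus attributes `endpoint` and `quartile_size`.
#' @export
quartile_labels <- function(response, endpoint = "response") {
  if (is.null(names(response))) names(response) <- sprintf("S%03d", seq_along(response))
  response <- response[!is.na(response)]
  n <- length(response)
  if (n < 8) stopf("quartile labelling needs at least 8 samples (got %d)", n)
  if (any(!is.finite(response))) stopf("responses must be finite")
  if (length(unique(response)) == 1)
    warnf("all responses equal; quartile split is id-ordered only")
  q <- n %/% 4
  ord <- order(response, names(response))
  lab <- rep("mid", n)
  lab[ord[seq_len(q)]] <- "low"
  lab[ord[seq(n - q + 1L, n)]] <- "high"
  out <- factor(lab, levels = c("low", "mid", "high"))
  names(out) <- names(response)
  attr(out, "endpoint") <- endpoint
  attr(out, "quartile_size") <- q
  out
}

#' SMOTE oversampling of the minority class
#'
#' Synthesizes minority samples by interpolation: each synthetic point is
#' `x + u * (x_nn - x)` with `u ~ U(0, 1)` and `x_nn` one of the `k`
#' Euclidean nearest minority neighbours of `x`, chosen at random.  The
#' minority class is oversampled to match the majority count; original
#' samples are retained unchanged.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (factor or vector), aligned with rows of `X`.
#' @param k number of nearest neighbours (capped at minority size - 1).
#' @param seed integer seed.
#' @return list with `X`, `y` (balanced), and `synthetic` (logical marking
#'   the appended synthetic rows).
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stopf("SMOTE requires binary labels")
  assert_count(k, "k")
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < 2) stopf("minority class of size 1: no neighbour to interpolate")
  need <- n_maj - n_min
  if (need == 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  k <- min(k, n_min - 1)
  Xm <- X[y == minority, , drop = FALSE]
  d <- as.matrix(dist(Xm))
  diag(d) <- Inf
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(d[i, ])[seq_len(k)]
  base_idx <- rep_len(seq_len(n_min), need)
  syn <- with_seed(child_seed(seed, 71), {
    t(vapply(seq_len(need), function(i) {
      b <- base_idx[i]
      nb <- nn[b, sample.int(k, 1)]
      u <- runif(1)
      Xm[b, ] + u * (Xm[nb, ] - Xm[b, ])
    }, numeric(ncol(X))))
  })
  colnames(syn) <- colnames(X)
  rownames(syn) <- sprintf("synth%03d", seq_len(need))
  min_idx <- which(y == minority)
  list(X = rbind(X, syn),
       y = factor(c(as.character(y), rep(minority, need)), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)),
       parent = min_idx[base_idx])
}

#' Random-forest classification with out-of-bag metrics
#'
#' Fits a `randomForest` ensemble (default 1000 trees, `sqrt(p)` features
#' per split) and reports out-of-bag error, the AUC of the OOB class
#' probability votes with a DeLong 95% confidence interval, and permutation
#' importances.  With `smote = TRUE` the training set is first balanced by
#' [smote_oversample()] and OOB metrics are computed over the original
#' samples with leakage-aware tree exclusion: a sample's OOB vote uses only
#' trees whose bootstrap bag contains neither the sample itself nor any
#' synthetic point interpolated from it, so information from a sample never
#' reaches its own evaluation through its synthetic copies (see the methods
#' vignette).
#'
#' @param X samples x features matrix.
#' @param y binary labels aligned with rows of `X`.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @param smote balance classes with SMOTE before fitting.
#' @param smote_k SMOTE neighbour count.
#' @return object of class `classification_report`: `auc`, `auc_ci`
#'   (2-vector), `oob_error`, `importance`, `votes`, `n_trees`, `seed`.
#' @export
rf_classify_oob <- function(X, y, n_trees = 1000, seed = 1,
                            smote = FALSE, smote_k = 5) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stopf("binary classification expected")
  if (any(table(y) < 2)) stopf("each class needs at least 2 members")
  assert_count(n_trees, "n_trees")
  y0 <- y
  n0 <- nrow(X)
  parent <- integer(0)
  if (smote) {
    sm <- smote_oversample(X, y, k = smote_k, seed = child_seed(seed, 72))
    X <- sm$X; y <- sm$y; parent <- sm$parent
  }
  colnames(X) <- make.names(colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
                            unique = TRUE)
  rf <- with_seed(child_seed(seed, 73),
                  randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                             importance = TRUE,
                                             keep.inbag = smote))
  pos <- levels(y)[2]
  if (!smote) {
    votes <- rf$votes
    prob <- votes[, pos]
  } else {
    ## leakage-aware OOB: drop trees whose bag holds the sample or any of
    ## its synthetic derivatives; fall back to plain OOB trees when none
    ## qualify
    ind <- predict(rf, X, predict.all = TRUE)$individual
    inbag <- rf$inbag
    prob <- vapply(seq_len(n0), function(i) {
      ok <- inbag[i, ] == 0
      kids <- n0 + which(parent == i)
      if (length(kids)) {
        strict <- ok & colSums(inbag[kids, , drop = FALSE]) == 0
        if (any(strict)) ok <- strict
      }
      if (!any(ok)) return(NA_real_)
      mean(ind[i, ok] == pos)
    }, 0)
    prob[is.na(prob)] <- 0.5
    votes <- cbind(1 - prob, prob)
    colnames(votes) <- levels(y)
  }
  votes <- votes[seq_len(n0), , drop = FALSE]
  prob <- prob[seq_len(n0)]
  pred <- factor(ifelse(prob > 0.5, pos, levels(y)[1]), levels = levels(y))
  oob_error <- mean(pred != y0)
  roc <- pROC::roc(response = y0, predictor = prob, quiet = TRUE,
                   levels = levels(y), direction = "<")
  ci <- suppressWarnings(
    tryCatch(as.numeric(pROC::ci.auc(roc, method = "delong"))[c(1, 3)],
             error = function(e) c(NA_real_, NA_real_)))
  structure(list(
    auc = as.numeric(pROC::auc(roc)),
    auc_ci = ci,
    oob_error = oob_error,
    importance = randomForest::importance(rf, type = 1)[, 1],
    votes = votes,
    n_trees = n_trees,
    seed = seed
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("rf: AUC %.3f (95%% CI %.3f-%.3f), OOB error %.3f, %d trees\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$oob_error, x$n_trees))
  invisible(x)
}

#' Boruta-style all-relevant feature selection
#'
#' Each iteration appends a column-permuted shadow copy of every feature,
#' fits a random forest (via `ranger` permutation importance), and records
#' for each real feature whether its importance exceeds the maximum shadow
#' importance (a "hit").  Features are classified by a two-sided binomial
#' test of the hit count against 0.5 with Bonferroni correction over
#' features: significantly more hits than chance = `confirmed`,
#' significantly fewer = `rejected`, undecided after `n_iter` iterations =
#' `tentative`.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param n_iter number of shadow iterations (default 100).
#' @param seed integer seed.
#' @param n_trees trees per internal forest.
#' @param alpha Bonferroni-corrected decision level.
#' @return list with `status` (named factor: confirmed/tentative/rejected),
#'   `hits`, `n_iter`, and `shadow` (per-iteration max/mean/min shadow
#'   importance).
#' @export
boruta_select <- function(X, y, n_iter = 100, seed = 1, n_trees = 200,
                          alpha = 0.01) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < 2)) stopf("each class needs at least 2 members")
  if (n_iter < 10) stopf("`n_iter` must be at least 10")
  p <- ncol(X)
  feat <- colnames(X) %||% sprintf("f%d", seq_len(p))
  colnames(X) <- feat
  hits <- setNames(integer(p), feat)
  shadow <- matrix(NA_real_, n_iter, 3,
                   dimnames = list(NULL, c("max", "mean", "min")))
  with_seed(child_seed(seed, 81), {
    for (it in seq_len(n_iter)) {
      Xs <- apply(X, 2, sample)
      colnames(Xs) <- paste0("shadow_", feat)
      df <- data.frame(cbind(X, Xs), check.names = TRUE)
      df$.y <- y
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            num.trees = n_trees, importance = "permutation",
                            seed = child_seed(seed, 81 + it),
                            num.threads = 1)
      imp <- fit$variable.importance
      sh <- imp[grepl("^shadow_", names(imp))]
      re <- imp[!grepl("^shadow_", names(imp))]
      shadow[it, ] <- c(max(sh), mean(sh), min(sh))
      hits <- hits + as.integer(re[make.names(feat)] > max(sh))
    }
  })
  p_hi <- pbinom(hits - 1L, n_iter, 0.5, lower.tail = FALSE)
  p_lo <- pbinom(hits, n_iter, 0.5)
  p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
  status <- rep("tentative", p)
  status[p_two * p < alpha & hits > n_iter / 2] <- "confirmed"
  status[p_two * p < alpha & hits < n_iter / 2] <- "rejected"
  list(status = setNames(factor(status,
                                levels = c("confirmed", "tentative", "rejected")),
                         feat),
       hits = hits, n_iter = n_iter, shadow = shadow)
}

#' PLS discriminant analysis (NIPALS)
#'
#' Iterative latent-variable extraction against the indicator-coded class
#' matrix with deflation (NIPALS).  `X` is column-centred internally.
#' Returns per-sample scores, per-feature loadings and weights, and the AUC
#' of the latent-space nearest-centroid rule.
#'
#' @param X samples x features matrix.
#' @param y class labels (binary or multi-class for scores; AUC reported
#'   for binary only).
#' @param n_components number of latent components
#'   (`<= min(n - 1, p)`).
#' @param max_iter,tol NIPALS iteration controls.
#' @return list with `scores`, `loadings`, `weights`, `y_loadings`, `auc`.
#' @export
pls_da_fit <- function(X, y, n_components = 2, max_iter = 200, tol = 1e-9) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); p <- ncol(X)
  assert_count(n_components, "n_components")
  if (n_components > min(n - 1, p))
    stopf("n_components exceeds min(n - 1, p) = %d", min(n - 1, p))
  if (all(apply(X, 2, var) == 0)) stopf("X has zero variance")
  Y <- model.matrix(~ 0 + y)
  colnames(Y) <- levels(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Tm <- matrix(0, n, n_components)
  W <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, ncol(Y), n_components, dimnames = list(colnames(Y), NULL))
  for (h in seq_len(n_components)) {
    u <- Yc[, which.max(apply(Yc, 2, var))]
    w <- crossprod(Xc, u)
    for (it in seq_len(max_iter)) {
      w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      q <- crossprod(Yc, tt) / sum(tt^2)
      u_new <- Yc %*% q / sum(q^2)
      w_new <- crossprod(Xc, u_new)
      if (sqrt(sum((w_new / sqrt(sum(w_new^2)) - w)^2)) < tol) { w <- w_new; break }
      w <- w_new; u <- u_new
    }
    w <- w / sqrt(sum(w^2))
    tt <- Xc %*% w
    pp <- crossprod(Xc, tt) / sum(tt^2)
    q <- crossprod(Yc, tt) / sum(tt^2)
    Xc <- Xc - tt %*% t(pp)
    Yc <- Yc - tt %*% t(q)
    Tm[, h] <- tt; W[, h] <- w; P[, h] <- pp; Q[, h] <- q
  }
  rownames(Tm) <- rownames(X)
  auc <- NA_real_
  if (nlevels(y) == 2) {
    cent <- lapply(levels(y), function(l) colMeans(Tm[y == l, , drop = FALSE]))
    d1 <- sqrt(colSums((t(Tm) - cent[[1]])^2))
    d2 <- sqrt(colSums((t(Tm) - cent[[2]])^2))
    score <- d1 - d2   # larger = closer to level 2
    roc <- pROC::roc(response = y, predictor = score, quiet = TRUE,
                     levels = levels(y), direction = "<")
    auc <- as.numeric(pROC::auc(roc))
  }
  list(scores = Tm, loadings = P, weights = W, y_loadings = Q, auc = auc)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces `X` to `n_pcs` principal components and runs linear discriminant
#' analysis on the retained scores.  The discriminant functions optimise
#' between-group relative to within-group variation.
#'
#' @param X samples x features matrix.
#' @param groups group labels (at least 2 groups, each with >= 2 members).
#' @param n_pcs number of retained principal components (`< n`).
#' @return list with `discriminants` (per-sample discriminant scores),
#'   `predicted`, `accuracy` (reassignment), `pca` and `lda` fits.
#' @export
dapc_fit <- function(X, groups, n_pcs) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 members")
  assert_count(n_pcs, "n_pcs")
  if (n_pcs >= nrow(X)) stopf("n_pcs must be smaller than the sample count")
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  S <- pca$x[, seq_len(n_pcs), drop = FALSE]
  ld <- MASS::lda(S, grouping = groups)
  pr <- predict(ld, S)
  list(discriminants = pr$x, predicted = pr$class,
       accuracy = mean(pr$class == groups), pca = pca, lda = ld)
}

#' Compare clinical-only and clinical+transcriptome classification
#'
#' Runs two [rf_classify_oob()] fits sharing seed and labels - one on the
#' baseline clinical features (age, weight SDS, birthweight SDS, distance to
#' target height SDS, plus peak GH where present), one on clinical features
#' plus the signature-gene expression - and reports the AUC and OOB-error
#' deltas.
#'
#' @param clinical samples x clinical-features matrix (or data.frame).
#' @param signature_expr signature genes x samples expression matrix (may
#'   have zero rows for a clinical-only comparison of pure noise).
#' @param labels binary labels named by sample id.
#' @param n_trees,seed,smote forwarded to [rf_classify_oob()].
#' @return list with `clinical`, `combined` (classification reports),
#'   `delta_auc`, `delta_oob`.
#' @export
compare_phenotype_models <- function(clinical, signature_expr, labels,
                                     n_trees = 1000, seed = 1, smote = TRUE) {
  clinical <- as.matrix(clinical)
  ids <- rownames(clinical)
  if (is.null(ids)) stopf("clinical matrix needs sample-id rownames")
  if (!setequal(ids, names(labels)))
    stopf("clinical features and labels cover different samples")
  labels <- labels[ids]
  if (ncol(signature_expr) && !all(ids %in% colnames(signature_expr)))
    stopf("expression matrix misses samples present in the clinical features")
  comb <- if (nrow(signature_expr))
    cbind(clinical, t(signature_expr[, ids, drop = FALSE])) else clinical
  rep_clin <- rf_classify_oob(clinical, labels, n_trees = n_trees,
                              seed = seed, smote = smote)
  rep_comb <- rf_classify_oob(comb, labels, n_trees = n_trees,
                              seed = seed, smote = smote)
  list(clinical = rep_clin, combined = rep_comb,
       delta_auc = rep_comb$auc - rep_clin$auc,
       delta_oob = rep_comb$oob_error - rep_clin$oob_error)
}
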