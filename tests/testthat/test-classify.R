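test_that("quartile labels follow the floor(n/4) rule with id tie-break", {
  r <- setNames(1:8, paste0("s", 1:8))
  lab <- quartile_labels(r)
  expect_setequal(names(lab)[lab == "low"], c("s1", "s2"))
  expect_setequal(names(lab)[lab == "high"], c("s7", "s8"))
  expect_equal(attr(lab, "quartile_size"), 2L)

  r71 <- setNames(rnorm(71), sprintf("p%03d", 1:71))
  lab71 <- quartile_labels(r71)
  expect_equal(sum(lab71 == "low"), 17L)
  expect_equal(sum(lab71 == "high"), 17L)

  ## ties broken by sample id, deterministically
  rt <- setNames(c(5, 5, 5, 5, 5, 5, 5, 5), paste0("s", 8:1))
  expect_warning(labt <- quartile_labels(rt), "id-ordered")
  expect_setequal(names(labt)[labt == "low"], c("s1", "s2"))
  expect_identical(labt, suppressWarnings(quartile_labels(rt)))

  expect_error(quartile_labels(setNames(1:5, paste0("s", 1:5))), "at least 8")
})

test_that("SMOTE balances classes with segment-interpolated points", {
  set.seed(5)
  X <- rbind(matrix(rnorm(5 * 3, mean = 4), 5, 3),
             matrix(rnorm(20 * 3), 20, 3))
  rownames(X) <- paste0("r", 1:25)
  y <- factor(rep(c("min", "maj"), c(5, 20)), levels = c("maj", "min"))
  sm <- smote_oversample(X, y, k = 3, seed = 5)
  expect_equal(as.integer(table(sm$y)), c(20L, 20L))
  expect_equal(sum(sm$synthetic), 15L)
  expect_equal(sm$X[!sm$synthetic, ], X)

  ## every synthetic point lies on a segment between two minority points
  Xm <- X[y == "min", ]
  syn <- sm$X[sm$synthetic, ]
  for (i in seq_len(nrow(syn))) {
    on_seg <- FALSE
    for (a in seq_len(nrow(Xm) - 1)) for (b in seq(a + 1, nrow(Xm))) {
      d <- Xm[b, ] - Xm[a, ]
      u <- sum((syn[i, ] - Xm[a, ]) * d) / sum(d * d)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((Xm[a, ] + u * d - syn[i, ])^2)) < 1e-9) on_seg <- TRUE
    }
    expect_true(on_seg)
  }

  ## k = 1 with two minority points: synthetic points on that one segment
  X2 <- rbind(p = c(0, 0), q = c(1, 1), matrix(rnorm(12), 6, 2))
  y2 <- factor(rep(c("m", "M"), c(2, 6)), levels = c("M", "m"))
  sm2 <- smote_oversample(X2, y2, k = 1, seed = 2)
  syn2 <- sm2$X[sm2$synthetic, , drop = FALSE]
  expect_true(all(abs(syn2[, 1] - syn2[, 2]) < 1e-12))
  expect_true(all(syn2 >= 0 & syn2 <= 1))

  expect_error(smote_oversample(rbind(c(0, 0), matrix(1, 4, 2)),
                                factor(c("m", rep("M", 4))), seed = 1),
               "size 1")
  ## already balanced: unchanged
  smb <- smote_oversample(X2[1:4, ], factor(c("a", "a", "b", "b")), seed = 1)
  expect_equal(sum(smb$synthetic), 0L)
})

test_that("random forest OOB metrics detect separable structure and stay null-calibrated", {
  ## a perfectly separating feature
  for (s in 1:3) {
    set.seed(s)
    X <- cbind(sep = c(rnorm(30, -3), rnorm(30, 3)),
               matrix(rnorm(60 * 5), 60, 5))
    y <- factor(rep(c("lo", "hi"), each = 30), levels = c("lo", "hi"))
    rep <- rf_classify_oob(X, y, n_trees = 500, seed = s)
    expect_lte(rep$oob_error, 0.05)
    expect_gte(rep$auc, 0.98)
    expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
    expect_equal(rep$n_trees, 500)
  }

  ## pure-noise features, permuted labels: AUC near 0.5
  aucs <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(100 * 20), 100, 20)
    y <- factor(rep(c("a", "b"), 50))
    rf_classify_oob(X, y, n_trees = 300, seed = s)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  ## reproducibility under a fixed seed
  set.seed(99)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- factor(rep(c("a", "b"), 20))
  expect_identical(rf_classify_oob(X, y, n_trees = 100, seed = 3)$votes,
                   rf_classify_oob(X, y, n_trees = 100, seed = 3)$votes)

  expect_error(rf_classify_oob(X[1:3, ], factor(c("a", "a", "b"))),
               "at least 2")
})

test_that("Boruta confirms a strong planted feature and rejects noise", {
  set.seed(11)
  X <- matrix(rnorm(100 * 30), 100, 30)
  colnames(X) <- sprintf("f%02d", 1:30)
  y <- factor(ifelse(2 * X[, 1] + rnorm(100) > 0, "a", "b"))
  bs <- boruta_select(X, y, n_iter = 60, seed = 11)
  expect_equal(unname(as.character(bs$status["f01"])), "confirmed")
  expect_gt(mean(bs$status[-1] == "rejected"), 0.9)
  expect_equal(ncol(bs$shadow), 3L)
  expect_true(all(bs$shadow[, "max"] >= bs$shadow[, "mean"]))
  expect_error(boruta_select(X, y, n_iter = 5), "at least 10")
})

test_that("PLS-DA first component matches the closed form and separates groups", {
  set.seed(13)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- factor(rep(c("g1", "g2"), each = 20))
  fit <- pls_da_fit(X, y, n_components = 2)
  ## first weight vector proportional to X'y (centred)
  Xc <- scale(X, scale = FALSE)
  yc <- as.numeric(y == "g2") - mean(y == "g2")
  w_closed <- crossprod(Xc, yc)
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  cosine <- abs(sum(fit$weights[, 1] * w_closed))
  expect_gt(cosine, 1 - 1e-8)

  ## groups shifted along one axis: component-1 scores separate completely
  X2 <- matrix(rnorm(30 * 5, sd = 0.2), 30, 5)
  X2[16:30, 1] <- X2[16:30, 1] + 5
  y2 <- factor(rep(c("a", "b"), each = 15))
  f2 <- pls_da_fit(X2, y2, n_components = 1)
  s1 <- f2$scores[, 1]
  expect_true(max(s1[y2 == "a"]) < min(s1[y2 == "b"]) ||
                min(s1[y2 == "a"]) > max(s1[y2 == "b"]))
  expect_gte(f2$auc, 0.99)

  expect_error(pls_da_fit(X, y, n_components = 50), "n_components")
  expect_error(pls_da_fit(matrix(1, 10, 3), factor(rep(c("a", "b"), 5)), 1),
               "zero variance")
})

test_that("PLS-DA agrees with the mixOmics reference on loadings", {
  set.seed(17)
  X <- matrix(rnorm(36 * 8), 36, 8)
  X[19:36, 1:2] <- X[19:36, 1:2] + 1.5
  y <- factor(rep(c("a", "b"), each = 18))
  mine <- pls_da_fit(X, y, n_components = 2)
  ref <- suppressMessages(mixOmics::plsda(X, y, ncomp = 2, scale = FALSE))
  for (h in 1:2) {
    cosine <- abs(sum(mine$weights[, h] * ref$loadings$X[, h])) /
      sqrt(sum(ref$loadings$X[, h]^2))
    expect_gt(cosine, 0.99)
  }
})

test_that("DAPC reduces to LDA at full rank and resolves separated clusters", {
  set.seed(19)
  X <- matrix(rnorm(50 * 4), 50, 4)
  grp <- factor(rep(c("u", "v"), each = 25))
  X[grp == "v", ] <- X[grp == "v", ] + 1
  d <- dapc_fit(X, grp, n_pcs = 4)
  ld <- MASS::lda(X, grouping = grp)
  plain <- predict(ld, X)$x
  expect_gt(abs(cor(d$discriminants[, 1], plain[, 1])), 1 - 1e-8)

  ## well-separated clusters: perfect reassignment
  X2 <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
              matrix(rnorm(40, 6, 0.3), 20, 2))
  g2 <- factor(rep(c("a", "b"), each = 20))
  expect_equal(dapc_fit(X2, g2, n_pcs = 2)$accuracy, 1)

  ## identical groups: discriminant separates nothing
  X3 <- matrix(rnorm(60 * 3), 60, 3)
  g3 <- factor(rep(c("a", "b"), 30))
  d3 <- dapc_fit(X3, g3, n_pcs = 2)
  expect_lt(d3$accuracy, 0.75)

  expect_error(dapc_fit(X2, factor(rep("a", 40)), 2), "at least 2 groups")
  expect_error(dapc_fit(X2, g2, n_pcs = 40), "smaller than the sample")
})

test_that("clinical-vs-combined comparison validates inputs and reports deltas", {
  fx <- toy_cohort(seed = 21, n_genes = 150)
  ph <- fx$phenotype[fx$phenotype$condition == "GHD", ]
  resp <- setNames(ph$hv_y1, ph$sample_id)
  lab <- quartile_labels(resp)
  bin <- factor(ifelse(lab == "low", "low", "rest"), levels = c("rest", "low"))
  names(bin) <- names(lab)
  clin <- netsig:::clinical_features(ph)
  genes <- fx$truth$planted_module_genes
  cmp <- compare_phenotype_models(clin, fx$expression[genes, ph$sample_id],
                                  bin, n_trees = 200, seed = 21)
  expect_s3_class(cmp$clinical, "classification_report")
  expect_equal(cmp$delta_auc, cmp$combined$auc - cmp$clinical$auc)
  expect_equal(cmp$delta_oob, cmp$combined$oob_error - cmp$clinical$oob_error)

  expect_error(compare_phenotype_models(clin[-1, ],
                                        fx$expression[genes, ph$sample_id],
                                        bin, n_trees = 50, seed = 1),
               "different samples")
})
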