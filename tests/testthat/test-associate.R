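test_that("residualization equals within-group centring for a nominal factor", {
  m <- matrix(c(1, 2, 3, 4), nrow = 1)
  cov <- data.frame(g = c("A", "A", "B", "B"))
  expect_equal(unname(residualize_covariates(m, cov)[1, ]),
               c(-0.5, 0.5, -0.5, 0.5))
  ## constant covariate reduces to mean-centring
  expect_equal(unname(residualize_covariates(m, data.frame(c = rep("A", 4)))[1, ]),
               c(1, 2, 3, 4) - 2.5)
  expect_equal(unname(residualize_covariates(m)[1, ]), c(1, 2, 3, 4) - 2.5)
})

test_that("residuals match the normal-equations oracle and are orthogonal", {
  set.seed(42)
  m <- matrix(rnorm(120), nrow = 6, ncol = 20,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:20)))
  cov <- data.frame(z = rnorm(20), grp = rep(c("u", "v"), 10))
  res <- residualize_covariates(m, cov)
  D <- model.matrix(~ z + grp, data = cov)
  beta_or <- solve(t(D) %*% D, t(D) %*% t(m))
  expect_equal(res, m - t(D %*% beta_or), tolerance = 1e-10)
  expect_lt(max(abs(res %*% D)), 1e-10)

  ## aliased design is rejected with the column named
  cov2 <- data.frame(a = 1:20, b = 2 * (1:20))
  expect_error(residualize_covariates(m, cov2), "rank deficient")
})

test_that("rank regression matches Spearman theory and handles degeneracy", {
  ## strictly monotone expression: positive sign, tiny p, Spearman-t oracle
  y <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 0.1)
  x <- rank(y) + 0   # strictly increasing in response, no ties
  m <- rbind(mono = x, flat = rep(1, 10))
  colnames(m) <- names(y) <- paste0("s", 1:10)
  tab <- rank_regression_scan(m, y, alpha = 0.01, exact_max_n = 0)
  expect_equal(tab$sign[1], "+")
  expect_lt(tab$p[1], 1e-4)
  expect_true(tab$degenerate[2])
  expect_equal(tab$p[2], 1)

  ## t-approximation agrees with cor.test for moderate n without ties
  set.seed(7)
  xx <- rnorm(30); yy <- 0.4 * xx + rnorm(30)
  names(yy) <- paste0("s", 1:30)
  m2 <- matrix(xx, 1, dimnames = list("g", names(yy)))
  t2 <- rank_regression_scan(m2, yy)
  ct <- suppressWarnings(cor.test(xx, yy, method = "spearman", exact = FALSE))
  expect_equal(t2$p, ct$p.value, tolerance = 1e-9)

  ## exact permutation path equals the enumeration oracle for n = 5..8
  for (n in 5:8) {
    set.seed(n)
    xs <- rnorm(n); ys <- rnorm(n)
    names(ys) <- paste0("s", seq_len(n))
    ms <- matrix(xs, 1, dimnames = list("g", names(ys)))
    got <- rank_regression_scan(ms, ys, exact_max_n = 8, min_n = 4)$p
    expect_equal(got, spearman_perm_oracle(xs, ys), tolerance = 1e-12)
  }

  expect_error(rank_regression_scan(m[, 1:5], y[1:5]), "at least 8")
})

test_that("scan results are invariant to sample order", {
  fx <- toy_cohort(seed = 9, n_genes = 80)
  ph <- fx$phenotype[fx$phenotype$condition == "GHD", ]
  resp <- setNames(ph$hv_y1, ph$sample_id)
  m <- fx$expression[, ph$sample_id]
  t1 <- rank_regression_scan(m, resp)
  perm <- sample(ncol(m))
  t2 <- rank_regression_scan(m[, perm], resp[perm])
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-12)
})

test_that("Kruskal-Wallis genetic models reproduce the rank-sum formula", {
  gt <- list(
    calls = matrix(c("AA", "AA", "AB", "AB", "BB", "BB"), nrow = 1,
                   dimnames = list("m1", paste0("s", 1:6))),
    info = data.frame(marker_id = "m1", gene = "G", chromosome = "1",
                      ld_block_id = "LD1", pseudoautosomal = FALSE))
  class(gt) <- "genotype_matrix"
  resp <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  tab <- kruskal_wallis_genetic(gt, resp, "genotypic")
  expect_equal(tab$statistic, 4.571, tolerance = 1e-3)

  ## all responses equal -> H = 0, p = 1
  tab0 <- kruskal_wallis_genetic(gt, setNames(rep(2, 6), names(resp)),
                                 "genotypic")
  expect_equal(tab0$statistic, 0, tolerance = 1e-12)
  expect_equal(tab0$p, 1)

  ## dominant model groups AB with BB
  tabd <- kruskal_wallis_genetic(gt, resp, "dominant")
  expect_equal(tabd$statistic, unname(kruskal.test(
    resp, factor(c("AA", "AA", "g2", "g2", "g2", "g2")))$statistic),
    tolerance = 1e-12)

  ## single-group marker is skipped with a recorded reason
  gt$calls[1, ] <- "AA"
  tabs <- kruskal_wallis_genetic(gt, resp, "genotypic")
  expect_equal(nrow(tabs), 0)
  expect_match(attr(tabs, "skipped"), "single group")
})

test_that("Kruskal-Wallis H equals the brute-force formula on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(8:20, 1)
    g <- sample(c("AA", "AB", "BB"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- sample(1:6, n, replace = TRUE)  # ties on purpose
    got <- unname(kruskal.test(y, factor(g))$statistic)
    expect_equal(got, kw_oracle(y, g), tolerance = 1e-10)
  }
})

test_that("LD-block Bonferroni and BH adjustments follow their definitions", {
  tab <- data.frame(feature_id = c("m1", "m2", "m3"),
                    p = c(1e-4, 0.5, 0.03))
  gb <- c(m1 = 3L, m2 = 5L, m3 = 1L)
  adj <- adjust_ld_bonferroni(tab, gb, total_blocks = 768)
  expect_equal(adj$p_adj_genome[1], 1e-4 * 768)   # 0.0768
  expect_equal(adj$p_adj_genome[2], 1)            # clipped
  expect_equal(adj$p_adj_gene[3], 0.03)           # one block: unchanged
  expect_error(adjust_ld_bonferroni(tab, gb[1:2], 768), "missing LD-block")

  ## BH step-up definition
  t2 <- data.frame(feature_id = letters[1:4], p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adjust_fdr_bh(t2)$p_adj, rep(0.04, 4))
  t3 <- data.frame(feature_id = "a", p = 0.2)
  expect_equal(adjust_fdr_bh(t3)$p_adj, 0.2)
  ## permutation invariance
  set.seed(1)
  p <- runif(50)
  tA <- adjust_fdr_bh(data.frame(feature_id = paste0("f", 1:50), p = p))
  sh <- sample(50)
  tB <- adjust_fdr_bh(data.frame(feature_id = paste0("f", sh), p = p[sh]))
  expect_equal(tA$p_adj[sh], tB$p_adj)
  ## manual step-up oracle
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * 50 / seq_len(50))))
  expect_equal(tA$p_adj[o], pmin(1, stepup))
})

test_that("variance filter keeps the right genes in both modes", {
  set.seed(3)
  m <- rbind(matrix(rnorm(5 * 30, sd = 4), 5, 30),
             matrix(rnorm(95 * 30, sd = 0.05), 95, 30))
  rownames(m) <- sprintf("g%03d", 1:100)
  expect_equal(variance_filter(m, n_keep = nrow(m)), m)
  kept <- variance_filter(m, n_keep = 5)
  expect_setequal(rownames(kept), sprintf("g%03d", 1:5))
  expect_error(variance_filter(m, n_keep = 0), "n_keep")
  expect_error(variance_filter(m, n_keep = 101), "exceeds")

  ## projection mode finds the informative scale on 3-cluster data
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    G <- 300; n <- 60; m_inf <- 30
    cl <- rep(1:3, each = n / 3)
    X <- matrix(rnorm(G * n), G, n)
    centers <- matrix(rnorm(m_inf * 3, 0, 2), m_inf, 3)
    X[1:m_inf, ] <- X[1:m_inf, ] + centers[, cl]
    rownames(X) <- sprintf("g%03d", 1:G)
    vf <- variance_filter(X, method = "projection", n_pc = 2, seed = s)
    if (nrow(vf) >= m_inf && nrow(vf) <= 2 * m_inf) ok <- ok + 1
  }
  expect_gte(ok, 8)
})
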