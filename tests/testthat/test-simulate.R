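test_that("planted-partition interactome realizes the requested topology", {
  ## forced cases: complete module, disjoint cliques
  gi <- generate_interactome(10, module_sizes = 10, p_in = 1, p_out = 0, seed = 1)
  expect_equal(nrow(gi$interactome$edges), 45)
  expect_setequal(names(gi$membership)[gi$membership == 1], gi$interactome$nodes)

  gi2 <- generate_interactome(10, c(5, 5), p_in = 1, p_out = 0, seed = 1)
  expect_equal(nrow(gi2$interactome$edges), 20)
  g <- igraph::graph_from_edgelist(gi2$interactome$edges, directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_equal(sort(comp$csize), c(5, 5))

  ## realized within-module density within 3 binomial SDs of p_in
  gi3 <- generate_interactome(200, c(30, 30), p_in = 0.3, p_out = 0.01, seed = 1)
  for (b in 1:2) {
    mem <- names(gi3$membership)[gi3$membership == b]
    within <- sum(gi3$interactome$edges[, 1] %in% mem &
                    gi3$interactome$edges[, 2] %in% mem)
    n_pairs <- choose(30, 2)
    expect_lt(abs(within - 0.3 * n_pairs), 3 * sqrt(n_pairs * 0.3 * 0.7))
  }

  ## determinism and parameter validation
  expect_identical(generate_interactome(50, 10, 0.5, 0.01, seed = 7),
                   generate_interactome(50, 10, 0.5, 0.01, seed = 7))
  expect_error(generate_interactome(10, 20, 0.5, 0.01, seed = 1), "exceeds")
  expect_error(generate_interactome(10, 5, 0.2, 0.5, seed = 1), "p_out")
})

test_that("cohort response decomposes into clinical and latent components", {
  gi <- generate_interactome(80, 10, 0.5, 0.001, seed = 3)
  planted <- names(gi$membership)[gi$membership > 0]

  ## clinical_r2 = 1 with no residual noise makes the clinical regression exact
  tr1 <- synthetic_truth(planted, clinical_r2 = c(GHD = 1, TS = 1),
                         bio_r2 = 0, seed = 3)
  co <- generate_cohort(tr1, gi$interactome, n_genes_expressed = 100,
                        seed = 3, hv_noise_sd = 0)
  ts <- co$phenotype[co$phenotype$condition == "TS", ]
  fit <- lm(hv_y1 ~ age + weight_sds + birthweight_sds + dth_sds, data = ts)
  expect_gt(summary(fit)$r.squared, 1 - 1e-6)

  ## height velocity declines from year 1 to year 5 in every seed
  tr <- synthetic_truth(planted, seed = 3)
  declines <- sapply(1:20, function(s) {
    ph <- generate_cohort(tr, gi$interactome, n_genes_expressed = 100,
                          seed = s)$phenotype
    gh <- ph[ph$condition == "GHD", ]
    mean(gh$hv_y1) > mean(gh$hv_y5, na.rm = TRUE)
  })
  expect_true(all(declines))

  ## structural invariants
  ph <- generate_cohort(tr, gi$interactome, n_genes_expressed = 100,
                        seed = 11)$phenotype
  expect_true(all(!is.na(ph$hv_y1)))
  expect_true(all(ph$hv_y1 >= 0))
  tann <- as.matrix(ph[paste0("tanner_y", 1:5)])
  expect_true(all(tann[, -1] >= tann[, -5]))
  expect_true(all(is.na(ph$peak_gh) == (ph$condition == "TS")))

  expect_error(generate_cohort(tr, gi$interactome,
                               n_per_condition = c(GHD = 5, TS = 40),
                               n_genes_expressed = 100, seed = 1),
               "at least 8")
})

test_that("realized clinical R2 tracks the requested share", {
  gi <- generate_interactome(80, 10, 0.5, 0.001, seed = 5)
  planted <- names(gi$membership)[gi$membership > 0]
  tr <- synthetic_truth(planted, clinical_r2 = c(GHD = 0.61, TS = 0.46),
                        bio_r2 = 0.2, seed = 5)
  r2 <- sapply(1:20, function(s) {
    ph <- generate_cohort(tr, gi$interactome, n_genes_expressed = 100,
                          seed = s)$phenotype
    gh <- ph[ph$condition == "GHD", ]
    summary(lm(hv_y1 ~ age + weight_sds + birthweight_sds + dth_sds +
                 log(peak_gh), data = gh))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.61), 0.1)
})

test_that("genotype generator respects LD blocks and X-chromosome dosage", {
  gi <- generate_interactome(60, 10, 0.5, 0.001, seed = 2)
  tr <- synthetic_truth(names(gi$membership)[gi$membership > 0], seed = 2)
  ph <- generate_cohort(tr, gi$interactome, n_genes_expressed = 80,
                        seed = 2)$phenotype

  gt <- generate_genotypes(200, 120, ph, seed = 2)
  expect_true(all(gt$calls %in% c("AA", "AB", "BB", "missing")))
  expect_silent(validate_genotypes(gt, ph))

  ## X markers carry no heterozygotes in single-X samples
  on_x <- gt$info$chromosome == "X" & !gt$info$pseudoautosomal
  single <- ph$condition == "TS" | (ph$condition == "GHD" & ph$sex == "M")
  expect_true(any(on_x))
  expect_false(any(gt$calls[on_x, ph$sample_id[single]] == "AB"))

  ## one marker per block -> between-marker correlation near zero
  gt1 <- generate_genotypes(100, 100, ph, seed = 4)
  dose <- apply(gt1$calls, 1, function(cl)
    c(AA = 0, AB = 1, BB = 2, missing = NA)[cl])
  cors <- cor(dose, use = "pairwise.complete.obs")
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.08)

  ## within-block correlation is substantial
  gt2 <- generate_genotypes(100, 10, ph, seed = 4)
  d2 <- apply(gt2$calls, 1, function(cl)
    c(AA = 0, AB = 1, BB = 2, missing = NA)[cl])
  blk <- gt2$info$ld_block_id
  same <- outer(blk, blk, "==") & upper.tri(diag(length(blk)))
  c2 <- cor(d2, use = "pairwise.complete.obs")
  expect_gt(mean(c2[same], na.rm = TRUE), 0.5)

  expect_error(generate_genotypes(50, 10, ph,
                                  assoc_markers = c(MX = 1), seed = 1),
               "not in panel")
})

test_that("null genotype panels give uniform Kruskal-Wallis p-values", {
  gi <- generate_interactome(60, 10, 0.5, 0.001, seed = 9)
  tr <- synthetic_truth(names(gi$membership)[gi$membership > 0], seed = 9)
  ok <- 0
  for (s in 1:20) {
    ph <- generate_cohort(tr, gi$interactome, n_genes_expressed = 80,
                          seed = s + 100)$phenotype
    gt <- generate_genotypes(500, 300, ph, seed = s)
    resp <- setNames(ph$hv_y1, ph$sample_id)
    tab <- kruskal_wallis_genetic(gt, resp, "genotypic")
    ks <- suppressWarnings(stats::ks.test(tab$p, "punif"))
    if (ks$p.value > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("methylation generator stays in [0,1] and plants directional skew", {
  gi <- generate_interactome(60, 10, 0.5, 0.001, seed = 6)
  planted <- names(gi$membership)[gi$membership > 0]
  tr <- synthetic_truth(planted, seed = 6)
  ph <- generate_cohort(tr, gi$interactome, n_genes_expressed = 80,
                        seed = 6)$phenotype
  gh <- ph[ph$condition == "GHD", ]

  beta <- generate_methylation(tr, gh, n_genes = 400, n_associated = 100,
                               seed = 6)
  expect_true(all(beta >= 0 & beta <= 1))
  sgn <- attr(beta, "planted_sign")
  expect_equal(length(sgn), 100)
  expect_lt(abs(mean(sgn == -1) - 425 / 497),
            3 * sqrt((425 / 497) * (72 / 497) / 100))

  ## planted signs drive the realized correlations
  resp <- gh$hv_y1
  r <- apply(beta[names(sgn), gh$sample_id], 1, cor, y = resp,
             method = "spearman")
  expect_gt(mean(sign(r) == sgn), 0.95)

  ## zero effects centre correlations on zero
  tr0 <- synthetic_truth(planted, effect_strong = 0, effect_weak = 0, seed = 6)
  b0 <- generate_methylation(tr0, gh, n_genes = 200, n_associated = 60,
                             seed = 6, effect = 0)
  r0 <- apply(b0[, gh$sample_id], 1, cor, y = resp, method = "spearman")
  expect_lt(abs(mean(r0)), 0.05)

  expect_error(generate_methylation(tr, gh[1, , drop = FALSE], n_genes = 100),
               "at least 2 samples")
})

test_that("generators are bit-identical under a fixed seed", {
  gi <- generate_interactome(60, 10, 0.5, 0.001, seed = 8)
  tr <- synthetic_truth(names(gi$membership)[gi$membership > 0], seed = 8)
  a <- generate_cohort(tr, gi$interactome, n_genes_expressed = 80, seed = 8)
  b <- generate_cohort(tr, gi$interactome, n_genes_expressed = 80, seed = 8)
  expect_identical(a, b)
  pa <- a$phenotype
  expect_identical(generate_genotypes(50, 30, pa, seed = 8),
                   generate_genotypes(50, 30, pa, seed = 8))
  expect_identical(generate_methylation(tr, pa, n_genes = 100, seed = 8),
                   generate_methylation(tr, pa, n_genes = 100, seed = 8))
})
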