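## ---------------------------------------------------------------------------
## Synthetic-data generators: interactome, cohort, genotypes, methylation.
##
## The generators emulate the statistical structure the downstream analysis
## assumes: two conditions (GHD-like n = 70, TS-like n = 43), ~8,000 expressed
## genes, five annual height-velocity endpoints that decline over treatment
## years, clinical covariates explaining roughly half of response variance
## (0.61 GHD / 0.46 TS), a planted interactome module whose members carry
## condition-specific expression-response associations through a shared latent
## biological component, methylation skewed towards hypermethylation at low
## response (negative fraction 425/497), and SNP markers organised in LD
## blocks with X-chromosome homozygote-only calls in TS and male GHD samples.
## ---------------------------------------------------------------------------

#' Construct the planted ground truth of a synthetic experiment
#'
#' The truth object fixes everything the generators need to plant signal:
#' the planted module genes, their per-condition standardized effect sizes on
#' the latent biological component of growth response, the share of response
#' variance carried by clinical covariates and by the latent biological
#' component, and the fraction of methylation-response correlations forced
#' negative (hypermethylated at low response).
#'
#' Per-condition effects are drawn from a two-tier mixture: each planted gene
#' is a strong responder (|effect| = `effect_strong`) with probability 1/2 and
#' a weak responder (|effect| = `effect_weak`) otherwise, independently per
#' condition, with a random sign per gene and condition.  This makes the
#' per-gene significant sets of the two conditions overlap only weakly while
#' the planted module itself is shared - network-level recovery, not per-gene
#' agreement, is then the interesting test.
#'
#' @param planted_genes character vector of planted module gene ids.
#' @param clinical_r2 named fraction of response variance explained by
#'   clinical covariates per condition; defaults to the published regression
#'   figures (0.61 GHD, 0.46 TS).
#' @param bio_r2 fraction of response variance carried by the latent
#'   biological component that planted genes load on (free parameter of the
#'   generator; see the methods vignette).
#' @param neg_methyl_fraction fraction of planted methylation-response
#'   correlations forced negative; default 425/497.
#' @param effect_strong,effect_weak absolute standardized effect sizes of the
#'   two responder tiers.
#' @param seed integer seed governing the effect draw.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_genes,
                            clinical_r2 = c(GHD = 0.61, TS = 0.46),
                            bio_r2 = 0.2,
                            neg_methyl_fraction = 425 / 497,
                            effect_strong = 1.2,
                            effect_weak = 0.3,
                            seed = 1) {
  planted_genes <- unique(as.character(planted_genes))
  if (!length(planted_genes)) stopf("`planted_genes` must be non-empty")
  if (!all(c("GHD", "TS") %in% names(clinical_r2)))
    stopf("`clinical_r2` must be named with conditions GHD and TS")
  for (cc in names(clinical_r2)) assert_prob(clinical_r2[[cc]], "clinical_r2")
  assert_prob(bio_r2, "bio_r2")
  assert_prob(neg_methyl_fraction, "neg_methyl_fraction")
  if (any(clinical_r2 + bio_r2 > 1))
    stopf("clinical_r2 + bio_r2 must not exceed 1")
  effects <- with_seed(child_seed(seed, 11), {
    sapply(c("GHD", "TS"), function(cc) {
      mag <- ifelse(runif(length(planted_genes)) < 0.5,
                    effect_strong, effect_weak)
      sgn <- ifelse(runif(length(planted_genes)) < 0.5, 1, -1)
      setNames(mag * sgn, planted_genes)
    })
  })
  structure(list(
    planted_module_genes = planted_genes,
    per_condition_effect = effects,   # genes x conditions matrix
    clinical_r2 = clinical_r2,
    bio_r2 = bio_r2,
    neg_methyl_fraction = neg_methyl_fraction,
    rng_seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d planted genes; clinical R2 GHD=%.2f TS=%.2f; bio R2 %.2f; neg methyl %.3f\n",
    length(x$planted_module_genes), x$clinical_r2[["GHD"]],
    x$clinical_r2[["TS"]], x$bio_r2, x$neg_methyl_fraction))
  invisible(x)
}

#' Generate a planted-partition interactome
#'
#' Builds a simple undirected gene graph with planted dense modules
#' (within-module edge probability `p_in`), sparse inter-module and
#' module-background edges (`p_out`), and a preferentially attached
#' background: each background gene beyond the first two attaches to
#' `m_background` previously placed background genes with probability
#' proportional to their current degree (Barabasi-Albert scheme), producing
#' the hub-dominated periphery typical of protein-interaction networks.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes.
#' @param p_in within-module edge probability.
#' @param p_out between-module and module-background edge probability;
#'   must satisfy `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @param m_background edges added per background gene.
#' @return A list with `interactome` (class `interactome`: `nodes`,
#'   `edges` two-column character matrix) and `membership` (named integer,
#'   0 = background).
#' @export
generate_interactome <- function(n_genes, module_sizes, p_in, p_out, seed,
                                 m_background = 2) {
  assert_count(n_genes, "n_genes")
  if (!is.numeric(module_sizes) || any(module_sizes < 1))
    stopf("`module_sizes` must be positive counts")
  if (sum(module_sizes) > n_genes)
    stopf("sum(module_sizes) = %d exceeds n_genes = %d",
          sum(module_sizes), n_genes)
  assert_prob(p_in, "p_in")
  assert_prob(p_out, "p_out")
  if (p_out >= p_in && p_in < 1)
    stopf("`p_out` must be strictly smaller than `p_in`")
  if (p_out > p_in) stopf("`p_out` must not exceed `p_in`")

  ids <- sprintf("G%05d", seq_len(n_genes))
  n_mod <- sum(module_sizes)
  membership <- integer(n_genes)
  membership[seq_len(n_mod)] <- rep(seq_along(module_sizes), module_sizes)
  names(membership) <- ids

  with_seed(child_seed(seed, 21), {
    edges <- list()
    ## within/between module and module-background Bernoulli edges
    blocks <- split(seq_len(n_mod), membership[seq_len(n_mod)])
    pair_edges <- function(i_idx, j_idx, p) {
      if (p <= 0) return(NULL)
      grid <- expand.grid(i = i_idx, j = j_idx)
      grid <- grid[grid$i < grid$j, , drop = FALSE]
      keep <- runif(nrow(grid)) < p
      if (!any(keep)) return(NULL)
      cbind(ids[grid$i[keep]], ids[grid$j[keep]])
    }
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      edges[[length(edges) + 1L]] <- pair_edges(idx, idx, p_in)
      if (b < length(blocks))
        for (b2 in seq(b + 1L, length(blocks)))
          edges[[length(edges) + 1L]] <- pair_edges(idx, blocks[[b2]], p_out)
    }
    bg <- if (n_mod < n_genes) seq(n_mod + 1L, n_genes) else integer(0)
    if (length(bg)) {
      for (b in seq_along(blocks))
        edges[[length(edges) + 1L]] <- pair_edges(blocks[[b]], bg, p_out)
      ## preferential attachment among background genes
      if (length(bg) >= 2) {
        deg <- setNames(numeric(length(bg)), ids[bg])
        ba <- matrix(character(0), 0, 2)
        placed <- ids[bg[1]]
        deg[placed] <- 0
        for (k in seq(2, length(bg))) {
          v <- ids[bg[k]]
          m <- min(m_background, length(placed))
          w <- deg[placed] + 1
          tgt <- sample(placed, m, prob = w / sum(w))
          ba <- rbind(ba, cbind(rep(v, m), tgt))
          deg[v] <- m
          deg[tgt] <- deg[tgt] + 1
          placed <- c(placed, v)
        }
        edges[[length(edges) + 1L]] <- ba
      }
    }
    em <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
    if (is.null(em)) em <- matrix(character(0), 0, 2)
    ## canonical order, no duplicates, no self loops
    em <- unique(t(apply(em, 1, sort)))
    em <- em[em[, 1] != em[, 2], , drop = FALSE]
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
    list(interactome = new_interactome(ids, em), membership = membership)
  })
}

#' Build an interactome object
#'
#' @param nodes character vector of unique gene ids.
#' @param edges two-column character matrix of undirected edges.
#' @return Object of class `interactome`.
#' @export
new_interactome <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) || any(!nzchar(nodes)))
    stopf("interactome node ids must be unique non-empty strings")
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stopf("interactome has self-loops")
    miss <- setdiff(unique(c(edges)), nodes)
    if (length(miss))
      stopf("edge endpoints absent from node set: %s",
            paste(head(miss, 5), collapse = ", "))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stopf("interactome has duplicate edges")
  }
  structure(list(nodes = nodes, edges = edges), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

## interactome -> igraph, keeping isolated nodes
interactome_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) g <- igraph::add_edges(g, t(net$edges))
  g
}

## Table 1 height-velocity calibration (cm/year, mean and SD per year)
hv_calibration <- function() {
  list(
    GHD = list(mean = c(8.9, 7.4, 6.6, 6.1, 5.1),
               sd   = c(2.1, 1.6, 2.0, 2.3, 2.3),
               retain = c(1, 65, 65, 60, 53) / c(1, 71, 71, 71, 71)),
    TS  = list(mean = c(7.6, 6.0, 5.3, 4.7, 3.7),
               sd   = c(1.4, 1.1, 1.5, 1.8, 1.6),
               retain = c(1, 31, 40, 41, 33) / c(1, 43, 43, 43, 43))
  )
}

## fixed standardized weights of the clinical response model; the clinical
## score is a deterministic linear function of the covariates so that a
## linear regression on them recovers exactly clinical_r2 of the variance
clinical_weights <- function(condition) {
  if (condition == "GHD")
    c(age = -0.35, weight_sds = 0.20, birthweight_sds = 0.20,
      dth_sds = -0.35, peak_gh = -0.45)
  else
    c(age = -0.40, weight_sds = 0.30, birthweight_sds = 0.25, dth_sds = -0.40)
}

#' Generate a synthetic two-condition cohort with expression and phenotype
#'
#' Growth response follows a latent-component model: for each year `y`,
#' `hv_y = mu_y + sd_y * (sqrt(c) z_clin + sqrt(b) z_bio + sqrt(1-c-b) eps_y)`
#' where `z_clin` is a fixed standardized linear combination of the clinical
#' covariates (so covariates explain exactly `c = clinical_r2` of the
#' variance in expectation), `z_bio` is the latent biological component that
#' planted genes load on (`b = bio_r2`), and `eps_y` is year-specific noise.
#' Year means and SDs are calibrated to the published height-velocity
#' trajectories, which decline from year 1 to year 5.  Expression of planted
#' genes is baseline + batch/age/BMI covariate effects + per-condition effect
#' x `z_bio` + Gaussian noise; non-planted genes carry covariate effects and
#' noise only.
#'
#' @param truth a [synthetic_truth()] object.
#' @param interactome an `interactome`; planted genes must be nodes.
#' @param n_per_condition named integer vector, e.g. `c(GHD = 70, TS = 43)`;
#'   each must be at least 8 (quartile machinery is degenerate below that).
#' @param n_genes_expressed number of expressed genes; includes all
#'   interactome nodes (planted first) and synthetic filler genes.
#' @param seed integer seed.
#' @param hv_noise_sd multiplier on the year-specific noise component; 0
#'   removes `eps_y` entirely (useful to force `clinical_r2 = 1` exactly).
#' @return list with `expression` (genes x samples matrix) and `phenotype`
#'   (data.frame, one row per sample).
#' @export
generate_cohort <- function(truth, interactome,
                            n_per_condition = c(GHD = 70, TS = 43),
                            n_genes_expressed = 8000, seed = 1,
                            hv_noise_sd = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(interactome, "interactome"))
  if (!all(c("GHD", "TS") %in% names(n_per_condition)))
    stopf("`n_per_condition` must name GHD and TS")
  if (any(n_per_condition < 8))
    stopf("need at least 8 samples per condition (quartile machinery degenerate)")
  planted <- truth$planted_module_genes
  if (!all(planted %in% interactome$nodes))
    stopf("planted genes must be interactome nodes")
  other <- setdiff(interactome$nodes, planted)
  n_extra <- n_genes_expressed - length(planted) - length(other)
  if (n_extra < 0)
    stopf("n_genes_expressed (%d) smaller than interactome size", n_genes_expressed)
  genes <- c(planted, other,
             if (n_extra > 0) sprintf("EXPR%05d", seq_len(n_extra)))

  cal <- hv_calibration()
  pheno <- list(); expr <- list()
  for (cond in c("GHD", "TS")) {
    n <- n_per_condition[[cond]]
    sm <- with_seed(child_seed(child_seed(seed, 31), match(cond, c("GHD", "TS"))), {
      sample_id <- sprintf("%s%03d", cond, seq_len(n))
      sex <- if (cond == "TS") rep("F", n) else
        ifelse(runif(n) < 0.643, "M", "F")
      age <- runif(n, 6, 12)
      bmi_sds <- rnorm(n, if (cond == "TS") 0.4 else -0.2, 1)
      weight_sds <- rnorm(n, -2, 0.8)
      birthweight_sds <- rnorm(n, -1, 1)
      dth_sds <- rnorm(n, -1.5, 0.8)
      peak_gh <- if (cond == "GHD") exp(rnorm(n, log(3.9), 0.5)) else rep(NA_real_, n)
      batch <- sprintf("B%d", 1 + (seq_len(n) + as.integer(runif(n) < 0.5)) %% 2)

      ## standardized covariates feeding the clinical score
      w <- clinical_weights(cond)
      std <- cbind(age = (age - 9) / sqrt(3),  # U(6,12): sd = 6/sqrt(12)
                   weight_sds = (weight_sds + 2) / 0.8,
                   birthweight_sds = (birthweight_sds + 1) / 1,
                   dth_sds = (dth_sds + 1.5) / 0.8,
                   peak_gh = if (cond == "GHD")
                     (log(peak_gh) - log(3.9)) / 0.5 else rep(0, n))
      z_clin <- drop(std[, names(w), drop = FALSE] %*% w) / sqrt(sum(w^2))
      z_bio <- rnorm(n)

      cc <- truth$clinical_r2[[cond]]
      bb <- truth$bio_r2
      res_sd <- sqrt(max(0, 1 - cc - bb)) * hv_noise_sd
      hv <- sapply(1:5, function(y) {
        z <- sqrt(cc) * z_clin + sqrt(bb) * z_bio + res_sd * rnorm(n)
        pmax(0, cal[[cond]]$mean[y] + cal[[cond]]$sd[y] * z)
      })
      colnames(hv) <- paste0("hv_y", 1:5)
      ## declining follow-up after year 1
      for (y in 2:5) hv[runif(n) > cal[[cond]]$retain[y], y] <- NA

      ## Tanner progression: deterministic threshold on age + noise
      onset <- ifelse(sex == "F", 10.5, 11.5) + rnorm(n, 0, 0.8)
      tanner <- sapply(1:5, function(y)
        pmin(5, pmax(1, 1 + floor((age + (y - 1) - onset) / 1.2 + 1))))
      tanner[, 1] <- 1   # all Tanner 1 at baseline
      for (y in 2:5) tanner[, y] <- pmax(tanner[, y], tanner[, y - 1])
      colnames(tanner) <- paste0("tanner_y", 1:5)

      ph <- data.frame(sample_id, condition = cond, sex, age, bmi_sds,
                       weight_sds, birthweight_sds, dth_sds, peak_gh, batch,
                       tanner, hv, stringsAsFactors = FALSE)

      ## expression: baseline + covariate effects + planted signal + noise
      G <- length(genes)
      base <- rnorm(G, 7, 1.5)
      b_batch <- rnorm(G, 0, 0.3)
      b_age <- rnorm(G, 0, 0.05)
      b_bmi <- rnorm(G, 0, 0.05)
      E <- matrix(rnorm(G * n, 0, 0.8), G, n, dimnames = list(genes, sample_id))
      E <- E + base +
        outer(b_batch, as.numeric(batch == "B2")) +
        outer(b_age, age - 9) +
        outer(b_bmi, bmi_sds)
      eff <- truth$per_condition_effect[, cond]
      E[planted, ] <- E[planted, ] + outer(eff[planted], z_bio)
      list(ph = ph, E = E)
    })
    pheno[[cond]] <- sm$ph
    expr[[cond]] <- sm$E
  }
  phenotype <- do.call(rbind, pheno)
  rownames(phenotype) <- NULL
  expression <- do.call(cbind, expr)
  list(expression = expression, phenotype = phenotype)
}

#' Generate genotypes with LD-block structure
#'
#' Markers are assigned to LD blocks nested within candidate genes.  Calls
#' are drawn under Hardy-Weinberg equilibrium from a per-block latent
#' Gaussian shared by markers of the same block (pairwise correlation `rho`
#' between within-block latents), so blocks of size one are independent
#' markers.  X-chromosome non-pseudoautosomal markers are emitted with only
#' homozygote codes (AA/BB) for TS samples and male GHD samples.  An
#' optional genotype-response association shifts the allele frequency with
#' the standardized first-year height velocity.
#'
#' @param n_markers number of markers.
#' @param n_blocks number of LD blocks (`<= n_markers`).
#' @param phenotype cohort phenotype data.frame (for sample ids, sex,
#'   condition, and the response used by `assoc_markers`).
#' @param assoc_markers named numeric vector mapping marker ids (of the form
#'   `M00001`...) to standardized log-odds effects on the allele frequency;
#'   `NULL` for a null panel.
#' @param seed integer seed.
#' @param rho within-block latent correlation.
#' @param n_genes number of candidate genes the blocks are nested in.
#' @param x_fraction fraction of blocks placed on the X chromosome.
#' @param missing_rate per-call missingness rate.
#' @return Object of class `genotype_matrix`: `calls` (markers x samples
#'   character matrix with codes AA/AB/BB/missing) and `info` (per-marker
#'   metadata: gene, chromosome, ld_block_id, pseudoautosomal).
#' @export
generate_genotypes <- function(n_markers, n_blocks, phenotype,
                               assoc_markers = NULL, seed = 1, rho = 0.9,
                               n_genes = 103, x_fraction = 0.05,
                               missing_rate = 0.005) {
  assert_count(n_markers, "n_markers")
  assert_count(n_blocks, "n_blocks")
  if (n_blocks > n_markers) stopf("n_blocks must not exceed n_markers")
  marker_ids <- sprintf("M%05d", seq_len(n_markers))
  if (!is.null(assoc_markers)) {
    bad <- setdiff(names(assoc_markers), marker_ids)
    if (length(bad))
      stopf("assoc_markers not in panel: %s", paste(head(bad, 5), collapse = ", "))
  }
  samples <- phenotype$sample_id
  n <- length(samples)
  ## samples with a single X copy for association purposes
  single_x <- phenotype$condition == "TS" |
    (phenotype$condition == "GHD" & phenotype$sex == "M")
  resp <- phenotype$hv_y1
  z_resp <- as.numeric(scale(resp))
  z_resp[is.na(z_resp)] <- 0

  with_seed(child_seed(seed, 41), {
    block_of <- sort(rep_len(seq_len(n_blocks), n_markers))
    gene_of_block <- rep_len(seq_len(min(n_genes, n_blocks)), n_blocks)
    x_blocks <- sample(seq_len(n_blocks), round(x_fraction * n_blocks))
    info <- data.frame(
      marker_id = marker_ids,
      gene = sprintf("CAND%03d", gene_of_block[block_of]),
      chromosome = ifelse(block_of %in% x_blocks, "X",
                          as.character(1 + (gene_of_block[block_of] %% 22))),
      ld_block_id = sprintf("LD%04d", block_of),
      pseudoautosomal = FALSE,
      stringsAsFactors = FALSE
    )
    maf_block <- runif(n_blocks, 0.1, 0.5)
    ## two latent allele draws per sample per block
    z1 <- matrix(rnorm(n_blocks * n), n_blocks, n)
    z2 <- matrix(rnorm(n_blocks * n), n_blocks, n)
    calls <- matrix(NA_character_, n_markers, n,
                    dimnames = list(marker_ids, samples))
    for (m in seq_len(n_markers)) {
      b <- block_of[m]
      p <- maf_block[b]
      eff <- if (!is.null(assoc_markers) && marker_ids[m] %in% names(assoc_markers))
        assoc_markers[[marker_ids[m]]] else 0
      pm <- plogis(qlogis(p) + eff * z_resp)
      th <- qnorm(pm)
      a1 <- (sqrt(rho) * z1[b, ] + sqrt(1 - rho) * rnorm(n)) < th
      a2 <- (sqrt(rho) * z2[b, ] + sqrt(1 - rho) * rnorm(n)) < th
      dose <- a1 + a2
      on_x <- info$chromosome[m] == "X" && !info$pseudoautosomal[m]
      if (on_x) dose[single_x] <- 2L * a1[single_x]  # hemizygous: AA or BB
      calls[m, ] <- c("AA", "AB", "BB")[dose + 1L]
    }
    if (missing_rate > 0) {
      miss <- runif(length(calls)) < missing_rate
      calls[miss] <- "missing"
    }
    structure(list(calls = calls, info = info), class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples, %d LD blocks\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$info$ld_block_id))))
  invisible(x)
}

#' Generate gene-level methylation with a planted response association
#'
#' Beta values are logistic-squashed Gaussians, guaranteeing the `[0, 1]`
#' range.  Planted module genes receive a methylation-response association
#' whose sign is negative (hypermethylated at low response) for a
#' `neg_methyl_fraction` share of genes, emulating the skew reported for the
#' knemometry methylation data (425/497 negative).
#'
#' @param truth a [synthetic_truth()] object.
#' @param phenotype cohort phenotype (response = first-year height velocity);
#'   at least 2 samples are required, otherwise correlation is undefined.
#' @param n_genes total number of methylation genes (planted module genes
#'   first, then additional associated genes, then null filler).
#' @param n_associated total number of response-associated genes, including
#'   the planted module genes; mirrors the ~500 associated genes of the
#'   knemometry methylation analysis.  The null background is scaled down
#'   relative to the 20,618-gene summary so that the direction tally of the
#'   downstream scan is dominated by true associations, as it was in the
#'   study (see the methods vignette).
#' @param seed integer seed.
#' @param effect standardized strength of the planted methylation signal on
#'   the logit scale.
#' @return numeric matrix (genes x samples) of beta values in `[0, 1]`, with
#'   attribute `planted_sign` (named -1/+1 for all associated genes).
#' @export
generate_methylation <- function(truth, phenotype, n_genes = 2000,
                                 n_associated = 500, seed = 1,
                                 effect = 1.5) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (nrow(phenotype) < 2)
    stopf("at least 2 samples required (correlation undefined for one sample)")
  planted <- truth$planted_module_genes
  if (n_genes < length(planted))
    stopf("n_genes must be at least the planted set size")
  n_associated <- max(n_associated, length(planted))
  n_associated <- min(n_associated, n_genes)
  genes <- c(planted,
             sprintf("METH%05d", seq_len(n_genes - length(planted))))
  assoc <- genes[seq_len(n_associated)]
  samples <- phenotype$sample_id
  resp <- phenotype$hv_y1
  z <- as.numeric(scale(resp))
  z[is.na(z)] <- 0
  with_seed(child_seed(seed, 51), {
    base <- qlogis(runif(n_genes, 0.2, 0.8))
    sgn <- ifelse(runif(length(assoc)) < truth$neg_methyl_fraction, -1, 1)
    names(sgn) <- assoc
    L <- matrix(rnorm(n_genes * length(samples), 0, 0.5),
                n_genes, length(samples), dimnames = list(genes, samples))
    L <- L + base
    L[assoc, ] <- L[assoc, ] + outer(sgn * effect, z)
    beta <- plogis(L)
    attr(beta, "planted_sign") <- sgn
    beta
  })
}
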