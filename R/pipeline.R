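## ---------------------------------------------------------------------------
## End-to-end orchestration of the synthetic experiment:
## simulate -> associate -> netmod -> signature -> classify -> methyl,
## per condition and treatment year, with recovery metrics against the
## planted truth.
## ---------------------------------------------------------------------------

## covariate data.frame for one condition-year, mirroring the published
## covariate sets: batch, age, BMI for both conditions, plus sex and peak GH
## for GHD, plus the Tanner stage of that treatment year
condition_covariates <- function(phenotype, year) {
  cov <- data.frame(batch = phenotype$batch, age = phenotype$age,
                    bmi_sds = phenotype$bmi_sds)
  if (all(phenotype$condition == "GHD")) {
    cov$sex <- phenotype$sex
    cov$peak_gh <- phenotype$peak_gh
  }
  cov$tanner <- factor(phenotype[[paste0("tanner_y", year)]])
  cov
}

## clinical baseline feature matrix for classification
clinical_features <- function(phenotype) {
  X <- cbind(age = phenotype$age, weight_sds = phenotype$weight_sds,
             birthweight_sds = phenotype$birthweight_sds,
             dth_sds = phenotype$dth_sds)
  if (all(phenotype$condition == "GHD")) X <- cbind(X, peak_gh = phenotype$peak_gh)
  rownames(X) <- phenotype$sample_id
  X
}

#' Cumulative growth over the five study years
#'
#' Total centimetres grown over years 1-5, defined only for samples with a
#' complete height-velocity series (mirroring the reduced cohorts of the
#' whole-period ordinations).
#'
#' @param phenotype phenotype data.frame.
#' @return named numeric vector (NA when any year is missing).
#' @export
cumulative_response <- function(phenotype) {
  hv <- as.matrix(phenotype[paste0("hv_y", 1:5)])
  out <- rowSums(hv)
  names(out) <- phenotype$sample_id
  out
}

#' Run the full synthetic discovery pipeline
#'
#' Generates a synthetic interactome, two-condition cohort, genotypes and
#' methylation with planted truth, then runs, per condition and treatment
#' year: the covariate-eliminated rank-regression scan, the seed-network /
#' module / metanode-core analysis, the cross-condition signature selection,
#' and the clinical-vs-combined random-forest comparison for the low and
#' high response quartiles; finally the methylation scan and signature
#' mapping, and recovery metrics against the planted truth.  Everything is
#' reproducible from `seed`.
#'
#' @param config a [netsig_config()].
#' @param seed integer master seed.
#' @param outdir optional directory; when given, [write_report()] output and
#'   the simulated inputs are written there.
#' @param stages subset of
#'   `c("genetics", "classify", "methyl")` to run in addition to the core
#'   simulate/associate/netmod/signature chain.
#' @return a `run_manifest` list: `config`, `seed`, `truth`, `associations`,
#'   `cores`, `signatures`, `classification` (Table-2-shaped data.frame),
#'   `genetics`, `methylation`, `recovery`, `stage_hashes`, `timings`.
#' @export
run_pipeline <- function(config = netsig_config(), seed = 1, outdir = NULL,
                         stages = c("genetics", "classify", "methyl")) {
  stopifnot(inherits(config, "netsig_config"))
  t_all <- list(); hashes <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## ---- simulate ----------------------------------------------------------
  gi <- generate_interactome(config$n_genes_interactome, config$module_sizes,
                             config$p_in, config$p_out,
                             seed = child_seed(seed, 1),
                             m_background = config$m_background)
  planted <- names(gi$membership)[gi$membership > 0]
  truth <- synthetic_truth(planted, clinical_r2 = config$clinical_r2,
                           bio_r2 = config$bio_r2,
                           neg_methyl_fraction = config$neg_methyl_fraction,
                           seed = child_seed(seed, 2))
  cohort <- generate_cohort(truth, gi$interactome,
                            n_per_condition = config$n_per_condition,
                            n_genes_expressed = config$n_genes_expressed,
                            seed = child_seed(seed, 3))
  expr <- cohort$expression
  pheno <- cohort$phenotype
  hashes$simulate <- object_hash(list(gi, pheno, dim(expr), sum(expr)))
  t_all$simulate <- tic() - t0

  ## ---- association scans -------------------------------------------------
  t0 <- tic()
  associations <- list()
  for (cond in c("GHD", "TS")) {
    ph <- pheno[pheno$condition == cond, ]
    E <- expr[, ph$sample_id, drop = FALSE]
    associations[[cond]] <- lapply(setNames(1:5, paste0("y", 1:5)), function(y) {
      resp <- setNames(ph[[paste0("hv_y", y)]], ph$sample_id)
      keep <- !is.na(resp)
      rank_regression_scan(E[, keep, drop = FALSE], resp[keep],
                           covariates = condition_covariates(ph[keep, ], y),
                           alpha = config$assoc_p)
    })
  }
  hashes$associate <- object_hash(associations)
  t_all$associate <- tic() - t0

  ## ---- network models and cores ------------------------------------------
  t0 <- tic()
  net_nodes <- gi$interactome$nodes
  cores <- list()
  for (cond in c("GHD", "TS")) {
    cores[[cond]] <- lapply(associations[[cond]], function(tab) {
      seeds <- intersect(tab$feature_id[tab$flagged], net_nodes)
      if (length(seeds) < 2) return(character(0))
      net <- build_seed_network(seeds, gi$interactome)
      land <- influence_landscape(net, lambda = config$lambda,
                                  depth = config$depth)
      mods <- detect_overlapping_modules(land, net, tau = config$tau,
                                         merge_ratio = config$merge_ratio)
      ## sub-scale modules (fewer than min_module_size members) carry no
      ## community structure and are left out of the functional core
      big <- Filter(function(mm) length(mm$members) >= config$min_module_size,
                    mods$modules)
      if (!length(big)) return(character(0))
      network_core(lapply(big, module_core, k = config$metanode_size))
    })
  }
  hashes$netmod <- object_hash(cores)
  t_all$netmod <- tic() - t0

  ## ---- signatures ----------------------------------------------------------
  t0 <- tic()
  universe <- length(intersect(rownames(expr), net_nodes))
  signatures <- lapply(setNames(paste0("y", 1:5), paste0("y", 1:5)), function(y) {
    ca <- cores$GHD[[y]]; cb <- cores$TS[[y]]
    if (!length(ca) || !length(cb))
      return(structure(list(year = as.integer(sub("y", "", y)),
                            genes = character(0),
                            provenance = data.frame(), overlap_p = NA_real_,
                            excluded = character(0)), class = "signature"))
    ov <- core_overlap_test(ca, cb, universe)
    select_signature(ov$shared, associations$GHD[[y]], associations$TS[[y]],
                     alpha = config$signature_p,
                     year = as.integer(sub("y", "", y)), overlap_p = ov$p)
  })
  sig_union <- unique(unlist(lapply(signatures, `[[`, "genes")))
  hashes$signature <- object_hash(signatures)
  t_all$signature <- tic() - t0

  ## ---- classification ------------------------------------------------------
  classification <- NULL
  if ("classify" %in% stages) {
    t0 <- tic()
    rows <- list()
    for (cond in c("GHD", "TS")) {
      ph <- pheno[pheno$condition == cond, ]
      for (y in 1:5) {
        resp <- setNames(ph[[paste0("hv_y", y)]], ph$sample_id)
        resp <- resp[!is.na(resp)]
        labels <- quartile_labels(resp, endpoint = paste0("hv_y", y))
        for (quart in c("low", "high")) {
          bin <- factor(ifelse(labels == quart, quart, "rest"),
                        levels = c("rest", quart))
          names(bin) <- names(labels)
          phq <- ph[match(names(bin), ph$sample_id), ]
          clin <- clinical_features(phq)
          sig_genes <- intersect(signatures[[paste0("y", y)]]$genes,
                                 rownames(expr))
          cmp <- compare_phenotype_models(
            clin, expr[sig_genes, , drop = FALSE], bin,
            n_trees = config$rf_trees,
            seed = child_seed(seed, 100 + y * 10 +
                                (cond == "TS") * 2 + (quart == "high")),
            smote = TRUE)
          for (fs in c("clinical", "combined")) {
            r <- cmp[[fs]]
            rows[[length(rows) + 1L]] <- data.frame(
              condition = cond, year = y, quartile = quart,
              features = if (fs == "clinical") "clinical_phenotype"
                         else "clinical_phenotype_plus_transcriptome",
              n = length(bin), n_signature_genes = length(sig_genes),
              auc = r$auc, ci_lo = r$auc_ci[1], ci_hi = r$auc_ci[2],
              oob_error = r$oob_error, stringsAsFactors = FALSE)
          }
        }
      }
    }
    classification <- do.call(rbind, rows)
    hashes$classify <- object_hash(classification)
    t_all$classify <- tic() - t0
  }

  ## ---- genetics -------------------------------------------------------------
  genetics <- NULL
  if ("genetics" %in% stages) {
    t0 <- tic()
    gt <- generate_genotypes(config$n_markers, config$n_ld_blocks, pheno,
                             seed = child_seed(seed, 4))
    validate_genotypes(gt, pheno)
    blocks_per_gene <- tapply(gt$info$ld_block_id, gt$info$gene,
                              function(x) length(unique(x)))
    gene_blocks <- setNames(as.integer(blocks_per_gene[gt$info$gene]),
                            gt$info$marker_id)
    genetics <- list()
    for (cond in c("GHD", "TS")) {
      ph <- pheno[pheno$condition == cond, ]
      resp <- setNames(ph$hv_y1, ph$sample_id)
      gsub_ <- gt
      gsub_$calls <- gt$calls[, ph$sample_id, drop = FALSE]
      scans <- lapply(c("genotypic", "dominant", "recessive"), function(m) {
        tab <- kruskal_wallis_genetic(gsub_, resp, model = m)
        tab <- adjust_ld_bonferroni(tab, gene_blocks,
                                    length(unique(gt$info$ld_block_id)))
        adjust_fdr_bh(tab)
      })
      names(scans) <- c("genotypic", "dominant", "recessive")
      genetics[[cond]] <- scans
    }
    hashes$genetics <- object_hash(genetics)
    t_all$genetics <- tic() - t0
  }

  ## ---- methylation ----------------------------------------------------------
  methylation <- NULL
  if ("methyl" %in% stages) {
    t0 <- tic()
    ph <- pheno[pheno$condition == "GHD", ]
    meth <- generate_methylation(truth, ph, n_genes = config$n_methyl_genes,
                                 n_associated = config$n_methyl_associated,
                                 seed = child_seed(seed, 5))
    resp <- setNames(ph$hv_y1, ph$sample_id)
    scan <- methylation_response_scan(meth, resp, alpha = config$assoc_p)
    mapping <- map_signature_methylation(sig_union, meth, resp,
                                         r_threshold = config$methyl_r)
    methylation <- list(scan_tally = scan$tally, mapping = mapping$table,
                        unmapped = mapping$unmapped)
    hashes$methyl <- object_hash(methylation)
    t_all$methyl <- tic() - t0
  }

  ## ---- recovery metrics -----------------------------------------------------
  recovery <- list(
    n_signature_union = length(sig_union),
    signature_sensitivity =
      length(intersect(sig_union, planted)) / length(planted),
    signature_contamination =
      if (length(sig_union))
        length(setdiff(sig_union, planted)) / length(sig_union) else 0
  )
  if (!is.null(classification)) {
    wide <- merge(
      classification[classification$features == "clinical_phenotype",
                     c("condition", "year", "quartile", "auc", "oob_error")],
      classification[classification$features != "clinical_phenotype",
                     c("condition", "year", "quartile", "auc", "oob_error")],
      by = c("condition", "year", "quartile"), suffixes = c("_clin", "_comb"))
    recovery$delta_auc_mean <- mean(wide$auc_comb - wide$auc_clin)
    recovery$delta_oob_mean <- mean(wide$oob_error_comb - wide$oob_error_clin)
  }
  if (!is.null(methylation))
    recovery$methyl_neg_share <- methylation$scan_tally$neg_share

  manifest <- structure(list(
    config = config, seed = as.integer(seed), truth = truth,
    associations = associations, cores = cores, signatures = signatures,
    classification = classification, genetics = genetics,
    methylation = methylation, recovery = recovery,
    stage_hashes = hashes, timings = t_all,
    interactome = gi$interactome, planted_membership = gi$membership,
    expression = expr, phenotype = pheno
  ), class = "run_manifest")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_expression(expr, file.path(outdir, "expression.tsv"))
    write_phenotype(pheno, file.path(outdir, "phenotype.tsv"))
    write_interactome(gi$interactome, file.path(outdir, "interactome.tsv"))
    write_truth(truth, file.path(outdir, "truth.json"))
    write_report(manifest, outdir)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (seed %d): %d-gene signature union, sensitivity %.2f, contamination %.2f\n",
              x$seed, x$recovery$n_signature_union,
              x$recovery$signature_sensitivity,
              x$recovery$signature_contamination))
  if (!is.null(x$recovery$delta_auc_mean))
    cat(sprintf("  mean delta AUC (combined - clinical): %+.3f\n",
                x$recovery$delta_auc_mean))
  invisible(x)
}
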