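## ---------------------------------------------------------------------------
## Readers/writers for the on-disk formats (TSV matrices, SIF/TSV edge lists,
## JSON truth and reports, YAML config), plus shared validation.  All numeric
## serialization uses 10 significant digits and C locale number formats.
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Collects every tunable constant of the analysis in one list: the
#' association threshold (`assoc_p = 0.01`), the signature inclusion
#' threshold (`signature_p = 0.05`), the overlap flag threshold
#' (`overlap_p = 0.01`), the methylation correlation threshold
#' (`methyl_r = 0.3`), metanode size 10, 1000 random-forest trees, 100
#' Boruta iterations, SMOTE with 5 neighbours, the floor(n/4) quartile rule,
#' and the influence-landscape parameters (`lambda = 0.5`, `depth = 3`,
#' membership floor `tau = 0.2`, merge ratio 0.25).
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `netsig_config`.
#' @export
netsig_config <- function(...) {
  cfg <- list(
    assoc_p = 0.01, signature_p = 0.05, overlap_p = 0.01, methyl_r = 0.3,
    metanode_size = 10, min_module_size = 5,
    rf_trees = 1000, boruta_perms = 100,
    boruta_trees = 200, smote_k = 5, quartile_rule = "floor_n_over_4",
    lambda = 0.5, depth = 3, tau = 0.2, merge_ratio = 0.25,
    ## synthetic experiment scale
    n_genes_interactome = 600, module_sizes = rep(10, 6),
    p_in = 0.55, p_out = 0.0002, m_background = 1,
    n_per_condition = c(GHD = 70, TS = 43), n_genes_expressed = 8000,
    clinical_r2 = c(GHD = 0.61, TS = 0.46), bio_r2 = 0.3,
    neg_methyl_fraction = 425 / 497,
    n_markers = 1219, n_ld_blocks = 768, n_methyl_genes = 2000,
    n_methyl_associated = 500,
    run_boruta = FALSE, run_ordinations = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  for (nm in c("assoc_p", "signature_p", "overlap_p"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stopf("`%s` must lie in (0, 1)", nm)
  for (nm in c("metanode_size", "rf_trees", "boruta_perms", "smote_k"))
    assert_count(cfg[[nm]], nm)
  class(cfg) <- "netsig_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys override [netsig_config()] defaults.
#' @return A `netsig_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$n_per_condition)) y$n_per_condition <- unlist(y$n_per_condition)
  if (!is.null(y$clinical_r2)) y$clinical_r2 <- unlist(y$clinical_r2)
  if (!is.null(y$module_sizes)) y$module_sizes <- as.numeric(unlist(y$module_sizes))
  do.call(netsig_config, y)
}

fmt_num <- function(x) trimws(formatC(x, digits = 10, format = "g"))

read_tsv_matrix <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stopf("%s file needs an id column plus data columns", what)
  ids <- as.character(df[[1]])
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn))
    stopf("%s file has duplicate sample ids: %s", what,
          paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stopf("%s file has non-numeric values in column '%s'",
          what, cn[bad])
  }
  dimnames(m) <- list(ids, cn)
  m
}

#' Read/write a normalized expression matrix
#'
#' The TSV layout is: first column `gene_id`, header row of sample ids, tab
#' separated, `#` comments allowed.  Duplicate gene rows are collapsed on
#' read by keeping the highest-variance row (`collapse = "max_var"`) or the
#' per-sample median (`collapse = "median"`).
#'
#' @param path file path.
#' @param collapse duplicate-gene collapse rule.
#' @return numeric matrix genes x samples.
#' @export
read_expression <- function(path, collapse = c("max_var", "median")) {
  collapse <- match.arg(collapse)
  m <- read_tsv_matrix(path, "expression")
  if (any(!is.finite(m))) stopf("expression matrix has non-finite values")
  if (anyDuplicated(rownames(m))) {
    ids <- rownames(m)
    if (collapse == "max_var") {
      v <- apply(m, 1, var)
      keep <- unlist(lapply(split(seq_along(ids), ids), function(ix)
        ix[which.max(v[ix])]))
      m <- m[sort(keep), , drop = FALSE]
    } else {
      m <- do.call(rbind, lapply(split(seq_along(ids), ids), function(ix)
        apply(m[ix, , drop = FALSE], 2, median)))
    }
  }
  m
}

#' @rdname read_expression
#' @param mat matrix to write.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   apply(mat, 2, fmt_num), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a methylation beta matrix
#'
#' Same layout as expression; values are checked to lie in `[0, 1]`.
#' @inheritParams read_expression
#' @export
read_methylation <- function(path) {
  m <- read_tsv_matrix(path, "methylation")
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stopf("methylation beta values must lie in [0, 1]")
  m
}

#' @rdname read_methylation
#' @param mat matrix to write.
#' @export
write_methylation <- function(mat, path) write_expression(mat, path)

#' Read/write the cohort phenotype table
#'
#' Columns: `sample_id`, `condition` (GHD/TS), `sex`, `age`, `bmi_sds`,
#' `weight_sds`, `birthweight_sds`, `dth_sds`, `peak_gh` (GHD only, NA
#' otherwise), `batch`, `tanner_y1..tanner_y5`, `hv_y1..hv_y5`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "condition", "sex", "age", "bmi_sds", "weight_sds",
            "birthweight_sds", "dth_sds", "peak_gh", "batch",
            paste0("tanner_y", 1:5), paste0("hv_y", 1:5))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("phenotype file missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample ids in phenotype: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  validate_phenotype(df)
  df
}

#' @rdname read_phenotype
#' @param phenotype data.frame to write.
#' @export
write_phenotype <- function(phenotype, path) {
  num <- vapply(phenotype, is.numeric, TRUE)
  out <- phenotype
  out[num] <- lapply(phenotype[num], fmt_num)
  out[out == "NA"] <- NA
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_phenotype <- function(df) {
  if (!all(df$condition %in% c("GHD", "TS")))
    stopf("condition must be GHD or TS")
  if (any(is.na(df$hv_y1))) stopf("year-1 height velocity must be present for all samples")
  tn <- as.matrix(df[paste0("tanner_y", 1:5)])
  if (any(tn[, -1] < tn[, -5], na.rm = TRUE))
    stopf("tanner stage must be non-decreasing over years")
  gh <- df$condition == "GHD"
  if (any(is.na(df$peak_gh[gh])) || any(!is.na(df$peak_gh[!gh])))
    stopf("peak_gh must be present iff condition is GHD")
  invisible(df)
}

#' Read/write an interactome edge list
#'
#' Two dialects are accepted: plain two-column TSV (`A<TAB>B`) and SIF
#' (`A pp B`, whitespace separated).  Both yield the same undirected edge.
#'
#' @param path file path.
#' @return An `interactome` object.
#' @export
read_interactome <- function(path) {
  if (!file.exists(path)) stopf("interactome file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  edges <- lapply(parts, function(p) {
    if (length(p) == 2) p
    else if (length(p) >= 3 && p[2] == "pp") c(p[1], p[3])
    else stopf("cannot parse interactome line: '%s'", paste(p, collapse = " "))
  })
  em <- do.call(rbind, edges)
  em <- unique(t(apply(em, 1, sort)))
  em <- em[em[, 1] != em[, 2], , drop = FALSE]
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  new_interactome(sort(unique(c(em))), em)
}

#' @rdname read_interactome
#' @param net interactome to write.
#' @param dialect `"tsv"` for two-column TSV, `"sif"` for `A pp B` lines.
#' @export
write_interactome <- function(net, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  lines <- if (dialect == "tsv")
    paste(net$edges[, 1], net$edges[, 2], sep = "\t")
  else paste(net$edges[, 1], "pp", net$edges[, 2])
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the genotype matrix
#'
#' TSV layout: metadata columns `marker_id`, `gene`, `chromosome`,
#' `ld_block_id`, `pseudoautosomal`, then one column per sample with codes
#' `AA`/`AB`/`BB`/`missing`.
#'
#' @param path file path.
#' @return A `genotype_matrix` object.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "", check.names = FALSE)
  meta <- c("marker_id", "gene", "chromosome", "ld_block_id", "pseudoautosomal")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stopf("genotype file missing metadata columns: %s", paste(miss, collapse = ", "))
  calls <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(calls) <- df$marker_id
  bad <- which(matrix(!(calls %in% c("AA", "AB", "BB", "missing")),
                      nrow(calls)), arr.ind = TRUE)
  if (nrow(bad))
    stopf("unknown genotype code '%s' at marker %s, sample %s",
          calls[bad[1, 1], bad[1, 2]], rownames(calls)[bad[1, 1]],
          colnames(calls)[bad[1, 2]])
  if (any(is.na(df$ld_block_id)) || any(!nzchar(df$ld_block_id)))
    stopf("every marker needs an ld_block_id")
  info <- df[meta]
  info$pseudoautosomal <- as.logical(info$pseudoautosomal)
  structure(list(calls = calls, info = info), class = "genotype_matrix")
}

#' @rdname read_genotypes
#' @param gt genotype matrix to write.
#' @export
write_genotypes <- function(gt, path) {
  df <- cbind(gt$info, as.data.frame(gt$calls, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-check sample ids between a matrix and the phenotype table
#'
#' @param mat genes x samples matrix.
#' @param phenotype phenotype data.frame.
#' @return invisibly `TRUE`; errors listing orphan ids otherwise.
#' @export
check_samples <- function(mat, phenotype) {
  orphans <- setdiff(colnames(mat), phenotype$sample_id)
  if (length(orphans))
    stopf("samples absent from phenotype: %s", paste(orphans, collapse = ", "))
  invisible(TRUE)
}

#' Validate genotype calls against the phenotype
#'
#' Non-pseudoautosomal X markers must carry no heterozygote (AB) calls in
#' samples with a single X dose (TS, male GHD).
#'
#' @param gt genotype matrix.
#' @param phenotype phenotype data.frame.
#' @return invisibly `TRUE`.
#' @export
validate_genotypes <- function(gt, phenotype) {
  check_samples(gt$calls, phenotype)
  ph <- phenotype[match(colnames(gt$calls), phenotype$sample_id), ]
  single_x <- ph$condition == "TS" | (ph$condition == "GHD" & ph$sex == "M")
  on_x <- gt$info$chromosome == "X" & !gt$info$pseudoautosomal
  if (any(on_x) && any(single_x)) {
    sub <- gt$calls[on_x, single_x, drop = FALSE]
    bad <- which(sub == "AB", arr.ind = TRUE)
    if (nrow(bad))
      stopf("heterozygote call on X marker %s in single-X sample %s",
            rownames(sub)[bad[1, 1]], colnames(sub)[bad[1, 2]])
  }
  invisible(TRUE)
}

#' Write synthetic truth to JSON / read it back
#'
#' @param truth a `synthetic_truth` object.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    planted_module_genes = truth$planted_module_genes,
    per_condition_effect = as.data.frame(truth$per_condition_effect),
    gene_order = rownames(truth$per_condition_effect),
    clinical_r2 = as.list(truth$clinical_r2),
    bio_r2 = truth$bio_r2,
    neg_methyl_fraction = truth$neg_methyl_fraction,
    rng_seed = truth$rng_seed
  ), path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- as.matrix(j$per_condition_effect)
  rownames(eff) <- j$gene_order
  structure(list(
    planted_module_genes = j$planted_module_genes,
    per_condition_effect = eff,
    clinical_r2 = unlist(j$clinical_r2),
    bio_r2 = j$bio_r2,
    neg_methyl_fraction = j$neg_methyl_fraction,
    rng_seed = j$rng_seed
  ), class = "synthetic_truth")
}

#' Write an association table as TSV
#'
#' @param table AssociationTable data.frame.
#' @param path output path.
#' @export
write_association <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run results (tables + JSON summary + log) to a directory
#'
#' Produces `association_<cond>_y<year>.tsv` tables, `signatures.json`,
#' `classification.tsv` (Table-2-shaped: per year/condition/quartile AUC,
#' 95% CI, OOB error for each feature set), and `summary.json` echoing the
#' configuration and seeds.  An empty signature is written with an explicit
#' `empty` marker rather than dropped.  A `run.log` records every threshold
#' used.  Output is byte-stable for a fixed config and seed.
#'
#' @param results a pipeline manifest as returned by [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly the directory path.
#' @export
write_report <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stopf("cannot create output directory %s", outdir)
  for (cond in names(results$associations))
    for (yr in names(results$associations[[cond]]))
      write_association(results$associations[[cond]][[yr]],
                        file.path(outdir, sprintf("association_%s_%s.tsv", cond, yr)))
  sig <- lapply(results$signatures, function(s) list(
    year = s$year,
    genes = if (length(s$genes)) as.list(s$genes) else list(),
    empty = length(s$genes) == 0,
    overlap_p = s$overlap_p
  ))
  jsonlite::write_json(sig, file.path(outdir, "signatures.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(results$classification))
    write.table(results$classification, file.path(outdir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(config = unclass(results$config), seed = results$seed,
                  recovery = results$recovery,
                  stage_hashes = results$stage_hashes)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  log <- c(
    sprintf("seed: %d", results$seed),
    sprintf("assoc_p: %g", results$config$assoc_p),
    sprintf("signature_p: %g", results$config$signature_p),
    sprintf("overlap_p: %g", results$config$overlap_p),
    sprintf("methyl_r: %g", results$config$methyl_r),
    sprintf("metanode_size: %d", results$config$metanode_size),
    sprintf("rf_trees: %d", results$config$rf_trees),
    sprintf("lambda: %g depth: %d tau: %g", results$config$lambda,
            results$config$depth, results$config$tau))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(outdir)
}
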