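# netsig

Network-guided discovery of blood gene-expression signatures that classify
year-by-year growth response to recombinant human growth hormone (r-hGH) in
growth hormone deficiency (GHD) and Turner syndrome (TS).

Response to r-hGH varies widely between children and is costly to get
wrong; baseline clinical models (age, weight SDS, birthweight SDS, distance
to target height SDS, peak GH) explain only ~46–61% of the variance.
`netsig` implements, as tested reusable R code, the full analysis chain
that links the pre-treatment blood transcriptome to height-velocity (HV)
response over five treatment years:

* **Association scans** — rank regression of expression on each year's HV
  after OLS elimination of clinical covariates (batch, age, BMI, sex, peak
  GH, Tanner stage), per condition, with exact small-n permutation
  p-values; Kruskal–Wallis genetic scans (genotypic/dominant/recessive,
  X-chromosome homozygote handling) with LD-block-aware Bonferroni and
  Benjamini–Hochberg correction.
* **Interactome models** — significant genes seed an induced first-
  neighbour network; overlapping modules are detected on an influence
  landscape (attenuated reach `sum lambda^d`, random-walk-restart zones,
  density merging and spectral splitting), each module's **metanode** (its
  ten most central genes, centrality = membership × influence) is
  extracted, and the metanode union forms the network's functional core.
* **Cross-condition signatures** — genes shared by the GHD and TS cores of
  a treatment year (hypergeometric overlap test) and associated with HV in
  either condition (p < 0.05) form that year's classification signature.
* **Classification** — random forests (1000 trees, √p splits) with SMOTE
  rebalancing and leakage-aware out-of-bag evaluation compare clinical
  phenotype alone against phenotype + transcriptome for the low and high
  response quartiles; Boruta shadow-feature selection confirms markers;
  PLS-DA and DAPC ordinations are included for visual checks.
* **Methylation** — median gene-level summaries, response scans with a
  hyper/hypo-methylation direction tally, and |r| > 0.3 correlation mapping
  of signature genes.
* **Synthetic cohorts with planted truth** — a first-class simulation
  module generates interactomes, two-condition cohorts (n = 70 GHD-like,
  43 TS-like, 8000 genes), LD-structured genotypes and methylation with a
  planted 60-gene module, so that every stage can be measured against a
  known answer (sensitivity, contamination, predictive uplift).

## Worked example

One call reproduces the whole synthetic experiment — simulation,
association scans, network models, signature selection, classification and
methylation mapping — for a given seed:

```r
library(netsig)
m <- run_pipeline(netsig_config(), seed = 1, stages = c("classify", "methyl"))
print(m)
#> run_manifest (seed 1): 54-gene signature union, sensitivity 0.90, contamination 0.00
#>   mean delta AUC (combined - clinical): +0.014
```

The manifest says that across the five yearly signatures the pipeline
recovered 90% of the 60 planted module genes with no false genes in the
union, and that adding the transcriptomic signature to the clinical
features improved the mean quartile-classification AUC.  The per-task
classification table mirrors the clinical-vs-combined comparison
(year 1, GHD shown):

```r
head(m$classification[m$classification$year == 1, ], 4)
#>   condition year quartile                              features  n
#> 1       GHD    1      low                    clinical_phenotype 70
#> 2       GHD    1      low clinical_phenotype_plus_transcriptome 70
#> 3       GHD    1     high                    clinical_phenotype 70
#> 4       GHD    1     high clinical_phenotype_plus_transcriptome 70
#>   n_signature_genes       auc     ci_lo     ci_hi  oob_error
#> 1                44 0.8962264 0.8222752 0.9701776 0.14285714
#> 2                44 0.9667037 0.9259960 1.0000000 0.08571429
#> 3                44 0.8712542 0.7787560 0.9637523 0.20000000
#> 4                44 0.8296337 0.7288066 0.9304609 0.27142857
```

For the low quartile of first-year response, the clinical-only forest
reaches AUC 0.90 (OOB error 0.14) and adding the 44-gene year-1 signature
raises it to 0.97 (OOB error 0.09).  The year-1 signature itself records
its cross-condition overlap evidence:

```r
m$signatures$y1
#> signature (year 1): 44 genes, overlap p = 4.213e-65
```

and the methylation scan's direction tally recovers the planted
hypermethylation-at-low-response skew:

```r
round(m$recovery$methyl_neg_share, 3)
#> [1] 0.857
```

Individual stages are exported and composable: `rank_regression_scan()`,
`build_seed_network()`, `influence_landscape()`,
`detect_overlapping_modules()`, `module_core()`, `core_overlap_test()`,
`select_signature()`, `quartile_labels()`, `smote_oversample()`,
`rf_classify_oob()`, `boruta_select()`, `pls_da_fit()`, `dapc_fit()`,
`compare_phenotype_models()`, `summarize_gene_methylation()`,
`methylation_response_scan()`, `map_signature_methylation()`, and the
generators `generate_interactome()`, `generate_cohort()`,
`generate_genotypes()`, `generate_methylation()`.  See
`vignettes/netsig-methods.Rmd` for the models, their assumptions and the
numerical choices.  A thin command-line wrapper is provided at
`inst/scripts/netsig-run.R`.

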