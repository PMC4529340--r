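# transbrca

Tools for asking whether breast cancer transcriptomes from cohorts of
different ancestry share the same molecular architecture. When two series
are profiled simultaneously on one platform, the interesting comparison is
not sample-by-sample but structural: are the same groups of co-expressed
genes present in both cohorts? Do the intrinsic subtypes (luminal A/B,
ERBB2-enriched, basal-like) and the extracellular-matrix classes (ECM1,
ECM3) found independently in each cohort correspond to one another? Does
ethnicity explain any differential expression once molecular subtype is
accounted for?

The package implements that full pipeline for bulk gene and miRNA
expression matrices, and ships a synthetic paired-cohort generator with
complete planted ground truth so every stage is testable end to end.

## What is inside

| Stage | Functions | Method |
|---|---|---|
| Preprocessing | `filter_by_detection`, `collapse_probes`, `quantile_normalize`, `iqr_filter`, `preprocess_dataset` | detection p < 0.01 in ≥ 1 sample; probe collapse by detection rate → IQR → id; type-7 quartiles |
| Cluster conservation | `discover_clusters`, `validate_cluster`, `conservation_summary`, `bidirectional_conservation`, `hypergeometric_enrichment` | average linkage on 1 − r, cut at r = 0.6 (genes) / 0.4 (miRNAs); validated when ≥ 3 members re-correlate in the other cohort |
| Subtyping | `bimodal_threshold`, `classify_marker_status`, `assign_intrinsic_subtypes`, `assign_claudin_low`, `ihc_subtype`, `frequency_table`, `pca_group_separation` | density-minimum receptor thresholds; PAM50-panel hierarchical clustering with centroid-majority labels; claudin-low rescue; Carey IHC classes |
| ECM biclustering | `las_score`, `las_search`, `identify_ecm_clusters`, `stability_analysis` | large-average-submatrix score −[log C(m,k) + log C(n,l) + log Φ(−τ√(kl))], greedy alternating search, seed-list labelling, Jaccard stability |
| Subclass mapping | `snr_marker_ranking`, `enrichment_pvalue`, `submap` | mutual marker enrichment (weighted KS) with a sample-permutation null and BH-adjusted association matrix |
| Differential expression | `fit_linear_models`, `bh_fdr`, `call_de`, `storage_screen` | per-gene OLS with ethnicity + subtype covariates; significant = FDR < 0.05 and \|log2FC\| ≥ 1; storage-time screen at p < 0.001 |
| Cohort statistics | `chi_square_test`, `fisher_exact`, `cohens_kappa`, `partial_correlation`, `percentage_and_ratio` | Yates-corrected chi-square for 2×2 tables, exact tests, κ, residual-based partial correlation |
| Synthetic data | `simulation_config`, `generate_cohort_pair`, `generate_detection_p`, `write_fixture` | latent-factor modules, subtype centroids, bimodal markers, planted ECM blocks, storage covariate |

A thin command-line wrapper (`pipeline_cli()`, installed as
`exec/transbrca`) exposes the stages as subcommands (`simulate`,
`preprocess`, `clusters`, `subtypes`, `ecm`, `submap`, `de`, `stats`) with
YAML/JSON configs.

## A worked example

Generate a paired cohort under the default study conditions, check cluster
conservation, assign subtypes, and map the subclasses across cohorts:

```r
library(transbrca)

cfg  <- simulation_config(seed = 1)          # 2 x 90 samples, 2000 genes
pair <- generate_cohort_pair(cfg)

## correlated clusters: discover in cohort A, validate in cohort B
ds_a        <- iqr_filter(pair$cohort_a, 0.4)
clusters    <- discover_clusters(ds_a, corr_cut = 0.6, min_size = 10)
validations <- lapply(clusters, validate_cluster, ds_b = pair$cohort_b)
conservation_summary(clusters, validations)
#> discovered 15 clusters; 14 validated (93%); size correlation r = 1.00

## intrinsic subtypes on the PAM50-like panel
calls <- assign_intrinsic_subtypes(pair$cohort_a)
table(planted = pair$truth$subtype_labels[calls$sample_id],
      called  = calls$intrinsic)
#>        called
#> planted Basal ERBB2 LumA LumB Unclassified
#>   Basal    14     0    0    0            1
#>   ERBB2     0    22    0    0            0
#>   LumA      0     0   21    0            1
#>   LumB      0     0    0   31            0

frequency_table(calls$intrinsic, rep("chinese", nrow(calls)))$luminal_ratio
#> 0.68

## do the subtypes found in the two cohorts correspond?
la <- pair$truth$subtype_labels[colnames(pair$cohort_a$values)]
lb <- pair$truth$subtype_labels[colnames(pair$cohort_b$values)]
submap(pair$cohort_a, la, pair$cohort_b, lb, seed = 2)$fdr
#>       Basal ERBB2 LumA LumB
#> Basal  0.02  1.00 1.00 1.00
#> ERBB2  1.00  0.02 1.00 1.00
#> LumA   1.00  1.00 0.02 1.00
#> LumB   1.00  1.00 1.00 0.02
```

Fifteen correlated clusters are discovered (the ten planted shared
modules, one cohort-private module, plus the emergent ER, proliferation
and ECM clusters the subtype and block structure create); fourteen
validate — all but the cohort-private one. Subtype calls agree with the
planted truth for 98% of samples, and the subclass association matrix is
diagonal: each subtype found in cohort A maps onto the same subtype in
cohort B (FDR 0.02, the permutation floor) and onto nothing else.

## License

MIT.
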