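# Synthetic paired-cohort generator.
#
# Emulates the data structure of a two-cohort breast cancer profiling study:
# latent-factor modules of correlated genes shared (or not) across cohorts,
# four intrinsic-subtype centroids over a PAM50-like 45-gene panel, bimodal
# ER/ERBB2 marker distributions, planted high-average ECM submatrices, an
# optional additive cohort batch shift, and a storage-time covariate acting
# on a small fraction of genes. Every planted entity is recorded in a
# ground-truth object so downstream stages can be scored.

#' The synthetic PAM50-like gene panel
#'
#' A 45-gene panel mirroring the usable part of the PAM50 signature (five
#' PAM50 genes are typically absent from bead-array platforms), organised
#' into expression modules: luminal/ER, proliferation, ERBB2 amplicon,
#' basal keratins, and small luminal-A- and luminal-B-specific groups.
#'
#' @return A data.frame with columns `gene` and `module`.
#' @export
pam50_panel <- function() {
  mods <- list(
    er     = c("ESR1", "PGR", "FOXA1", "MLPH", "NAT1", "SLC39A6", "MAPT",
               "BAG1", "GPR160", "MDM2"),
    prolif = c("MKI67", "CCNB1", "BIRC5", "CDC20", "UBE2C", "RRM2", "TYMS",
               "CENPF", "KIF2C", "CCNE1"),
    erbb2  = c("ERBB2", "GRB7", "FGFR4", "TMEM45B", "MMP11"),
    basal  = c("KRT5", "KRT14", "KRT17", "FOXC1", "SFRP1", "EGFR", "CDH3",
               "PHGDH", "ACTR3B", "MYC"),
    luma   = c("BCL2", "BLVRA", "CDC6", "ANLN", "EXO1"),
    lumb   = c("NDC80", "PTTG1", "CEP55", "UBE2T", "MELK"))
  data.frame(gene = unlist(mods, use.names = FALSE),
             module = rep(names(mods), lengths(mods)),
             stringsAsFactors = FALSE)
}

#' Subtype centroids over the synthetic PAM50-like panel
#'
#' Per-gene expected deviation (in units of half the marker separation)
#' for each of the four intrinsic subtypes. Luminal subtypes are high on
#' the ER module, luminal B and basal-like are high on proliferation,
#' ERBB2 is high on the ERBB2-amplicon module, ER-negative subtypes are
#' low on the ER module, and each luminal subtype carries a small
#' exclusive module, as the real panel does.
#'
#' @return Numeric matrix, panel genes x subtypes (LumA, LumB, ERBB2, Basal).
#' @export
pam50_centroids <- function() {
  pat <- rbind(  #      LumA LumB ERBB2 Basal
    er     = c( 1,  1, -1, -1),
    prolif = c(-1,  1,  0,  1),
    erbb2  = c( 0,  0,  1,  0),
    basal  = c( 0,  0,  0,  1),
    luma   = c( 1,  0,  0,  0),
    lumb   = c( 0,  1,  0,  0))
  colnames(pat) <- c("LumA", "LumB", "ERBB2", "Basal")
  panel <- pam50_panel()
  out <- pat[panel$module, , drop = FALSE]
  rownames(out) <- panel$gene
  out
}

#' Claudin/E-cadherin panel used for claudin-low rescue
#' @return Character vector of epithelial junction genes.
#' @export
claudin_panel <- function() c("CLDN3", "CLDN4", "CLDN7", "CDH1", "OCLN")

# ECM gene pools: a collagen/stromal pool (ECM3-like) and an immune
# protease/adhesion pool (ECM1-like), plus anonymous filler to reach the
# requested universe size.
ecm3_pool <- function() c(
  "SPARC", "BGN", "CDH11", "FN1", "LAMA4", "MMP2", "COL1A1", "COL1A2",
  "COL5A1", "COL5A2", "COL5A3", "COL6A1", "COL6A2", "COL6A3", "COL3A1",
  "THBS2", "POSTN", "LUM", "DCN", "FBN1")

ecm1_pool <- function() c(
  "CTSS", "GZMK", "MMP7", "MMP9", "SELL", "SPOCK2", "VCAM1", "GZMA",
  "GZMB", "GZMH", "GZMM", "CTSC", "CTSH", "CTSW", "CTSZ", "ITGA4",
  "ITGAL", "ITGAX", "ITGB2", "ITGB7", "ADAM7", "ADAM28")

#' The synthetic ECM-related gene universe
#'
#' Union of the collagen/stromal (ECM3-like) and immune protease/adhesion
#' (ECM1-like) pools planted by the generator; the universe LAS
#' biclustering is run on.
#'
#' @return Character vector of gene symbols.
#' @export
ecm_universe_genes <- function() c(ecm3_pool(), ecm1_pool())

#' Seed gene lists used to label ECM biclusters
#' @return A gene-set list (name, description, members) for the requested list.
#' @param which `"ecm1"` (immune protease seed genes) or `"ecm3"`
#'   (collagen/stromal signature).
#' @export
ecm_seed_genes <- function(which = c("ecm1", "ecm3")) {
  which <- match.arg(which)
  if (which == "ecm1")
    list(name = "ECM1_seed", description = "immune protease/adhesion markers",
         members = c("CTSS", "GZMK", "MMP7", "MMP9", "SELL", "SPOCK2", "VCAM1"))
  else
    list(name = "ECM3_seed", description = "collagen/stromal signature",
         members = ecm3_pool()[1:14])
}

#' Build a validated simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: two
#' cohorts of 90 samples, 2000 genes with ten shared and two
#' cohort-private correlated modules, a subtype mixture close to the
#' Shanghai series, clearly bimodal receptor markers, disjoint planted
#' ECM3/ECM1 submatrices, no batch shift, and a storage-time effect on
#' 0.3% of genes.
#'
#' @param n_samples_per_cohort Samples per cohort.
#' @param n_genes,n_mirnas Feature counts for the gene and miRNA assays.
#' @param modules List of gene modules, each
#'   `list(size =, latent_loading =, shared = TRUE/FALSE)`; non-shared
#'   modules are correlated in one cohort only (alternating A, B).
#' @param mirna_modules Same structure for the miRNA assay.
#' @param subtype_mixture Named proportions over LumA, LumB, ERBB2, Basal
#'   summing to 1.
#' @param marker_separation Distance (log2 units) between the two modes of
#'   bimodal marker genes; also scales the subtype centroids (amplitude
#'   `marker_separation / 2`).
#' @param ecm_blocks Named list of planted submatrices, each
#'   `list(n_rows =, col_frac =, shift =)`, keyed `ECM3`/`ECM1`.
#' @param batch_shift Additive log2 offset applied to the whole second cohort.
#' @param storage_effect `list(n_genes_affected =, slope =)`, slope in log2
#'   units per hour of pre-freezing storage.
#' @param noise_sd Per-gene Gaussian noise standard deviation (log2 units).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples_per_cohort = 90,
                              n_genes = 2000,
                              n_mirnas = 400,
                              modules = default_gene_modules(),
                              mirna_modules = default_mirna_modules(),
                              subtype_mixture = c(LumA = 0.30, LumB = 0.30,
                                                  ERBB2 = 0.22, Basal = 0.18),
                              marker_separation = 4,
                              ecm_blocks = default_ecm_blocks(),
                              batch_shift = 0,
                              storage_effect = list(
                                n_genes_affected = max(1L, round(0.003 * n_genes)),
                                slope = 0.3),
                              noise_sd = 0.5,
                              seed = 1L) {
  cfg <- list(n_samples_per_cohort = n_samples_per_cohort, n_genes = n_genes,
              n_mirnas = n_mirnas, modules = modules,
              mirna_modules = mirna_modules,
              subtype_mixture = subtype_mixture,
              marker_separation = marker_separation, ecm_blocks = ecm_blocks,
              batch_shift = batch_shift, storage_effect = storage_effect,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

default_gene_modules <- function() {
  sizes <- c(40, 30, 25, 20, 18, 15, 14, 12, 11, 10)
  shared <- lapply(sizes, function(s)
    list(size = s, latent_loading = 0.9, shared = TRUE))
  private <- list(list(size = 15, latent_loading = 0.9, shared = FALSE),
                  list(size = 12, latent_loading = 0.9, shared = FALSE))
  c(shared, private)
}

default_mirna_modules <- function() {
  sizes <- c(15, 12, 10, 8, 8, 6)
  c(lapply(sizes, function(s) list(size = s, latent_loading = 0.9, shared = TRUE)),
    list(list(size = 8, latent_loading = 0.9, shared = FALSE)))
}

default_ecm_blocks <- function() {
  list(ECM3 = list(n_rows = 20, col_frac = 0.30, shift = 1.5),
       ECM1 = list(n_rows = 15, col_frac = 0.20, shift = 1.5))
}

validate_simulation_config <- function(cfg) {
  counts <- c(n_samples_per_cohort = cfg$n_samples_per_cohort,
              n_genes = cfg$n_genes, n_mirnas = cfg$n_mirnas)
  bad <- names(counts)[!vapply(counts, is_count, TRUE)]
  if (length(bad)) tb_stop("configuration error: %s must be positive integers",
                           paste(bad, collapse = ", "))
  mix <- cfg$subtype_mixture
  if (!setequal(names(mix), c("LumA", "LumB", "ERBB2", "Basal")))
    tb_stop("configuration error: subtype_mixture must be named LumA, LumB, ERBB2, Basal")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    tb_stop("configuration error: subtype_mixture must be non-negative and sum to 1 (got %.12f)",
            sum(mix))
  for (m in cfg$modules) {
    if (!is_count(m$size) || m$size < 2)
      tb_stop("configuration error: module sizes must be integers >= 2")
    if (m$latent_loading <= 0 || m$latent_loading > 1)
      tb_stop("configuration error: latent_loading must lie in (0, 1]")
  }
  reserved <- nrow(pam50_panel()) + length(claudin_panel()) +
    length(ecm3_pool()) + length(ecm1_pool())
  need <- reserved + sum(vapply(cfg$modules, `[[`, 0, "size"))
  if (need > cfg$n_genes)
    tb_stop("configuration error: %d genes needed for panels and modules but n_genes = %d",
            need, cfg$n_genes)
  if (sum(vapply(cfg$mirna_modules, `[[`, 0, "size")) > cfg$n_mirnas)
    tb_stop("configuration error: miRNA module sizes exceed n_mirnas")
  if (cfg$noise_sd <= 0) tb_stop("configuration error: noise_sd must be > 0")
  invisible(cfg)
}

#' Generate a paired-cohort synthetic dataset with ground truth
#'
#' Draws a per-sample annotation (subtype, age, storage hours) once per
#' seed, then an expression matrix per cohort. Module genes follow a
#' single-latent-factor model (`loading * factor + noise`); shared modules
#' keep identical membership across cohorts but use independent factor
#' draws, so the cross-cohort signal is the correlation structure, not the
#' values. Panel genes add the subtype centroid; ECM pool genes add the
#' planted submatrix shifts; storage-affected genes add `slope * hours`.
#'
#' @param config A [simulation_config()].
#' @param assay `"gene"` or `"mirna"`. The same seed yields the same sample
#'   annotation for both assays, so gene and miRNA datasets are matched.
#' @return A list with `cohort_a`, `cohort_b` (both [expression_dataset()])
#'   and `truth` (ground-truth record; see Details).
#' @details `truth` contains `module_membership` (feature -> module id),
#'   `module_cohort` (module id -> "both"/"A"/"B"), `subtype_labels`,
#'   `er_status`, `erbb2_status`, `thresholds` (true bimodal cuts for ESR1
#'   and ERBB2), `ecm` (planted rows and per-cohort columns per block),
#'   `storage_genes`, `storage_slope`, and the sample `annotation` table.
#' @export
generate_cohort_pair <- function(config, assay = c("gene", "mirna")) {
  assay <- match.arg(assay)
  validate_simulation_config(config)
  withr::with_seed(config$seed, generate_pair_impl(config, assay))
}

generate_pair_impl <- function(cfg, assay) {
  n <- cfg$n_samples_per_cohort
  sep <- cfg$marker_separation
  amp <- sep / 2

  ## --- annotation, drawn identically for both assays -------------------
  sid_a <- sprintf("CH_S%03d", seq_len(n))
  sid_b <- sprintf("IT_S%03d", seq_len(n))
  subtypes <- names(cfg$subtype_mixture)
  lab_a <- sample(subtypes, n, replace = TRUE, prob = cfg$subtype_mixture)
  lab_b <- sample(subtypes, n, replace = TRUE, prob = cfg$subtype_mixture)
  labels <- stats::setNames(c(lab_a, lab_b), c(sid_a, sid_b))
  er_true <- labels %in% c("LumA", "LumB")
  erbb2_true <- labels == "ERBB2"
  names(er_true) <- names(erbb2_true) <- names(labels)
  age <- round(c(stats::rnorm(n, 50, 9), stats::rnorm(n, 60, 10)))
  hours <- c(stats::runif(n, 0.25, 1), stats::runif(n, 0.5, 4))
  flip <- stats::runif(2 * n) < 0.03   # small IHC/expression discordance
  er_ihc <- ifelse(xor(er_true, flip), "pos", "neg")
  pr_ihc <- ifelse(er_true & stats::runif(2 * n) < 0.8, "pos", "neg")
  her2_ihc <- ifelse(erbb2_true, "pos", "neg")
  annotation <- data.frame(
    sample_id = names(labels),
    cohort = rep(c("chinese", "caucasian"), each = n),
    age = age, er_ihc = er_ihc, pr_ihc = pr_ihc, her2_ihc = her2_ihc,
    storage_hours = hours, true_subtype = unname(labels),
    stringsAsFactors = FALSE)

  ## --- feature layout --------------------------------------------------
  if (assay == "gene") {
    panel <- pam50_panel()
    centroids <- pam50_centroids()
    named <- c(panel$gene, claudin_panel(), ecm3_pool(), ecm1_pool())
    mods <- cfg$modules
    mod_sizes <- vapply(mods, `[[`, 0, "size")
    n_named <- length(named)
    n_free <- cfg$n_genes - n_named
    free_ids <- sprintf("G%05d", seq_len(n_free))
    features <- c(named, free_ids)
  } else {
    mods <- cfg$mirna_modules
    mod_sizes <- vapply(mods, `[[`, 0, "size")
    features <- sprintf("hsa-miR-%04d", seq_len(cfg$n_mirnas))
    free_ids <- features
  }
  n_feat <- length(features)

  # module membership drawn from the anonymous pool
  mod_ids <- sprintf("M%02d", seq_along(mods))
  mod_cohort <- vapply(seq_along(mods), function(i) {
    if (isTRUE(mods[[i]]$shared) || is.null(mods[[i]]$shared)) "both"
    else c("A", "B")[1 + (i %% 2)]
  }, "")
  names(mod_cohort) <- mod_ids
  membership <- character(0)
  if (length(mods)) {
    pool <- if (assay == "gene") free_ids else features
    picked <- sample(pool, sum(mod_sizes))
    membership <- stats::setNames(rep(mod_ids, mod_sizes), picked)
  }

  baseline <- stats::setNames(stats::rnorm(n_feat, if (assay == "gene") 8 else 6,
                                           1.5), features)

  ## --- per-cohort matrices ---------------------------------------------
  make_cohort <- function(sids, labs, hrs, which, truth_env) {
    m <- matrix(stats::rnorm(n_feat * n, 0, cfg$noise_sd), n_feat, n,
                dimnames = list(features, sids))
    m <- m + baseline
    # latent-factor modules (independent factors per cohort)
    for (i in seq_along(mods)) {
      if (!(mod_cohort[i] %in% c("both", which))) next
      genes <- names(membership)[membership == mod_ids[i]]
      f <- stats::rnorm(n)
      m[genes, ] <- m[genes, ] +
        mods[[i]]$latent_loading * matrix(f, length(genes), n, byrow = TRUE)
    }
    if (assay == "gene") {
      # subtype centroids over the panel
      m[rownames(centroids), ] <- m[rownames(centroids), ] +
        amp * centroids[, labs, drop = FALSE]
      # claudin genes: epithelial-high in all intrinsic subtypes
      m[claudin_panel(), ] <- m[claudin_panel(), ] + 1
      # planted ECM blocks (disjoint rows and columns)
      pools <- list(ECM3 = ecm3_pool(), ECM1 = ecm1_pool())
      used_cols <- character(0)
      for (bl in names(cfg$ecm_blocks)) {
        b <- cfg$ecm_blocks[[bl]]
        rows <- pools[[bl]][seq_len(min(b$n_rows, length(pools[[bl]])))]
        ncols <- max(2L, round(b$col_frac * n))
        # ECM3 tumours drawn mainly from ER-positive samples, ECM1 from
        # ER-negative, mirroring the observed receptor composition
        w <- if (bl == "ECM3") ifelse(labs %in% c("LumA", "LumB"), 0.78, 0.22)
             else ifelse(labs %in% c("LumA", "LumB"), 0.25, 0.75)
        w[sids %in% used_cols] <- 1e-9
        cols <- sample(sids, ncols, prob = w)
        used_cols <- c(used_cols, cols)
        m[rows, cols] <- m[rows, cols] + b$shift
        truth_env$ecm[[bl]]$rows <- rows
        truth_env$ecm[[bl]]$cols[[which]] <- sort(cols)
      }
      # storage-time effect on a small gene fraction
      m[truth_env$storage_genes, ] <- m[truth_env$storage_genes, ] +
        truth_env$storage_slope * matrix(hrs, length(truth_env$storage_genes),
                                         n, byrow = TRUE)
    } else {
      # a modest subtype signal so miRNA PCA groups by subtype
      sig <- truth_env$mirna_subtype_features
      pat <- truth_env$mirna_subtype_pattern
      m[sig, ] <- m[sig, ] + (amp / 2) * pat[, labs, drop = FALSE]
    }
    if (which == "B") m <- m + cfg$batch_shift
    m
  }

  truth_env <- new.env()
  truth_env$ecm <- list(ECM3 = list(rows = NULL, cols = list()),
                        ECM1 = list(rows = NULL, cols = list()))
  if (assay == "gene") {
    unreserved <- setdiff(free_ids, names(membership))
    k <- min(cfg$storage_effect$n_genes_affected, length(unreserved))
    truth_env$storage_genes <- sample(unreserved, k)
    truth_env$storage_slope <- cfg$storage_effect$slope
  } else {
    truth_env$storage_genes <- character(0)
    truth_env$storage_slope <- 0
    n_sig <- min(60L, length(setdiff(features, names(membership))))
    sig <- sample(setdiff(features, names(membership)), n_sig)
    pat <- matrix(stats::rnorm(n_sig * 4), n_sig, 4,
                  dimnames = list(sig, subtypes))
    pat <- sign(pat)          # +/-1 patterns, distinct per subtype
    truth_env$mirna_subtype_features <- sig
    truth_env$mirna_subtype_pattern <- pat
  }

  m_a <- make_cohort(sid_a, lab_a, hours[seq_len(n)], "A", truth_env)
  m_b <- make_cohort(sid_b, lab_b, hours[n + seq_len(n)], "B", truth_env)

  thresholds <- if (assay == "gene")
    c(ESR1 = unname(baseline["ESR1"]),
      ERBB2 = unname(baseline["ERBB2"]) + sep / 4)
  else numeric(0)

  truth <- list(
    module_membership = membership,
    module_cohort = mod_cohort,
    subtype_labels = labels,
    er_status = er_true,
    erbb2_status = erbb2_true,
    thresholds = thresholds,
    ecm = truth_env$ecm,
    storage_genes = truth_env$storage_genes,
    storage_slope = truth_env$storage_slope,
    annotation = annotation,
    assay = assay)

  list(cohort_a = expression_dataset(m_a, cohort = "chinese"),
       cohort_b = expression_dataset(m_b, cohort = "caucasian"),
       truth = truth)
}

#' Attach constructed detection p-values to a dataset
#'
#' A designated fraction of features is made "undetected" (detection
#' p >= alpha in every sample); every other feature receives p < alpha in
#' at least one sample, so it survives [filter_by_detection()].
#'
#' @param ds An [expression_dataset()].
#' @param frac_undetected Fraction of features to mark undetected, in \[0, 1).
#' @param alpha Detection threshold the downstream filter will use.
#' @param seed Integer seed.
#' @return The dataset with a `detection_p` matrix attached.
#' @export
generate_detection_p <- function(ds, frac_undetected, alpha = 0.01, seed = 1L) {
  if (!is.numeric(frac_undetected) || frac_undetected < 0 || frac_undetected >= 1)
    tb_stop("frac_undetected must lie in [0, 1)")
  nf <- nrow(ds$values); ns <- ncol(ds$values)
  withr::with_seed(seed, {
    p <- matrix(stats::runif(nf * ns, alpha, 1), nf, ns,
                dimnames = dimnames(ds$values))
    k <- round(frac_undetected * nf)
    detected <- if (k > 0) -sample.int(nf, k) else seq_len(nf)
    for (i in seq_len(nf)[detected]) {
      j <- sample.int(ns, 1)
      p[i, j] <- stats::runif(1, 0, alpha * 0.9)
    }
    expression_dataset(ds$values, detection_p = p, cohort = ds$cohort)
  })
}

#' Write a synthetic fixture to disk
#'
#' Writes per-dataset expression (and detection) TSVs, the sample
#' annotation, a ground-truth JSON, the panel gene sets as GMT, and the
#' subtype centroid table, such that reading the files back reproduces the
#' matrices to full precision.
#'
#' @param datasets Named list of [expression_dataset()] objects.
#' @param truth Ground-truth record from [generate_cohort_pair()].
#' @param directory Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture <- function(datasets, truth, directory) {
  if (length(datasets) == 0) tb_stop("no datasets supplied; nothing written")
  if (!all(vapply(datasets, inherits, TRUE, "ExpressionDataset")))
    tb_stop("all datasets must be ExpressionDataset objects")
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    tb_stop("datasets must be a named list")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(datasets)) {
    f <- file.path(directory, paste0(nm, "_expression.tsv"))
    write_expression_tsv(datasets[[nm]], f)
    files <- c(files, f)
    if (!is.null(datasets[[nm]]$detection_p)) {
      f <- file.path(directory, paste0(nm, "_detection.tsv"))
      write_expression_tsv(datasets[[nm]], f, what = "detection_p")
      files <- c(files, f)
    }
  }
  f <- file.path(directory, "sample_annotation.tsv")
  utils::write.table(truth$annotation, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(directory, "truth.json")
  tr <- truth[setdiff(names(truth), "annotation")]
  named_fields <- c("module_membership", "module_cohort", "subtype_labels",
                    "er_status", "erbb2_status", "thresholds")
  for (nf in intersect(named_fields, names(tr)))
    tr[[nf]] <- as.list(tr[[nf]])          # keep names in the JSON objects
  jsonlite::write_json(tr, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)
  panel <- pam50_panel()
  sets <- c(list(PAM50_like = list(name = "PAM50_like",
                                   description = "synthetic intrinsic panel",
                                   members = panel$gene),
                 claudin = list(name = "claudin", description =
                                  "claudin/E-cadherin epithelial panel",
                                members = claudin_panel()),
                 ECM_universe = list(name = "ECM_universe", description =
                                       "synthetic ECM-related universe",
                                     members = c(ecm3_pool(), ecm1_pool()))),
            list(ECM1_seed = ecm_seed_genes("ecm1"),
                 ECM3_seed = ecm_seed_genes("ecm3")))
  f <- file.path(directory, "gene_sets.gmt")
  write_gmt(sets, f)
  files <- c(files, f)
  f <- file.path(directory, "pam50_centroids.tsv")
  write_matrix_tsv(pam50_centroids(), f, id_label = "gene")
  files <- c(files, f)
  invisible(files)
}
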