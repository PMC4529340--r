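# Bimodal thresholding, marker status, PAM50-panel subtyping, claudin-low
# rescue, Carey IHC classes, frequency tables, PCA separation.

test_that("bimodal threshold finds the density pit between modes", {
  withr::local_seed(201)
  x <- c(rnorm(200), rnorm(200, 6))
  bt <- bimodal_threshold(x)
  expect_gt(bt$threshold, 2.5)   # true minimum at 3 by symmetry
  expect_lt(bt$threshold, 3.5)

  # weighted mixture: compare with the analytic density minimum
  y <- c(rnorm(280), rnorm(120, 6))
  mix_density <- function(z) 0.7 * dnorm(z) + 0.3 * dnorm(z, 6)
  true_min <- optimize(mix_density, c(1, 5))$minimum
  expect_lt(abs(bimodal_threshold(y)$threshold - true_min), 0.5)

  expect_error(bimodal_threshold(rnorm(400)), class = "transbrca_non_bimodal")
  expect_error(bimodal_threshold(rnorm(10)), "20")
  expect_error(bimodal_threshold(rep(1, 30)), "constant")
})

test_that("marker status calls recover planted receptor status", {
  cfg <- small_config(noise_sd = 1, marker_separation = 4, seed = 211)
  pair <- suppressMessages(generate_cohort_pair(cfg))
  er <- classify_marker_status(pair$cohort_a, "ESR1")
  truth <- pair$truth$er_status[names(er)]
  expect_gte(mean(er == truth), 0.95)
  # threshold is interior: both classes occur
  expect_true(any(er) && !all(er))
  # translation equivariance
  shifted <- pair$cohort_a
  shifted$values <- shifted$values + 3
  er2 <- classify_marker_status(shifted, "ESR1")
  expect_identical(as.logical(er), as.logical(er2))
  expect_equal(attr(er2, "threshold"), attr(er, "threshold") + 3,
               tolerance = 1e-8)
})

test_that("intrinsic subtyping recovers planted centroids", {
  cfg <- simulation_config(n_samples_per_cohort = 100, n_genes = 400,
                           n_mirnas = 50,
                           modules = list(), mirna_modules = list(),
                           subtype_mixture = c(LumA = .25, LumB = .25,
                                               ERBB2 = .25, Basal = .25),
                           seed = 221)
  pair <- generate_cohort_pair(cfg)
  calls <- assign_intrinsic_subtypes(pair$cohort_a)
  truth <- pair$truth$subtype_labels[calls$sample_id]
  classified <- calls$intrinsic != "Unclassified"
  expect_gte(mean(calls$intrinsic == truth), 0.95)
  # invariance to sample order and to adding a constant
  perm <- sample(ncol(pair$cohort_a$values))
  ds_p <- expression_dataset(pair$cohort_a$values[, perm] + 2)
  calls_p <- assign_intrinsic_subtypes(ds_p)
  expect_equal(calls_p$intrinsic[match(calls$sample_id, calls_p$sample_id)],
               calls$intrinsic)
  # panel coverage floor
  small <- expression_dataset(
    pair$cohort_a$values[pam50_panel()$gene[1:10], ])
  expect_error(assign_intrinsic_subtypes(small), "panel genes present")
})

test_that("two identical samples receive identical intrinsic labels", {
  cfg <- small_config(seed = 231)
  pair <- suppressMessages(generate_cohort_pair(cfg))
  v <- pair$cohort_a$values
  v[, 2] <- v[, 1]
  colnames(v)[2] <- "clone_of_1"
  calls <- assign_intrinsic_subtypes(expression_dataset(v))
  expect_equal(calls$intrinsic[1], calls$intrinsic[2])
})

test_that("claudin-low rescue relabels low-claudin unclassified samples", {
  withr::local_seed(241)
  n_hi <- 25; n_lo <- 5
  genes <- claudin_panel()
  v <- cbind(matrix(rnorm(length(genes) * n_hi, 9, 0.5), length(genes)),
             matrix(rnorm(length(genes) * n_lo, 5, 0.5), length(genes)))
  rownames(v) <- genes
  colnames(v) <- sprintf("s%02d", seq_len(n_hi + n_lo))
  ds <- expression_dataset(v)
  calls <- data.frame(sample_id = colnames(v),
                      intrinsic = c(rep("LumA", 20),
                                    rep("Unclassified", 5),  # high claudin
                                    rep("Unclassified", 5))) # low claudin
  out <- assign_claudin_low(ds, calls)
  expect_equal(out$intrinsic[26:30], rep("ClaudinLow", 5))
  expect_equal(out$intrinsic[21:25], rep("Unclassified", 5))
  expect_equal(out$intrinsic[1:20], rep("LumA", 20))   # only candidates change
  # empty candidate set: no changes
  none <- calls; none$intrinsic <- "LumA"
  expect_identical(assign_claudin_low(ds, none), none)
  no_claudin <- expression_dataset(
    matrix(as.numeric(1:4), 2, 2, dimnames = list(c("a", "b"), c("s01", "s02"))))
  unk <- data.frame(sample_id = c("s01", "s02"), intrinsic = "Unclassified")
  expect_error(assign_claudin_low(no_claudin, unk), "claudin")
})

test_that("Carey IHC rules are total and mutually exclusive", {
  expect_equal(ihc_subtype(TRUE, FALSE, FALSE), "LumHER2neg")
  expect_equal(ihc_subtype(FALSE, FALSE, TRUE), "HER2posERneg")
  expect_equal(ihc_subtype(FALSE, FALSE, FALSE), "TripleNeg")
  expect_equal(ihc_subtype(FALSE, TRUE, TRUE), "LumHER2pos")
  combos <- expand.grid(er = c(TRUE, FALSE), pr = c(TRUE, FALSE),
                        her2 = c(TRUE, FALSE))
  cls <- ihc_subtype(combos$er, combos$pr, combos$her2)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls),
                  c("LumHER2neg", "LumHER2pos", "HER2posERneg", "TripleNeg"))
  expect_true(is.na(ihc_subtype(NA, TRUE, FALSE)))
})

test_that("frequency table reproduces the printed percentage arithmetic", {
  # Shanghai-style counts: 21 LumA and 23 LumB of 78
  calls <- rep(c("LumA", "LumB", "Basal", "ERBB2", "Unclassified"),
               c(21, 23, 10, 17, 7))
  ft <- frequency_table(calls, rep("shanghai", 78))
  expect_equal(unname(ft$percentages["LumA", 1]), 27)
  expect_equal(unname(ft$percentages["LumB", 1]), 29)
  expect_equal(unname(ft$luminal_ratio), 0.93)
  expect_equal(sum(ft$counts), 78)
  # Singapore-style counts: 25 and 38 of 100
  calls2 <- rep(c("LumA", "LumB", "Basal", "ERBB2", "Unclassified"),
                c(25, 38, 8, 17, 12))
  expect_equal(unname(frequency_table(calls2, rep("sg", 100))$luminal_ratio),
               0.66)
  # equal counts give ratio 1
  calls3 <- rep(c("LumA", "LumB"), c(10, 10))
  expect_equal(unname(frequency_table(calls3, rep("x", 20))$luminal_ratio), 1)
  # percentages sum to ~100 and counts exactly to n
  expect_lte(abs(sum(frequency_table(calls, rep("a", 78))$percentages) - 100),
             length(unique(calls)))
})

test_that("PCA separation ranks subtype structure above cohort labels", {
  cfg <- small_config(seed = 251)
  pm <- suppressMessages(generate_cohort_pair(cfg, assay = "mirna"))
  m <- merge_pair(pm)
  res <- pca_group_separation(m$ds, m$subtype, m$ethnicity)
  expect_gt(res$silhouette_a, res$silhouette_b)
  # perfect two-blob labels give silhouette near 1
  withr::local_seed(252)
  blob <- cbind(matrix(rnorm(40 * 10, 0, 0.1), 40),
                matrix(rnorm(40 * 10, 5, 0.1), 40))
  rownames(blob) <- paste0("g", 1:40); colnames(blob) <- paste0("s", 1:20)
  res2 <- pca_group_separation(expression_dataset(blob),
                               rep(c("a", "b"), each = 10),
                               sample(rep(c("x", "y"), 10)))
  expect_gt(res2$silhouette_a, 0.9)
  # random labels hover near zero
  expect_lt(abs(res2$silhouette_b), 0.2)
})
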