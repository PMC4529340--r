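# Cluster discovery at the correlation cut, cross-cohort validation,
# conservation summaries, hypergeometric enrichment.

planted_two_modules <- function(seed = 101, n = 100) {
  # 2 modules of 15 genes (loading 0.95) + 10 independent genes
  withr::with_seed(seed, {
    f1 <- rnorm(n); f2 <- rnorm(n)
    m <- rbind(
      t(sapply(1:15, function(i) 0.95 * f1 + rnorm(n, sd = 0.3))),
      t(sapply(1:15, function(i) 0.95 * f2 + rnorm(n, sd = 0.3))),
      matrix(rnorm(10 * n), 10, n))
    rownames(m) <- c(sprintf("m1_%02d", 1:15), sprintf("m2_%02d", 1:15),
                     sprintf("bg_%02d", 1:10))
    colnames(m) <- sprintf("s%03d", 1:n)
    expression_dataset(m, cohort = "seedco")
  })
}

test_that("discovery recovers planted modules exactly at the cut", {
  ds <- planted_two_modules()
  cl <- discover_clusters(ds, corr_cut = 0.6, min_size = 10)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, sprintf("m1_%02d", 1:15))
  expect_setequal(cl[[2]]$members, sprintf("m2_%02d", 1:15))
  expect_equal(vapply(cl, `[[`, "", "id"), c("C1", "C2"))
  expect_error(discover_clusters(ds, corr_cut = 1.2), "corr_cut")
})

test_that("duplicate rows merge at height zero and constant rows error", {
  base <- noise_dataset(20, 30, seed = 7)
  v <- base$values
  v["g002", ] <- v["g001", ]                   # r exactly 1
  v <- rbind(v, extra = v["g001", ] + rnorm(30, sd = 1e-6))
  ds <- expression_dataset(v)
  cl <- discover_clusters(ds, corr_cut = 0.6, min_size = 2)
  grp <- Filter(function(c0) "g001" %in% c0$members, cl)[[1]]
  expect_true(all(c("g002", "extra") %in% grp$members))

  v["g003", ] <- 5
  expect_error(discover_clusters(expression_dataset(v), 0.6, 2),
               "constant feature")
})

test_that("independent features yield no clusters", {
  ds <- noise_dataset(60, 50, seed = 13)
  expect_length(discover_clusters(ds, corr_cut = 0.6, min_size = 10), 0)
})

test_that("validation is self-consistent and detects non-conserved clusters", {
  ds <- planted_two_modules(seed = 5)
  cl <- discover_clusters(ds, corr_cut = 0.6, min_size = 10)
  # self-validation: every member re-correlates
  v_self <- validate_cluster(cl[[1]], ds)
  expect_equal(v_self$n_confirmed, length(cl[[1]]$members))
  expect_true(v_self$validated)
  # shared structure in an independent draw of the same generator
  ds_b <- planted_two_modules(seed = 6)
  v_shared <- validate_cluster(cl[[1]], ds_b)
  expect_true(v_shared$validated)
  expect_gte(v_shared$n_confirmed, 13)
  # independent data: nothing to confirm
  null_b <- noise_dataset(40, 100, seed = 8)
  rownames(null_b$values) <- rownames(ds$values)
  v_null <- validate_cluster(cl[[1]], null_b)
  expect_false(v_null$validated)
  expect_lt(v_null$n_confirmed, 3)
  # members absent from the validation data are dropped with a warning
  small <- subset_b <- expression_dataset(
    ds_b$values[c(cl[[1]]$members[1:5], "bg_01"), ])
  expect_warning(v_drop <- validate_cluster(cl[[1]], small), "absent")
  expect_equal(v_drop$n_present, 5)
  expect_error(suppressWarnings(validate_cluster(cl[[1]],
    expression_dataset(ds_b$values["bg_01", , drop = FALSE]))), "fewer than 2")
})

test_that("conservation summary reports fraction and size correlation", {
  ds <- planted_two_modules(seed = 9)
  cl <- discover_clusters(ds, corr_cut = 0.6, min_size = 10)
  va <- lapply(cl, validate_cluster, ds_b = ds)
  s <- conservation_summary(cl, va)
  expect_equal(s$fraction, 1)
  expect_true(is.na(s$size_pearson_r))      # only 2 pairs: undefined
  # fully conserved clusters with distinct sizes give r = 1
  fake_cl <- lapply(c(10, 14, 20), function(k)
    structure(list(id = paste0("C", k), members = paste0("g", seq_len(k)),
                   seed_cohort = "x", corr_cut = 0.6, min_size = 10L),
              class = "CorrelatedCluster"))
  fake_va <- lapply(fake_cl, function(c0)
    structure(list(cluster_id = c0$id, n_confirmed = length(c0$members),
                   validated = TRUE, min_confirm = 3L,
                   n_present = length(c0$members)),
              class = "ClusterValidation"))
  expect_equal(conservation_summary(fake_cl, fake_va)$size_pearson_r, 1)
  expect_error(conservation_summary(list(), list()), "undefined")
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  # worked instance N=20, K=5, n=6, k=4
  universe <- paste0("u", 1:20)
  gene_set <- universe[1:5]
  cluster <- c(universe[1:4], universe[10:11])
  res <- hypergeometric_enrichment(cluster, gene_set, universe)
  expect_equal(res$k, 4)
  expect_equal(res$p, oracle_hyper_tail(4, 5, 20, 6), tolerance = 1e-12)
  expect_equal(res$p, 0.01393189, tolerance = 1e-6)
  # k = 0: tail from zero includes everything
  res0 <- hypergeometric_enrichment(universe[10:12], universe[1:4], universe)
  expect_equal(res0$p, 1)
  # exhaustive agreement for all small configurations
  for (N in 5:12) {
    u <- paste0("x", seq_len(N))
    for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
      k <- min(K, n)       # maximal overlap case k = n or k = K
      res <- hypergeometric_enrichment(u[seq_len(k)],
                                       u[seq_len(K)], u)
      expect_equal(res$p, oracle_hyper_tail(k, K, N, min(k, n)),
                   tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_enrichment("a", "a", character(0)), "universe")
})

test_that("bidirectional conservation is symmetric for identical cohorts", {
  ds <- planted_two_modules(seed = 15)
  rep1 <- bidirectional_conservation(ds, ds, corr_cut = 0.6, min_size = 10)
  expect_equal(rep1$a_to_b$summary$fraction, 1)
  expect_equal(rep1$b_to_a$summary$fraction, 1)
  # symmetric generators give close fractions in the two directions
  ds_b <- planted_two_modules(seed = 16)
  rep2 <- bidirectional_conservation(ds, ds_b, corr_cut = 0.6, min_size = 10)
  expect_lte(abs(rep2$a_to_b$summary$fraction - rep2$b_to_a$summary$fraction),
             0.1)
})
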