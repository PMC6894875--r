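test_that("balanced factor cohort has the documented structure", {
  co <- simulate_factor_cohort(sim_config(n_samples = 40, seed = 11))
  expect_equal(dim(co), c(1000L, 40L))
  truth <- cohort_truth(co)
  expect_equal(sum(truth != "none"), 60)
  expect_equal(unname(table(truth)[c("sex", "age", "subtype")]),
               rep(20L, 3), ignore_attr = TRUE)
  ann <- cohort_annotation(co)
  groups <- table(ann$subtype, ann$sex, ann$age)
  expect_true(all(groups == 5))  # eight equally sized homogeneous groups
})

test_that("condition restricts genes and Only is a row-subset of All", {
  cfg_all <- sim_config(40, condition = "All", seed = 3)
  cfg_only <- sim_config(40, condition = "Only", seed = 3)
  cfg_wo <- sim_config(40, condition = "Without", seed = 3)
  all_co <- simulate_factor_cohort(cfg_all)
  only_co <- simulate_factor_cohort(cfg_only)
  wo_co <- simulate_factor_cohort(cfg_wo)
  expect_equal(nrow(only_co), 20L)
  expect_equal(nrow(wo_co), 1000L - 40L)
  Xa <- cohort_expression(all_co)
  Xo <- cohort_expression(only_co)
  expect_identical(Xa[rownames(Xo), ], Xo)
  expect_true(all(cohort_truth(only_co) == "subtype"))
})

test_that("generation is reproducible from the seed and seeds differ", {
  a <- cohort_expression(simulate_factor_cohort(sim_config(24, seed = 5)))
  b <- cohort_expression(simulate_factor_cohort(sim_config(24, seed = 5)))
  c <- cohort_expression(simulate_factor_cohort(sim_config(24, seed = 6)))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("affected-gene group means recover the effect size", {
  co <- simulate_factor_cohort(sim_config(n_samples = 1200, seed = 21))
  X <- cohort_expression(co)
  truth <- cohort_truth(co)
  ann <- cohort_annotation(co)
  tol <- 3 * 1 / sqrt(1200 * 20 / 2)  # 3 * noise_sd / sqrt(values per level)
  for (fac in c("sex", "age", "subtype")) {
    rows <- names(truth)[truth == fac]
    low_level <- switch(fac, sex = "male", age = "young", subtype = "A")
    low <- ann$sample_id[ann[[fac]] == low_level]
    high <- setdiff(ann$sample_id, low)
    expect_lt(abs(mean(X[rows, low]) + 1), tol)
    expect_lt(abs(mean(X[rows, high]) - 1), tol)
  }
  # non-affected genes are centered noise
  expect_lt(abs(mean(X[names(truth)[truth == "none"], ])), 0.01)
})

test_that("zero effect gives exchangeable noise but truth keeps memberships", {
  co <- simulate_factor_cohort(sim_config(40, effect_size = 0, seed = 2))
  expect_equal(sum(cohort_truth(co) != "none"), 60)
  X <- cohort_expression(co)
  expect_lt(abs(mean(X)), 0.05)
  expect_lt(abs(sd(X) - 1), 0.05)
})

test_that("with no effect the clustering ARI is centered on zero", {
  aris <- vapply(1:200, function(s) {
    co <- simulate_factor_cohort(sim_config(16, n_genes = 60,
                                            genes_per_factor = 10,
                                            effect_size = 0, seed = 500 + s))
    F <- t(cohort_expression(co))
    p <- hclust_ward(dissimilarity(F, "manhattan"), k = 2)
    as.numeric(ari(gold_partition(co), p))
  }, numeric(1))
  se <- sd(aris) / sqrt(length(aris))
  expect_lt(abs(mean(aris)), 3 * se)
})

test_that("sim_config rejects invalid settings", {
  expect_error(sim_config(40, n_genes = 50, genes_per_factor = 20),
               "exceeds n_genes")
  expect_error(sim_config(40, noise_sd = 0), "positive")
  expect_error(sim_config(40, effect_size = -1), ">= 0")
  expect_error(sim_config(40, fraction_subtype1 = 1), "strictly")
})

test_that("two-subtype cohort generator honors the rounding rule", {
  co <- simulate_tcga_like(100, 0.5, 0.5, seed = 1)
  ann <- cohort_annotation(co)
  expect_equal(unname(table(ann$subtype)), c(50L, 50L), ignore_attr = TRUE)
  expect_equal(unname(table(ann$sex)), c(50L, 50L), ignore_attr = TRUE)

  ann2 <- cohort_annotation(simulate_tcga_like(100, 0.2, seed = 1))
  expect_equal(sum(ann2$subtype == "A"), 20L)

  ann3 <- cohort_annotation(simulate_tcga_like(65, 0.4, seed = 1))
  expect_equal(sum(ann3$subtype == "A"), 26L)

  expect_error(simulate_tcga_like(3, 0.5), ">= 4")
  expect_error(simulate_tcga_like(10, 0), "strictly")
})

test_that("cohorts roundtrip through the plain-text writers", {
  co <- simulate_tcga_like(12, 0.5, seed = 9, n_genes = 30,
                           block_sizes = c(subtype = 5, sex = 3, age = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  X <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(X, cohort_expression(co), tolerance = 1e-8)
  ann <- read.delim(file.path(dir, "annotation.tsv"))
  expect_equal(ann$sample_id, cohort_annotation(co)$sample_id)
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(sum(tr$factor == "subtype"), 5)
})
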