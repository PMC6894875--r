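# Small cohort used across these tests: modest gene count keeps the grid
# machinery fast while leaving every canonical selection except top1000
# applicable.
small_cohort <- function(seed = 33, n = 120) {
  simulate_tcga_like(n, 0.5, 0.5, seed = seed, n_genes = 150,
                     block_sizes = c(subtype = 30, sex = 15, age = 10))
}

test_that("the canonical grid enumerates exactly 30 approaches", {
  g <- approach_grid()
  expect_equal(nrow(g), 30L)
  expect_equal(anyDuplicated(g$id), 0L)
  expect_equal(length(unique(g$selection)), 5L)
  expect_equal(length(unique(g$method)), 6L)
})

test_that("stratified subsampling honors counts, caps and determinism", {
  co <- simulate_tcga_like(300, 0.5, 0.5, seed = 1, n_genes = 60,
                           block_sizes = c(subtype = 10, sex = 5, age = 5))
  ids <- subsample(co, 100, 0.5, seed = 2)
  ann <- cohort_annotation(co)
  sub <- ann[match(ids, ann$sample_id), ]
  expect_equal(unname(table(sub$subtype)), c(50L, 50L), ignore_attr = TRUE)

  ids2 <- subsample(co, 65, 0.4, seed = 2)
  sub2 <- ann[match(ids2, ann$sample_id), ]
  expect_equal(sum(sub2$subtype == "A"), 26L)
  expect_equal(sum(sub2$subtype == "B"), 39L)

  expect_identical(subsample(co, 80, 0.5, seed = 9),
                   subsample(co, 80, 0.5, seed = 9))
  expect_false(identical(subsample(co, 80, 0.5, seed = 9),
                         subsample(co, 80, 0.5, seed = 10)))

  # cap: 150 per subtype available, 0.7 * 150 = 105
  expect_error(subsample(co, 240, 0.5, seed = 1), "cap")
  expect_error(subsample(co, 400, 0.5, seed = 1,
                         max_sampling_fraction = Inf), "exhausted")
  # full cohort is reachable with the cap disabled
  expect_setequal(subsample(co, 300, 0.5, seed = 1,
                            max_sampling_fraction = Inf), ann$sample_id)
})

test_that("design specifications validate their fields", {
  expect_error(design_spec("sample_size_sweep"), "n_values")
  expect_error(design_spec("distribution_sweep", fraction_values = 0.5),
               "n_fixed")
  expect_error(design_spec("distribution_sweep", fraction_values = c(0, 0.5),
                           n_fixed = 50), "strictly")
  d <- design_spec("sample_size_sweep", n_values = c(40, 60), seed = 7)
  expect_s3_class(d, "design_spec")
  expect_equal(d$replicates, 10L)
  expect_equal(d$max_sampling_fraction, 0.70)
})

test_that("run_grid emits one record per condition, replicate and approach", {
  co <- small_cohort()
  apps <- approach_grid(selections = c("top100", "pc5"))
  design <- design_spec("sample_size_sweep", n_values = 40, replicates = 2,
                        seed = 17)
  run <- run_grid(co, design, approaches = apps)
  expect_s3_class(run, "eval_run")
  rec <- run$records
  expect_equal(nrow(rec), 1 * 2 * nrow(apps))
  expect_true(all(!rec$skipped))
  expect_true(all(rec$ari <= 1))
  expect_true(all(table(rec$replicate) == nrow(apps)))

  # determinism: a rerun reproduces the records exactly
  run2 <- run_grid(co, design, approaches = apps)
  expect_identical(run$records, run2$records)
})

test_that("30-PC approaches are skipped below 30 samples", {
  co <- small_cohort()
  apps <- approach_grid(selections = c("top100", "pc30"),
                        methods = c("hclust_manhattan", "kmeans"))
  design <- design_spec("sample_size_sweep", n_values = 20, replicates = 1,
                        seed = 3)
  run <- run_grid(co, design, approaches = apps)
  rec <- run$records
  skipped <- rec[rec$skipped, ]
  expect_setequal(skipped$selection, "pc30")
  expect_equal(nrow(skipped), 2L)
  expect_true(all(is.na(skipped$ari)))
  expect_true(all(grepl("components", skipped$message)))
})

test_that("paired Wilcoxon comparisons follow the documented conventions", {
  apps <- approach_grid()$id
  recs <- function(ari_by_approach, skipped = rep(FALSE, length(apps))) {
    data.frame(condition = "c", n = 40, fraction = 0.5, stratum = NA,
               replicate = 1, approach = apps, selection = "x",
               method = "y", ari = ari_by_approach, degenerate = FALSE,
               skipped = skipped, message = "", stringsAsFactors = FALSE)
  }
  set.seed(51)
  base <- runif(30, 0.2, 0.6)
  cmp <- wilcoxon_compare(recs(base + 0.1), recs(base))
  expect_equal(cmp$median_delta, 0.1)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$n_approaches, 30L)
  expect_equal(cmp$test, "signed_rank_one_sample")

  # symmetric differences: no evidence of a shift
  sym <- c(rep(0.1, 15), rep(-0.1, 15))
  cmp2 <- wilcoxon_compare(recs(base + sym), recs(base))
  expect_gt(cmp2$p_value, 0.5)

  cmp3 <- wilcoxon_compare(recs(base), recs(base))
  expect_true(cmp3$all_zero)
  expect_equal(cmp3$p_value, 1)
  expect_equal(cmp3$median_delta, 0)

  # approaches missing on either side are dropped from the pairing
  skip30 <- grepl("^pc30", apps)
  a <- recs(base + 0.1); a$ari[skip30] <- NA; a$skipped[skip30] <- TRUE
  cmp4 <- wilcoxon_compare(a, recs(base))
  expect_equal(cmp4$n_approaches, 24L)

  cmp5 <- wilcoxon_compare(recs(base + 0.3), recs(base), paired = FALSE)
  expect_equal(cmp5$test, "rank_sum")
  expect_lt(cmp5$p_value, 0.01)
})

test_that("apARI per condition averages replicate cells", {
  ids <- paste0("s", 1:6)
  A <- partition(c(1, 1, 1, 2, 2, 2), sample_ids = ids)
  B <- partition(c(1, 1, 2, 2, 2, 2), sample_ids = ids)
  run <- structure(list(
    records = NULL,
    partitions = list(
      cond1 = list(list(m1 = A, m2 = A, m3 = A),
                   list(m1 = A, m2 = B, m3 = A))),
    design = NULL), class = "eval_run")
  out <- apari_by_condition(run)
  cell2 <- as.numeric(apari(list(A, B, A)))
  expect_equal(out$apari, mean(c(1, cell2)))
  expect_equal(out$n_replicates, 2L)
})

test_that("the sex-homogeneity design tags all five strata", {
  co <- simulate_tcga_like(160, 0.5, 0.5, seed = 8, n_genes = 120,
                           block_sizes = c(subtype = 30, sex = 30, age = 10))
  apps <- approach_grid(selections = "top100",
                        methods = c("hclust_manhattan", "kmeans"))
  run <- gender_design(co, n_per_arm = 24, approaches = apps,
                       replicates = 2, seed = 5)
  rec <- run$records
  expect_setequal(unique(rec$stratum),
                  c("Females", "Males", "Mixed_all", "Mixed_females",
                    "Mixed_males"))
  expect_equal(nrow(rec), 5 * 2 * nrow(apps))
  expect_true(all(rec$n[rec$stratum == "Mixed_females"] == 12))
  ann <- cohort_annotation(co)
  # single-sex arms really are single-sex and subtype-balanced
  expect_true(all(!rec$skipped))
})

test_that("simulation studies are deterministic and shaped as expected", {
  st <- simulation_study(n_values = 20, n_sims = 3, n_genes = 60,
                         genes_per_factor = 10, seed = 12)
  expect_equal(nrow(st$results), 3 * 3)
  expect_setequal(unique(st$results$condition), c("All", "Without", "Only"))
  expect_true(all(st$results$ari <= 1))
  st2 <- simulation_study(n_values = 20, n_sims = 3, n_genes = 60,
                          genes_per_factor = 10, seed = 12)
  expect_identical(st$results, st2$results)
  expect_equal(st$summary$n_sims, rep(3, 3))
})

test_that("evaluation configs parse from YAML", {
  cfg <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("design:",
               "  design: sample_size_sweep",
               "  n_values: [40, 60]",
               "  replicates: 4",
               "  seed: 2",
               "approaches:",
               "  - top100_kmeans",
               "  - pc5_som"), cfg)
  parsed <- read_eval_config(cfg)
  expect_s3_class(parsed$design, "design_spec")
  expect_equal(parsed$design$n_values, c(40, 60))
  expect_equal(nrow(parsed$approaches), 2L)
  writeLines(c("approaches:", "  - nope_kmeans"), cfg)
  expect_error(read_eval_config(cfg), "unknown approaches")
})
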