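#' The canonical grid of clustering approaches
#'
#' A clustering approach is one (selection, method) pair. The canonical
#' grid crosses the five selection/extraction methods (`top100`, `top1000`,
#' `all`, `pc5`, `pc30`) with the six clustering methods (Ward hierarchical
#' clustering under Manhattan and absolute-correlation distance, k-means,
#' SOM, affinity propagation, and the consensus ensemble over the other
#' five methods within the same selection), giving 30 approaches.
#'
#' @param selections character vector of selection names (default the
#'   canonical five).
#' @param methods character vector of method names (default the canonical
#'   six).
#' @return A data.frame with columns `id`, `selection`, `method`.
#' @export
approach_grid <- function(selections = names(canonical_selections()),
                          methods = c("hclust_manhattan",
                                      "hclust_correlation", "kmeans", "som",
                                      "affinity_propagation",
                                      "cluster_ensemble")) {
  g <- expand.grid(selection = selections, method = methods,
                   stringsAsFactors = FALSE)
  g <- g[order(match(g$selection, selections),
               match(g$method, methods)), ]
  data.frame(id = paste(g$selection, g$method, sep = "_"),
             selection = g$selection, method = g$method,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Experiment design specification
#'
#' @param design one of `"sample_size_sweep"` (vary `n_values` at a fixed
#'   subtype fraction), `"distribution_sweep"` (vary `fraction_values` at a
#'   fixed `n`), `"gender_design"`, `"simulation_study"`.
#' @param n_values sample sizes to sweep.
#' @param fraction_values subtype-1 fractions to sweep (each in (0,1)).
#' @param n_fixed fixed sample size for the distribution sweep.
#' @param fraction_fixed fixed subtype-1 fraction for the sample-size sweep
#'   (default 0.5).
#' @param replicates independent subsamplings per condition (default 10).
#' @param max_sampling_fraction at most this fraction of each stratum may
#'   be drawn (default 0.70).
#' @param seed master seed; replicate `r` uses child seed `seed + r`.
#' @return A list of class `"design_spec"`.
#' @export
design_spec <- function(design = c("sample_size_sweep", "distribution_sweep",
                                   "gender_design", "simulation_study"),
                        n_values = NULL, fraction_values = NULL,
                        n_fixed = NULL, fraction_fixed = 0.5,
                        replicates = 10, max_sampling_fraction = 0.70,
                        seed = 1L) {
  design <- match.arg(design)
  if (!is.null(fraction_values) &&
      any(fraction_values <= 0 | fraction_values >= 1)) {
    stopf("fraction_values must lie strictly in (0,1)")
  }
  if (design == "sample_size_sweep" && is.null(n_values)) {
    stopf("sample_size_sweep requires n_values")
  }
  if (design == "distribution_sweep" &&
      (is.null(fraction_values) || is.null(n_fixed))) {
    stopf("distribution_sweep requires fraction_values and n_fixed")
  }
  structure(list(design = design, n_values = n_values,
                 fraction_values = fraction_values, n_fixed = n_fixed,
                 fraction_fixed = fraction_fixed,
                 replicates = as.integer(replicates),
                 max_sampling_fraction = max_sampling_fraction,
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Stratified subsampling without replacement
#'
#' Draws `round(n * fraction_subtype1)` (half rounded up) subtype-1 samples
#' and the remainder from subtype 2, uniformly without replacement. A cap
#' limits how much of each stratum may be drawn, preventing near-total
#' resampling of a small stratum.
#'
#' @param cohort a simulated (or loaded) cohort with subtype annotation.
#' @param n subsample size.
#' @param fraction_subtype1 target subtype-1 fraction, in (0,1).
#' @param seed integer seed.
#' @param max_sampling_fraction per-stratum cap (default 0.70); `Inf`
#'   disables it.
#' @param sex restrict sampling to one sex (`"female"` or `"male"`).
#' @return Character vector of sampled sample ids.
#' @export
subsample <- function(cohort, n, fraction_subtype1, seed = 1L,
                      max_sampling_fraction = 0.70, sex = NULL) {
  ann <- cohort_annotation(cohort)
  if (!is.null(sex)) ann <- ann[ann$sex == sex, ]
  n1 <- as.integer(round_half_up(n * fraction_subtype1))
  n2 <- n - n1
  pools <- split(ann$sample_id, ann$subtype)
  need <- c(A = n1, B = n2)
  for (st in names(need)) {
    avail <- length(pools[[st]] %||% character(0))
    if (need[[st]] > avail) {
      stopf("stratum subtype %s exhausted: need %d, have %d",
            st, need[[st]], avail)
    }
    if (need[[st]] > max_sampling_fraction * avail) {
      stopf("stratum subtype %s: need %d exceeds cap of %.0f%% of %d samples",
            st, need[[st]], 100 * max_sampling_fraction, avail)
    }
  }
  set.seed(seed)
  c(sample(pools[["A"]], n1), sample(pools[["B"]], n2))
}

# Run all approaches on one feature-selected data set. Returns per-approach
# partitions plus error messages. Base methods run first; the consensus
# ensemble then consumes the five base partitions of the same selection.
run_approaches_on_subset <- function(X, approaches, k = 2, seed = 1L,
                                     min_n_for_pc30 = 30) {
  n <- ncol(X)
  filt <- filter_genes(X)
  Xf <- filt$expr
  selections <- unique(approaches$selection)
  feats <- list(); ferr <- list()
  for (sel in selections) {
    spec <- parse_selection(sel)
    if (spec$kind == "pca" && spec$M >= min_n_for_pc30 && n < spec$M) {
      ferr[[sel]] <- sprintf("skipped: n = %d < %d components", n, spec$M)
      next
    }
    feats[[sel]] <- tryCatch(apply_selection(Xf, spec),
                             error = function(e) conditionMessage(e))
    if (is.character(feats[[sel]])) {
      ferr[[sel]] <- feats[[sel]]; feats[[sel]] <- NULL
    }
  }
  base_methods <- setdiff(unique(approaches$method), "cluster_ensemble")
  parts <- list(); errs <- list()
  for (sel in selections) {
    if (is.null(feats[[sel]])) next
    F <- feats[[sel]]
    for (m in base_methods) {
      id <- paste(sel, m, sep = "_")
      res <- tryCatch(cluster_samples(F, m, k = k, seed = seed),
                      error = function(e) conditionMessage(e))
      if (inherits(res, "partition")) parts[[id]] <- res
      else errs[[id]] <- res
    }
    if ("cluster_ensemble" %in% approaches$method) {
      id <- paste(sel, "cluster_ensemble", sep = "_")
      inputs <- parts[paste(sel, base_methods, sep = "_")]
      inputs <- inputs[!vapply(inputs, is.null, logical(1))]
      if (length(inputs) >= 2) {
        res <- tryCatch(consensus_partition(inputs, k = k, seed = seed),
                        error = function(e) conditionMessage(e))
        if (inherits(res, "partition")) parts[[id]] <- res
        else errs[[id]] <- res
      } else {
        errs[[id]] <- "fewer than 2 base partitions available"
      }
    }
  }
  for (sel in names(ferr)) {
    for (m in unique(approaches$method)) {
      errs[[paste(sel, m, sep = "_")]] <- ferr[[sel]]
    }
  }
  list(partitions = parts, errors = errs)
}

record_rows <- function(run, approaches, gold, condition, n, fraction,
                        stratum, replicate) {
  do.call(rbind, lapply(seq_len(nrow(approaches)), function(i) {
    id <- approaches$id[i]
    p <- run$partitions[[id]]
    if (is.null(p)) {
      data.frame(condition = condition, n = n, fraction = fraction,
                 stratum = stratum, replicate = replicate, approach = id,
                 selection = approaches$selection[i],
                 method = approaches$method[i], ari = NA_real_,
                 degenerate = NA, skipped = TRUE,
                 message = run$errors[[id]] %||% "unknown failure",
                 stringsAsFactors = FALSE)
    } else {
      a <- ari(gold, p)
      data.frame(condition = condition, n = n, fraction = fraction,
                 stratum = stratum, replicate = replicate, approach = id,
                 selection = approaches$selection[i],
                 method = approaches$method[i], ari = as.numeric(a),
                 degenerate = isTRUE(attr(p, "degenerate")), skipped = FALSE,
                 message = "", stringsAsFactors = FALSE)
    }
  }))
}

#' Run the approach grid over a subsampling design
#'
#' For every design condition and replicate, draws a stratified subsample,
#' re-applies the gene filters within the subsample, computes each
#' selection's feature matrix, runs every clustering method, and scores the
#' resulting partition against the subtype gold standard with the adjusted
#' Rand index. Approaches requesting more principal components than there
#' are samples (the 30-PC selections when `n < 30`) are recorded as skipped
#' rather than run; per-record failures are logged, never aborting the
#' grid.
#'
#' @param cohort a cohort with subtype gold standard.
#' @param design a [design_spec()] (`sample_size_sweep` or
#'   `distribution_sweep`).
#' @param approaches approach table from [approach_grid()].
#' @param k number of clusters (default 2).
#' @return An object of class `"eval_run"`: a list with `records` (one row
#'   per condition x replicate x approach, columns `condition`, `n`,
#'   `fraction`, `replicate`, `approach`, `selection`, `method`, `ari`,
#'   `degenerate`, `skipped`, `message`) and `partitions` (nested list
#'   `[[condition]][[replicate]]` of the per-approach partitions, for
#'   [apari_by_condition()]).
#' @export
run_grid <- function(cohort, design, approaches = approach_grid(), k = 2) {
  stopifnot(inherits(design, "design_spec"))
  conds <- switch(design$design,
    sample_size_sweep = data.frame(n = design$n_values,
                                   fraction = design$fraction_fixed),
    distribution_sweep = data.frame(n = design$n_fixed,
                                    fraction = design$fraction_values),
    stopf("run_grid handles sample_size_sweep and distribution_sweep; use
 gender_design() or simulation_study() for the other designs"))
  X_all <- cohort_expression(cohort)
  records <- list(); partitions <- list()
  for (ci in seq_len(nrow(conds))) {
    n <- conds$n[ci]; fraction <- conds$fraction[ci]
    cond_id <- sprintf("n%d_f%02d", n, round(100 * fraction))
    partitions[[cond_id]] <- list()
    for (r in seq_len(design$replicates)) {
      seed_r <- design$seed + r
      ids <- subsample(cohort, n, fraction, seed = seed_r,
                       max_sampling_fraction = design$max_sampling_fraction)
      X <- X_all[, ids, drop = FALSE]
      gold <- gold_partition(cohort, ids)
      run <- run_approaches_on_subset(X, approaches, k = k, seed = seed_r)
      partitions[[cond_id]][[r]] <- run$partitions
      records[[length(records) + 1]] <-
        record_rows(run, approaches, gold, cond_id, n, fraction,
                    NA_character_, r)
    }
  }
  structure(list(records = do.call(rbind, records), partitions = partitions,
                 design = design),
            class = "eval_run")
}

#' The sex-homogeneity design
#'
#' Builds, per replicate, three clustering arms of equal size and balanced
#' subtypes: females only, males only, and a mixed arm with 50% of each
#' sex. The mixed arm is clustered on all its samples but scored three
#' ways: on all samples (`Mixed_all`), on its female subset
#' (`Mixed_females`) and on its male subset (`Mixed_males`), restricting
#' both the partition and the gold standard to the subset.
#'
#' @param cohort a cohort with subtype and sex annotation.
#' @param n_per_arm samples per arm (divisible by 4 recommended, so each
#'   sex x subtype cell is balanced in the mixed arm).
#' @param approaches approach table.
#' @param replicates subsampling replicates (default 10).
#' @param seed master seed.
#' @param max_sampling_fraction per-stratum cap (default 0.70).
#' @param k clusters (default 2).
#' @return An `"eval_run"` with records tagged by `stratum` in
#'   `{Females, Males, Mixed_all, Mixed_females, Mixed_males}`.
#' @export
gender_design <- function(cohort, n_per_arm, approaches = approach_grid(),
                          replicates = 10, seed = 1L,
                          max_sampling_fraction = 0.70, k = 2) {
  X_all <- cohort_expression(cohort)
  records <- list(); partitions <- list()
  for (r in seq_len(replicates)) {
    seed_r <- seed + r
    ids_f <- subsample(cohort, n_per_arm, 0.5, seed = seed_r,
                       max_sampling_fraction = max_sampling_fraction,
                       sex = "female")
    ids_m <- subsample(cohort, n_per_arm, 0.5, seed = seed_r + 10000L,
                       max_sampling_fraction = max_sampling_fraction,
                       sex = "male")
    half <- n_per_arm / 2
    ids_mix <- c(subsample(cohort, half, 0.5, seed = seed_r + 20000L,
                           max_sampling_fraction = max_sampling_fraction,
                           sex = "female"),
                 subsample(cohort, n_per_arm - half, 0.5,
                           seed = seed_r + 30000L,
                           max_sampling_fraction = max_sampling_fraction,
                           sex = "male"))
    arms <- list(Females = ids_f, Males = ids_m, Mixed_all = ids_mix)
    for (arm in names(arms)) {
      ids <- arms[[arm]]
      run <- run_approaches_on_subset(X_all[, ids, drop = FALSE],
                                      approaches, k = k, seed = seed_r)
      gold <- gold_partition(cohort, ids)
      records[[length(records) + 1]] <-
        record_rows(run, approaches, gold, arm, n_per_arm, 0.5, arm, r)
      partitions[[arm]][[r]] <- run$partitions
      if (arm == "Mixed_all") {
        ann <- cohort_annotation(cohort)
        for (sx in c("female", "male")) {
          sub_ids <- intersect(ids, ann$sample_id[ann$sex == sx])
          tag <- if (sx == "female") "Mixed_females" else "Mixed_males"
          sub_run <- list(
            partitions = lapply(run$partitions, subset_partition,
                                ids = sub_ids),
            errors = run$errors)
          records[[length(records) + 1]] <-
            record_rows(sub_run, approaches,
                        gold_partition(cohort, sub_ids),
                        tag, length(sub_ids), 0.5, tag, r)
        }
      }
    }
  }
  structure(list(records = do.call(rbind, records), partitions = partitions,
                 design = list(design = "gender_design",
                               n_per_arm = n_per_arm,
                               replicates = replicates, seed = seed)),
            class = "eval_run")
}

#' Wilcoxon comparison of two record sets
#'
#' Per-approach ARIs are first averaged over replicates (as in the
#' replicate-averaged result tables), then compared. In `paired` mode a
#' one-sample Wilcoxon signed-rank test is applied to the per-approach
#' differences (two-sided; exact distribution when there are at most 25
#' non-zero differences, otherwise the normal approximation with
#' continuity correction). Approaches missing (skipped or failed) in
#' either set are dropped from both, so 30-PC approaches are excluded
#' whenever one condition has fewer than 30 samples. Unpaired mode runs a
#' Wilcoxon rank-sum test, as used for comparing apARI values.
#'
#' @param records_a,records_b record data.frames (from an `eval_run`),
#'   each covering one condition.
#' @param paired use the signed-rank test on matched approaches (default
#'   `TRUE`).
#' @param contrast optional label describing the comparison.
#' @return A list of class `"comparison_summary"` with `contrast`, `test`,
#'   `n_approaches`, `median_delta`, `p_value`, `all_zero`.
#' @export
wilcoxon_compare <- function(records_a, records_b, paired = TRUE,
                             contrast = "A vs B") {
  mean_by_approach <- function(rec) {
    rec <- rec[!rec$skipped & !is.na(rec$ari), ]
    tapply(rec$ari, rec$approach, mean)
  }
  xa <- mean_by_approach(records_a)
  xb <- mean_by_approach(records_b)
  common <- intersect(names(xa), names(xb))
  if (length(common) < 2) stopf("fewer than 2 matched approaches")
  xa <- xa[common]; xb <- xb[common]
  if (paired) {
    d <- xa - xb
    nz <- sum(d != 0)
    if (nz == 0) {
      return(structure(list(contrast = contrast,
                            test = "signed_rank_one_sample",
                            n_approaches = length(common), median_delta = 0,
                            p_value = 1, all_zero = TRUE),
                       class = "comparison_summary"))
    }
    exact <- nz <= 25
    wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact,
                                       correct = TRUE))
    structure(list(contrast = contrast, test = "signed_rank_one_sample",
                   n_approaches = length(common),
                   median_delta = median(d), p_value = wt$p.value,
                   all_zero = FALSE),
              class = "comparison_summary")
  } else {
    wt <- suppressWarnings(wilcox.test(xa, xb))
    structure(list(contrast = contrast, test = "rank_sum",
                   n_approaches = length(common),
                   median_delta = median(xa) - median(xb),
                   p_value = wt$p.value, all_zero = FALSE),
              class = "comparison_summary")
  }
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("%s [%s, %d approaches]: median delta ARI = %.4f, p = %.4g%s\n",
              x$contrast, x$test, x$n_approaches, x$median_delta, x$p_value,
              if (isTRUE(x$all_zero)) " (all differences zero)" else ""))
  invisible(x)
}

#' Average pairwise ARI per design condition
#'
#' Within each condition x replicate cell, computes the apARI over all
#' approach partitions that were produced, then averages over replicates.
#' Cells with fewer than 2 partitions are reported as missing.
#'
#' @param run an `"eval_run"` from [run_grid()] or [gender_design()].
#' @return A data.frame with columns `condition`, `apari`, `n_replicates`.
#' @export
apari_by_condition <- function(run) {
  out <- lapply(names(run$partitions), function(cond) {
    reps <- run$partitions[[cond]]
    vals <- vapply(reps, function(parts) {
      if (length(parts) < 2) return(NA_real_)
      as.numeric(apari(parts))
    }, numeric(1))
    data.frame(condition = cond, apari = mean(vals, na.rm = TRUE),
               n_replicates = sum(!is.na(vals)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Factor-model simulation study
#'
#' Repeats the generative simulation of [simulate_factor_cohort()] for each
#' sample size, scoring the three gene conditions (`All`, `Without`,
#' `Only`) on the same simulated matrix: each cohort is generated once
#' under condition `All` and the other two conditions are row-subsets by
#' the known factor membership. Every data set is clustered by
#' agglomerative hierarchical clustering with the Manhattan distance and
#' complete linkage, cut into 2 clusters, and scored against the subtype
#' partition with the ARI.
#'
#' @param n_values sample sizes (default `c(40, 80, 160)`).
#' @param n_sims independent simulated cohorts per sample size
#'   (default 300).
#' @param conditions subset of `c("All", "Without", "Only")`.
#' @param effect_size,noise_sd,n_genes,genes_per_factor passed to
#'   [sim_config()].
#' @param seed master seed; cohort `s` at the `i`-th sample size uses seed
#'   `seed + s + 100000 * (i - 1)`.
#' @return A list of class `"simulation_study"` with `results` (long
#'   data.frame: `condition`, `n`, `sim`, `ari`) and `summary`
#'   (`condition`, `n`, `mean_ari`, `se`, `n_sims`).
#' @export
simulation_study <- function(n_values = c(40, 80, 160), n_sims = 300,
                             conditions = c("All", "Without", "Only"),
                             effect_size = 1, noise_sd = 1, n_genes = 1000,
                             genes_per_factor = 20, seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  rows <- vector("list", length(n_values) * n_sims * length(conditions))
  ri <- 0
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    for (s in seq_len(n_sims)) {
      cfg <- sim_config(n_samples = n, n_genes = n_genes,
                        genes_per_factor = genes_per_factor,
                        effect_size = effect_size, noise_sd = noise_sd,
                        condition = "All",
                        seed = seed + s + 100000L * (i - 1L))
      co <- simulate_factor_cohort(cfg)
      X <- cohort_expression(co)
      truth <- cohort_truth(co)
      gold <- gold_partition(co)
      for (cond in conditions) {
        keep <- switch(cond,
                       All = rep(TRUE, nrow(X)),
                       Without = !truth %in% c("sex", "age"),
                       Only = truth == "subtype")
        D <- dissimilarity(t(X[keep, , drop = FALSE]), "manhattan")
        p <- hclust_complete(D, k = 2)
        ri <- ri + 1
        rows[[ri]] <- data.frame(condition = cond, n = n, sim = s,
                                 ari = as.numeric(ari(gold, p)),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows[seq_len(ri)])
  summary <- aggregate(ari ~ condition + n, data = results,
                       FUN = function(x) c(mean = mean(x),
                                           se = sd(x) / sqrt(length(x)),
                                           n_sims = length(x)))
  summary <- data.frame(condition = summary$condition, n = summary$n,
                        mean_ari = summary$ari[, "mean"],
                        se = summary$ari[, "se"],
                        n_sims = summary$ari[, "n_sims"],
                        stringsAsFactors = FALSE)
  structure(list(results = results, summary = summary),
            class = "simulation_study")
}

#' Read an evaluation configuration file
#'
#' A single YAML or JSON file describing a run: an optional `simulate`
#' block (fields of [sim_config()] or [simulate_tcga_like()]), a `design`
#' block (fields of [design_spec()]) and an optional `approaches` list of
#' canonical approach ids.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A list with elements `simulate`, `design`, `approaches`.
#' @export
read_eval_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  design <- if (!is.null(cfg$design)) do.call(design_spec, cfg$design)
  approaches <- if (!is.null(cfg$approaches)) {
    g <- approach_grid()
    unknown <- setdiff(cfg$approaches, g$id)
    if (length(unknown)) {
      stopf("unknown approaches in config: %s",
            paste(unknown, collapse = ", "))
    }
    g[g$id %in% cfg$approaches, ]
  }
  list(simulate = cfg$simulate, design = design, approaches = approaches)
}

#' Write evaluation records as CSV
#'
#' Long format (one row per condition x replicate x approach) or a
#' replicate-averaged wide layout with approaches as rows and conditions as
#' columns, mirroring a supplementary-table layout.
#'
#' @param run an `"eval_run"`.
#' @param path output file.
#' @param wide write the replicate-averaged approaches x conditions table
#'   (default `FALSE`).
#' @export
write_records <- function(run, path, wide = FALSE) {
  rec <- run$records
  if (wide) {
    rec <- rec[!rec$skipped, ]
    means <- aggregate(ari ~ approach + condition, data = rec, FUN = mean)
    tab <- reshape(means, idvar = "approach", timevar = "condition",
                   direction = "wide")
    names(tab) <- sub("^ari\\.", "", names(tab))
    write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    write.table(rec, path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
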