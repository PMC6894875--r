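#' Configuration for the factor-model expression simulator
#'
#' The simulator emulates a log-scale expression cohort in which samples are
#' cross-classified by three binary factors -- sex (male/female), age
#' (young/old) and subtype (A/B) -- and each factor perturbs its own small,
#' disjoint block of genes. Non-affected genes are `N(0, noise_sd^2)`;
#' affected genes are `N(-effect_size, noise_sd^2)` for male/young/type-A
#' samples and `N(+effect_size, noise_sd^2)` for female/old/type-B samples.
#'
#' @param n_samples number of samples. When all three factors are balanced
#'   and `n_samples` is divisible by 8 the cohort splits into eight equally
#'   sized homogeneous groups; otherwise samples are distributed as evenly
#'   as possible (round-robin).
#' @param n_genes number of simulated genes (default 1000).
#' @param genes_per_factor genes affected by each factor (default 20).
#' @param effect_size absolute group mean on the log-expression scale
#'   (default 1, i.e. group means -1 vs +1); must be >= 0.
#' @param noise_sd residual standard deviation (default 1); must be > 0.
#' @param condition which genes the returned matrix keeps: `"All"` keeps
#'   every gene, `"Without"` drops the sex- and age-affected blocks,
#'   `"Only"` keeps only the subtype-affected block.
#' @param fraction_subtype1 fraction of samples in subtype A, strictly in
#'   (0, 1); default 0.5.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_factor_cohort()]
#' @export
sim_config <- function(n_samples, n_genes = 1000, genes_per_factor = 20,
                       effect_size = 1, noise_sd = 1,
                       condition = c("All", "Without", "Only"),
                       fraction_subtype1 = 0.5, seed = 1L) {
  condition <- match.arg(condition)
  if (genes_per_factor * 3 > n_genes) {
    stopf("genes_per_factor * 3 (%d) exceeds n_genes (%d)",
          genes_per_factor * 3, n_genes)
  }
  if (noise_sd <= 0) stopf("noise_sd must be positive (got %g)", noise_sd)
  if (effect_size < 0) stopf("effect_size must be >= 0 (got %g)", effect_size)
  if (fraction_subtype1 <= 0 || fraction_subtype1 >= 1) {
    stopf("fraction_subtype1 must lie strictly in (0,1)")
  }
  if (n_samples < 2) stopf("need at least 2 samples")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 genes_per_factor = as.integer(genes_per_factor),
                 effect_size = effect_size, noise_sd = noise_sd,
                 condition = condition,
                 fraction_subtype1 = fraction_subtype1,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic cross-classification of samples: subtype counts by
# round-half-up on fraction_subtype1, then (sex, age) combinations assigned
# round-robin within each subtype so the design stays near-balanced.
sample_annotation_frame <- function(n, fraction_subtype1,
                                    fraction_female = 0.5) {
  n1 <- round_half_up(n * fraction_subtype1)
  n1 <- max(1L, min(n - 1L, as.integer(n1)))
  subtype <- rep(c("A", "B"), c(n1, n - n1))
  sex <- character(n); age <- character(n)
  for (st in c("A", "B")) {
    i <- which(subtype == st)
    ni <- length(i)
    nf <- as.integer(round_half_up(ni * fraction_female))
    sx <- rep(c("female", "male"), c(nf, ni - nf))
    sex[i] <- sx
    for (s in c("female", "male")) {
      j <- i[sx == s]
      age[j] <- c("young", "old")[(seq_along(j) - 1L) %% 2L + 1L]
    }
  }
  data.frame(sample_id = sprintf("sample%03d", seq_len(n)),
             subtype = subtype, sex = sex, age = age,
             stringsAsFactors = FALSE)
}

# Shared generative core: draw affected gene blocks, fill the noise matrix,
# then add +/- effect offsets per factor block. Factor level conventions:
# male/young/A get -effect, female/old/B get +effect.
simulate_blocks <- function(ann, n_genes, block_sizes, effect_size, noise_sd,
                            seed) {
  set.seed(seed)
  n <- nrow(ann)
  total_affected <- sum(block_sizes)
  affected <- sample.int(n_genes, total_affected)
  idx <- split(affected, rep(names(block_sizes), block_sizes))
  X <- matrix(rnorm(n_genes * n, mean = 0, sd = noise_sd), n_genes, n)
  signs <- list(sex = ifelse(ann$sex == "male", -1, 1),
                age = ifelse(ann$age == "young", -1, 1),
                subtype = ifelse(ann$subtype == "A", -1, 1))
  truth <- rep("none", n_genes)
  for (f in names(block_sizes)) {
    rows <- idx[[f]]
    truth[rows] <- f
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                       effect_size * signs[[f]], "+")
  }
  rownames(X) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(X) <- ann$sample_id
  list(X = X, truth = truth)
}

build_cohort <- function(X, ann, truth) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = X),
    colData = S4Vectors::DataFrame(ann[, c("subtype", "sex", "age")],
                                   row.names = ann$sample_id),
    rowData = S4Vectors::DataFrame(factor = truth, row.names = rownames(X))
  )
  se
}

#' Simulate a factor-structured expression cohort
#'
#' Generates log-scale expression for `n_genes` genes and `n_samples`
#' samples under the three-binary-factor model described in [sim_config()].
#' The `condition` field selects which genes the returned cohort keeps; the
#' underlying matrix is generated once, so under the same seed the `"Only"`
#' output is an exact row-subset of the `"All"` output.
#'
#' @param cfg a [sim_config()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `logexpr` (genes x samples), per-sample `colData` columns `subtype`,
#'   `sex`, `age`, and a per-gene `rowData` column `factor` in
#'   `{"none","sex","age","subtype"}` recording which factor, if any,
#'   affects each gene.
#' @examples
#' co <- simulate_factor_cohort(sim_config(n_samples = 40, seed = 7))
#' dim(co)
#' table(SummarizedExperiment::rowData(co)$factor)
#' @export
simulate_factor_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- sample_annotation_frame(cfg$n_samples, cfg$fraction_subtype1)
  gpf <- cfg$genes_per_factor
  sim <- simulate_blocks(ann, cfg$n_genes,
                         c(sex = gpf, age = gpf, subtype = gpf),
                         cfg$effect_size, cfg$noise_sd, cfg$seed)
  keep <- switch(cfg$condition,
                 All = rep(TRUE, cfg$n_genes),
                 Without = !sim$truth %in% c("sex", "age"),
                 Only = sim$truth == "subtype")
  build_cohort(sim$X[keep, , drop = FALSE], ann, sim$truth[keep])
}

#' Simulate a two-subtype cohort resembling a tumor expression study
#'
#' A convenience generator for the evaluation designs: a two-subtype cohort
#' with sex and age labels, using the same per-factor gene-block
#' architecture as [simulate_factor_cohort()] but with larger, configurable
#' blocks so the subtype signal is strong, as in real tumor cohorts where
#' known subtypes are accurately separable by supervised classifiers.
#'
#' @param n_samples number of samples (>= 4).
#' @param fraction_subtype1 fraction of samples in subtype A, in (0,1);
#'   subtype-1 count is `round(n * fraction)` with half rounded up, the
#'   remainder going to subtype B.
#' @param fraction_female fraction of female samples, in (0,1).
#' @param effect_size per-gene group mean offset (default 1).
#' @param seed integer seed.
#' @param n_genes number of genes (default 1200).
#' @param block_sizes named integer vector giving the number of genes
#'   affected by each factor; default `c(subtype = 100, sex = 60, age = 40)`.
#' @param noise_sd residual standard deviation (default 1).
#' @return A `SummarizedExperiment`, as for [simulate_factor_cohort()].
#' @export
simulate_tcga_like <- function(n_samples, fraction_subtype1 = 0.5,
                               fraction_female = 0.5, effect_size = 1,
                               seed = 1L, n_genes = 1200,
                               block_sizes = c(subtype = 100, sex = 60,
                                               age = 40),
                               noise_sd = 1) {
  if (n_samples < 4) stopf("n_samples must be >= 4 (got %d)", n_samples)
  for (f in c(fraction_subtype1, fraction_female)) {
    if (f <= 0 || f >= 1) stopf("fractions must lie strictly in (0,1)")
  }
  if (sum(block_sizes) > n_genes) {
    stopf("sum of block sizes (%d) exceeds n_genes (%d)",
          sum(block_sizes), n_genes)
  }
  ann <- sample_annotation_frame(n_samples, fraction_subtype1,
                                 fraction_female)
  sim <- simulate_blocks(ann, n_genes, block_sizes, effect_size, noise_sd,
                         seed)
  build_cohort(sim$X, ann, sim$truth)
}

#' Cohort accessors
#'
#' Small helpers around the `SummarizedExperiment` container used for
#' simulated cohorts.
#'
#' @param cohort a `SummarizedExperiment` produced by the simulators.
#' @return `cohort_expression`: the genes x samples log-expression matrix;
#'   `cohort_annotation`: a data.frame with `sample_id`, `subtype`, `sex`,
#'   `age`; `cohort_truth`: per-gene factor membership; `gold_partition`:
#'   the subtype labelling as a [partition()].
#' @export
cohort_expression <- function(cohort) {
  SummarizedExperiment::assay(cohort, "logexpr")
}

#' @rdname cohort_expression
#' @export
cohort_annotation <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  data.frame(sample_id = rownames(cd), as.data.frame(cd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname cohort_expression
#' @export
cohort_truth <- function(cohort) {
  rd <- SummarizedExperiment::rowData(cohort)
  setNames(as.character(rd$factor), rownames(rd))
}

#' @rdname cohort_expression
#' @param samples optional sample ids to restrict to.
#' @export
gold_partition <- function(cohort, samples = NULL) {
  ann <- cohort_annotation(cohort)
  if (!is.null(samples)) ann <- ann[match(samples, ann$sample_id), ]
  partition(ann$subtype, sample_ids = ann$sample_id)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expression.tsv` (genes as rows, first column `gene_id`),
#' `annotation.tsv` (`sample_id`, `subtype`, `sex`, `age`) and `truth.tsv`
#' (`gene_id`, `factor`) into `dir`.
#'
#' @param cohort a simulated cohort.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort_expression(cohort),
                   file.path(dir, "expression.tsv"))
  write.table(cohort_annotation(cohort), file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort_truth(cohort)
  write.table(data.frame(gene_id = names(tr), factor = unname(tr)),
              file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
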