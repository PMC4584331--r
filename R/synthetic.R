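#' Specify a planted gene module for the cohort generator
#'
#' A module is a block of genes sharing a beta shift `delta_beta` and/or a
#' log2 expression shift `delta_expr` in a set of affected classes. The
#' coupling tag states which modality carries signal and must be consistent
#' with the shifts: `positive` and `negative` need both shifts non-zero with
#' a positive / negative product; `met_only` and `exp_only` zero out the
#' other modality.
#'
#' @param name module label.
#' @param n_genes number of member genes.
#' @param classes character vector of affected class labels.
#' @param delta_beta beta-scale shift in \[-1, 1\] applied in affected
#'   classes.
#' @param delta_expr log2 expression shift applied in affected classes.
#' @param coupling one of `"positive"`, `"negative"`, `"met_only"`,
#'   `"exp_only"`.
#' @return a `module_spec` list.
#' @export
module_spec <- function(name, n_genes, classes, delta_beta, delta_expr,
                        coupling = c("positive", "negative", "met_only", "exp_only")) {
  coupling <- match.arg(coupling)
  if (abs(delta_beta) > 1) stop("delta_beta must lie in [-1, 1]")
  ok <- switch(coupling,
    positive = delta_beta * delta_expr > 0,
    negative = delta_beta * delta_expr < 0,
    met_only = delta_beta != 0 && delta_expr == 0,
    exp_only = delta_beta == 0 && delta_expr != 0
  )
  if (!ok) stop(sprintf("shifts (%g, %g) inconsistent with coupling '%s'",
                        delta_beta, delta_expr, coupling))
  structure(list(name = name, n_genes = as.integer(n_genes),
                 classes = as.character(classes),
                 delta_beta = delta_beta, delta_expr = delta_expr,
                 coupling = coupling), class = "module_spec")
}

#' Configuration of a synthetic paired methylation/expression cohort
#'
#' The stated world the generator emulates: per-gene methylation baselines
#' from a two-mode beta mixture (modes near 0 and near 1, reproducing the
#' bimodal beta distribution of healthy reference cells), planted modules
#' that shift betas and/or log2 expression in selected classes, and Gaussian
#' measurement noise. Methylation and expression sample sets are disjoint
#' (unmatched design) but share class labels.
#'
#' @param classes data.frame with columns `label`, `n_met`, `n_exp` (sample
#'   counts per modality).
#' @param n_genes total number of genes (modules are carved from the front).
#' @param modules list of [module_spec()] objects.
#' @param beta_lo,beta_hi shape pairs `c(a, b)` of the low and high baseline
#'   modes (defaults Beta(2, 20) and Beta(20, 2)).
#' @param high_frac fraction of genes in the high mode (default 0.4).
#' @param met_noise_sd per-measurement Gaussian noise on the beta scale.
#' @param expr_noise_sd per-measurement Gaussian noise on the log2 scale.
#' @param sample_offset_sd per-sample global offset (both modalities).
#' @param expr_baseline_mean,expr_baseline_sd distribution of per-gene log2
#'   expression baselines.
#' @param seed mandatory integer seed.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(classes, n_genes, modules = list(),
                                    beta_lo = c(2, 20), beta_hi = c(20, 2),
                                    high_frac = 0.4,
                                    met_noise_sd = 0.05, expr_noise_sd = 0.5,
                                    sample_offset_sd = 0.01,
                                    expr_baseline_mean = 8, expr_baseline_sd = 2,
                                    seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(is.data.frame(classes), all(c("label", "n_met", "n_exp") %in% names(classes)))
  n_mod_genes <- sum(vapply(modules, `[[`, integer(1L), "n_genes"))
  if (n_mod_genes > n_genes) stop("module gene counts exceed total genes")
  for (mod in modules) {
    bad <- setdiff(mod$classes, classes$label)
    if (length(bad)) stop("module '", mod$name, "' references unknown class: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    classes = classes, n_genes = as.integer(n_genes), modules = modules,
    beta_lo = beta_lo, beta_hi = beta_hi, high_frac = high_frac,
    met_noise_sd = met_noise_sd, expr_noise_sd = expr_noise_sd,
    sample_offset_sd = sample_offset_sd,
    expr_baseline_mean = expr_baseline_mean, expr_baseline_sd = expr_baseline_sd,
    seed = as.integer(seed)
  ), class = "synthetic_cohort_config")
}

#' Cohort configuration mirroring the reference lymphoma setting
#'
#' Eight classes with the canonical sample roster (DLBCL 54, mBL 18, IntL 16,
#' FL 14, MCL 10, MM 14, B 5, GCB 2; 133 methylation samples) over 768 genes,
#' with six planted modules: five differential-methylation modules emulating
#' the spot-clusters of a differential-methylation SOM (two positive
#' coupling, one negative, two methylation-only) plus one expression-only
#' proliferation module. Expression samples reuse the class roster (disjoint
#' patient ids, unmatched design).
#'
#' @param seed mandatory integer seed.
#' @return a `synthetic_cohort_config`.
#' @export
default_paper_like_config <- function(seed) {
  if (missing(seed)) stop("a seed is mandatory")
  roster <- data.frame(
    label = c("DLBCL", "mBL", "IntL", "FL", "MCL", "MM", "B", "GCB"),
    n_met = c(54L, 18L, 16L, 14L, 10L, 14L, 5L, 2L),
    n_exp = c(54L, 18L, 16L, 14L, 10L, 14L, 5L, 2L),
    stringsAsFactors = FALSE
  )
  modules <- list(
    module_spec("spot_i",   40L, c("DLBCL", "IntL"), +0.30, +1.0, "positive"),
    module_spec("spot_ii",  40L, c("mBL", "MCL"),    +0.25,  0.0, "met_only"),
    module_spec("spot_iii", 40L, c("DLBCL", "IntL"), -0.30, +1.0, "negative"),
    module_spec("spot_iv",  40L, c("B", "GCB", "MM"), +0.30, 0.0, "met_only"),
    module_spec("spot_v",   40L, c("FL"),            +0.28, +0.8, "positive"),
    module_spec("prolif",   40L, c("mBL"),            0.0,  +1.5, "exp_only")
  )
  synthetic_cohort_config(roster, n_genes = 768L, modules = modules, seed = seed)
}

#' Generate a synthetic paired cohort with ground truth
#'
#' Draws gene baselines, applies the planted module shifts and emits the
#' methylation matrix (clipped to \[0, 1\]), the expression matrix, both
#' annotations and a `synthetic_truth` record. Hypermethylation modules draw
#' their baselines from the low mode and hypomethylation modules from the
#' high mode (a promoter can only gain methylation it does not have), keeping
#' clipping negligible; a warning reports clipping beyond 5% of cells.
#' Bit-reproducible for a fixed config (the seed lives in the config).
#'
#' @param config a [synthetic_cohort_config()].
#' @return list with `met`, `exp` ([gene_sample_matrix()]), `met_ann`,
#'   `exp_ann` and `truth` (gene-to-module map, module table, per-class
#'   expected delta beta, and the member gene lists).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))

  gene_module <- rep("background", n_genes)
  module_genes <- list()
  cursor <- 0L
  for (mod in config$modules) {
    idx <- cursor + seq_len(mod$n_genes)
    gene_module[idx] <- mod$name
    module_genes[[mod$name]] <- genes[idx]
    cursor <- cursor + mod$n_genes
  }
  names(gene_module) <- genes

  # baseline mode: hyper modules start low, hypo modules start high,
  # everything else follows the mixture
  high <- stats::runif(n_genes) < config$high_frac
  for (mod in config$modules) {
    idx <- which(gene_module == mod$name)
    if (mod$delta_beta > 0) high[idx] <- FALSE
    if (mod$delta_beta < 0) high[idx] <- TRUE
  }
  a <- ifelse(high, config$beta_hi[1L], config$beta_lo[1L])
  b <- ifelse(high, config$beta_hi[2L], config$beta_lo[2L])
  base_met <- stats::rbeta(n_genes, a, b)
  base_exp <- stats::rnorm(n_genes, config$expr_baseline_mean, config$expr_baseline_sd)

  cl <- config$classes
  met_class <- rep(cl$label, cl$n_met)
  exp_class <- rep(cl$label, cl$n_exp)
  met_ids <- unlist(lapply(seq_len(nrow(cl)), function(i)
    sprintf("%s_M%02d", cl$label[i], seq_len(cl$n_met[i]))))
  exp_ids <- unlist(lapply(seq_len(nrow(cl)), function(i)
    sprintf("%s_E%02d", cl$label[i], seq_len(cl$n_exp[i]))))

  shift_for <- function(sample_class, field) {
    sh <- matrix(0, n_genes, length(sample_class))
    for (mod in config$modules) {
      d <- mod[[field]]
      if (d == 0) next
      sh[gene_module == mod$name, sample_class %in% mod$classes] <- d
    }
    sh
  }

  met_off <- stats::rnorm(length(met_ids), 0, config$sample_offset_sd)
  met_raw <- base_met + shift_for(met_class, "delta_beta") +
    matrix(met_off, n_genes, length(met_ids), byrow = TRUE) +
    matrix(stats::rnorm(n_genes * length(met_ids), 0, config$met_noise_sd),
           n_genes)
  clipped <- sum(met_raw < 0 | met_raw > 1)
  if (clipped > 0.05 * length(met_raw)) {
    warning(sprintf("clipping affected %d of %d methylation values (> 5%%)",
                    clipped, length(met_raw)))
  }
  met_vals <- pmin(pmax(met_raw, 0), 1)
  dimnames(met_vals) <- list(genes, met_ids)

  exp_off <- stats::rnorm(length(exp_ids), 0, config$sample_offset_sd)
  exp_vals <- base_exp + shift_for(exp_class, "delta_expr") +
    matrix(exp_off, n_genes, length(exp_ids), byrow = TRUE) +
    matrix(stats::rnorm(n_genes * length(exp_ids), 0, config$expr_noise_sd),
           n_genes)
  dimnames(exp_vals) <- list(genes, exp_ids)

  modules_df <- do.call(rbind, lapply(config$modules, function(mod) {
    data.frame(module = mod$name, n_genes = mod$n_genes,
               classes = paste(mod$classes, collapse = ";"),
               delta_beta = mod$delta_beta, delta_expr = mod$delta_expr,
               coupling = mod$coupling, stringsAsFactors = FALSE)
  }))
  expected <- do.call(rbind, lapply(config$modules, function(mod) {
    data.frame(module = mod$name, class = cl$label,
               expected_delta_beta = ifelse(cl$label %in% mod$classes,
                                            mod$delta_beta, 0),
               stringsAsFactors = FALSE)
  }))

  list(
    met = gene_sample_matrix(met_vals, "methylation_beta"),
    exp = gene_sample_matrix(exp_vals, "log_expression"),
    met_ann = sample_annotation(met_ids, met_class),
    exp_ann = sample_annotation(exp_ids, exp_class),
    truth = structure(list(gene_module = gene_module,
                           modules = modules_df %||% data.frame(),
                           expected_delta = expected %||% data.frame(),
                           module_genes = module_genes,
                           n_clipped = clipped),
                      class = "synthetic_truth")
  )
}

#' Module gene sets of a synthetic truth as a GMT-style collection
#'
#' @param truth a `synthetic_truth`.
#' @return named list of upper-cased gene symbol vectors (one per module).
#' @export
truth_gene_sets <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  lapply(truth$module_genes, function(g)
    structure(toupper(g), description = "synthetic planted module"))
}

#' Write a generated cohort to a directory as plain text
#'
#' Emits `met.tsv`, `exp.tsv`, `met_ann.tsv`, `exp_ann.tsv`, the planted
#' module gene sets as `modules.gmt` and the truth tables as `truth.json`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$met, file.path(dir, "met.tsv"))
  write_matrix(cohort$exp, file.path(dir, "exp.tsv"))
  write_annotation(cohort$met_ann, file.path(dir, "met_ann.tsv"))
  write_annotation(cohort$exp_ann, file.path(dir, "exp_ann.tsv"))
  write_gmt(truth_gene_sets(cohort$truth), file.path(dir, "modules.gmt"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(gene_module = as.list(tr$gene_module), modules = tr$modules,
         expected_delta = tr$expected_delta, n_clipped = tr$n_clipped),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
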