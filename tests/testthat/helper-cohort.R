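# shared fixtures and metrics for the suite; everything is generated in code

# small gene x sample matrix with deterministic values
tiny_gsm <- function(values, modality = "methylation_beta", centralized = FALSE,
                     genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  gene_sample_matrix(values, modality, centralized = centralized)
}

# a compact two-class cohort with one planted module per coupling mode
small_cohort <- function(seed, n_genes = 300L, n_per_class = 25L,
                         modules = NULL) {
  roster <- data.frame(label = c("REF", "TUM"),
                       n_met = c(n_per_class, n_per_class),
                       n_exp = c(n_per_class, n_per_class),
                       stringsAsFactors = FALSE)
  if (is.null(modules)) {
    modules <- list(module_spec("up", 40L, "TUM", +0.3, +1.0, "positive"))
  }
  cfg <- synthetic_cohort_config(roster, n_genes = n_genes, modules = modules,
                                 seed = seed)
  suppressWarnings(generate_cohort(cfg))
}

# a som_model built directly from a codebook (for unit tests of pure lookups)
fake_model <- function(codebook, grid_rows, grid_cols, bmu = NULL, data = NULL,
                       modality = "methylation_beta", centralized = TRUE) {
  if (is.null(data)) data <- codebook[seq_len(min(4L, nrow(codebook))), , drop = FALSE]
  if (is.null(rownames(data))) rownames(data) <- sprintf("G%03d", seq_len(nrow(data)))
  if (is.null(bmu)) bmu <- stats::setNames(seq_len(nrow(data)) - 1L, rownames(data))
  structure(list(codebook = codebook, bmu = bmu,
                 grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 data = data, modality = modality, centralized = centralized,
                 variant = "test", seed = 0L, epochs = 0L,
                 radius = c(initial = 1, final = 1), qe = numeric(0)),
            class = "som_model")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  (s_ij - expected) / ((s_a + s_b) / 2 - expected)
}

# best-tail spot recovery: both-tail detection, best Jaccard per planted module
recover_modules <- function(model, truth, ...) {
  spots <- c(
    detect_spots(overview_spot_map(model, "high", ...), model, polarity = "high"),
    detect_spots(overview_spot_map(model, "low", ...), model, polarity = "low")
  )
  met_mods <- truth$modules$module[truth$modules$delta_beta != 0]
  jac <- vapply(met_mods, function(mn) {
    tg <- truth$module_genes[[mn]]
    if (!length(spots)) return(0)
    max(vapply(spots, function(sp) jaccard(sp$genes, tg), numeric(1L)))
  }, numeric(1L))
  list(spots = spots, jaccard = jac)
}
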