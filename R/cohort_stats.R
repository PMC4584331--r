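#' Differential methylation versus a reference class
#'
#' For every gene and class, the difference between the class-mean beta and
#' the reference-class-mean beta (positive = hypermethylation relative to the
#' reference, negative = hypomethylation). Means are taken over non-missing
#' samples of each class.
#'
#' @param m a [gene_sample_matrix()] (typically methylation beta values).
#' @param ann sample annotation (see [sample_annotation()]).
#' @param reference_class class label used as baseline; must exist in `ann`.
#' @return numeric matrix genes x classes of delta values; the reference
#'   column is identically zero.
#' @export
delta_beta <- function(m, ann, reference_class) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  check_annotation(m, ann)
  cls <- ann[sample_ids(m)]
  if (!reference_class %in% cls) {
    stop("unknown reference class: '", reference_class, "'")
  }
  labs <- unique(cls)
  means <- vapply(labs, function(l) {
    rowMeans(m$values[, cls == l, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m$values)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1, dimnames = list(gene_ids(m), labs))
  d <- means - means[, reference_class]
  dimnames(d) <- list(gene_ids(m), labs)
  d
}

#' Integral hyper- and hypomethylation
#'
#' Mean differential methylation averaged separately over the positive and
#' the negative delta beta values. A side with no values contributes 0 with
#' count 0.
#'
#' @param deltas numeric vector of delta beta values (NA dropped).
#' @return list with `hyper` (>= 0), `hypo` (<= 0), `n_hyper`, `n_hypo`.
#' @export
integral_differential_methylation <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  if (!length(deltas)) {
    warning("empty delta vector; integral methylation set to (0, 0)")
    return(list(hyper = 0, hypo = 0, n_hyper = 0L, n_hypo = 0L))
  }
  pos <- deltas[deltas > 0]
  neg <- deltas[deltas < 0]
  list(
    hyper = if (length(pos)) mean(pos) else 0,
    hypo = if (length(neg)) mean(neg) else 0,
    n_hyper = length(pos),
    n_hypo = length(neg)
  )
}

#' Per-sample variance across genes
#'
#' Population variance (divisor n) of the values of each sample over its
#' non-missing genes. In methylation data this tracks the bimodality of the
#' beta distribution: collapsing the near-0/near-1 modes toward intermediate
#' levels shrinks it.
#'
#' @param m a [gene_sample_matrix()] with >= 2 genes.
#' @return named numeric vector, one variance per sample (`NA` with a warning
#'   when a sample has < 2 non-missing genes).
#' @export
per_sample_variance <- function(m) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  if (nrow(m$values) < 2L) stop("per-sample variance needs >= 2 genes")
  v <- apply(m$values, 2L, pop_var)
  if (anyNA(v)) warning(sum(is.na(v)), " sample(s) with < 2 non-missing genes")
  v
}

#' Pooled beta-value distribution of a class
#'
#' Histogram over \[0, 1\] of the beta values of all samples of one class
#' (equal-width bins, pooled over class samples), plus Sarle's bimodality
#' coefficient of the pooled values (see [bimodality_coefficient()]).
#'
#' @inheritParams delta_beta
#' @param class class label to pool.
#' @param n_bins number of equal-width bins over \[0, 1\] (>= 2).
#' @return list with `breaks`, `counts`, `mids`, `n` (pooled non-missing
#'   values) and `bimodality`.
#' @export
beta_distribution <- function(m, ann, class, n_bins = 50L) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  check_annotation(m, ann)
  cls <- ann[sample_ids(m)]
  if (!class %in% cls) stop("class '", class, "' has no samples")
  x <- as.vector(m$values[, cls == class, drop = FALSE])
  x <- x[!is.na(x)]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = breaks, counts = h$counts, mids = h$mids,
       n = length(x), bimodality = bimodality_coefficient(x))
}

#' Cohort methylation summary per class
#'
#' One row per class: integral hyper-/hypomethylation versus the reference
#' class, delta counts, mean total beta, mean per-sample variance and the
#' pooled bimodality coefficient. This is the per-cohort descriptive table of
#' the methylation analysis.
#'
#' @inheritParams delta_beta
#' @return data.frame with columns `class`, `hyper`, `hypo`, `n_hyper`,
#'   `n_hypo`, `mean_beta`, `mean_sample_variance`, `bimodality`.
#' @export
delta_beta_summary <- function(m, ann, reference_class) {
  d <- delta_beta(m, ann, reference_class)
  cls <- ann[sample_ids(m)]
  psv <- per_sample_variance(m)
  out <- lapply(colnames(d), function(l) {
    idm <- integral_differential_methylation(d[, l])
    sel <- cls == l
    data.frame(
      class = l,
      hyper = idm$hyper, hypo = idm$hypo,
      n_hyper = idm$n_hyper, n_hypo = idm$n_hypo,
      mean_beta = mean(m$values[, sel, drop = FALSE], na.rm = TRUE),
      mean_sample_variance = mean(psv[sel], na.rm = TRUE),
      bimodality = bimodality_coefficient(as.vector(m$values[, sel, drop = FALSE])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
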