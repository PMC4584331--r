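#' Gene set Z-score (GSZ)
#'
#' Signed enrichment of a gene set within a per-gene score vector: the
#' z-score of the set's mean score under the null of drawing `n_S` genes
#' without replacement from the universe,
#' \deqn{GSZ = \frac{\bar{x}_{set} - \bar{x}_{univ}}
#'   {\sigma_{univ}/\sqrt{n_S} \cdot \sqrt{(N - n_S)/(N - 1)}}}
#' with \eqn{\sigma_{univ}} the population standard deviation and the square
#' root the finite-population correction. Positive values mean the set scores
#' above the universe average.
#'
#' @param scores named numeric vector of per-gene scores for one contrast
#'   (names = symbols; `NA` dropped). The universe is the set of scored genes.
#' @param set character vector of gene symbols (case-insensitive).
#' @return a single GSZ value; 0 with a warning when the universe has zero
#'   dispersion or the set equals the universe; `NA` with a warning when the
#'   set does not intersect the universe.
#' @export
gsz_score <- function(scores, set) {
  if (is.null(names(scores))) stop("'scores' must be named by gene symbol")
  scores <- scores[!is.na(scores)]
  N <- length(scores)
  if (N < 2L) stop("universe must contain >= 2 scored genes")
  in_set <- toupper(names(scores)) %in% toupper(set)
  n_s <- sum(in_set)
  if (n_s == 0L) {
    warning("gene set does not intersect the scored universe")
    return(NA_real_)
  }
  sd_u <- sqrt(pop_var(scores))
  if (sd_u == 0) {
    warning("universe has zero dispersion; GSZ defined as 0")
    return(0)
  }
  if (n_s == N) {
    warning("set equals the universe; finite-population correction is 0, GSZ defined as 0")
    return(0)
  }
  denom <- sd_u / sqrt(n_s) * sqrt((N - n_s) / (N - 1))
  (mean(scores[in_set]) - mean(scores)) / denom
}

#' Per-class GSZ profile of a gene set
#'
#' For each class, [gsz_score()] applied to the class-mean centralized values
#' of all genes (the universe = all genes of the matrix). The resulting
#' signed profile is stratified into high / moderate / low with
#' [stratify_levels()].
#'
#' @param m a centralized [gene_sample_matrix()].
#' @param ann sample annotation.
#' @param set character vector of gene symbols.
#' @param set_name optional label stored on the result.
#' @param t stratification threshold passed to [stratify_levels()].
#' @return object of class `gsz_profile`: data.frame with columns `class`,
#'   `gsz`, `stratum`; attributes `set_name`, `N`, `n_set`.
#' @export
gsz_class_profile <- function(m, ann, set, set_name = "set", t = 1.0) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  if (!m$centralized) stop("gsz_class_profile expects a centralized matrix; call centralize() first")
  check_annotation(m, ann)
  cls <- ann[sample_ids(m)]
  labs <- unique(cls)
  gsz <- vapply(labs, function(l) {
    scores <- rowMeans(m$values[, cls == l, drop = FALSE], na.rm = TRUE)
    gsz_score(scores, set)
  }, numeric(1L))
  out <- data.frame(class = labs, gsz = unname(gsz), stringsAsFactors = FALSE)
  out$stratum <- stratify_levels(out$gsz, t = t)
  structure(out, class = c("gsz_profile", "data.frame"),
            set_name = set_name, N = nrow(m$values),
            n_set = sum(toupper(gene_ids(m)) %in% toupper(set)))
}

#' Stratify GSZ values into high / moderate / low
#'
#' `gsz > t` is high, `gsz < -t` is low, anything else (including exactly
#' +/- t, and `NA` which stays `NA`) is moderate.
#'
#' @param gsz numeric vector of GSZ values (or a `gsz_profile`).
#' @param t positive threshold (default 1.0).
#' @return character vector of strata.
#' @export
stratify_levels <- function(gsz, t = 1.0) {
  if (inherits(gsz, "gsz_profile")) gsz <- gsz$gsz
  if (!(t > 0)) stop("threshold t must be > 0")
  out <- ifelse(gsz > t, "high", ifelse(gsz < -t, "low", "moderate"))
  out[is.na(gsz)] <- NA_character_
  out
}

#' Overlap percentage of two gene sets with hypergeometric assessment
#'
#' Percentage of set `a` also found in set `b` (both intersected with the
#' universe first, case-insensitive), and the upper-tail hypergeometric
#' probability of observing at least that many shared genes when `|a|` genes
#' are drawn at random from the universe.
#'
#' @param a,b character vectors of gene symbols.
#' @param universe character vector of the measured gene pool.
#' @return list with `percent`, `p`, `k` (overlap count), `n_a`, `n_b`, `N`.
#' @export
set_overlap_percentage <- function(a, b, universe) {
  U <- unique(toupper(universe))
  a <- intersect(unique(toupper(a)), U)
  b <- intersect(unique(toupper(b)), U)
  if (!length(a)) stop("set 'a' is empty after intersection with the universe")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1L, length(b), length(U) - length(b), length(a),
                     lower.tail = FALSE)
  list(percent = 100 * k / length(a), p = p,
       k = k, n_a = length(a), n_b = length(b), N = length(U))
}

#' Enrichment table of spot modules against a gene-set collection
#'
#' For every (spot, set) pair: overlap percentage and hypergeometric p-value
#' via [set_overlap_percentage()], with Benjamini-Hochberg adjusted q-values
#' across the whole table. The universe is the full gene roster of the model
#' the spots were derived from.
#'
#' @param spots list of `spot_module` objects.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of measured genes.
#' @return data.frame with columns `spot`, `set`, `overlap_pct`, `k`,
#'   `n_spot`, `n_set`, `p`, `q`.
#' @export
enrich_spots <- function(spots, sets, universe) {
  rows <- list()
  for (sp in spots) {
    if (!sp$n_genes) next
    for (nm in names(sets)) {
      ov <- set_overlap_percentage(sp$genes, sets[[nm]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        spot = sp$label, set = nm, overlap_pct = ov$percent,
        k = ov$k, n_spot = ov$n_a, n_set = ov$n_b, p = ov$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
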