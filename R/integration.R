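#' Class-level methylation-expression coupling of a gene group
#'
#' The integrative step for unmatched cohorts: methylation and expression
#' samples are different patients, so the two modalities are joined at the
#' class level only. For every class present in both annotations, `x` is the
#' mean (over the group genes) of the class-mean centralized methylation and
#' `y` the analogue for expression; error bars (`sd_x`, `sd_y`) are standard
#' deviations over the class samples of the gene-averaged value. The
#' across-class Pearson correlation of (x, y) plus the displacement from a
#' reference class (e.g. GCB) to a target class (e.g. DLBCL) summarize the
#' direction of coupling, and [classify_coupling()] assigns one of the
#' pattern labels `positive`, `negative`, `methylation-only`,
#' `expression-only`, `silent`.
#'
#' @param met,exp centralized [gene_sample_matrix()] objects (methylation
#'   beta / log2 expression).
#' @param group character vector of gene symbols; matched across platforms
#'   case-insensitively.
#' @param met_ann,exp_ann sample annotations of the two cohorts (the class
#'   labels are the join key; harmonize them beforehand if they differ).
#' @param ref_class,target_class classes anchoring the slope indicator.
#' @param group_name label stored on the result.
#' @param ... thresholds forwarded to [classify_coupling()].
#' @return object of class `coupling_summary`: list with `classes`
#'   (data.frame `class`, `x`, `y`, `sd_x`, `sd_y`, `n_met`, `n_exp`),
#'   `rho`, `slope` (`c(dx, dy)`), `pattern`, `group`, `n_genes`.
#' @export
coupling_summary <- function(met, exp, group, met_ann, exp_ann,
                             ref_class, target_class, group_name = "group", ...) {
  stopifnot(inherits(met, "gene_sample_matrix"), inherits(exp, "gene_sample_matrix"))
  if (!met$centralized || !exp$centralized) {
    stop("coupling_summary expects centralized matrices; call centralize() first")
  }
  check_annotation(met, met_ann)
  check_annotation(exp, exp_ann)
  pairs <- match_genes(met, exp)
  pairs <- pairs[toupper(pairs$gene_a) %in% toupper(group), , drop = FALSE]
  if (!nrow(pairs)) stop("no group gene present on both platforms")
  gm <- met$values[pairs$gene_a, , drop = FALSE]
  ge <- exp$values[pairs$gene_b, , drop = FALSE]
  cls_m <- met_ann[sample_ids(met)]
  cls_e <- exp_ann[sample_ids(exp)]
  shared <- intersect(unique(cls_m), unique(cls_e))
  for (cl in c(ref_class, target_class)) {
    if (!cl %in% shared) stop("class '", cl, "' absent from one of the cohorts")
  }
  rows <- lapply(shared, function(l) {
    xs <- colMeans(gm[, cls_m == l, drop = FALSE], na.rm = TRUE)  # per-sample gene average
    ys <- colMeans(ge[, cls_e == l, drop = FALSE], na.rm = TRUE)
    data.frame(class = l, x = mean(xs), y = mean(ys),
               sd_x = stats::sd(xs), sd_y = stats::sd(ys),
               n_met = length(xs), n_exp = length(ys), stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, rows)
  rho <- NA_real_
  if (nrow(classes) >= 3L) {
    rho <- stats::cor(classes$x, classes$y)
  } else {
    warning("fewer than 3 shared classes; across-class correlation not computed")
  }
  out <- structure(list(
    classes = classes, rho = rho,
    slope = c(dx = classes$x[classes$class == target_class] -
                classes$x[classes$class == ref_class],
              dy = classes$y[classes$class == target_class] -
                classes$y[classes$class == ref_class]),
    ref_class = ref_class, target_class = target_class,
    group = group_name, n_genes = nrow(pairs), pattern = NA_character_
  ), class = "coupling_summary")
  if (nrow(classes) >= 3L) out$pattern <- classify_coupling(out, ...)
  out
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("coupling_summary '%s': %d genes, %d classes, rho = %.3f, pattern = %s\n",
              x$group, x$n_genes, nrow(x$classes), x$rho, x$pattern))
  invisible(x)
}

#' Classify a coupling summary into a pattern label
#'
#' Using the across-class ranges `Rx`, `Ry` of the mean centralized
#' methylation and expression and the across-class correlation `rho`:
#' both ranges small -> `silent`; only methylation varies ->
#' `methylation-only`; only expression varies -> `expression-only`; both vary
#' -> `positive` (`rho >= rho_min`) or `negative` (`rho <= -rho_min`),
#' otherwise `silent` with a warning (variation without consistent coupling).
#'
#' @param summary a `coupling_summary`.
#' @param dx_min methylation range threshold, beta units (default 0.05).
#' @param dy_min expression range threshold, log2 units (default 0.3).
#' @param rho_min minimum |correlation| for a signed pattern (default 0.6).
#' @return pattern label (single string).
#' @export
classify_coupling <- function(summary, dx_min = 0.05, dy_min = 0.3, rho_min = 0.6) {
  stopifnot(inherits(summary, "coupling_summary"))
  cl <- summary$classes
  if (nrow(cl) < 3L) stop("coupling classification needs >= 3 classes")
  rx <- diff(range(cl$x))
  ry <- diff(range(cl$y))
  if (rx < dx_min && ry < dy_min) return("silent")
  if (rx >= dx_min && ry < dy_min) return("methylation-only")
  if (rx < dx_min && ry >= dy_min) return("expression-only")
  if (!is.na(summary$rho)) {
    if (summary$rho >= rho_min) return("positive")
    if (summary$rho <= -rho_min) return("negative")
  }
  warning("both modalities vary but |rho| < rho_min; labeled 'silent'")
  "silent"
}

#' Reference-to-target slope indicator
#'
#' The displacement `(x_target - x_ref, y_target - y_ref)` between the two
#' anchor classes of a coupling summary and its sign pair, indicating the
#' direction of the methylation-expression association.
#'
#' @param summary a `coupling_summary`.
#' @return list with `vector` (`c(dx, dy)`) and `signs` (character pair of
#'   `"+"`, `"-"` or `"0"`).
#' @export
slope_indicator <- function(summary) {
  stopifnot(inherits(summary, "coupling_summary"))
  v <- summary$slope
  list(vector = v,
       signs = ifelse(v > 0, "+", ifelse(v < 0, "-", "0")))
}
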