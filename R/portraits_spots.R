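#' Class-mean portrait
#'
#' Per-unit arithmetic mean of the portraits of all samples belonging to one
#' class; the standard way to visualize class-specific methylation or
#' expression signatures.
#'
#' @param model a `som_model`.
#' @param ann sample annotation covering the model's samples.
#' @param class class label.
#' @return numeric matrix `grid_rows x grid_cols`.
#' @export
class_mean_portrait <- function(model, ann, class) {
  stopifnot(inherits(model, "som_model"))
  cls <- ann[colnames(model$codebook)]
  if (anyNA(cls)) stop("samples without class annotation")
  if (!class %in% cls) stop("unknown class: '", class, "'")
  v <- rowMeans(model$codebook[, cls == class, drop = FALSE])
  matrix(v, nrow = model$grid_rows, ncol = model$grid_cols, byrow = TRUE)
}

#' Per-unit variance map
#'
#' Population variance of every prototype vector across samples; high-variance
#' regions contain the genes whose values differ most between samples.
#'
#' @param model a `som_model` with >= 2 samples.
#' @return numeric matrix `grid_rows x grid_cols`.
#' @export
variance_map <- function(model) {
  stopifnot(inherits(model, "som_model"))
  if (ncol(model$codebook) < 2L) stop("variance map needs >= 2 samples")
  v <- rowMeans(model$codebook^2) - rowMeans(model$codebook)^2
  matrix(pmax(v, 0), nrow = model$grid_rows, ncol = model$grid_cols, byrow = TRUE)
}

#' Overview spot mask
#'
#' Collects the extreme-tail units of every individual sample portrait into a
#' single boolean grid: a unit is marked if, in at least one sample, its
#' portrait value strictly exceeds that sample's `q`-quantile (`tail =
#' "high"`) or falls strictly below the `1 - q` quantile (`tail = "low"`).
#' This reproduces the construction of overview spot maps as the union of the
#' hypermethylation (or overexpression) spots of all individual portraits.
#'
#' In addition to the quantile rule, a unit must deviate from the sample's
#' median portrait level by at least `min_amplitude` (measurement units).
#' Quantile exceedance alone marks 2\% of units in every sample regardless of
#' scale, so a cohort with no differential signal would still produce large
#' masks; the amplitude floor — set at about twice a typical technical noise
#' standard deviation, well below biologically meaningful shifts — restores
#' the intended sparseness. Pass `min_amplitude = 0` for the pure quantile
#' rule.
#'
#' @param model a `som_model`.
#' @param tail `"high"` or `"low"`.
#' @param q per-sample quantile, `0.5 < q < 1` (default 0.98).
#' @param min_amplitude minimum deviation from the sample's median portrait
#'   value; default (`NULL`) is 0.1 for methylation beta data and 0.5 for
#'   log2 expression.
#' @return logical matrix `grid_rows x grid_cols`.
#' @export
overview_spot_map <- function(model, tail = c("high", "low"), q = 0.98,
                              min_amplitude = NULL) {
  stopifnot(inherits(model, "som_model"))
  tail <- match.arg(tail)
  if (!(q > 0.5 && q < 1)) stop("q must satisfy 0.5 < q < 1")
  if (is.null(min_amplitude)) {
    min_amplitude <- if (model$modality == "log_expression") 0.5 else 0.1
  }
  W <- model$codebook
  mask <- rep(FALSE, nrow(W))
  for (j in seq_len(ncol(W))) {
    v <- W[, j]
    md <- stats::median(v)
    if (tail == "high") {
      mask <- mask | (v > stats::quantile(v, q, names = FALSE) &
                        v - md > min_amplitude)
    } else {
      mask <- mask | (v < stats::quantile(v, 1 - q, names = FALSE) &
                        md - v > min_amplitude)
    }
  }
  matrix(mask, nrow = model$grid_rows, ncol = model$grid_cols, byrow = TRUE)
}

# label 8-connected components of a logical matrix; 0 = background
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(rep(-1:1, each = 3L), rep(-1:1, times = 3L))
  offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), , drop = FALSE]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2L)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        ni <- p[1L] + offs[k, 1L]; nj <- p[2L] + offs[k, 2L]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

#' Segment a spot mask into spot modules
#'
#' 8-connected components of the mask with at least `min_units` units become
#' spot modules, labeled `"1"`, `"2"`, ... in decreasing size order. Each
#' module carries its unit coordinates, the genes whose BMU lies inside the
#' region, and the per-sample profile (mean of the analyzed values over the
#' member genes).
#'
#' @param mask logical grid, e.g. from [overview_spot_map()].
#' @param model the `som_model` the mask was derived from.
#' @param min_units minimum component size (default 4).
#' @param polarity tag stored on each spot (`"high"` or `"low"` tail).
#' @return list of `spot_module` objects (possibly empty).
#' @export
detect_spots <- function(mask, model, min_units = 4L, polarity = "high") {
  stopifnot(inherits(model, "som_model"))
  if (!identical(dim(mask), c(model$grid_rows, model$grid_cols))) {
    stop("mask shape does not match the model grid")
  }
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(list())
  sizes <- table(lab[lab > 0L])
  keep <- as.integer(names(sizes)[sizes >= min_units])
  keep <- keep[order(-sizes[as.character(keep)], keep)]
  bmu_coord <- unit_to_coord(model$bmu, model$grid_cols)
  bmu_lab <- lab[cbind(bmu_coord[, "row"] + 1L, bmu_coord[, "col"] + 1L)]
  spots <- vector("list", length(keep))
  for (s in seq_along(keep)) {
    idx <- which(lab == keep[s], arr.ind = TRUE)
    units <- cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
    genes <- names(model$bmu)[bmu_lab == keep[s]]
    profile <- if (length(genes)) {
      colMeans(model$data[genes, , drop = FALSE])
    } else {
      stats::setNames(rep(NA_real_, ncol(model$data)), colnames(model$data))
    }
    spots[[s]] <- structure(list(
      label = as.character(s), polarity = polarity,
      units = units, genes = genes, sample_profile = profile,
      n_units = nrow(units), n_genes = length(genes)
    ), class = "spot_module")
  }
  spots
}

#' @export
print.spot_module <- function(x, ...) {
  cat(sprintf("spot_module %s (%s tail): %d units, %d genes\n",
              x$label, x$polarity, x$n_units, x$n_genes))
  invisible(x)
}

#' Per-class profile of a spot module
#'
#' For each class, mean and standard deviation (over the class samples) of
#' the spot's gene-averaged value.
#'
#' @param spot a `spot_module` with >= 1 gene.
#' @param ann sample annotation covering the profile's samples.
#' @return data.frame with columns `class`, `mean`, `sd`, `n`.
#' @export
spot_profile <- function(spot, ann) {
  stopifnot(inherits(spot, "spot_module"))
  if (!spot$n_genes) stop("spot has no member genes")
  cls <- ann[names(spot$sample_profile)]
  if (anyNA(cls)) stop("samples without class annotation")
  out <- lapply(unique(cls), function(l) {
    v <- spot$sample_profile[cls == l]
    data.frame(class = l, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map a spot's genes into another SOM
#'
#' Carries the member genes of a spot (via a symbol pairing from
#' [match_genes()], `gene_a` = source side) into a second model and reports
#' where they land: occupied unit coordinates with counts, the fraction of
#' spot genes mapped, a spatial concentration score, and (optionally) the
#' overlap with the other model's spots.
#'
#' The concentration score is `u50 / n_mapped`, where `u50` is the size of
#' the smallest set of units covering at least half of the mapped genes.
#' Genes piled into few units give scores near 0; genes scattered one-per-unit
#' give 0.5 (the theoretical maximum).
#'
#' @param spot a `spot_module` from the source model.
#' @param other the target `som_model`.
#' @param pairs data.frame from [match_genes()] with `gene_a` (source
#'   symbols) and `gene_b` (target symbols).
#' @param other_spots optional list of the target model's `spot_module`s for
#'   overlap counting.
#' @return list with `coords`, `counts`, `n_mapped`, `fraction_mapped`,
#'   `concentration`, `spot_overlap` (named counts or `NULL`).
#' @export
cross_map <- function(spot, other, pairs, other_spots = NULL) {
  stopifnot(inherits(spot, "spot_module"), inherits(other, "som_model"))
  if (!nrow(pairs)) stop("empty gene pairing")
  tgt <- pairs$gene_b[pairs$gene_a %in% spot$genes]
  tgt <- tgt[tgt %in% names(other$bmu)]
  if (!length(tgt)) {
    warning("no spot gene present in the other SOM")
    return(list(coords = unit_to_coord(integer(0), other$grid_cols),
                counts = integer(0), n_mapped = 0L, fraction_mapped = 0,
                concentration = NA_real_, spot_overlap = NULL))
  }
  occ <- map_gene_group(other, tgt)
  cnt_sorted <- sort(occ$counts, decreasing = TRUE)
  u50 <- which(cumsum(cnt_sorted) >= occ$n_mapped / 2)[1L]
  overlap <- NULL
  if (!is.null(other_spots)) {
    overlap <- vapply(other_spots, function(sp) sum(tgt %in% sp$genes), integer(1L))
    names(overlap) <- vapply(other_spots, `[[`, character(1L), "label")
  }
  list(coords = occ$coords, counts = occ$counts, n_mapped = occ$n_mapped,
       fraction_mapped = occ$n_mapped / spot$n_genes,
       concentration = u50 / occ$n_mapped, spot_overlap = overlap)
}
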