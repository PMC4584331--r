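#' Train a self-organizing map on a gene-centric matrix
#'
#' Genes are the observations, samples the input dimensions: the SOM clusters
#' genes with similar profiles across samples into metagenes arranged on a
#' planar rectangular grid (default 50 x 50). Three trainings are customary:
#' on raw beta values (MetSOM), on centralized beta values (DmetSOM) and on
#' centralized log-expression (DexSOM); pass the already-centralized matrix
#' for the differential variants.
#'
#' Training is batch-mode and fully deterministic for a fixed seed:
#' initialization interpolates the codebook linearly over the grid along the
#' first two principal axes of the gene cloud (seeded random fallback when
#' the data have rank < 2), then each epoch reassigns every gene to its
#' best-matching unit (BMU; Euclidean distance, lowest unit index on ties)
#' and replaces every prototype by the Gaussian-neighborhood-weighted mean of
#' the assigned genes. The neighborhood radius decays linearly from
#' `max(grid_rows, grid_cols)/2` to 1 over the epochs.
#'
#' @param m a [gene_sample_matrix()] with >= 2 genes and >= 2 samples; all
#'   values must be finite (no `NA`).
#' @param grid_rows,grid_cols grid dimensions (>= 2); defaults 50 x 50.
#' @param epochs number of batch epochs (default 30).
#' @param seed integer seed; controls the random-init fallback and makes the
#'   run bit-reproducible.
#' @param variant free tag recorded in the model (`"MetSOM"`, `"DmetSOM"`,
#'   `"DexSOM"`); inferred from modality/centralization when `NULL`.
#' @return an object of class `som_model` with elements `codebook`
#'   (units x samples, row-major 0-based unit order), `bmu` (named 0-based
#'   unit index per gene), `grid_rows`, `grid_cols`, `data` (the training
#'   matrix), `qe` (mean quantization error per epoch, last entry after the
#'   final update), and the training record.
#' @export
train_som <- function(m, grid_rows = 50L, grid_cols = 50L, epochs = 30L,
                      seed = 1L, variant = NULL) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  X <- m$values
  if (nrow(X) < 2L || ncol(X) < 2L) stop("SOM training needs >= 2 genes and >= 2 samples")
  if (grid_rows < 2L || grid_cols < 2L) stop("grid dimensions must be >= 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!all(is.finite(X))) stop("SOM training input must be finite (no NA/Inf)")
  if (is.null(variant)) {
    variant <- if (m$modality == "log_expression") "DexSOM"
    else if (m$centralized) "DmetSOM" else "MetSOM"
  }
  set.seed(as.integer(seed))
  n <- nrow(X); d <- ncol(X)
  U <- as.integer(grid_rows) * as.integer(grid_cols)

  coords <- unit_to_coord(seq_len(U) - 1L, grid_cols)
  grid_d2 <- outer(coords[, "row"], coords[, "row"], `-`)^2 +
    outer(coords[, "col"], coords[, "col"], `-`)^2

  W <- som_init(X, grid_rows, grid_cols)

  r0 <- max(grid_rows, grid_cols) / 2
  qe <- numeric(epochs + 1L)
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    asg <- bmu_all(X, W)
    bmu <- asg$bmu
    qe[e] <- mean(sqrt(pmax(asg$d2, 0)))
    sigma <- if (epochs == 1L) 1 else r0 + (e - 1L) / (epochs - 1L) * (1 - r0)
    H <- exp(-grid_d2 / (2 * sigma^2))
    cnt <- tabulate(bmu + 1L, nbins = U)
    S <- matrix(0, U, d)
    rs <- rowsum(X, group = bmu, reorder = FALSE)
    S[as.integer(rownames(rs)) + 1L, ] <- rs
    denom <- as.vector(H %*% cnt)
    W <- (H %*% S) / denom
  }
  asg <- bmu_all(X, W)
  bmu <- asg$bmu
  qe[epochs + 1L] <- mean(sqrt(pmax(asg$d2, 0)))

  colnames(W) <- colnames(X)
  structure(list(
    codebook = W,
    bmu = stats::setNames(bmu, rownames(X)),
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    data = X, modality = m$modality, centralized = m$centralized,
    variant = variant, seed = as.integer(seed), epochs = as.integer(epochs),
    radius = c(initial = r0, final = 1), qe = qe
  ), class = "som_model")
}

# BMU of every row of X against codebook W; 0-based, lowest index on ties.
bmu_all <- function(X, W) {
  wn <- rowSums(W^2)
  score <- 2 * (X %*% t(W))
  score <- sweep(score, 2L, wn)           # 2 x.w - |w|^2 (maximize)
  bmu <- max.col(score, ties.method = "first") - 1L
  d2 <- rowSums(X^2) - score[cbind(seq_len(nrow(X)), bmu + 1L)]
  list(bmu = bmu, d2 = d2)
}

# PCA-grid initialization; seeded random fallback for rank-deficient data.
som_init <- function(X, grid_rows, grid_cols) {
  n <- nrow(X)
  U <- grid_rows * grid_cols
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = 2L)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  if (length(sv$d) < 2L || !is.finite(sv$d[2L]) || sv$d[2L] <= max(tol, 1e-12)) {
    idx <- sample.int(n, U, replace = TRUE)
    return(X[idx, , drop = FALSE] +
             matrix(stats::rnorm(U * ncol(X), sd = 1e-6), U))
  }
  v1 <- sv$v[, 1L]; v2 <- sv$v[, 2L]
  # sign convention keyed to the largest-magnitude loading, so that training
  # commutes with sample (column) permutation
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  if (v2[which.max(abs(v2))] < 0) v2 <- -v2
  s1 <- 2 * sv$d[1L] / sqrt(n - 1)
  s2 <- 2 * sv$d[2L] / sqrt(n - 1)
  coords <- unit_to_coord(seq_len(U) - 1L, grid_cols)
  a_col <- 2 * coords[, "col"] / (grid_cols - 1) - 1
  a_row <- 2 * coords[, "row"] / (grid_rows - 1) - 1
  matrix(mu, U, ncol(X), byrow = TRUE) + outer(a_col * s1, v1) + outer(a_row * s2, v2)
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model [%s]: %d x %d grid, %d genes, %d samples, %d epochs (seed %d)\n",
              x$variant, x$grid_rows, x$grid_cols, length(x$bmu),
              ncol(x$codebook), x$epochs, x$seed))
  cat(sprintf("  quantization error: %.4g (epoch 1) -> %.4g (final)\n",
              x$qe[1L], x$qe[length(x$qe)]))
  invisible(x)
}

#' Best-matching unit of a profile vector
#'
#' Returns the 0-based (row-major) index of the codebook unit with minimal
#' Euclidean distance to `gene_vector`; the lowest index wins ties.
#'
#' @param model a `som_model`.
#' @param gene_vector numeric vector of length `n_samples`.
#' @return integer unit index in `0 .. grid_rows*grid_cols - 1`.
#' @export
assign_bmu <- function(model, gene_vector) {
  stopifnot(inherits(model, "som_model"))
  if (length(gene_vector) != ncol(model$codebook)) {
    stop(sprintf("gene vector has length %d but the model has %d samples",
                 length(gene_vector), ncol(model$codebook)))
  }
  d2 <- rowSums(sweep(model$codebook, 2L, gene_vector)^2)
  which.min(d2) - 1L
}

#' Metagene portrait of one sample
#'
#' The grid of metagene values of a single sample: cell (r, c) holds the
#' sample's component of the prototype vector of unit `r*grid_cols + c`.
#' These mosaics are the fingerprint portraits of each sample's molecular
#' landscape.
#'
#' @param model a `som_model`.
#' @param sample_id a sample known to the model.
#' @return numeric matrix `grid_rows x grid_cols`.
#' @export
sample_portrait <- function(model, sample_id) {
  stopifnot(inherits(model, "som_model"))
  if (!sample_id %in% colnames(model$codebook)) {
    stop("unknown sample: '", sample_id, "'")
  }
  matrix(model$codebook[, sample_id], nrow = model$grid_rows,
         ncol = model$grid_cols, byrow = TRUE)
}

#' Map a gene group onto the grid
#'
#' Marks the metagenes occupied by at least one gene of the group, with
#' per-unit occupancy counts. Genes unknown to the model are skipped with a
#' warning.
#'
#' @param model a `som_model`.
#' @param genes character vector of gene symbols.
#' @return list with `coords` (0-based `(row, col)` matrix of occupied units),
#'   `counts` (occupancy per occupied unit, same order), `n_mapped`,
#'   `n_skipped`.
#' @export
map_gene_group <- function(model, genes) {
  stopifnot(inherits(model, "som_model"))
  known <- genes[genes %in% names(model$bmu)]
  n_skipped <- length(genes) - length(known)
  if (n_skipped > 0) warning(n_skipped, " gene(s) not in the trained model skipped")
  if (!length(known)) {
    warning("no genes of the group are mapped in this model")
    return(list(coords = unit_to_coord(integer(0), model$grid_cols),
                counts = integer(0), n_mapped = 0L, n_skipped = n_skipped))
  }
  tab <- table(model$bmu[known])
  units <- as.integer(names(tab))
  list(coords = unit_to_coord(units, model$grid_cols),
       counts = as.integer(tab), n_mapped = length(known), n_skipped = n_skipped)
}

# mean quantization error of a model state (exposed for diagnostics)
quantization_error <- function(model) {
  asg <- bmu_all(model$data, model$codebook)
  mean(sqrt(pmax(asg$d2, 0)))
}

#' Serialize / load a trained SOM as plain text
#'
#' Writes `codebook.tsv`, `bmu.tsv`, `data.tsv` and `meta.json` into a
#' directory; `load_som()` restores the model.
#'
#' @param model a `som_model`.
#' @param dir output directory (created if needed).
#' @return `dir` (`save_som`) or the restored `som_model` (`load_som`).
#' @export
save_som <- function(model, dir) {
  stopifnot(inherits(model, "som_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cb <- data.frame(unit = seq_len(nrow(model$codebook)) - 1L,
                   format(model$codebook, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(cb) <- c("unit", colnames(model$codebook))
  utils::write.table(cb, file.path(dir, "codebook.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(model$bmu), unit = unname(model$bmu)),
                     file.path(dir, "bmu.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  m <- gene_sample_matrix(model$data,
                          modality = model$modality, centralized = model$centralized)
  write_matrix(m, file.path(dir, "data.tsv"))
  meta <- model[c("grid_rows", "grid_cols", "modality", "centralized",
                  "variant", "seed", "epochs")]
  meta$qe <- model$qe
  meta$radius <- as.list(model$radius)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_som
#' @export
load_som <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cb <- utils::read.delim(file.path(dir, "codebook.tsv"), check.names = FALSE)
  W <- as.matrix(cb[, -1L, drop = FALSE])
  rownames(W) <- NULL
  bm <- utils::read.delim(file.path(dir, "bmu.tsv"), check.names = FALSE,
                          colClasses = c("character", "integer"))
  m <- read_matrix(file.path(dir, "data.tsv"), modality = meta$modality,
                   centralized = meta$centralized)
  structure(list(
    codebook = W, bmu = stats::setNames(bm$unit, bm$gene),
    grid_rows = meta$grid_rows, grid_cols = meta$grid_cols,
    data = m$values, modality = meta$modality, centralized = meta$centralized,
    variant = meta$variant, seed = meta$seed, epochs = meta$epochs,
    radius = unlist(meta$radius), qe = meta$qe
  ), class = "som_model")
}
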