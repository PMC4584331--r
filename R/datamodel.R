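#' Gene x sample matrix with a modality flag
#'
#' The central data container of the package: a numeric matrix with genes as
#' rows and samples as columns, tagged with a modality. Methylation matrices
#' carry promoter beta values in \[0, 1\] (0 = unmethylated, 1 = fully
#' methylated); expression matrices carry log2 intensities. Missing values are
#' `NA` and are excluded from all statistics.
#'
#' @param values numeric matrix with unique rownames (gene symbols) and unique
#'   colnames (sample ids).
#' @param modality `"methylation_beta"` or `"log_expression"`.
#' @param centralized logical; `TRUE` when each gene's cross-sample mean has
#'   been subtracted (see [centralize()]). Centralized beta values are no
#'   longer constrained to \[0, 1\].
#' @return an object of class `gene_sample_matrix`.
#' @export
gene_sample_matrix <- function(values, modality = c("methylation_beta", "log_expression"),
                               centralized = FALSE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("'values' must have rownames (gene ids) and colnames (sample ids)")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (modality == "methylation_beta" && !centralized) {
    bad <- which(!is.na(values) & (values < -1e-9 | values > 1 + 1e-9), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "beta value out of [0,1]: gene '%s', sample '%s' (value %.6g)",
        genes[bad[1L, 1L]], samples[bad[1L, 2L]], values[bad[1L, , drop = FALSE]]
      ))
    }
  }
  structure(
    list(values = values, modality = modality, centralized = centralized),
    class = "gene_sample_matrix"
  )
}

#' @export
print.gene_sample_matrix <- function(x, ...) {
  cat(sprintf(
    "gene_sample_matrix: %d genes x %d samples [%s%s]\n",
    nrow(x$values), ncol(x$values), x$modality,
    if (x$centralized) ", centralized" else ""
  ))
  invisible(x)
}

#' @export
dim.gene_sample_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Read a gene x sample matrix from TSV
#'
#' Expected layout: header row of sample ids, first column gene symbols,
#' tab-separated numeric cells. Duplicated gene or sample ids, non-numeric
#' cells and (for methylation) beta values outside \[0, 1\] beyond a 1e-9
#' tolerance are hard errors.
#'
#' @inheritParams gene_sample_matrix
#' @param path TSV file path.
#' @return a [gene_sample_matrix()].
#' @export
read_matrix <- function(path, modality = c("methylation_beta", "log_expression"),
                        centralized = FALSE) {
  modality <- match.arg(modality)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  if (ncol(tab) < 2L) stop("matrix file needs a gene column plus >= 1 sample column")
  genes <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 genes[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]],
                 raw[bad[1L, , drop = FALSE]]))
  }
  dimnames(num) <- list(genes, colnames(raw))
  gene_sample_matrix(num, modality, centralized = centralized)
}

#' Write a gene x sample matrix as TSV
#'
#' Inverse of [read_matrix()]; full-precision (`format` with 17 significant
#' digits) so that a read/write round trip is value-exact for finite inputs.
#'
#' @param m a [gene_sample_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  df <- data.frame(gene = gene_ids(m),
                   format(m$values, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", sample_ids(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Two-column TSV (`sample_id`, `class`); returns a named character vector
#' mapping sample id to class label. A header line is detected and skipped if
#' its first field equals `"sample_id"`.
#'
#' @param path TSV file path.
#' @return named character vector (names = sample ids, values = class labels).
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(tab) < 2L) stop("annotation file needs two columns (sample_id, class)")
  if (tab[1L, 1L] == "sample_id") tab <- tab[-1L, , drop = FALSE]
  ann <- sample_annotation(tab[[1L]], tab[[2L]])
  ann
}

#' Build a sample annotation from vectors
#'
#' @param sample_id character vector of unique sample ids.
#' @param class character vector of class labels, same length.
#' @return named character vector mapping sample id to class.
#' @export
sample_annotation <- function(sample_id, class) {
  if (length(sample_id) != length(class)) stop("sample_id and class differ in length")
  if (!length(sample_id)) stop("annotation must contain >= 1 sample")
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids in annotation: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  stats::setNames(as.character(class), as.character(sample_id))
}

#' @rdname sample_annotation
#' @param ann an annotation vector.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(
    data.frame(sample_id = names(ann), class = unname(ann)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# every sample of m must be annotated with exactly one class
check_annotation <- function(m, ann) {
  missing <- setdiff(sample_ids(m), names(ann))
  if (length(missing)) {
    stop("samples without class annotation: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name<TAB>description<TAB>gene...`.
#' Symbols are upper-cased and de-duplicated within each set; empty sets are
#' rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line (need name, description, >=1 gene): ", ln)
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set in GMT: ", parts[1L])
    sets[[parts[1L]]] <- structure(genes, description = parts[2L])
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, attr(sets[[nm]], "description") %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Centralize a gene x sample matrix
#'
#' Subtracts from every value the gene's mean over all (non-missing) samples,
#' so values express deviation from the cohort average. This is the
#' preprocessing behind the differential-methylation and differential
#' -expression SOM variants. A gene with all values missing stays all-missing
#' (with a warning).
#'
#' @param m a [gene_sample_matrix()].
#' @return a [gene_sample_matrix()] with `centralized = TRUE`; per-gene means
#'   of the result are 0 to within 1e-12.
#' @export
centralize <- function(m) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  if (ncol(m$values) < 1L) stop("centralize needs >= 1 sample")
  mu <- rowMeans(m$values, na.rm = TRUE)
  all_na <- !is.finite(mu)
  if (any(all_na)) {
    warning(sum(all_na), " gene(s) with all values missing left all-missing")
    mu[all_na] <- 0
  }
  gene_sample_matrix(m$values - mu, m$modality, centralized = TRUE)
}

#' Match genes between two matrices by symbol
#'
#' Case-insensitive symbol matching; each symbol contributes at most one pair
#' per side. Used to carry gene modules between the methylation and expression
#' platforms.
#'
#' @param a,b [gene_sample_matrix()] objects or character vectors of symbols.
#' @return data.frame with columns `gene_a`, `gene_b` (original-case symbols).
#' @export
match_genes <- function(a, b) {
  ga <- if (inherits(a, "gene_sample_matrix")) gene_ids(a) else as.character(a)
  gb <- if (inherits(b, "gene_sample_matrix")) gene_ids(b) else as.character(b)
  ga <- ga[!duplicated(toupper(ga))]
  gb <- gb[!duplicated(toupper(gb))]
  idx <- match(toupper(ga), toupper(gb))
  keep <- !is.na(idx)
  out <- data.frame(gene_a = ga[keep], gene_b = gb[idx[keep]],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) warning("no genes shared between the two matrices")
  out
}

#' Collapse probe-level rows to gene level by arithmetic mean
#'
#' Methylation panels often probe several CpGs per promoter; analysis here is
#' gene-centric, so probe rows sharing a gene are averaged (NA-aware). The
#' mean keeps beta values inside \[0, 1\].
#'
#' @param m a [gene_sample_matrix()] whose rownames are probe ids.
#' @param probe_gene named character vector mapping probe id to gene symbol.
#' @return a gene-level [gene_sample_matrix()].
#' @export
collapse_probes <- function(m, probe_gene) {
  stopifnot(inherits(m, "gene_sample_matrix"))
  genes <- probe_gene[gene_ids(m)]
  if (anyNA(genes)) stop("probes without gene mapping: ",
                         paste(gene_ids(m)[is.na(genes)], collapse = ", "))
  grp <- factor(toupper(genes))
  cnt <- rowsum((!is.na(m$values)) * 1, grp)
  tot <- rowsum(ifelse(is.na(m$values), 0, m$values), grp)
  val <- tot / cnt
  val[cnt == 0] <- NA_real_
  gene_sample_matrix(val, m$modality, centralized = m$centralized)
}
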