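#' Sample similarity matrix of metagene landscapes
#'
#' Pearson correlation between the metagene landscape vectors (codebook
#' columns) of every pair of samples. The SOM acts as a denoiser here;
#' `raw = TRUE` correlates the original gene vectors instead.
#'
#' @param model a `som_model` with >= 2 samples.
#' @param raw correlate gene-level data instead of metagene landscapes.
#' @return symmetric correlation matrix with unit diagonal; rows/columns of a
#'   zero-variance landscape are `NA` (with a warning).
#' @export
sample_similarity <- function(model, raw = FALSE) {
  stopifnot(inherits(model, "som_model"))
  M <- if (raw) model$data else model$codebook
  if (ncol(M) < 2L) stop("similarity needs >= 2 samples")
  if (nrow(M) < 2L) stop("similarity needs >= 2 units")
  sds <- apply(M, 2L, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(M))
  if (any(flat)) {
    warning("zero-variance landscape(s): ", paste(colnames(M)[flat], collapse = ", "))
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Build a thresholded sample similarity network
#'
#' Connects samples whose landscapes correlate strictly above `r_min`
#' (default r > 0.5); isolated samples are retained as singleton nodes.
#' Clusters are the connected components of the resulting graph.
#'
#' @param sim symmetric correlation matrix from [sample_similarity()].
#' @param ann sample annotation covering the matrix's samples.
#' @param r_min correlation threshold; edges require `r > r_min`.
#' @return object of class `sample_network`: list with `nodes` (data.frame
#'   `sample`, `class`, `component`), `edges` (data.frame `a`, `b`, `r`),
#'   `r_min`, `n_components`, and the underlying `igraph` object.
#' @export
build_network <- function(sim, ann, r_min = 0.5) {
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-8))) {
    stop("similarity matrix must be symmetric")
  }
  ids <- colnames(sim)
  cls <- ann[ids]
  if (anyNA(cls)) stop("samples without class annotation")
  adj <- !is.na(sim) & sim > r_min
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  ut <- which(upper.tri(sim) & adj, arr.ind = TRUE)
  edges <- data.frame(a = ids[ut[, 1L]], b = ids[ut[, 2L]],
                      r = sim[ut], stringsAsFactors = FALSE)
  nodes <- data.frame(sample = ids, class = unname(cls),
                      component = comp$membership, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, r_min = r_min,
                 n_components = comp$no, graph = g),
            class = "sample_network")
}

#' @export
print.sample_network <- function(x, ...) {
  cat(sprintf("sample_network: %d samples, %d edges (r > %g), %d components\n",
              nrow(x$nodes), nrow(x$edges), x$r_min, x$n_components))
  invisible(x)
}

#' Class composition of network components
#'
#' For every connected component, the count of each class and the percentage
#' of that class's samples falling into the component; percentages of one
#' class sum to 100 across components (singletons included).
#'
#' @param net a `sample_network`.
#' @return data.frame with columns `component`, `class`, `n`, `pct_of_class`.
#' @export
component_composition <- function(net) {
  stopifnot(inherits(net, "sample_network"))
  nd <- net$nodes
  class_tot <- table(nd$class)
  tab <- as.data.frame(table(component = nd$component, class = nd$class),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  data.frame(component = as.integer(tab$component), class = tab$class,
             n = tab$Freq,
             pct_of_class = 100 * tab$Freq / as.integer(class_tot[tab$class]),
             stringsAsFactors = FALSE, row.names = NULL)
}
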