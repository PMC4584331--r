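`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sarle's bimodality coefficient
#'
#' \eqn{b = (g_1^2 + 1) / (g_2 + 3(n-1)^2 / ((n-2)(n-3)))} with \eqn{g_1} the
#' sample skewness and \eqn{g_2} the sample excess kurtosis. A uniform
#' distribution gives \eqn{b = 5/9}; values above that threshold indicate
#' bimodality (a balanced two-point distribution approaches \eqn{b = 1}).
#'
#' @param x numeric vector; missing values are dropped.
#' @return the coefficient, a value in (0, 1].
#' @export
bimodality_coefficient <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("bimodality coefficient needs >= 4 non-missing values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("bimodality coefficient undefined for constant data (zero variance)")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# population variance (divisor n), NA-aware
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Convert between row-major unit indices and grid coordinates
#'
#' Units are indexed 0-based in row-major order: unit `u` sits at row
#' `u %/% grid_cols`, column `u %% grid_cols` (both 0-based).
#'
#' @param unit integer vector of 0-based unit indices.
#' @param row,col integer vectors of 0-based grid coordinates.
#' @param grid_cols number of grid columns.
#' @return `unit_to_coord()`: a matrix with columns `row`, `col`;
#'   `coord_to_unit()`: an integer vector of unit indices.
#' @export
unit_to_coord <- function(unit, grid_cols) {
  cbind(row = unit %/% grid_cols, col = unit %% grid_cols)
}

#' @rdname unit_to_coord
#' @export
coord_to_unit <- function(row, col, grid_cols) {
  row * grid_cols + col
}

stop_if_not_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single string", what))
  }
}
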