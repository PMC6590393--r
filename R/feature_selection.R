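# Feature table container, z-normalization, the moment-based multimodality
# index, and the correlation-threshold / multimodality-ranked parameter
# filter.

#' Feature table of cells x morphometric parameters
#'
#' @param values numeric matrix, rows = cells, columns = named parameters.
#' @param cell_ids character vector of row identifiers.
#' @param normalized whether columns are already z-scored.
#' @return object of class `feature_table` with fields `values`,
#'   `cell_ids`, `parameter_names`, `normalized`.
#' @export
feature_table <- function(values, cell_ids = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("feature table columns must be named")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%03d", seq_len(nrow(values)))
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length does not match rows")
  if (anyNA(values)) stop("feature table holds missing values")
  rownames(values) <- cell_ids
  structure(list(values = values, cell_ids = cell_ids,
                 parameter_names = colnames(values),
                 normalized = isTRUE(normalized)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d cells x %d parameters%s>\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

#' Column-wise z-normalization
#'
#' Standardizes every parameter by subtracting its mean and dividing by its
#' standard deviation (n-1 divisor) so all parameters contribute equally as
#' cluster variables. Idempotent on already-normalized tables.
#'
#' @param table a [feature_table()].
#' @return the normalized [feature_table()].
#' @export
zscore <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  sds <- apply(table$values, 2, sd)
  if (any(sds == 0))
    stop("zero-variance parameter: ",
         paste(colnames(table$values)[sds == 0], collapse = ", "))
  v <- scale(table$values)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  feature_table(v, cell_ids = table$cell_ids, normalized = TRUE)
}

#' Multimodality index of a sample
#'
#' Sarle's bimodality coefficient
#' `b = (g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3)))`
#' with bias-corrected sample skewness `g1` and excess kurtosis `g2`.
#' Asymptotically 1/3 for a normal sample, 5/9 for a uniform one, and 1 for
#' a symmetric two-point distribution; larger values flag bi-/multimodal
#' (classification-relevant) parameters.
#'
#' @param values numeric vector, `n >= 4`, nonzero variance.
#' @return the coefficient, in `(0, 1]` up to sampling noise.
#' @export
multimodality_index <- function(values) {
  n <- length(values)
  if (n < 4) stop("insufficient sample (n < 4)")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance")
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  (G1^2 + 1) / (G2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Correlation-threshold parameter filter ranked by multimodality
#'
#' Greedy screen of redundant parameters: parameters are visited in order of
#' decreasing multimodality index (ties broken alphabetically) and retained
#' iff their absolute Pearson correlation with every already-retained
#' parameter stays below `r_threshold`. Each drop records the retained
#' parameter that blocked it.
#'
#' @param table a normalized [feature_table()] with >= 2 parameters.
#' @param r_threshold Pearson threshold (default 0.7).
#' @return object of class `selection_report`: `mmi` (named vector),
#'   `correlation` and `p_values` matrices, `retained` (ordered by MMI),
#'   `dropped` (data.frame parameter/reason/blocked_by), `r_threshold`.
#' @export
correlation_filter <- function(table, r_threshold = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$normalized) stop("correlation_filter expects a z-scored table")
  v <- table$values
  p <- ncol(v)
  if (p < 2) stop("need >= 2 parameters")
  mmi <- apply(v, 2, multimodality_index)
  rmat <- cor(v)
  n <- nrow(v)
  tstat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  pmat <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(pmat) <- 0

  ord <- order(-mmi, colnames(v))
  retained <- character(0)
  dropped <- data.frame(parameter = character(0), reason = character(0),
                        blocked_by = character(0),
                        stringsAsFactors = FALSE)
  for (j in ord) {
    nm <- colnames(v)[j]
    if (length(retained)) {
      rr <- abs(rmat[nm, retained])
      if (any(rr >= r_threshold)) {
        blocker <- retained[which.max(rr)]
        dropped <- rbind(dropped, data.frame(
          parameter = nm,
          reason = sprintf("|r| = %.3f >= %.2f", max(rr), r_threshold),
          blocked_by = blocker, stringsAsFactors = FALSE))
        next
      }
    }
    retained <- c(retained, nm)
  }
  structure(list(mmi = mmi, correlation = rmat, p_values = pmat,
                 retained = retained, dropped = dropped,
                 r_threshold = r_threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report: %d retained, %d dropped (|r| >= %.2f)>\n",
              length(x$retained), nrow(x$dropped), x$r_threshold))
  cat("retained (by multimodality index):\n")
  for (nm in x$retained)
    cat(sprintf("  %-15s %.3f\n", nm, x$mmi[nm]))
  invisible(x)
}

# restrict a feature table to a set of parameters
subset_features <- function(table, parameters) {
  feature_table(table$values[, parameters, drop = FALSE],
                cell_ids = table$cell_ids, normalized = table$normalized)
}
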