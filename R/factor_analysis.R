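# Principal-axis factoring, raw Varimax rotation, and the retention rule
# that turns a rotated factor model into a small set of clustering
# parameters.

#' Principal-axis factoring of a correlation matrix
#'
#' Iterative common-factor extraction: the diagonal of the correlation
#' matrix is replaced by communality estimates (squared multiple
#' correlations to start), the reduced matrix is eigendecomposed, loadings
#' are rebuilt from the top `n_factors` eigenpairs, and the cycle repeats
#' until the largest communality change falls below `tol`.
#'
#' @param corr symmetric correlation matrix with named rows/columns.
#' @param n_factors number of factors to extract; default: eigenvalues of
#'   the reduced matrix above 1, capped at 5.
#' @param max_iter iteration cap (default 1000). Non-convergence raises an
#'   error of class `cytofractal_nonconvergence` carrying the last iterate
#'   in its `model` field.
#' @param tol convergence tolerance on communalities (default 1e-6).
#' @return object of class `factor_model`: `loadings` (parameters x
#'   factors), `explained_variance` (column sums of squared loadings),
#'   `communalities`, `n_factors`, `rotation` (`"none"`), `iterations`.
#' @export
principal_axis_factoring <- function(corr, n_factors = NULL, max_iter = 1000,
                                     tol = 1e-6) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (is.null(rownames(corr))) stop("correlation matrix must be named")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
    stop("correlation matrix not positive semi-definite")

  # squared multiple correlations as starting communalities
  h2 <- tryCatch(1 - 1 / diag(solve(corr)),
                 error = function(e) apply(abs(corr - diag(p)), 1, max))
  h2 <- pmin(pmax(h2, 0), 1)

  if (is.null(n_factors)) {
    red <- corr; diag(red) <- h2
    ev <- eigen(red, symmetric = TRUE, only.values = TRUE)$values
    n_factors <- max(1L, min(5L, sum(ev > 1)))
  }
  if (n_factors >= p) stop("n_factors must be < number of parameters")

  heywood <- FALSE
  loadings <- NULL
  for (it in seq_len(max_iter)) {
    red <- corr
    diag(red) <- h2
    e <- eigen(red, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(n_factors)], 0)
    loadings <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(lam), n_factors)
    h2_new <- rowSums(loadings^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1)
    }
    delta <- max(abs(h2_new - h2))
    # damped update after the initial sweeps: near-collinear parameter
    # pairs can set up a two-cycle in the communality iteration
    h2 <- if (it > 50) (h2 + h2_new) / 2 else h2_new
    if (delta < tol) break
  }
  dimnames(loadings) <- list(rownames(corr),
                             paste0("Factor", seq_len(n_factors)))
  model <- structure(
    list(loadings = loadings,
         explained_variance = colSums(loadings^2),
         communalities = setNames(h2, rownames(corr)),
         n_factors = n_factors, rotation = "none",
         corr = corr, iterations = it, converged = delta < tol),
    class = "factor_model")
  if (heywood)
    warning("Heywood case: communalities clipped at 1")
  if (!model$converged) {
    cond <- structure(
      class = c("cytofractal_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "principal-axis factoring did not converge in %d iterations (last change %.2e)",
        max_iter, delta),
        call = sys.call(-1), model = model))
    stop(cond)
  }
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model: %d parameters, %d factors, rotation=%s>\n",
              nrow(x$loadings), x$n_factors, x$rotation))
  cat("explained variance:",
      paste(sprintf("%.2f", x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

# raw varimax criterion: sum over factors of the variance of squared
# loadings, not normalized by communalities
varimax_criterion <- function(loadings) {
  sq <- loadings^2
  sum(apply(sq, 2, function(col) mean((col - mean(col))^2)))
}

#' Raw Varimax rotation of a factor model
#'
#' Orthogonal rotation maximizing the raw varimax criterion (variance of
#' squared loadings per factor, without Kaiser normalization), which
#' polarizes loadings towards 0 or +/-1 while preserving per-parameter
#' communalities. Factors are re-ordered by explained variance and
#' sign-flipped so the dominant loading of each factor is positive.
#'
#' @param model an unrotated [principal_axis_factoring()] model.
#' @return the rotated `factor_model` (rotation `"varimax_raw"`, with the
#'   rotation matrix in `$rotmat`).
#' @export
varimax_rotate <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  if (model$rotation != "none") stop("model already rotated")
  if (model$n_factors == 1L) {
    message("single factor: varimax rotation is the identity")
    model$rotation <- "varimax_raw"
    model$rotmat <- matrix(1, 1, 1)
    return(model)
  }
  # multi-start: symmetric loading patterns can be exact stationary points
  # of the criterion where the default iteration never moves
  m <- model$n_factors
  starts <- c(list(diag(m)),
              with_seed(1703, lapply(1:4, function(i)
                qr.Q(qr(matrix(rnorm(m * m), m))))))
  best <- NULL
  for (S in starts) {
    v <- stats::varimax(model$loadings %*% S, normalize = FALSE,
                        eps = 1e-10)
    Lc <- model$loadings %*% S %*% v$rotmat
    if (is.null(best) || varimax_criterion(Lc) > varimax_criterion(best$L))
      best <- list(L = Lc, rot = S %*% v$rotmat)
  }
  L <- best$L
  rot <- best$rot
  # deterministic presentation: order by explained variance, dominant sign +
  ev <- colSums(L^2)
  ord <- order(-ev)
  L <- L[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      rot[, j] <- -rot[, j]
    }
  }
  colnames(L) <- paste0("Factor", seq_len(ncol(L)))
  model$loadings <- L
  model$rotmat <- rot
  model$explained_variance <- colSums(L^2)
  model$rotation <- "varimax_raw"
  model
}

#' Retain factors and pick one parameter per factor
#'
#' Applies the two retention thresholds — explained variance above
#' `explvar_min` and at least one parameter with `|loading| >=
#' loading_min` — then selects, per retained factor, the loading parameter
#' with the highest multimodality index. A parameter loading several
#' retained factors is assigned to the factor where its absolute loading is
#' largest, and the next-best loader fills the vacated factor.
#'
#' @param model a rotated [factor_model].
#' @param mmi named multimodality indices covering all parameters.
#' @param explvar_min explained-variance threshold (default 3).
#' @param loading_min loading threshold (default 0.70).
#' @return object of class `factor_selection`: `retained_factors`,
#'   `loaders` (list per factor), `chosen` (named character, one parameter
#'   per factor), `thresholds`.
#' @export
select_factors_and_parameters <- function(model, mmi, explvar_min = 3,
                                          loading_min = 0.70) {
  stopifnot(inherits(model, "factor_model"))
  if (model$rotation == "none")
    stop("selection expects a rotated model")
  L <- model$loadings
  if (!all(rownames(L) %in% names(mmi)))
    stop("mmi does not cover all parameters")
  loaders_all <- apply(abs(L) >= loading_min, 2, function(m)
    rownames(L)[m], simplify = FALSE)
  keep <- model$explained_variance > explvar_min &
    vapply(loaders_all, length, 0L) > 0L
  if (!any(keep))
    stop(sprintf("no factors retained (explvar_min=%g, loading_min=%g)",
                 explvar_min, loading_min))
  retained <- colnames(L)[keep]
  loaders <- loaders_all[retained]

  # resolve parameters loading several retained factors: keep them only in
  # the factor where |loading| is maximal
  all_pars <- unique(unlist(loaders))
  for (par in all_pars) {
    inf <- retained[vapply(loaders, function(s) par %in% s, TRUE)]
    if (length(inf) > 1L) {
      best <- inf[which.max(abs(L[par, inf]))]
      for (f in setdiff(inf, best))
        loaders[[f]] <- setdiff(loaders[[f]], par)
    }
  }
  empty <- vapply(loaders, length, 0L) == 0L
  if (any(empty)) {
    warning("factor(s) left without loaders after assignment: ",
            paste(names(loaders)[empty], collapse = ", "))
    retained <- retained[!empty]
    loaders <- loaders[retained]
  }
  chosen <- vapply(loaders, function(s) s[which.max(mmi[s])], "")
  structure(list(retained_factors = retained, loaders = loaders,
                 chosen = chosen,
                 thresholds = c(explvar_min = explvar_min,
                                loading_min = loading_min)),
            class = "factor_selection")
}

#' @export
print.factor_selection <- function(x, ...) {
  cat(sprintf("<factor_selection: %d factors retained>\n",
              length(x$retained_factors)))
  for (f in x$retained_factors)
    cat(sprintf("  %s: %s  (loaders: %s)\n", f, x$chosen[[f]],
                paste(x$loaders[[f]], collapse = ", ")))
  invisible(x)
}

#' Factor scores by the regression method
#'
#' @param model a (rotated) [factor_model].
#' @param table the normalized [feature_table()] the model was fitted on.
#' @param factors which factors to score (default all).
#' @return matrix of cells x factor scores.
#' @export
factor_scores <- function(model, table, factors = NULL) {
  stopifnot(inherits(model, "factor_model"),
            inherits(table, "feature_table"))
  if (!table$normalized) stop("factor scores expect a z-scored table")
  L <- model$loadings
  Z <- table$values[, rownames(L), drop = FALSE]
  # pseudo-inverse: exactly collinear parameter pairs (e.g. a dimension and
  # its sign-flipped mass twin) make the correlation matrix singular
  S <- Z %*% (MASS::ginv(model$corr) %*% L)
  if (!is.null(factors)) S <- S[, factors, drop = FALSE]
  S
}
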