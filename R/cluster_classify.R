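# Ward clustering over candidate k and the discriminant evaluation of a
# cluster solution: squared Mahalanobis distances between cluster centroids,
# pairwise F statistics (Hotelling conversion), Wilks' lambda with
# per-variable partial lambda and F-remove, and Tukey-Kramer all-pairs
# comparisons.

#' Ward clustering of a feature table
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean distances
#' of the z-scored features, cut at `k` clusters. Cluster ids are assigned
#' by decreasing cluster size for reporting stability.
#'
#' @param table a normalized [feature_table()].
#' @param k number of clusters, `2 <= k <= n/3`.
#' @return object of class `cluster_solution`: `k`, `labels` (named by cell
#'   id), `feature_names`, `linkage_record` (merge pairs and heights),
#'   `hclust` (the underlying tree).
#' @export
ward_cluster <- function(table, k) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$normalized) stop("ward_cluster expects a z-scored table")
  n <- nrow(table$values)
  if (k < 2 || k > n / 3) stop("k out of range [2, n/3]")
  hc <- hclust(dist(table$values), method = "ward.D2")
  raw <- cutree(hc, k = k)
  # relabel by decreasing size, ties broken by first occurrence
  sizes <- tabulate(raw, nbins = k)
  ord <- order(-sizes, match(seq_len(k), raw))
  labels <- match(raw, ord)
  names(labels) <- table$cell_ids
  structure(
    list(k = k, labels = labels, feature_names = table$parameter_names,
         linkage_record = data.frame(left = hc$merge[, 1],
                                     right = hc$merge[, 2],
                                     height = hc$height),
         hclust = hc),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution: k=%d, sizes %s, features: %s>\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/"),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

# pooled within-cluster covariance (divisor n - k) and centroids
pooled_within <- function(X, labels, k) {
  p <- ncol(X)
  n <- nrow(X)
  centroids <- matrix(NA_real_, k, p)
  W <- matrix(0, p, p)
  for (g in seq_len(k)) {
    Xg <- X[labels == g, , drop = FALSE]
    centroids[g, ] <- colMeans(Xg)
    cc <- sweep(Xg, 2, centroids[g, ])
    W <- W + crossprod(cc)
  }
  list(centroids = centroids, S = W / (n - k), W = W)
}

#' Squared Mahalanobis distances between cluster centroids
#'
#' `D2[i, j] = (c_i - c_j)' S^-1 (c_i - c_j)` with the pooled
#' within-cluster covariance `S` (divisor `n - k`).
#'
#' @param table the normalized [feature_table()] the solution was built on
#'   (restricted to the clustering features).
#' @param sol a [ward_cluster()] solution; every cluster must hold more
#'   cells than there are features.
#' @return k x k symmetric matrix with zero diagonal.
#' @export
mahalanobis_matrix <- function(table, sol) {
  stopifnot(inherits(table, "feature_table"),
            inherits(sol, "cluster_solution"))
  X <- table$values
  p <- ncol(X)
  sizes <- tabulate(sol$labels, sol$k)
  if (any(sizes <= p))
    stop("every cluster must be larger than the feature count")
  pw <- pooled_within(X, sol$labels, sol$k)
  Sinv <- tryCatch(solve(pw$S), error = function(e)
    stop("pooled within-cluster covariance is singular; reduce features"))
  k <- sol$k
  D2 <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- pw$centroids[i, ] - pw$centroids[j, ]
    D2[i, j] <- D2[j, i] <- drop(t(d) %*% Sinv %*% d)
  }
  D2
}

#' Pairwise cluster F statistics from Mahalanobis distances
#'
#' Hotelling two-sample conversion with the all-cluster pooled covariance:
#' `F_ij = (n_i n_j / (n_i + n_j)) * ((n-k-p+1) / (p (n-k))) * D2_ij`
#' on `(p, n-k-p+1)` degrees of freedom. The summary `F_average` is the
#' unweighted mean over distinct cluster pairs.
#'
#' @param D2 matrix from [mahalanobis_matrix()].
#' @param sizes per-cluster cell counts.
#' @param p number of features used.
#' @return list with `F` matrix, `p_values`, `F_average`, `D2_average`,
#'   `df = c(p, n - k - p + 1)`.
#' @export
pairwise_cluster_F <- function(D2, sizes, p) {
  k <- length(sizes)
  stopifnot(nrow(D2) == k, ncol(D2) == k)
  n <- sum(sizes)
  df2 <- n - k - p + 1
  if (df2 <= 0) stop("n - k - p + 1 must be positive")
  Fm <- matrix(0, k, k)
  Pm <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- (sizes[i] * sizes[j] / (sizes[i] + sizes[j])) *
      (df2 / (p * (n - k))) * D2[i, j]
    Fm[i, j] <- Fm[j, i] <- f
    Pm[i, j] <- Pm[j, i] <- pf(f, p, df2, lower.tail = FALSE)
  }
  ut <- upper.tri(D2)
  list(F = Fm, p_values = Pm, F_average = mean(Fm[ut]),
       D2_average = mean(D2[ut]), df = c(p, df2))
}

#' Wilks' lambda and per-variable discriminant contribution
#'
#' Overall `Lambda = det(W) / det(T)` (within vs total SSCP). Per variable,
#' `lambda_without` is the overall lambda with that variable removed,
#' `partial_lambda = Lambda / lambda_without`, and
#' `F_remove = ((n-k-p+1)/(k-1)) * (1 - partial) / partial` on
#' `(k-1, n-k-p+1)` degrees of freedom.
#'
#' @param table normalized [feature_table()] of the clustering features.
#' @param sol a [ward_cluster()] solution.
#' @return list with `lambda` (overall) and `per_variable` data.frame
#'   (`variable`, `lambda_without`, `partial_lambda`, `F_remove`, `p_value`)
#'   plus `df = c(k-1, n-k-p+1)`.
#' @export
wilks_statistics <- function(table, sol) {
  stopifnot(inherits(table, "feature_table"),
            inherits(sol, "cluster_solution"))
  X <- table$values
  n <- nrow(X); p <- ncol(X); k <- sol$k
  df2 <- n - k - p + 1
  if (df2 <= 0) stop("n - k - p + 1 must be positive")
  lambda_of <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    Tm <- crossprod(sweep(Xs, 2, colMeans(Xs)))
    W <- pooled_within(Xs, sol$labels, k)$W
    dT <- det(Tm)
    if (dT <= 0) stop("singular total SSCP")
    det(W) / dT
  }
  lam <- lambda_of(seq_len(p))
  rows <- lapply(seq_len(p), function(j) {
    lw <- lambda_of(setdiff(seq_len(p), j))
    partial <- lam / lw
    f <- (df2 / (k - 1)) * (1 - partial) / partial
    data.frame(variable = colnames(X)[j], lambda_without = lw,
               partial_lambda = partial, F_remove = f,
               p_value = pf(f, k - 1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  list(lambda = lam, per_variable = do.call(rbind, rows),
       df = c(k - 1, df2))
}

#' Tukey-Kramer all-pairs comparison of cluster means
#'
#' Studentized-range test on the cluster means of one variable, with the
#' Kramer adjustment for unequal cluster sizes:
#' `q_ij = |m_i - m_j| / sqrt((MSE/2) (1/n_i + 1/n_j))`, compared against
#' the studentized range distribution with `k` groups and `n - k` df.
#'
#' @param values numeric vector (one variable).
#' @param labels cluster ids `1..k`, each cluster with >= 2 members.
#' @param alpha family-wise significance level (default 0.05).
#' @return list with `pairs` (data.frame `g1`, `g2`, `diff`, `p_adj`) and
#'   `significant` (the subset with `p_adj < alpha`).
#' @export
tukey_kramer <- function(values, labels, alpha = 0.05) {
  k <- max(labels)
  sizes <- tabulate(labels, k)
  if (k < 2 || any(sizes < 2)) stop("need >= 2 clusters with >= 2 members")
  n <- length(values)
  means <- vapply(seq_len(k), function(g) mean(values[labels == g]), 0)
  sse <- sum(vapply(seq_len(k), function(g)
    sum((values[labels == g] - means[g])^2), 0))
  df <- n - k
  mse <- sse / df
  if (mse == 0) stop("zero within-cluster variance")
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((mse / 2) * (1 / sizes[i] + 1 / sizes[j]))
    q <- abs(means[i] - means[j]) / se
    rows[[length(rows) + 1]] <- data.frame(
      g1 = i, g2 = j, diff = means[i] - means[j],
      p_adj = ptukey(q, k, df, lower.tail = FALSE))
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, significant = pairs[pairs$p_adj < alpha, ,
                                          drop = FALSE],
       alpha = alpha)
}

#' Full discriminant evaluation of one cluster solution
#'
#' @param table normalized [feature_table()] restricted to the clustering
#'   features.
#' @param sol a [ward_cluster()] solution.
#' @param alpha significance level for the Tukey-Kramer tables.
#' @return object of class `cluster_evaluation`: `D2`, `F`, `p_values`,
#'   `F_average`, `D2_average`, `df`, `wilks`, `tukey` (per variable),
#'   `sizes`.
#' @export
evaluate_clusters <- function(table, sol, alpha = 0.05) {
  D2 <- mahalanobis_matrix(table, sol)
  sizes <- tabulate(sol$labels, sol$k)
  pf_ <- pairwise_cluster_F(D2, sizes, ncol(table$values))
  wk <- wilks_statistics(table, sol)
  tk <- lapply(setNames(colnames(table$values), colnames(table$values)),
               function(v) tukey_kramer(table$values[, v], sol$labels,
                                        alpha))
  structure(
    list(D2 = D2, F = pf_$F, p_values = pf_$p_values,
         F_average = pf_$F_average, D2_average = pf_$D2_average,
         df = pf_$df, wilks = wk, tukey = tk, sizes = sizes, k = sol$k),
    class = "cluster_evaluation")
}

#' @export
print.cluster_evaluation <- function(x, ...) {
  cat(sprintf("<cluster_evaluation: k=%d, F df=(%d,%d), average F=%.2f, average D2=%.2f>\n",
              x$k, x$df[1], x$df[2], x$F_average, x$D2_average))
  invisible(x)
}

#' Compare clustering strategies over a range of k
#'
#' Builds the three candidate feature sets and picks the best Ward
#' solution. The factor analysis runs on the full parameter table (factors
#' bundle correlated parameters, so it is a parallel dimensionality
#' reduction, not a downstream step of the correlation filter), while the
#' top-multimodality strategy draws from the correlation-filtered retained
#' list:
#' \describe{
#'   \item{factor_scores}{regression scores of the retained factors.}
#'   \item{top_mmi_params}{the `m` highest-multimodality parameters among
#'     `retained`, `m` = number of retained factors.}
#'   \item{factor_loading_params}{the single best (max-MMI) parameter
#'     loading each retained factor.}
#' }
#' Every feature set is clustered with Ward over `k_range`, each solution
#' is evaluated, and the declared winner is the (strategy, k) with the
#' highest average pairwise F.
#'
#' @param table normalized [feature_table()] holding all measured
#'   parameters.
#' @param mmi named multimodality indices for the parameters in `table`
#'   (computed if missing).
#' @param retained parameter subset eligible for `top_mmi_params`
#'   (typically `correlation_filter(...)$retained`; default all).
#' @param k_range candidate cluster counts (default `2:7`).
#' @param strategies subset of
#'   `c("factor_scores", "top_mmi_params", "factor_loading_params")`.
#' @param explvar_min,loading_min thresholds for
#'   [select_factors_and_parameters()].
#' @param n_factors forwarded to [principal_axis_factoring()].
#' @param alpha forwarded to [evaluate_clusters()].
#' @return object of class `strategy_comparison`: `report` (data.frame
#'   strategy/k/F_average/D2_average), `winner` (strategy, k, solution,
#'   evaluation, features), `factor_model`, `factor_selection`.
#' @export
compare_strategies <- function(table, mmi = NULL, retained = NULL,
                               k_range = 2:7,
                               strategies = c("factor_scores",
                                              "top_mmi_params",
                                              "factor_loading_params"),
                               explvar_min = 3, loading_min = 0.70,
                               n_factors = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$normalized) stop("compare_strategies expects a z-scored table")
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (is.null(mmi)) mmi <- apply(table$values, 2, multimodality_index)
  if (is.null(retained)) retained <- table$parameter_names

  model <- tryCatch(
    principal_axis_factoring(cor(table$values), n_factors = n_factors),
    cytofractal_nonconvergence = function(cond) {
      # exactly collinear parameter pairs can leave one communality
      # direction indeterminate; the last iterate is a valid model there
      warning(conditionMessage(cond), "; using last iterate")
      cond$model
    })
  model <- varimax_rotate(model)
  selection <- select_factors_and_parameters(model, mmi, explvar_min,
                                             loading_min)
  m <- length(selection$retained_factors)

  feature_sets <- list()
  if ("factor_scores" %in% strategies) {
    sc <- factor_scores(model, table, selection$retained_factors)
    feature_sets$factor_scores <-
      zscore(feature_table(sc, cell_ids = table$cell_ids))
  }
  if ("top_mmi_params" %in% strategies) {
    mr <- mmi[retained]
    top <- names(sort(mr, decreasing = TRUE))[seq_len(min(m, length(mr)))]
    feature_sets$top_mmi_params <- subset_features(table, top)
  }
  if ("factor_loading_params" %in% strategies) {
    feature_sets$factor_loading_params <-
      subset_features(table, unname(selection$chosen))
  }

  rows <- list()
  best <- NULL
  for (snm in names(feature_sets)) {
    ft <- feature_sets[[snm]]
    if (ncol(ft$values) < 2) {
      warning("strategy ", snm, " yields < 2 features; skipped")
      next
    }
    for (k in k_range) {
      sol <- ward_cluster(ft, k)
      ev <- tryCatch(evaluate_clusters(ft, sol, alpha),
                     error = function(e) NULL)
      if (is.null(ev)) next
      rows[[length(rows) + 1]] <- data.frame(
        strategy = snm, k = k, F_average = ev$F_average,
        D2_average = ev$D2_average, stringsAsFactors = FALSE)
      if (is.null(best) || ev$F_average > best$evaluation$F_average)
        best <- list(strategy = snm, k = k, solution = sol,
                     evaluation = ev, features = ft)
    }
  }
  if (is.null(best)) stop("no evaluable cluster solution")
  report <- do.call(rbind, rows)
  report <- report[order(-report$F_average), ]
  rownames(report) <- NULL
  structure(list(report = report, winner = best, factor_model = model,
                 factor_selection = selection),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison: winner %s, k=%d (average F %.2f)>\n",
              x$winner$strategy, x$winner$k,
              x$winner$evaluation$F_average))
  print(head(x$report, 8))
  invisible(x)
}
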