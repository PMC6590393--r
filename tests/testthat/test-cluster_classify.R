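two_cloud_table <- function(n = 50, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n, 0, sd), rnorm(n, 0, sd)),
             cbind(rnorm(n, 10, sd), rnorm(n, 10, sd)))
  colnames(X) <- c("u", "v")
  zscore(feature_table(X))
}

test_that("Ward clustering separates well-separated clouds and is exact on toys", {
  tab <- two_cloud_table()
  sol <- ward_cluster(tab, 2)
  truth <- rep(1:2, each = 50)
  expect_gte(abs(adjusted_rand_index(truth, sol$labels)), 1 - 1e-12)
  expect_true(all(diff(sol$linkage_record$height) >= -1e-9))

  # five points with a hand-checkable merge order vs the brute-force
  # minimum-variance oracle
  X <- cbind(c(0, 0.4, 5, 5.3, 12), c(0, 0, 0, 0, 0.2))
  colnames(X) <- c("x", "y")
  hc <- hclust(dist(X), method = "ward.D2")
  brute <- brute_ward_merges(X)
  # member sets at each merge must coincide
  memb <- function(merge, step) {
    grab <- function(i) if (i < 0) -i else memb(merge, i)
    sort(c(grab(merge[step, 1]), grab(merge[step, 2])))
  }
  for (s in seq_len(nrow(hc$merge)))
    expect_equal(memb(hc$merge, s), brute[[s]]$members)
  # heights carry the merge cost: h = sqrt(2 * delta SS)
  expect_equal(hc$height, sqrt(2 * vapply(brute, `[[`, 0, "dss")),
               tolerance = 1e-9)

  # duplicated rows co-cluster at height zero
  Xd <- rbind(X, X)
  rownames(Xd) <- NULL
  hcd <- hclust(dist(Xd), method = "ward.D2")
  expect_equal(sort(hcd$height)[1:5], rep(0, 5), tolerance = 1e-12)

  expect_error(ward_cluster(tab, 60), "k out of range")
})

test_that("Mahalanobis distances agree with direct quadratic forms", {
  tab <- two_cloud_table(n = 30, sd = 1, seed = 4)
  sol <- ward_cluster(tab, 2)
  D2 <- mahalanobis_matrix(tab, sol)
  expect_equal(diag(D2), c(0, 0))
  expect_equal(D2[1, 2], D2[2, 1])

  # independent evaluation via explicit inverse
  X <- tab$values
  g <- sol$labels
  c1 <- colMeans(X[g == 1, ]); c2 <- colMeans(X[g == 2, ])
  W <- crossprod(sweep(X[g == 1, ], 2, c1)) +
    crossprod(sweep(X[g == 2, ], 2, c2))
  S <- W / (nrow(X) - 2)
  ref <- drop(t(c1 - c2) %*% solve(S) %*% (c1 - c2))
  expect_equal(D2[1, 2], ref, tolerance = 1e-9)

  # identical centroids give zero distance
  set.seed(8)
  Xe <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
  tabe <- zscore(feature_table(Xe))
  sole <- structure(list(k = 2L, labels = setNames(rep(1:2, 30),
                                                   tabe$cell_ids),
                         feature_names = c("a", "b")),
                    class = "cluster_solution")
  Xe[seq(2, 60, 2), ] <- Xe[seq(1, 59, 2), ]   # force equal centroids
  tab0 <- feature_table(Xe, normalized = TRUE)
  D0 <- mahalanobis_matrix(tab0, sole)
  expect_equal(D0[1, 2], 0, tolerance = 1e-12)
})

test_that("pairwise F reproduces the printed degrees of freedom and Hotelling", {
  # design of the larger study: n = 628, k = 3, p = 4 -> denominator 622
  D2 <- matrix(c(0, 15, 13, 15, 0, 7, 13, 7, 0), 3, 3)
  pf_ <- pairwise_cluster_F(D2, sizes = c(210, 209, 209), p = 4)
  expect_equal(pf_$df, c(4, 622))
  expect_equal(pf_$F_average, mean(pf_$F[upper.tri(pf_$F)]))

  # zero distance -> F 0, p-value 1
  pf0 <- pairwise_cluster_F(matrix(0, 2, 2), sizes = c(20, 20), p = 2)
  expect_equal(pf0$F[1, 2], 0)
  expect_equal(pf0$p_values[1, 2], 1)

  # two-cluster F equals Hotelling's T2 via an independent manova fit
  set.seed(12)
  X <- rbind(matrix(rnorm(40 * 3), 40, 3),
             sweep(matrix(rnorm(35 * 3), 35, 3), 2, c(1, 0.5, -0.7), `+`))
  colnames(X) <- c("a", "b", "c")
  g <- factor(rep(1:2, c(40, 35)))
  tab <- feature_table(X, normalized = TRUE)
  sol <- structure(list(k = 2L, labels = setNames(as.integer(g),
                                                  tab$cell_ids),
                        feature_names = colnames(X)),
                   class = "cluster_solution")
  D2x <- mahalanobis_matrix(tab, sol)
  Fx <- pairwise_cluster_F(D2x, sizes = c(40, 35), p = 3)
  hl <- summary(manova(X ~ g), test = "Hotelling-Lawley")$stats
  T2 <- hl[1, "Hotelling-Lawley"] * (75 - 2)
  Fref <- T2 * (75 - 3 - 1) / (3 * (75 - 2))
  expect_equal(Fx$F[1, 2], unname(Fref), tolerance = 1e-9)

  expect_error(pairwise_cluster_F(matrix(0, 3, 3), sizes = c(2, 2, 2), p = 5),
               "positive")
})

test_that("Wilks statistics match determinant-ratio and manova oracles", {
  set.seed(31)
  X <- rbind(matrix(rnorm(10 * 2), 10, 2),
             sweep(matrix(rnorm(10 * 2), 10, 2), 2, c(2, 0), `+`),
             sweep(matrix(rnorm(10 * 2), 10, 2), 2, c(0, 2.5), `+`))
  colnames(X) <- c("a", "b")
  tab <- feature_table(X, normalized = TRUE)
  labels <- rep(1:3, each = 10)
  sol <- structure(list(k = 3L, labels = setNames(labels, tab$cell_ids),
                        feature_names = colnames(X)),
                   class = "cluster_solution")
  wk <- wilks_statistics(tab, sol)

  g <- factor(labels)
  lam_manova <- summary(manova(X ~ g), test = "Wilks")$stats[1, "Wilks"]
  expect_equal(wk$lambda, unname(lam_manova), tolerance = 1e-9)
  # per-variable lambdas from a from-scratch SSCP assembly
  lam_of <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    Tm <- crossprod(sweep(Xs, 2, colMeans(Xs)))
    W <- Reduce(`+`, lapply(1:3, function(gg) {
      Xg <- Xs[labels == gg, , drop = FALSE]
      crossprod(sweep(Xg, 2, colMeans(Xg)))
    }))
    det(W) / det(Tm)
  }
  for (j in 1:2) {
    lam_wo <- lam_of(setdiff(1:2, j))
    expect_equal(wk$per_variable$lambda_without[j], lam_wo,
                 tolerance = 1e-9)
    partial <- lam_of(1:2) / lam_wo
    Fref <- ((30 - 3 - 2 + 1) / (3 - 1)) * (1 - partial) / partial
    expect_equal(wk$per_variable$F_remove[j], Fref, tolerance = 1e-9)
  }

  # a pure-noise variable has no discriminating power, a label-aligned one
  # dominates
  set.seed(32)
  X2 <- cbind(signal = labels + rnorm(30, sd = 0.05), noise = rnorm(30))
  tab2 <- feature_table(X2, normalized = TRUE)
  sol2 <- sol
  sol2$feature_names <- colnames(X2)
  wk2 <- wilks_statistics(tab2, sol2)
  pv <- wk2$per_variable
  expect_gt(pv$partial_lambda[pv$variable == "noise"], 0.5)
  expect_lt(pv$partial_lambda[pv$variable == "signal"], 0.1)
  expect_gt(pv$F_remove[pv$variable == "signal"],
            50 * pv$F_remove[pv$variable == "noise"])
})

test_that("Tukey-Kramer controls the null, flags real shifts, and reduces to a t-test", {
  # 10-sigma separated groups: every pair significant
  set.seed(41)
  v <- c(rnorm(30, 0), rnorm(30, 10), rnorm(30, 20))
  g <- rep(1:3, each = 30)
  tk <- tukey_kramer(v, g)
  expect_equal(nrow(tk$significant), 3L)

  # k = 2 equals the pooled two-sample t-test
  set.seed(42)
  v2 <- c(rnorm(20), rnorm(25, 0.6))
  g2 <- rep(1:2, c(20, 25))
  tk2 <- tukey_kramer(v2, g2)
  tt <- t.test(v2[g2 == 1], v2[g2 == 2], var.equal = TRUE)
  expect_equal(tk2$pairs$p_adj, tt$p.value, tolerance = 1e-6)

  # null calibration: three equal groups rarely yield any significant pair
  set.seed(43)
  hits <- vapply(1:100, function(i) {
    vv <- rnorm(60)
    nrow(tukey_kramer(vv, rep(1:3, each = 20))$significant) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.10)

  expect_error(tukey_kramer(rep(1, 10), rep(1:2, 5)), "zero within")
})

test_that("evaluation is equivariant under relabeling and duplication", {
  tab <- two_cloud_table(n = 25, sd = 1.2, seed = 6)
  sol <- ward_cluster(tab, 2)
  ev <- evaluate_clusters(tab, sol)

  # relabel clusters: D2 and F matrices permute accordingly
  sol2 <- sol
  sol2$labels <- 3L - sol$labels
  ev2 <- evaluate_clusters(tab, sol2)
  expect_equal(ev$D2[1, 2], ev2$D2[2, 1], tolerance = 1e-12)
  expect_equal(ev$F_average, ev2$F_average, tolerance = 1e-12)

  # duplicating every point leaves D2 unchanged and raises F
  tabd <- feature_table(rbind(tab$values, tab$values), normalized = TRUE)
  sold <- structure(list(k = 2L,
                         labels = setNames(rep(sol$labels, 2), tabd$cell_ids),
                         feature_names = sol$feature_names),
                    class = "cluster_solution")
  evd <- evaluate_clusters(tabd, sold)
  expect_equal(evd$D2[1, 2], ev$D2[1, 2], tolerance = 0.05)
  expect_gt(evd$F_average, ev$F_average)
})

test_that("strategy comparison recovers the planted three-type structure", {
  ppl <- shared_population()
  tab <- zscore(ppl$features)
  sel <- correlation_filter(tab)
  cmp <- suppressWarnings(suppressMessages(
    compare_strategies(tab, mmi = sel$mmi, retained = sel$retained,
                       k_range = 2:5, n_factors = 5)))
  expect_s3_class(cmp, "strategy_comparison")
  expect_true(all(c("strategy", "k", "F_average", "D2_average") %in%
                    colnames(cmp$report)))
  expect_equal(cmp$report$F_average, sort(cmp$report$F_average,
                                          decreasing = TRUE))
  # winner reproducibly the maximum of its own report
  expect_equal(cmp$winner$evaluation$F_average, max(cmp$report$F_average))
  # same input, same result
  cmp2 <- suppressWarnings(suppressMessages(
    compare_strategies(tab, mmi = sel$mmi, retained = sel$retained,
                       k_range = 2:5, n_factors = 5)))
  expect_equal(cmp$report, cmp2$report)
})
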