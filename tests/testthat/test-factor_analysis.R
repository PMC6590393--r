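named_corr <- function(m, names) {
  dimnames(m) <- list(names, names)
  m
}

test_that("principal-axis factoring recovers planted structures", {
  # identity correlation: no shared variance anywhere
  id <- named_corr(diag(5), paste0("p", 1:5))
  m0 <- principal_axis_factoring(id, n_factors = 2)
  expect_lt(max(m0$communalities), 1e-6)
  expect_lt(max(m0$explained_variance), 1e-6)

  # one-factor model corr_ij = lambda_i lambda_j
  lam <- c(0.9, 0.8, 0.7, 0.6)
  R1 <- outer(lam, lam)
  diag(R1) <- 1
  m1 <- principal_axis_factoring(named_corr(R1, paste0("v", 1:4)),
                                 n_factors = 1)
  expect_equal(unname(abs(m1$loadings[, 1])), lam, tolerance = 0.01)

  # block-diagonal two-factor structure
  l2 <- c(0.85, 0.8, 0.75)
  B <- outer(l2, l2); diag(B) <- 1
  R2 <- named_corr(rbind(cbind(B, matrix(0, 3, 3)),
                         cbind(matrix(0, 3, 3), B)), paste0("w", 1:6))
  m2 <- varimax_rotate(principal_axis_factoring(R2, n_factors = 2))
  L <- abs(m2$loadings)
  blk1 <- apply(L[1:3, ], 1, which.max)
  blk2 <- apply(L[4:6, ], 1, which.max)
  expect_true(all(blk1 == blk1[1]))
  expect_true(all(blk2 == blk2[1]))
  expect_true(blk1[1] != blk2[1])
  expect_true(all(apply(L, 1, max) >= 0.7))

  # reconstruction of the off-diagonal
  rec <- m2$loadings %*% t(m2$loadings)
  expect_lt(max(abs((rec - R2)[upper.tri(R2)])), 0.02)
})

test_that("raw varimax preserves communalities and maximises its criterion", {
  set.seed(21)
  L0 <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("x", 1:6), NULL))
  model <- structure(list(loadings = L0, explained_variance = colSums(L0^2),
                          communalities = rowSums(L0^2), n_factors = 2L,
                          rotation = "none", corr = diag(6)),
                     class = "factor_model")
  rot <- varimax_rotate(model)
  expect_equal(rowSums(rot$loadings^2), rowSums(L0^2), tolerance = 1e-9)
  expect_equal(t(rot$rotmat) %*% rot$rotmat, diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)

  crit <- cytofractal:::varimax_criterion
  ours <- crit(rot$loadings)
  set.seed(22)
  beaten <- sum(vapply(1:1000, function(i) {
    a <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    crit(L0 %*% Rm) > ours + 1e-9
  }, TRUE))
  expect_equal(beaten, 0)

  # already perfectly simple loadings stay put up to sign/permutation
  Ls <- matrix(0, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  Ls[1:2, 1] <- c(0.9, 0.8); Ls[3:4, 2] <- c(0.85, 0.7)
  ms <- structure(list(loadings = Ls, explained_variance = colSums(Ls^2),
                       communalities = rowSums(Ls^2), n_factors = 2L,
                       rotation = "none", corr = diag(4)),
                  class = "factor_model")
  rs <- varimax_rotate(ms)
  expect_equal(abs(rs$loadings), abs(Ls), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("factor retention applies both thresholds and the MMI choice", {
  L <- matrix(0, 6, 3, dimnames = list(LETTERS[1:6], paste0("Factor", 1:3)))
  L[1:2, 1] <- c(0.9, 0.85)
  L[3:4, 2] <- c(0.88, 0.8)
  L[5:6, 3] <- c(0.6, 0.5)        # nothing loads factor 3 at 0.7
  model <- structure(list(loadings = L,
                          explained_variance = c(4, 3.5, 1),
                          communalities = rowSums(L^2), n_factors = 3L,
                          rotation = "varimax_raw", corr = diag(6)),
                     class = "factor_model")
  mmi <- c(A = 0.6, B = 0.7, C = 0.5, D = 0.65, E = 0.4, F = 0.3)
  sel <- select_factors_and_parameters(model, mmi)
  expect_equal(sel$retained_factors, c("Factor1", "Factor2"))
  expect_equal(unname(sel$chosen), c("B", "D"))

  # a parameter loading two retained factors goes to its max-|loading|
  # factor and the vacated one falls to the next-best MMI loader
  L2 <- L
  L2[1, 2] <- 0.95               # A loads both factors, stronger on 2
  model2 <- model
  model2$loadings <- L2
  mmi2 <- c(A = 0.9, B = 0.7, C = 0.5, D = 0.65, E = 0.4, F = 0.3)
  sel2 <- select_factors_and_parameters(model2, mmi2)
  expect_equal(unname(sel2$chosen["Factor2"]), "A")
  expect_equal(unname(sel2$chosen["Factor1"]), "B")

  expect_error(select_factors_and_parameters(model, mmi, explvar_min = 10),
               "no factors retained")
})

test_that("selection is deterministic given model and indices", {
  ppl <- shared_population()
  tab <- zscore(ppl$features)
  mmi <- apply(tab$values, 2, multimodality_index)
  m <- suppressWarnings(suppressMessages(
    varimax_rotate(principal_axis_factoring(cor(tab$values), n_factors = 5))))
  s1 <- select_factors_and_parameters(m, mmi)
  s2 <- select_factors_and_parameters(m, mmi)
  expect_identical(s1, s2)
})
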