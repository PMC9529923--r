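test_that("least squares is exact algebra in the noise-free full-rank case", {
  # 2-gene hand case
  A <- matrix(c(-1, 1, 0, -1), 2, 2)
  P <- as_perturbation_design(diag(-1, 2))
  Y <- steady_state_response(grn_network(A), P)
  fit <- grn_infer(Y, P, method = "ls")
  expect_equal(unname(coef(fit)), A, tolerance = 1e-12)
  # replicated 100x300 noise-free system: recovery to 1e-8, AUPR exactly 1
  sys <- toy_system(n = 100, seed = 10)
  fit100 <- grn_infer(sys$X, sys$P, method = "ls")
  expect_lt(max(abs(coef(fit100) - unclass(sys$net))), 1e-8)
  expect_equal(grn_evaluate(fit100, sys$net)$aupr, 1.0)
  expect_error(grn_infer(matrix(0, 2, 2), as_perturbation_design(diag(-1, 2)), method = "ls"),
               "zero")
})

test_that("ridge closed form matches an independent glmnet fit at a converging penalty", {
  sys <- toy_system(n = 15, seed = 11, snr = 1)
  lam <- 0.05
  fit <- grn_infer(sys$Y, sys$P, method = "ridge", penalties = c(lam, 0.5))
  co <- fit$coefficients[, , 1]  # smallest penalty first
  X <- t(sys$Y)
  for (i in c(1, 7, 15)) {
    g <- glmnet::glmnet(X, -unclass(sys$P)[i, ], alpha = 0, lambda = c(1, 0.2, lam),
                        intercept = FALSE, standardize = FALSE, thresh = 1e-14)
    b <- as.numeric(glmnet::coef.glmnet(g, s = lam, exact = TRUE, x = X,
                                        y = -unclass(sys$P)[i, ], thresh = 1e-14))[-1]
    expect_equal(unname(co[i, ]), b, tolerance = 1e-6)
  }
  # and the documented closed form -P Y^T (Y Y^T + (M lam / s) I)^{-1}
  s_y <- sqrt(mean(unclass(sys$P)[1, ]^2))
  closed <- -unclass(sys$P) %*% t(sys$Y) %*%
    solve(sys$Y %*% t(sys$Y) + ncol(sys$Y) * lam / s_y * diag(15))
  expect_equal(co, closed, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("penalty sweeps run dense to empty and recover the support without noise", {
  sys <- toy_system(n = 40, seed = 12)
  for (m in c("lasso", "elnet")) {
    fit <- grn_infer(sys$X, sys$P, method = m)
    sizes <- vapply(fit$sweep, sum, integer(1))
    # densest network at the smallest penalty, empty network at the largest
    expect_equal(sizes[length(sizes)], 0L)
    expect_gt(sizes[1], sum(unclass(sys$net) != 0) * 0.9)
    expect_true(all(sort(fit$penalties) == fit$penalties))
  }
  # noise-free support recovery: every penalized sweep contains a network
  # that nearly reproduces the true support (elastic-net grouping spreads a
  # little weight over correlated predictors in small systems, so the bound
  # is looser here than at study scale)
  for (s in 1:5) {
    sys <- toy_system(n = 40, seed = 100 + s)
    for (m in c("lasso", "elnet", "ridge")) {
      ev <- grn_evaluate(grn_infer(sys$X, sys$P, method = m), sys$net)
      expect_gte(ev$max_f1, 0.95)
    }
  }
  expect_error(grn_infer(toy_system(5)$X, toy_system(5)$P, method = "lasso",
                         mixing_alpha = 1.5), "mixing_alpha")
})

test_that("z-scores agree with direct two-pass mean/sd arithmetic on a toy case", {
  # 3 genes, 2 replicates; compute the expected score for edge 1 -> 2 by hand
  Y <- rbind(c(-1.0, -1.2, 0.3, 0.1, 0.2, -0.1),
             c(-0.9, -1.1, 0.1, -0.1, 0.0, 0.2),
             c(0.3, 0.1, -0.2, 0.0, -1.1, -0.9))
  P <- perturbation_design(3, replicates = 2)
  fit <- grn_infer(Y, P, method = "zscore")
  means <- sapply(1:3, function(j) rowMeans(Y[, (2 * j - 1):(2 * j)]))
  x <- means[2, ]                       # gene 2 across the 3 targets
  z_hand <- abs((x[1] - mean(x[-1])) / sd(x[-1]))
  expect_equal(fit$weights[2, 1], z_hand, ignore_attr = TRUE)
  # column order invariance
  perm <- c(3, 6, 1, 4, 2, 5)
  fit_perm <- grn_infer(Y[, perm], unclass(P)[, perm], method = "zscore")
  expect_equal(unname(fit_perm$weights), unname(fit$weights))
})

test_that("a constant gene gets zero incoming scores and a warning", {
  sys <- toy_system(n = 6, seed = 14, snr = 1)
  Y <- sys$Y; Y[4, ] <- 2
  expect_warning(fit <- grn_infer(Y, sys$P, method = "zscore"), "standard deviation")
  expect_true(all(fit$weights[4, ] == 0))
})

test_that("scrambling the design sends every P-based method to the random baseline", {
  auprs <- sapply(1:10, function(s) {
    sys <- toy_system(n = 30, seed = 200 + s, snr = 1)
    Ps <- scramble_design(sys$P, seed = s)
    sapply(c("ls", "lasso", "ridge", "zscore"), function(m)
      grn_evaluate(grn_infer(sys$Y, Ps, method = m), sys$net)$aupr)
  })
  prevalence <- mean(sapply(1:10, function(s) {
    A <- unclass(toy_system(n = 30, seed = 200 + s)$net); mean(A != 0)
  }))
  expect_true(all(rowMeans(auprs) < 2 * prevalence))
})

test_that("P-based accuracy is non-decreasing from high to low noise", {
  methods <- c("ls", "lasso", "elnet", "ridge", "zscore")
  mean_aupr <- matrix(0, length(methods), 3, dimnames = list(methods, NULL))
  for (s in 1:5) {
    sys <- toy_system(n = 40, seed = 300 + s)
    for (k in 1:3) {
      snr <- c(0.01, 0.1, 1)[k]
      Y <- add_noise(sys$X, snr = snr, seed = 400 + s)
      for (m in methods)
        mean_aupr[m, k] <- mean_aupr[m, k] +
          grn_evaluate(grn_infer(Y, sys$P, method = m), sys$net)$aupr / 5
    }
  }
  for (m in methods) expect_true(all(diff(mean_aupr[m, ]) > -0.02), label = m)
})
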