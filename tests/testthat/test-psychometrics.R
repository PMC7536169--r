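test_that("alpha is 1 for identical items and ~0 for independent ones", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  set.seed(2)
  y <- matrix(rnorm(2 * 10000), ncol = 2)
  expect_lt(abs(cronbach_alpha(y)), 0.05)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), "at least")
})

test_that("alpha matches the brute-force formula on a fixed covariance", {
  # 3 items, unit variances, all covariances 0.5:
  # alpha = (3/2) * (1 - 3/6) = 0.75
  Sigma <- matrix(0.5, 3, 3); diag(Sigma) <- 1
  X <- exact_mvn(200, Sigma, seed = 3)
  expect_equal(cronbach_alpha(X), 0.75, tolerance = 1e-10)
  # brute-force oracle: k/(k-1) (1 - sum diag(S)/sum(S))
  S <- var(X)
  expect_equal(cronbach_alpha(X),
               3 / 2 * (1 - sum(diag(S)) / sum(S)), tolerance = 1e-12)
})

test_that("omega equals alpha under exact tau-equivalence", {
  Sigma <- matrix(0.5, 3, 3); diag(Sigma) <- 1
  X <- exact_mvn(200, Sigma, seed = 4)
  expect_equal(omega_total(X), cronbach_alpha(X), tolerance = 1e-6)
})

test_that("omega and alpha diverge when a weak item breaks tau-equivalence", {
  # congeneric: loadings (0.9, 0.9, 0.9, 0.1); omega should exceed alpha
  lam <- c(0.9, 0.9, 0.9, 0.1)
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  X <- exact_mvn(300, Sigma, seed = 5)
  a <- cronbach_alpha(X)
  o <- omega_total(X)
  expect_gt(o, a)
  expect_gt(o - a, 0.01)
})

test_that("omega approaches 1 for near-noiseless unidimensional data", {
  lam <- rep(0.999, 4)
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  X <- exact_mvn(100, Sigma, seed = 6)
  expect_equal(suppressWarnings(omega_total(X)), 1, tolerance = 1e-2)
})

test_that("ICC(A,1) is 1 on identical pairs and penalizes constant shifts", {
  set.seed(7)
  x <- rnorm(25)
  same <- icc_absolute(x, x)
  expect_equal(same$icc, 1, tolerance = 1e-12)
  expect_equal(same$df, 24)
  shifted <- icc_absolute(x, x + 1)
  expect_lt(shifted$icc, 1)
  # consistency-type correlation would still be 1; absolute agreement is not
  expect_equal(cor(x, x + 1), 1)
  expect_error(icc_absolute(rep(1, 10), rep(1, 10)), "between-subject")
  expect_error(icc_absolute(1:2, 1:2), "at least 3")
})

test_that("ICC(A,1) recovers the variance-component ratio", {
  # y_ij = s_i + e_ij, var(s) = 1, var(e) = 0.25 -> ICC = 1/1.25 = 0.8
  set.seed(8)
  iccs <- replicate(200, {
    s <- rnorm(25, 0, 1)
    icc_absolute(s + rnorm(25, 0, 0.5), s + rnorm(25, 0, 0.5))$icc
  })
  expect_equal(mean(iccs), 0.8, tolerance = 0.05)
})

test_that("Bartlett's test matches its closed form and the identity case", {
  ident <- bartlett(diag(6), 100)
  expect_equal(ident$chi2, 0)
  expect_equal(ident$df, 15)
  expect_equal(ident$p_value, 1)
  # 3 variables, all off-diagonal 0.5, n = 100:
  # det R = (1 - 0.5)^2 (1 + 2*0.5) = 0.5
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  got <- bartlett(R, 100)
  expect_equal(got$chi2, -(100 - 1 - 11 / 6) * log(0.5), tolerance = 1e-12)
  expect_equal(got$df, 3)
})

test_that("KMO is high for factor-driven data and low for near-independence", {
  lam <- rep(0.8, 6)
  R <- tcrossprod(lam); diag(R) <- 1
  expect_gt(kmo(R), 0.8)
  set.seed(9)
  X <- matrix(rnorm(6 * 200), 200, 6)
  expect_lt(kmo(cor(X)), 0.65)
  expect_true(kmo(cor(X)) >= 0 && kmo(cor(X)) <= 1)
})

test_that("minres EFA recovers a one-factor structure", {
  lam <- rep(0.8, 6)
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  set.seed(10)
  X <- exact_mvn(5000, Sigma, seed = 10)
  fit <- efa_minres(X, n_factors = 1, seed = 11)
  expect_true(all(abs(fit$loadings[, 1] - 0.8) < 0.05))
  expect_equal(fit$n_factors_kaiser, 1)
  expect_equal(fit$n_factors_parallel, 1)
  expect_equal(fit$variance_explained, 0.64, tolerance = 0.05)
})

test_that("minres residual gradient vanishes at the solution", {
  lam <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  X <- exact_mvn(1000, Sigma, seed = 12)
  R <- cor(X)
  fit <- efa_minres(X, n_factors = 1, seed = 13)
  L <- fit$loadings[, 1]
  resid <- R - tcrossprod(L); diag(resid) <- 0
  # d/dL_i of sum_{j != i} (r_ij - L_i L_j)^2 = -4 sum_j resid_ij L_j
  grad <- -4 * resid %*% L
  expect_lt(max(abs(grad)), 1e-3)
})

test_that("an orthogonal two-factor structure is recovered with clean loadings", {
  lam <- cbind(c(0.8, 0.8, 0.8, 0, 0, 0), c(0, 0, 0, 0.8, 0.8, 0.8))
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  X <- exact_mvn(2000, Sigma, seed = 14)
  fit <- efa_minres(X, seed = 15)
  expect_equal(fit$n_factors, 2)
  expect_equal(fit$n_factors_parallel, 2)
  primary <- apply(abs(fit$loadings), 1, max)
  cross <- apply(abs(fit$loadings), 1, min)
  expect_true(all(primary > 0.7))
  expect_true(all(cross < 0.2))
})

test_that("minres loadings agree with an independent ML factor fit", {
  lam <- c(0.9, 0.75, 0.6, 0.8, 0.7)
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  X <- exact_mvn(2000, Sigma, seed = 21)
  ours <- efa_minres(X, n_factors = 1, seed = 22)$loadings[, 1]
  ml <- as.numeric(stats::factanal(X, factors = 1)$loadings)
  if (sum(ml) < 0) ml <- -ml
  expect_true(all(abs(ours - ml) < 0.05))
})

test_that("efa_minres accepts a correlation matrix with explicit n_obs", {
  lam <- rep(0.7, 6)
  R <- tcrossprod(lam); diag(R) <- 1
  fit <- efa_minres(R, n_factors = 1, n_obs = 200, seed = 16)
  expect_true(all(abs(fit$loadings[, 1] - 0.7) < 0.01))
  expect_error(efa_minres(R, n_factors = 1), "n_obs")
})

test_that("BH step-up reproduces the hand-worked example and edge cases", {
  # p = (0.01, 0.02, 0.03, 0.04), m = 4, q = 0.05: largest i with
  # p_(i) <= i q / m is i = 4 (0.04 <= 0.05), so all four are significant
  expect_equal(bh_flags(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  # step-up rescues p-values above their own threshold:
  # 0.013 > 0.0125 alone, but i = 4 still passes
  expect_equal(bh_flags(c(0.013, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_flags(c(0.001, 0.2, 0.5, 0.9), 0.05),
               c(TRUE, FALSE, FALSE, FALSE))
  # independent manual step-up oracle on random p-values
  set.seed(17)
  p <- runif(20)^2
  manual <- {
    ord <- order(p)
    ok <- p[ord] <= seq_along(p) * 0.05 / length(p)
    cut <- if (any(ok)) max(which(ok)) else 0
    flags <- logical(length(p))
    if (cut > 0) flags[ord[seq_len(cut)]] <- TRUE
    flags
  }
  expect_equal(bh_flags(p, 0.05), manual)
})

test_that("spearman_bh reports rank correlations with one BH family", {
  set.seed(18)
  x <- rnorm(200)
  df <- data.frame(a = x, b = exp(2 * x), c = rnorm(200), d = rnorm(200))
  rep_ <- spearman_bh(df)
  expect_equal(nrow(rep_), choose(4, 2))
  ab <- rep_[rep_$var1 == "a" & rep_$var2 == "b", ]
  expect_equal(ab$rho, 1, tolerance = 1e-12)  # monotone transform
  expect_true(ab$significant)
  expect_equal(rep_$p_adjusted, p.adjust(rep_$p_value, "BH"))
  # adjusted flags monotone in raw p within the family
  ord <- order(rep_$p_value)
  expect_true(all(diff(rep_$significant[ord]) <= 0))
})

test_that("independent columns show near-zero rho; constant columns are excluded", {
  set.seed(19)
  big <- data.frame(x = rnorm(10000), y = rnorm(10000))
  expect_lt(abs(spearman_bh(big)$rho[1]), 0.05)
  df <- data.frame(a = rnorm(50), b = rnorm(50), k = rep(2, 50))
  rep_ <- spearman_bh(df)
  expect_equal(attr(rep_, "excluded"), "k")
  expect_equal(nrow(rep_), 1)
})

test_that("retest_reliability bundles ICC with both correlations", {
  set.seed(20)
  x <- rnorm(25)
  y <- 0.8 * x + rnorm(25, 0, 0.5)
  rr <- retest_reliability(x, y)
  expect_equal(rr$pearson_r, cor(x, y))
  expect_equal(rr$spearman_rho, cor(x, y, method = "spearman"))
  expect_equal(rr$icc$df, 24)
  expect_lt(rr$icc$icc, 1)
})
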