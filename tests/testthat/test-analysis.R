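# Deflation PCA against the eigendecomposition oracle, and hyperplane
# fits including recovery of a known generating plane.

test_that("rank-1 data yields a single axis explaining all variance", {
  set.seed(1)
  t_scores <- rnorm(20)
  x <- cbind(a = 2 * t_scores, b = -t_scores, c = 0.5 * t_scores)
  x <- sweep(x, 2, c(1, 1, 1), "+")
  p <- sf_pca(x)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-10)
  dir <- c(2, -1, 0.5) / sqrt(sum(c(2, -1, 0.5)^2))
  expect_equal(abs(sum(p$loadings[, 1] * dir)), 1, tolerance = 1e-8)
})

test_that("deflation loadings match covariance eigenvectors up to sign", {
  for (seed in c(2, 9, 31)) {
    set.seed(seed)
    x <- matrix(rnorm(20 * 6), 20, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
    colnames(x) <- letters[1:6]
    p <- sf_pca(x)
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    for (k in 1:6) {
      expect_equal(abs(sum(p$loadings[, k] * ev$vectors[, k])), 1,
                   tolerance = 1e-6, info = paste("seed", seed, "PC", k))
    }
    # variances match eigenvalues
    expect_equal(p$sdev^2, ev$values, tolerance = 1e-8)
  }
})

test_that("loadings are orthonormal and reconstruct the centered data", {
  set.seed(5)
  x <- matrix(rnorm(40 * 4), 40, 4)
  p <- sf_pca(x)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude entry of each loading is positive
  for (k in 1:4) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
})

test_that("constant ensembles are rejected as degenerate", {
  x <- matrix(1, 10, 3)
  expect_error(sf_pca(x), "degenerate")
})

test_that("points exactly on a plane are fitted with R^2 = 1", {
  set.seed(7)
  a <- runif(25); b <- runif(25)
  pts <- data.frame(a = a, b = b, c = (1 - 0.5 * a - 0.3 * b))
  fit <- fit_plane(pts, method = "tls")
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # recovered normalized coefficients proportional to (0.5, 0.3, 1)
  aa <- fit$coefficients / fit$coefficients[["c"]]
  expect_equal(unname(aa[c("a", "b")]), c(0.5, 0.3), tolerance = 1e-8)
  expect_equal(fit$constant / fit$coefficients[["c"]], 1, tolerance = 1e-8)
})

test_that("a known generating plane is recovered from noisy points", {
  # generator: 0.762 sf_ha - 0.619 sf_K1 + 0.191 sf_bNSC = 0.333554
  gen <- c(ha = 0.762, K1 = -0.619, bNSC = 0.191)
  const <- 0.333554
  set.seed(11)
  ha <- runif(40, 0.8, 1.2)
  bnsc <- runif(40, 0.8, 1.2)
  k1 <- (0.762 * ha + 0.191 * bnsc - const) / 0.619
  pts <- cbind(ha = ha, K1 = k1 + rnorm(40, 0, 0.004), bNSC = bnsc)
  fit <- fit_plane(pts, method = "tls")
  gn <- gen / sqrt(sum(gen^2))
  est <- fit$coefficients
  if (sign(est[["ha"]]) != sign(gn[["ha"]])) est <- -est
  expect_equal(unname(est[names(gen)]), unname(gn), tolerance = 0.05)
  expect_equal(fit$constant * sign(sum(est * gn)),
               const / sqrt(sum(gen^2)), tolerance = 0.05)
  expect_gt(fit$r_squared, 0.8)
  # OLS route agrees on the normalized direction
  fit_ols <- fit_plane(pts, response = "K1", method = "ols")
  expect_equal(abs(sum(fit_ols$coefficients * est)), 1, tolerance = 0.01)
})

test_that("underdetermined and degenerate plane fits are rejected", {
  pts <- data.frame(a = runif(3), b = runif(3), c = runif(3))
  expect_error(fit_plane(pts), "at least 4 points")
  same <- data.frame(a = rep(1, 10), b = runif(10), c = runif(10))
  expect_error(fit_plane(same), "zero-variance")
})

test_that("plane fits are invariant to point order", {
  set.seed(13)
  pts <- data.frame(a = runif(15), b = runif(15))
  pts$c <- 0.7 * pts$a - 0.2 * pts$b + rnorm(15, 0, 0.01)
  f1 <- fit_plane(pts)
  f2 <- fit_plane(pts[sample(15), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
})

test_that("OLS residuals are orthogonal to the regressors", {
  set.seed(17)
  pts <- data.frame(a = runif(20), b = runif(20))
  pts$c <- 0.3 * pts$a + 0.4 * pts$b + rnorm(20, 0, 0.05)
  fit <- fit_plane(pts, response = "c", method = "ols")
  a <- fit$coefficients
  pred_resid <- as.matrix(pts) %*% a - fit$constant
  expect_lt(abs(sum(pred_resid * (pts$a - mean(pts$a)))), 1e-8)
  expect_lt(abs(sum(pred_resid * (pts$b - mean(pts$b)))), 1e-8)
})

test_that("complementarity of independent noise scores a low R^2", {
  set.seed(19)
  toy <- structure(list(
    selected = c("ha", "K1", "bNSC"),
    finals = tibble::tibble(
      run = 1:20, seed = 1:20, final_mse = runif(20, 1e-5, 1e-3),
      converged = TRUE, n_evals = 1,
      Na_i = 6.1, Ca_tot = 79,
      sf_ha = runif(20, 0.9, 1.1),
      sf_K1 = runif(20, 0.9, 1.1),
      sf_bNSC = runif(20, 0.9, 1.1))
  ), class = "orp_result")
  rep1 <- complementarity_report(toy, k = 20)
  # permutation null for 2-regressor OLS on 20 points: R^2 rarely > 0.5
  expect_lt(rep1$plane$r_squared, 0.5)
  expect_error(complementarity_report(toy, currents = c("ha", "Kur")),
               "not optimized")
  toy$finals$sf_ha <- 1
  expect_error(complementarity_report(toy, k = 20), "zero-variance")
})
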