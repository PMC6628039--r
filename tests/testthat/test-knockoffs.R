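# Second-order Gaussian knockoff construction: covariance estimation,
# the equicorrelated s vector, and conditional sampling.

test_that("covariance estimation matches a hand-computed shrunken covariance", {
  # two distinct rows each repeated: sample covariance is computable by hand
  X <- rbind(c(1, 2), c(3, 1), c(1, 2), c(3, 1))
  colnames(X) <- c("a", "b")
  # hand computation: var1 = 4/3, var2 = 1/3, cov12 = -2/3, corr = -1;
  # correlation-scale shrinkage with gamma: off-diag -> (1 - gamma) * r
  gamma <- 0.3
  fit <- estimate_gaussian_model(X, shrinkage = gamma)
  expect_equal(unname(fit$mean), c(2, 1.5))
  expect_equal(unname(diag(fit$covariance)), c(4 / 3, 1 / 3))
  expect_equal(fit$covariance[1, 2], (1 - gamma) * (-1) * sqrt(4 / 3 * 1 / 3),
               tolerance = 1e-12)
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("estimation recovers the identity for iid standard normals", {
  set.seed(1)
  X <- matrix(rnorm(10000 * 3), 10000, 3)
  fit <- estimate_gaussian_model(X, shrinkage = "auto")
  expect_lt(max(abs(fit$covariance - diag(3))), 0.1)
  expect_lt(max(abs(fit$mean)), 0.05)
})

test_that("constant columns are rejected with the feature named", {
  X <- cbind(gene_a = rnorm(20), dead_gene = rep(0, 20))
  expect_error(estimate_gaussian_model(X), "dead_gene")
  expect_error(standardize_columns(X), "dead_gene")
})

test_that("equicorrelated s solves min(1, 2 lambda_min) on the correlation scale", {
  expect_equal(solve_equicorrelated_s(diag(5)), rep(1, 5))

  R <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(solve_equicorrelated_s(R), rep(1, 2))  # 2 * 0.7 > 1

  # AR(1), rho = 0.3, p = 10: compare against a direct eigen-solver oracle
  p <- 10; rho <- 0.3
  R <- rho^abs(outer(1:p, 1:p, "-"))
  lam_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  s <- solve_equicorrelated_s(R)
  expect_equal(s, rep(min(1, 2 * lam_min), p), tolerance = 1e-4)
  # joint-covariance PSD condition: 2 diag(s) - diag(s) R^-1 diag(s) >= 0
  C <- 2 * diag(s) - diag(s) %*% solve(R) %*% diag(s)
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # variance rescaling: s scales with the diagonal of Sigma
  Sigma <- diag(c(2, 3)) %*% matrix(c(1, 0.3, 0.3, 1), 2) %*% diag(c(2, 3))
  expect_equal(solve_equicorrelated_s(Sigma), c(4, 9))

  expect_error(solve_equicorrelated_s(matrix(c(1, 1, 1, 1), 2)),
               "positive-definite")
})

test_that("knockoff sampling honours the degenerate and independent cases", {
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50, 4)
  model <- estimate_gaussian_model(X, shrinkage = 0)

  # s = 0: zero conditional variance and conditional mean x => knockoff = X
  model0 <- model
  model0$s <- rep(0, 4)
  aug0 <- sample_knockoffs(X, model0, seed = 3)
  expect_equal(unname(aug0$values[, 5:8]), unname(X), tolerance = 1e-12)

  # Sigma = I, s = 1: knockoffs are independent fresh draws
  modelI <- structure(list(mean = rep(0, 4), covariance = diag(4),
                           s = rep(1, 4), shrinkage = 0),
                      class = "gaussian_knockoff_model")
  n <- 10000
  Xi <- matrix(rnorm(n * 4), n, 4)
  augI <- sample_knockoffs(Xi, modelI, seed = 4)
  for (j in 1:4)
    expect_lt(abs(cor(augI$values[, j], augI$values[, j + 4])), 3 / sqrt(n))
})

test_that("knockoff sampling is deterministic given the seed and outcome-blind", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3)
  model <- estimate_gaussian_model(X)
  a1 <- sample_knockoffs(X, model, seed = 7)
  a2 <- sample_knockoffs(X, model, seed = 7)
  a3 <- sample_knockoffs(X, model, seed = 8)
  expect_identical(a1$values, a2$values)
  expect_false(identical(a1$values, a3$values))
  # the interface has no outcome argument at all
  expect_false("y" %in% names(formals(sample_knockoffs)))
  # mismatched dimensions are refused
  expect_error(sample_knockoffs(X[, 1:2], model, seed = 1), "dimension")
})

test_that("empirical knockoff moments match the model (AR(1), closed form)", {
  n <- 20000; p <- 20; rho <- 0.3
  X <- simulate_covariates(n, p, rho, seed = 10)
  Sigma <- rho^abs(outer(1:p, 1:p, "-"))
  model <- structure(list(mean = rep(0, p), covariance = Sigma,
                          s = solve_equicorrelated_s(Sigma), shrinkage = 0),
                     class = "gaussian_knockoff_model")
  aug <- sample_knockoffs(X, model, seed = 11)
  Xk <- aug$values[, p + 1:p]
  bound <- 5 * sqrt(1 / n) * max(diag(Sigma))
  expect_lt(max(abs(cov(Xk) - Sigma)), bound)
  expect_lt(max(abs(cov(X, Xk) - (Sigma - diag(model$s)))), bound)
})

test_that("covariates round-trip through the TSV reader/writer", {
  X <- matrix(round(rnorm(12), 3), 4, 3,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  path <- tempfile(fileext = ".tsv")
  write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_covariates(path), X)

  # augmented design writer tags knockoff columns with _ko
  model <- estimate_gaussian_model(matrix(rnorm(40 * 3), 40, 3,
                                          dimnames = list(NULL, colnames(X))))
  aug <- sample_knockoffs(matrix(rnorm(40 * 3), 40, 3,
                                 dimnames = list(NULL, colnames(X))),
                          model, seed = 1)
  out <- tempfile(fileext = ".tsv")
  write_augmented_design(aug, out)
  hdr <- strsplit(readLines(out, n = 1), "\t")[[1]]
  expect_equal(hdr, c("g1", "g2", "g3", "g1_ko", "g2_ko", "g3_ko"))
})
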