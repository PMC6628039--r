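# Simulation designs: AR(1) covariates, sparse signals, gaussian and
# survival outcomes, FDP/power bookkeeping, replicated experiments.

test_that("AR(1) covariates have the rho^|i-j| correlation structure", {
  X0 <- simulate_covariates(20000, 5, 0, seed = 1)
  off <- cor(X0) - diag(5)
  expect_lt(max(abs(off)), 3 / sqrt(20000) * 1.5)

  X <- simulate_covariates(50000, 3, 0.3, seed = 2)
  expect_equal(cor(X[, 1], X[, 2]), 0.3, tolerance = 0.02)
  expect_equal(cor(X[, 1], X[, 3]), 0.09, tolerance = 0.02)

  expect_identical(simulate_covariates(50, 4, 0.3, seed = 3),
                   simulate_covariates(50, 4, 0.3, seed = 3))
  expect_error(simulate_covariates(10, 2, 1, seed = 1), "rho")
})

test_that("coefficient assignment places k random-sign amplitudes", {
  cf <- assign_coefficients(10, 10, 2.5, seed = 4)
  expect_true(all(abs(cf$beta) == 2.5))

  cf2 <- assign_coefficients(100, 10, 2.5, seed = 5)
  expect_equal(sum(cf2$beta != 0), 10)
  expect_true(all(abs(cf2$beta[cf2$true_set]) == 2.5))
  expect_length(cf2$true_set, 10)

  signs <- vapply(1:1000, function(s)
    mean(sign(assign_coefficients(20, 5, 1, seed = s)$beta[
      assign_coefficients(20, 5, 1, seed = s)$true_set])), numeric(1))
  expect_lt(abs(mean(signs)), 3 * sd(signs) / sqrt(1000))
})

test_that("linear predictor matches a naive double loop for both links", {
  set.seed(6)
  X <- matrix(rnorm(12 * 5), 12, 5)
  beta <- rnorm(5)
  expect_equal(linear_predictor(X, rep(0, 5)), rep(0, 12))

  naive <- function(X, b, square) {
    out <- numeric(nrow(X))
    for (i in seq_len(nrow(X)))
      for (j in seq_len(ncol(X)))
        out[i] <- out[i] + (if (square) X[i, j]^2 else X[i, j]) * b[j]
    out
  }
  expect_equal(linear_predictor(X, beta, "linear"), naive(X, beta, FALSE))
  expect_equal(linear_predictor(X, beta, "quadratic"), naive(X, beta, TRUE))

  # one-hot row under the quadratic link picks out beta_j * x_ij^2
  Xh <- matrix(0, 1, 5); Xh[1, 3] <- 2
  expect_equal(linear_predictor(Xh, beta, "quadratic"), 4 * beta[3])
})

test_that("gaussian outcomes carry the requested noise variance", {
  eta <- rnorm(10)
  expect_equal(simulate_gaussian_outcome(eta, 0, seed = 7), eta)
  y <- simulate_gaussian_outcome(rep(0, 50000), 2.5, seed = 8)
  expect_equal(var(y), 2.5, tolerance = 0.05)
  expect_identical(simulate_gaussian_outcome(eta, 1, seed = 9),
                   simulate_gaussian_outcome(eta, 1, seed = 9))
})

test_that("survival outcomes follow competing exponentials at the stated rates", {
  n <- 30000
  y <- simulate_survival_outcome(rep(0, n), seed = 10)
  # P(event) = h0 / (h0 + hc) = 0.002 / 0.006 = 1/3
  p_hat <- mean(y[, "event"])
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
  # observed time is exponential with rate h0 + hc = 0.006
  expect_equal(mean(y[, "time"]), 1 / 0.006, tolerance = 0.03 * 1 / 0.006)
})

test_that("a proportional-hazards fit recovers a unit coefficient on eta", {
  set.seed(11)
  eta <- rnorm(5000, sd = 0.7)
  y <- simulate_survival_outcome(eta, seed = 12)
  fit <- survival::coxph(survival::Surv(y[, "time"], y[, "event"]) ~ eta)
  expect_equal(unname(coef(fit)), 1, tolerance = 0.1)
})

test_that("FDP and power follow the stated conventions", {
  expect_equal(evaluate_replication(integer(0), 1:4),
               c(fdp = 0, power = 0))                       # 0/0 = 0
  expect_equal(evaluate_replication(2:5, 2:5), c(fdp = 0, power = 1))
  expect_equal(evaluate_replication(c(1, 2, 3), c(2, 3, 4, 5)),
               c(fdp = 1 / 3, power = 2 / 4))
})

test_that("experiments are reproducible and saturate under strong signal", {
  cfg <- simulation_config(n = 100, p = 50, k = 10, amplitudes = 8,
                           reps = 2, q = 0.2, seed = 13)
  res <- run_experiment(cfg, methods = "rrb", mstop = 100)
  expect_equal(nrow(res$summary), 1)           # one method x one amplitude
  expect_true(all(res$records$power == 1))
  expect_true(all(res$records$fdp <= 0.4))

  res2 <- run_experiment(cfg, methods = "rrb", mstop = 100)
  expect_identical(res$records, res2$records)
  expect_identical(res$summary, res2$summary)

  tsv <- tempfile(fileext = ".tsv")
  write_experiment(res, tsv)
  expect_equal(read.table(tsv, header = TRUE, sep = "\t")$power,
               res$summary$power)
})

test_that("simulated datasets respect the configuration invariants", {
  cfg <- simulation_config(n = 50, p = 20, k = 4, amplitudes = 1.5,
                           link = "quadratic", seed = 14)
  dat <- simulate_dataset(cfg)
  expect_equal(dim(dat$X), c(50, 20))
  expect_equal(which(dat$beta != 0), dat$true_set)
  expect_length(dat$true_set, 4)
  expect_equal(drop(dat$X^2 %*% dat$beta),
               linear_predictor(dat$X, dat$beta, "quadratic"))

  cfgs <- simulation_config(n = 40, p = 10, k = 2, amplitudes = 1,
                            family = "cox", seed = 15)
  ds <- simulate_dataset(cfgs)
  expect_true(all(ds$y[, "event"] %in% c(0, 1)))
  expect_true(all(ds$y[, "time"] > 0))
})
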