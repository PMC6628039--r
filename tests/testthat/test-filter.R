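# Screening, thresholding, selection, BH adjustment, prefilter, lasso+CV.

test_that("knockoff threshold matches hand-worked examples", {
  # (1 + 0) / 4 = 0.25 <= q: all four selected at t = 1
  expect_equal(knockoff_threshold(c(1, 1, 1, 1), q = 0.25), 1)
  sel <- knockoff_select(c(1, 1, 1, 1), q = 0.25)
  expect_equal(sel$selected, 1:4)

  # all-negative and all-zero W: no selection, not an error
  expect_equal(knockoff_threshold(c(-1, -2, -0.5), q = 0.3), Inf)
  expect_equal(knockoff_threshold(rep(0, 10), q = 0.3), Inf)
  expect_length(knockoff_select(rep(0, 10), q = 0.3)$selected, 0)

  # worked mixed example against the brute-force scan
  w <- c(3, -1, 2, -2, 0.5)
  expect_equal(knockoff_threshold(w, q = 0.5, variant = "knockoff_plus"),
               brute_force_threshold(w, 0.5, offset = 1))

  expect_error(knockoff_threshold(c(1, 2), q = 0), "q must be")
  expect_error(knockoff_threshold(c(1, 2), q = 1), "q must be")
})

test_that("threshold and selection agree with exhaustive enumeration on random W", {
  set.seed(1)
  for (i in 1:200) {
    m <- sample(5:50, 1)
    w <- round(rnorm(m) * sample(c(0.5, 1, 5), 1), 2)
    w[sample(m, sample(0:3, 1))] <- 0
    q <- runif(1, 0.05, 0.6)
    for (variant in c("knockoff_plus", "knockoff")) {
      offset <- if (variant == "knockoff_plus") 1 else 0
      t_star <- brute_force_threshold(w, q, offset)
      expect_equal(knockoff_threshold(w, q, variant), t_star)
      sel <- knockoff_select(w, q, variant)$selected
      expected <- if (is.infinite(t_star)) integer(0) else
        which(w >= t_star)
      expect_equal(sel, expected)
    }
  }
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(2)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    expect_equal(bh_adjust(p), brute_force_bh(p))
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  }
})

test_that("screening bypasses when 2p <= n and keeps ties by lower index", {
  set.seed(3)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y <- rnorm(100)
  scr <- nonlinear_screen(X, y)         # n_keep defaults to n = 100 > 8
  expect_warning(nonlinear_screen(X, y, n_keep = 20), "keeping all")
  expect_equal(scr$kept_columns, 1:8)
  expect_length(scr$scores, 8)
  expect_true(all(scr$scores >= 0))

  # identical columns score identically; lower indices are kept first
  Xd <- cbind(X[, 1], X[, 1], X[, 1])
  sd3 <- nonlinear_screen(Xd, rnorm(100), n_keep = 2)
  expect_equal(sd3$kept_columns, c(1, 2))
})

test_that("screening ranks a true signal column highly across seeds", {
  hits <- 0L
  for (s in 1:20) {
    X <- simulate_covariates(60, 100, 0, seed = 900 + s)
    y <- simulate_gaussian_outcome(X[, 1], 1, seed = 950 + s)
    scr <- nonlinear_screen(X, y, n_keep = 10)
    if (rank(-scr$scores)[1] <= 10) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("screened-out pairs cannot create negative W: selection stays in kept pairs", {
  fix <- make_linear_fixture(n = 60, p = 40, k = 5, amplitude = 3, seed = 51)
  aug <- make_augmented(fix, seed = 52)
  scr <- nonlinear_screen(aug, fix$y, n_keep = 60)
  kept <- scr$kept_columns
  fit <- fit_boosting(aug$values[, kept, drop = FALSE], fix$y, mstop = 50)
  w <- rrb_statistic(fit, aug$pairing, col_ids = kept)
  both_out <- which(w$screened_out)
  expect_true(all(w$w[both_out] == 0))
  sel <- knockoff_select(w, 0.2)$selected
  kept_pairs <- unique(c(aug$pairing[aug$pairing[, 1] %in% kept, 1],
                         aug$pairing[aug$pairing[, 2] %in% kept, 1]))
  expect_true(all(sel %in% kept_pairs))
})

test_that("the expression prefilter applies the TPM and q-value rules", {
  # 10 samples x 5 genes, hand-checkable
  set.seed(6)
  n <- 10
  y <- seq(-1.5, 1.5, length.out = n)
  expr <- cbind(
    dead = rep(0, n),                        # fails mean TPM > 1
    low = rep(0.5, n) + abs(rnorm(n, 0, 0.01)),   # fails mean TPM > 1
    signal = 5 + 3 * y + abs(rnorm(n, 0, 0.01)),  # survives both rules
    collinear = 3.5 + 2 * y,                 # perfectly collinear: survives
    noise = 5 + abs(rnorm(n))                # passes TPM, fails q-value
  )
  out <- prefilter_features(expr, y, tpm_min = 1, q_max = 0.2)
  expect_equal(colnames(out), c("signal", "collinear"))
  expect_equal(unname(attr(out, "counts")), c(5, 3, 2))
  # hand-check the surviving count by applying the two rules directly
  keep_tpm <- colMeans(expr) > 1
  pv <- sapply(which(keep_tpm), function(j) cor.test(expr[, j], y)$p.value)
  expect_equal(sum(bh_adjust(pv) < 0.2), ncol(out))
  # log transform applied with pseudocount 1
  expect_equal(out[, "collinear"], log(expr[, "collinear"] + 1))

  expect_error(prefilter_features(expr, y, tpm_min = 100), "no features")
  expect_error(prefilter_features(-expr, y), "nonnegative")
})

test_that("lasso+CV baseline finds strong signals and is seed-deterministic", {
  hits <- 0L
  for (s in 1:20) {
    X <- simulate_covariates(100, 20, 0.3, seed = 970 + s)
    y <- simulate_gaussian_outcome(3 * X[, 7], 1, seed = 980 + s)
    if (7 %in% lasso_cv_select(X, y, seed = s)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  fix <- make_linear_fixture(n = 100, p = 20, k = 3, seed = 61)
  expect_identical(lasso_cv_select(fix$X, fix$y, seed = 5),
                   lasso_cv_select(fix$X, fix$y, seed = 5))
})
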