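# Independent oracles and small fixture generators used across test files.
# Everything here is deliberately naive (loops, direct definitions) so that
# it stays independent of the package's vectorized implementations.

# Breslow negative log partial likelihood, direct double loop over events.
naive_cox_nll <- function(time, event, f) {
  nll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      riskset <- which(time >= time[i])
      nll <- nll - (f[i] - log(sum(exp(f[riskset]))))
    }
  }
  nll
}

# central finite-difference gradient of a scalar function of f
fd_gradient <- function(fun, f, h = 1e-6) {
  vapply(seq_along(f), function(i) {
    fp <- f; fp[i] <- fp[i] + h
    fm <- f; fm[i] <- fm[i] - h
    (fun(fp) - fun(fm)) / (2 * h)
  }, numeric(1))
}

# exhaustive-scan oracle for the knockoff threshold
brute_force_threshold <- function(w, q, offset) {
  cand <- sort(unique(abs(w[w != 0])))
  ok <- cand[vapply(cand, function(t) {
    (offset + sum(w <= -t)) / max(1, sum(w >= t)) <= q
  }, logical(1))]
  if (length(ok)) min(ok) else Inf
}

# direct step-up BH definition: q_(i) = min_{k >= i} m p_(k) / k, capped
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# a small linear-signal dataset with knockoff-ready dimensions
make_linear_fixture <- function(n = 200, p = 50, k = 5, amplitude = 3,
                                rho = 0.3, seed = 42) {
  X <- simulate_covariates(n, p, rho, seed)
  cf <- assign_coefficients(p, k, amplitude, seed + 1)
  y <- simulate_gaussian_outcome(linear_predictor(X, cf$beta, "linear"),
                                 1, seed + 2)
  list(X = X, y = y, beta = cf$beta, true_set = cf$true_set)
}

# standardized augmented design for a fixture (no screening)
make_augmented <- function(fix, seed = 99) {
  Xs <- standardize_columns(fix$X)
  model <- estimate_gaussian_model(Xs)
  sample_knockoffs(Xs, model, seed = seed)
}
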