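# Simulation designs used to benchmark the knockoff filter: AR(1) Gaussian
# covariates, sparse linear or quadratic signals, Gaussian or survival
# (exponential / Weibull shape 1) outcomes, and replicated experiments
# reporting empirical FDP and power.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate AR(1) Gaussian covariates
#'
#' Draws `n` i.i.d. rows from \eqn{N(0, \Sigma)} with
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}} (first-order autoregressive
#' correlation), using the O(np) recursion
#' \eqn{X_j = \rho X_{j-1} + \sqrt{1-\rho^2}\, Z_j}.
#'
#' @param n,p dimensions.
#' @param rho autoregressive coefficient, `|rho| < 1`.
#' @param seed integer seed.
#' @return n x p matrix with columns named `X1..Xp`.
#' @export
simulate_covariates <- function(n, p, rho, seed) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  with_seed(seed, {
    X <- matrix(0, n, p)
    X[, 1] <- rnorm(n)
    if (p > 1) {
      fac <- sqrt(1 - rho^2)
      for (j in 2:p) X[, j] <- rho * X[, j - 1] + fac * rnorm(n)
    }
    colnames(X) <- paste0("X", seq_len(p))
    X
  })
}

#' Assign sparse random-sign coefficients
#'
#' Chooses `k` of `p` positions uniformly without replacement and sets
#' their coefficients to `amplitude` with independent fair random signs;
#' all other coefficients are zero.
#'
#' @param p number of features.
#' @param k number of nonzero coefficients.
#' @param amplitude positive magnitude A of each nonzero coefficient.
#' @param seed integer seed.
#' @return list with `beta` (length p) and `true_set` (sorted indices).
#' @export
assign_coefficients <- function(p, k, amplitude, seed) {
  if (k > p) stop("k must not exceed p")
  if (amplitude <= 0) stop("amplitude must be positive")
  with_seed(seed, {
    idx <- sort(sample.int(p, k))
    signs <- sample(c(-1, 1), k, replace = TRUE)
    beta <- numeric(p)
    beta[idx] <- signs * amplitude
    list(beta = beta, true_set = idx)
  })
}

#' Linear predictor under a linear or quadratic link
#'
#' `link = "linear"` gives \eqn{\eta = X\beta}; `link = "quadratic"`
#' replaces each covariate by its square, \eqn{\eta = (X \circ X)\beta},
#' the nonlinear benchmark design.
#'
#' @param X covariate matrix.
#' @param beta coefficient vector.
#' @param link `"linear"` or `"quadratic"`.
#' @return numeric vector of length n.
#' @export
linear_predictor <- function(X, beta, link = c("linear", "quadratic")) {
  link <- match.arg(link)
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) stop("beta length must equal ncol(X)")
  if (link == "quadratic") X <- X^2
  drop(X %*% beta)
}

#' Simulate a Gaussian outcome
#'
#' \eqn{y = \eta + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d.
#'
#' @param eta linear predictor.
#' @param sigma2 noise variance.
#' @param seed integer seed.
#' @return numeric vector.
#' @export
simulate_gaussian_outcome <- function(eta, sigma2, seed) {
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  with_seed(seed, eta + sqrt(sigma2) * rnorm(length(eta)))
}

#' Simulate right-censored survival outcomes
#'
#' Event times follow a Weibull distribution with shape 1 -- i.e. an
#' exponential -- with hazard rate \eqn{h_0 \exp(\eta)} (proportional
#' hazards); censoring times are independent exponentials with rate
#' `censor_hazard`.  The observation is the smaller of the two with an
#' event indicator.  At \eqn{\eta = 0} the event probability is
#' \eqn{h_0 / (h_0 + h_c)}.
#'
#' @param eta linear predictor on the log-hazard scale.
#' @param baseline_hazard event hazard rate at `eta = 0` (default 0.002).
#' @param censor_hazard censoring hazard rate (default 0.004).
#' @param seed integer seed.
#' @return two-column matrix `(time, event)`.
#' @export
simulate_survival_outcome <- function(eta, baseline_hazard = 0.002,
                                      censor_hazard = 0.004, seed) {
  if (baseline_hazard <= 0 || censor_hazard <= 0)
    stop("hazard rates must be positive")
  with_seed(seed, {
    n <- length(eta)
    t_event <- rexp(n, rate = baseline_hazard * exp(eta))
    t_cens <- rexp(n, rate = censor_hazard)
    cbind(time = pmin(t_event, t_cens),
          event = as.numeric(t_event <= t_cens))
  })
}

#' False discovery proportion and power of one selection
#'
#' \eqn{FDP = |S_{sel} \setminus S| / |S_{sel}|} with the convention
#' 0/0 = 0, and \eqn{power = |S_{sel} \cap S| / |S|}.
#'
#' @param selected integer vector of selected indices.
#' @param true_set integer vector of truly associated indices.
#' @return named numeric vector `c(fdp, power)`.
#' @export
evaluate_replication <- function(selected, true_set) {
  selected <- unique(as.integer(selected))
  true_set <- unique(as.integer(true_set))
  n_sel <- length(selected)
  fdp <- if (n_sel == 0) 0 else length(setdiff(selected, true_set)) / n_sel
  power <- if (length(true_set) == 0) 0 else
    length(intersect(selected, true_set)) / length(true_set)
  c(fdp = fdp, power = power)
}

#' Configuration of a simulation experiment
#'
#' Bundles and validates the generative and analysis settings of a
#' replicated experiment.  The defaults follow the benchmark designs:
#' AR(1) covariates with `rho = 0.3`, `n = 300`, `k = 10` random-sign
#' coefficients, unit noise variance, target FDR `q = 0.2`, and survival
#' hazards 0.002 (event) / 0.004 (censoring).  `p` and `reps` default to a
#' desk-scale 500 x 10; the full-scale benchmark profile is
#' `simulation_config(p = 2000, reps = 30, amplitudes = ...)`.
#'
#' @param n,p,k sample size, dimension and number of signals.
#' @param rho AR(1) coefficient.
#' @param sigma2 Gaussian noise variance.
#' @param amplitudes vector of signal amplitudes to sweep.
#' @param link `"linear"` or `"quadratic"`.
#' @param family `"gaussian"` or `"cox"`.
#' @param baseline_hazard,censor_hazard survival hazard rates.
#' @param reps replications per amplitude.
#' @param q target FDR level.
#' @param seed master seed; per-replication seeds are derived as
#'   `seed + rep * 10007 + amplitude_index`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n = 300, p = 500, k = 10, rho = 0.3,
                              sigma2 = 1, amplitudes = c(0.25, 0.5, 0.75, 1),
                              link = c("linear", "quadratic"),
                              family = c("gaussian", "cox"),
                              baseline_hazard = 0.002, censor_hazard = 0.004,
                              reps = 10, q = 0.2, seed = 1) {
  link <- match.arg(link)
  family <- match.arg(family)
  stopifnot(k <= p, reps >= 1, q > 0, q < 1, abs(rho) < 1, sigma2 >= 0,
            all(amplitudes > 0))
  structure(list(n = n, p = p, k = k, rho = rho, sigma2 = sigma2,
                 amplitudes = amplitudes, link = link, family = family,
                 baseline_hazard = baseline_hazard,
                 censor_hazard = censor_hazard, reps = reps, q = q,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate one simulated dataset from a configuration
#'
#' @param config a [simulation_config()].
#' @param seed replication seed (sub-seeds for covariates, coefficients
#'   and noise are derived deterministically from it).
#' @return list with `X`, `beta`, `true_set` and `y` (vector, or
#'   (time, event) matrix for `family = "cox"`).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  seed <- as.integer(seed)
  X <- simulate_covariates(config$n, config$p, config$rho, seed)
  cf <- assign_coefficients(config$p, config$k, config$amplitudes[1],
                            seed + 1L)
  eta <- linear_predictor(X, cf$beta, config$link)
  y <- if (config$family == "gaussian")
    simulate_gaussian_outcome(eta, config$sigma2, seed + 2L)
  else
    simulate_survival_outcome(eta, config$baseline_hazard,
                              config$censor_hazard, seed = seed + 2L)
  list(X = X, beta = cf$beta, true_set = cf$true_set, y = y)
}

#' Run a replicated knockoff simulation experiment
#'
#' For each amplitude and replication: simulate a dataset, construct
#' second-order Gaussian knockoffs (outcome-blind), screen to `n` columns
#' when `2p > n`, compute the requested statistics, select at level `q`
#' with the knockoff(+) filter (`lasso_cv` selects directly from the
#' original covariates instead), and record the false discovery proportion
#' and power against the known signal set.  All randomness derives from
#' `config$seed`, so a repeated call reproduces the result exactly.
#'
#' Methods share each replication's dataset and knockoffs, so comparisons
#' between methods are paired.
#'
#' @param config a [simulation_config()].
#' @param methods character subset of `c("rrb", "lcd", "lasso_cv")`.
#' @param variant threshold variant, see [knockoff_threshold()].
#' @param mstop,nu boosting parameters for the RRB statistic.
#' @param verbose print one line per replication.
#' @return object of class `knockoff_experiment`: `summary` data frame
#'   (one row per method x amplitude with mean/SE of FDP and power) and
#'   `records` (per-replication results).
#' @export
run_experiment <- function(config, methods = "rrb",
                           variant = c("knockoff_plus", "knockoff"),
                           mstop = 100, nu = 0.1, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  variant <- match.arg(variant)
  methods <- match.arg(methods, c("rrb", "lcd", "lasso_cv"),
                       several.ok = TRUE)
  records <- list()
  for (ai in seq_along(config$amplitudes)) {
    A <- config$amplitudes[ai]
    cfg_a <- config
    cfg_a$amplitudes <- A
    for (r in seq_len(config$reps)) {
      rep_seed <- config$seed + r * 10007L + ai
      dat <- simulate_dataset(cfg_a, seed = rep_seed)
      sel_by_method <- replication_selections(
        dat, config, methods, variant, mstop, nu, seed = rep_seed)
      for (mth in methods) {
        ev <- evaluate_replication(sel_by_method[[mth]], dat$true_set)
        records[[length(records) + 1L]] <-
          data.frame(method = mth, amplitude = A, rep = r,
                     fdp = ev["fdp"], power = ev["power"],
                     n_selected = length(sel_by_method[[mth]]),
                     row.names = NULL)
      }
      if (verbose)
        message(sprintf("amplitude %g rep %d done", A, r))
    }
  }
  records <- do.call(rbind, records)
  summary <- aggregate_records(records)
  structure(list(summary = summary, records = records, config = config,
                 methods = methods, variant = variant),
            class = "knockoff_experiment")
}

# one replication's selections for each requested method, sharing the
# dataset and (for rrb/lcd) the knockoffs and screening
replication_selections <- function(dat, config, methods, variant,
                                   mstop, nu, seed) {
  out <- list()
  need_ko <- any(methods %in% c("rrb", "lcd"))
  if (need_ko) {
    Xs <- standardize_columns(dat$X)
    model <- estimate_gaussian_model(Xs)
    aug <- sample_knockoffs(Xs, model, seed = seed + 5000L)
    m <- ncol(aug$values)
    if (m > config$n) {
      scr <- nonlinear_screen(aug, dat$y, n_keep = config$n,
                              family = config$family)
      kept <- scr$kept_columns
    } else kept <- seq_len(m)
    design_kept <- aug$values[, kept, drop = FALSE]
  }
  for (mth in methods) {
    if (mth == "rrb") {
      fit <- fit_boosting(design_kept, dat$y, family = config$family,
                          nu = nu, mstop = mstop)
      w <- rrb_statistic(fit, aug$pairing, col_ids = kept)
      out[[mth]] <- knockoff_select(w, config$q, variant)$selected
    } else if (mth == "lcd") {
      w <- lcd_statistic(design_kept, dat$y, family = config$family,
                         seed = seed + 7000L, pairing = aug$pairing,
                         col_ids = kept)
      out[[mth]] <- knockoff_select(w, config$q, variant)$selected
    } else {
      out[[mth]] <- as.integer(
        lasso_cv_select(dat$X, dat$y, family = config$family,
                        seed = seed + 9000L))
    }
  }
  out
}

aggregate_records <- function(records) {
  agg <- function(v) c(mean = mean(v), se = sd(v) / sqrt(length(v)))
  out <- do.call(rbind, lapply(
    split(records, list(records$method, records$amplitude), drop = TRUE),
    function(d) {
      f <- agg(d$fdp); pw <- agg(d$power)
      data.frame(method = d$method[1], amplitude = d$amplitude[1],
                 reps = nrow(d), fdp = f["mean"], fdp_se = f["se"],
                 power = pw["mean"], power_se = pw["se"],
                 row.names = NULL)
    }))
  out[order(out$method, out$amplitude), , drop = FALSE]
}

#' @export
print.knockoff_experiment <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf("Knockoff simulation experiment (%s link, %s family)\n",
              cfg$link, cfg$family))
  cat(sprintf("  n = %d, p = %d, k = %d, rho = %g, q = %g, reps = %d, seed = %d\n",
              cfg$n, cfg$p, cfg$k, cfg$rho, cfg$q, cfg$reps, cfg$seed))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Plot empirical FDP and power of an experiment
#'
#' Two panels against amplitude, one curve per method, with +/- 1 SE bars
#' and the nominal level `q` marked in the FDP panel -- the standard layout
#' for knockoff benchmark figures.
#'
#' @param x a `knockoff_experiment`.
#' @param ... unused.
#' @export
plot.knockoff_experiment <- function(x, ...) {
  s <- x$summary
  methods <- unique(s$method)
  cols <- setNames(seq_along(methods) + 1, methods)
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (what in c("fdp", "power")) {
    se_col <- paste0(what, "_se")
    ylim <- c(0, max(1e-6, s[[what]] + s[[se_col]], if (what == "fdp") x$config$q * 1.5))
    plot(NA, xlim = range(s$amplitude), ylim = ylim,
         xlab = "amplitude", ylab = toupper(what), main = toupper(what))
    if (what == "fdp") abline(h = x$config$q, lty = 3)
    for (mth in methods) {
      d <- s[s$method == mth, ]
      lines(d$amplitude, d[[what]], type = "b", col = cols[mth], pch = 16)
      segments(d$amplitude, d[[what]] - d[[se_col]],
               d$amplitude, d[[what]] + d[[se_col]], col = cols[mth])
    }
    if (what == "fdp")
      legend("topleft", legend = methods, col = cols, lty = 1, pch = 16,
             bty = "n")
  }
  invisible(x)
}

#' Write an experiment summary to TSV
#'
#' @param experiment a `knockoff_experiment`.
#' @param path output file (one row per method x amplitude).
#' @export
write_experiment <- function(experiment, path) {
  stopifnot(inherits(experiment, "knockoff_experiment"))
  write.table(experiment$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
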