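# Antisymmetric knockoff importance statistics.
#
# Each statistic assigns W_j = (importance of X_j) - (importance of X~_j).
# Because a null feature and its knockoff are exchangeable, W_j is
# symmetric about zero under the null, which is what the knockoff
# threshold exploits to estimate the false discovery proportion.

new_wstat <- function(w, method, names = NULL, screened_out = NULL) {
  p <- length(w)
  screened_out <- screened_out %||% rep(FALSE, p)
  w[screened_out] <- 0
  structure(
    list(w = setNames(as.numeric(w), names), method = method,
         screened_out = screened_out),
    class = "knockoff_stats"
  )
}

#' @export
print.knockoff_stats <- function(x, ...) {
  cat(sprintf("Knockoff importance statistics (%s), p = %d\n",
              x$method, length(x$w)))
  cat(sprintf("  positive: %d, negative: %d, zero: %d (screened out: %d)\n",
              sum(x$w > 0), sum(x$w < 0), sum(x$w == 0),
              sum(x$screened_out)))
  invisible(x)
}

# resolve per-pair importances from a per-design-column vector, honouring
# columns dropped by screening (a missing member counts as importance 0)
pair_difference <- function(imp_by_col, pairing, col_ids) {
  p <- nrow(pairing)
  w <- numeric(p)
  for (j in seq_len(p)) {
    io <- match(pairing[j, 1], col_ids)
    ik <- match(pairing[j, 2], col_ids)
    vo <- if (is.na(io)) 0 else imp_by_col[io]
    vk <- if (is.na(ik)) 0 else imp_by_col[ik]
    w[j] <- vo - vk
  }
  w
}

#' Risk reduction in boosting (RRB) statistic
#'
#' The flagship model-free statistic: fit a component-wise boosting model
#' on the augmented design `[X, X~]` and set
#' \eqn{W_j = \mathrm{riskred}(X_j) - \mathrm{riskred}(\tilde X_j)},
#' the difference of accumulated in-bag risk reductions between a feature
#' and its knockoff.  A feature genuinely driving the outcome attracts
#' boosting updates that its knockoff cannot, pushing W_j positive; a null
#' feature and its knockoff compete on equal footing, making W_j
#' sign-symmetric.
#'
#' @param model a [fit_boosting()] fit on the (possibly screened) augmented
#'   design.
#' @param pairing two-column matrix mapping each feature to its original
#'   and knockoff column indices in the full augmented design (as stored in
#'   an `augmented_design`).
#' @param col_ids indices (into the full augmented design) of the columns
#'   the model was actually fit on; defaults to all `2p` columns.  Columns
#'   absent from the fit (screened out) contribute importance 0, and a pair
#'   with both members absent gets `W_j = 0`.
#' @return a `knockoff_stats` object.
#' @export
rrb_statistic <- function(model, pairing, col_ids = NULL) {
  stopifnot(inherits(model, "boost_model"))
  imp <- variable_importance(model)
  col_ids <- col_ids %||% seq_len(length(imp))
  if (length(col_ids) != length(imp))
    stop("col_ids must have one entry per fitted design column")
  if (max(pairing) > 2 * nrow(pairing))
    stop("pairing refers to columns beyond the augmented design")
  w <- pair_difference(imp, pairing, col_ids)
  both_out <- !(pairing[, 1] %in% col_ids) & !(pairing[, 2] %in% col_ids)
  new_wstat(w, "RRB", screened_out = both_out)
}

#' Lasso coefficient difference (LCD) statistic
#'
#' The classical knockoff statistic used as a baseline: fit an L1-penalized
#' regression on the augmented design with the penalty chosen by k-fold
#' cross-validation, and set \eqn{W_j = |\hat\beta_j| - |\hat\beta_{j+p}|}.
#'
#' @param design an `augmented_design`, or a numeric matrix of fitted
#'   columns (in which case `pairing`/`col_ids` describe the layout).
#' @param y outcome (numeric for gaussian, (time, event) for cox).
#' @param family `"gaussian"` or `"cox"`.
#' @param n_folds folds for `glmnet::cv.glmnet` (default 5).
#' @param seed seed for the fold assignment.
#' @param pairing,col_ids as in [rrb_statistic()]; defaults taken from
#'   `design` when it is an `augmented_design`.
#' @return a `knockoff_stats` object.  If the cross-validated path is
#'   entirely null the statistic is all zeros (with a warning), not an
#'   error.
#' @export
lcd_statistic <- function(design, y, family = c("gaussian", "cox"),
                          n_folds = 5, seed = 1,
                          pairing = NULL, col_ids = NULL) {
  family <- match.arg(family)
  if (inherits(design, "augmented_design")) {
    X <- design$values
    pairing <- pairing %||% design$pairing
  } else X <- as.matrix(design)
  if (is.null(pairing)) stop("pairing is required")
  col_ids <- col_ids %||% seq_len(ncol(X))
  n <- nrow(X)
  y <- check_outcome(y, family, n)
  if (n_folds < 2) stop("n_folds must be >= 2")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(n_folds), n))

  yy <- if (family == "cox") survival::Surv(y[, "time"], y[, "event"]) else y
  cvfit <- tryCatch(
    glmnet::cv.glmnet(X, yy, family = family, foldid = foldid,
                      standardize = FALSE, thresh = 1e-9),
    error = function(e) NULL)
  if (is.null(cvfit)) {
    warning("cross-validated lasso path degenerate; returning all-zero W")
    return(new_wstat(numeric(nrow(pairing)), "LCD"))
  }
  b <- as.numeric(coef(cvfit, s = "lambda.min"))
  if (family == "gaussian") b <- b[-1]          # drop intercept
  w <- pair_difference(abs(b), pairing, col_ids)
  both_out <- !(pairing[, 1] %in% col_ids) & !(pairing[, 2] %in% col_ids)
  new_wstat(w, "LCD", screened_out = both_out)
}

# ---- DRS -------------------------------------------------------------

# Gaussian-kernel ridge regression, the pluggable flexible regressor
# behind DRS.  Bandwidth from the median heuristic on pairwise distances.
# Returns in-sample R^2 given a precomputed squared-distance matrix.
krr_r2 <- function(D2, y, gamma, lambda = 1) {
  n <- length(y)
  K <- exp(-gamma * D2)
  alpha <- solve(K + lambda * diag(n), y - mean(y))
  fit <- mean(y) + drop(K %*% alpha)
  1 - sum((y - fit)^2) / sum((y - mean(y))^2)
}

col_sqdist <- function(x) outer(x, x, "-")^2

#' Difference in R-squared (DRS) statistic
#'
#' For each retained design column, DRS is the drop of in-sample R-squared
#' when that column is removed from a flexible full-model fit (a genuine
#' refit, not coefficient zeroing), floored at zero;
#' \eqn{W_j = \mathrm{DRS}(X_j) - \mathrm{DRS}(\tilde X_j)}.  The flexible
#' regressor is Gaussian-kernel ridge regression with the median-heuristic
#' bandwidth and unit ridge -- a fixed, deterministic stand-in for kernel
#' machines generally.  DRS costs `2 p + 1` model fits and is intended for
#' use after screening; RRB is the faster, recommended statistic.
#'
#' @param design an `augmented_design` or numeric matrix.
#' @param y continuous outcome.
#' @param lambda ridge penalty of the kernel regressor.
#' @param pairing,col_ids as in [rrb_statistic()].
#' @return a `knockoff_stats` object.
#' @export
drs_statistic <- function(design, y, lambda = 1,
                          pairing = NULL, col_ids = NULL) {
  if (inherits(design, "augmented_design")) {
    X <- design$values
    pairing <- pairing %||% design$pairing
  } else X <- as.matrix(design)
  if (is.null(pairing)) stop("pairing is required")
  col_ids <- col_ids %||% seq_len(ncol(X))
  y <- as.numeric(y)
  if (sd(y) < .Machine$double.eps^0.5)
    stop("constant outcome: full-model R-squared is undefined")
  n <- nrow(X); m <- ncol(X)

  d2_by_col <- lapply(seq_len(m), function(j) col_sqdist(X[, j]))
  D2_full <- Reduce(`+`, d2_by_col)
  med <- median(D2_full[upper.tri(D2_full)])
  gamma <- if (med > 0) 1 / med else 1

  r2_full <- krr_r2(D2_full, y, gamma, lambda)
  drs <- vapply(seq_len(m), function(j) {
    r2_part <- krr_r2(D2_full - d2_by_col[[j]], y, gamma, lambda)
    max(0, r2_full - r2_part)
  }, numeric(1))

  w <- pair_difference(drs, pairing, col_ids)
  both_out <- !(pairing[, 1] %in% col_ids) & !(pairing[, 2] %in% col_ids)
  new_wstat(w, "DRS", screened_out = both_out)
}
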