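# Component-wise functional gradient descent boosting.
#
# At every step each candidate P-spline base-learner is fit to the current
# negative gradient of the empirical risk; only the learner with the
# smallest residual sum of squares is updated, by a fraction nu of its fit.
# The realized decrease in empirical risk at the step is credited to the
# selected design column; these accumulated in-bag risk reductions are the
# raw material of the RRB importance statistic.
#
# Risk conventions (internal; any common scale cancels in W differences):
#   gaussian: 0.5 * mean((y - f)^2)
#   cox:      mean negative log partial likelihood, Breslow tie handling

#' Negative gradient of the empirical risk
#'
#' Returns the per-observation negative gradient of the loss at the current
#' fitted scores `f` -- the working response each base-learner is fit to.
#' For `family = "gaussian"` this is the ordinary residual `y - f`.  For
#' `family = "cox"` it is the derivative of the log partial likelihood with
#' Breslow handling of ties: event indicator minus the accumulated hazard
#' \eqn{\exp(f_i) \sum_{k: t_k \le t_i} d_k / \sum_{l \in R_k} \exp(f_l)}.
#'
#' @param family `"gaussian"` or `"cox"`.
#' @param y outcome: numeric vector (gaussian) or two-column (time, event)
#'   matrix / `survival::Surv` object (cox; at least one event required).
#' @param f numeric vector of current fitted scores.
#' @return numeric vector of length n.
#' @export
negative_gradient <- function(family, y, f) {
  family <- match.arg(family, c("gaussian", "cox"))
  if (family == "gaussian") {
    y <- as.numeric(y)
    return(y - f)
  }
  y <- check_outcome(y, "cox")
  cox_neg_gradient(y[, "time"], y[, "event"], f)
}

# Breslow cumulative baseline hazard increments at each subject's time,
# computed on the time-sorted order with reverse cumulative sums.
cox_risk_parts <- function(time, event, f) {
  n <- length(time)
  ord <- order(time)
  t_o <- time[ord]; d_o <- event[ord]; f_o <- f[ord]
  ef <- exp(f_o)
  # risk-set denominators: sum of exp(f) over {l : t_l >= t_i}
  denom <- rev(cumsum(rev(ef)))
  # collapse ties: subjects sharing a time share the denominator of the
  # first (Breslow)
  first_of_tie <- c(TRUE, diff(t_o) > 0)
  grp <- cumsum(first_of_tie)
  denom_grp <- denom[first_of_tie][grp]
  # events per unique time / denominator, accumulated over event times <= t_i
  dk_over_denom <- tapply(d_o, grp, sum) / denom[first_of_tie]
  cumhaz_grp <- cumsum(dk_over_denom)[grp]
  list(ord = ord, d = d_o, f = f_o, ef = ef,
       denom = denom_grp, cumhaz = cumhaz_grp)
}

cox_neg_gradient <- function(time, event, f) {
  parts <- cox_risk_parts(time, event, f)
  g_sorted <- parts$d - parts$ef * parts$cumhaz
  g <- numeric(length(f))
  g[parts$ord] <- g_sorted
  g
}

cox_neg_loglik <- function(time, event, f) {
  parts <- cox_risk_parts(time, event, f)
  -sum(parts$d * (parts$f - log(parts$denom))) / length(f)
}

empirical_risk <- function(family, y, f) {
  if (family == "gaussian") 0.5 * mean((as.numeric(y) - f)^2)
  else cox_neg_loglik(y[, "time"], y[, "event"], f)
}

#' Fit a component-wise P-spline boosting model
#'
#' Functional gradient descent on the given design: at each of `mstop`
#' steps, every column's P-spline learner is fit by penalized least squares
#' to the current negative gradient, the learner with the smallest residual
#' sum of squares is selected (ties broken toward the lowest column index),
#' and the fit, damped by the learning rate `nu`, is added to the ensemble.
#' The decrease in empirical risk realized at each step is accumulated per
#' selected column; by construction these per-column risk reductions sum to
#' the total drop of the risk path (conservation), and a column that is
#' never selected keeps importance exactly zero.
#'
#' @param design numeric matrix or [sample_knockoffs()] `augmented_design`;
#'   columns should be standardized so that learner selection is
#'   scale-free.
#' @param y outcome, see [negative_gradient()].
#' @param family `"gaussian"` (default) or `"cox"`.
#' @param nu learning rate in (0, 1]; small values give the slow, stable
#'   fits boosting is known for.
#' @param mstop number of boosting steps.
#' @param n_knots,degree,penalty_order,target_df P-spline learner
#'   configuration, see [build_pspline_learner()].
#' @return object of class `boost_model` with the fitted scores, the risk
#'   path (length `mstop + 1`), per-column accumulated risk reductions,
#'   selection path and per-column basis coefficients.
#' @export
fit_boosting <- function(design, y, family = c("gaussian", "cox"),
                         nu = 0.1, mstop = 100,
                         n_knots = 20, degree = 3, penalty_order = 2,
                         target_df = 4) {
  family <- match.arg(family)
  X <- if (inherits(design, "augmented_design")) design$values else as.matrix(design)
  n <- nrow(X); m <- ncol(X)
  y <- check_outcome(y, family, n)
  if (mstop < 1) stop("mstop must be >= 1")
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")

  learners <- vector("list", m)
  for (j in seq_len(m))
    learners[[j]] <- build_pspline_learner(X[, j], n_knots, degree,
                                           penalty_order, target_df)

  offset <- if (family == "gaussian") mean(as.numeric(y)) else 0
  f <- rep(offset, n)
  risk_path <- numeric(mstop + 1)
  risk_path[1] <- empirical_risk(family, y, f)
  riskred <- numeric(m)
  coefs <- matrix(0, ncol(learners[[1]]$basis), m)
  selected <- integer(mstop)

  for (step in seq_len(mstop)) {
    u <- if (family == "gaussian") as.numeric(y) - f
         else cox_neg_gradient(y[, "time"], y[, "event"], f)
    best <- 0L; best_rss <- Inf; best_fit <- NULL
    for (j in seq_len(m)) {
      fit <- pspline_fit(learners[[j]], u)
      rss <- sum((u - fit$fitted)^2)
      if (is.finite(rss) && rss < best_rss) {   # strict: ties keep lowest j
        best <- j; best_rss <- rss; best_fit <- fit
      }
    }
    f <- f + nu * best_fit$fitted
    coefs[, best] <- coefs[, best] + nu * best_fit$coef
    risk <- empirical_risk(family, y, f)
    if (!is.finite(risk))
      stop("non-finite empirical risk at boosting step ", step)
    riskred[best] <- riskred[best] + (risk_path[step] - risk)
    risk_path[step + 1] <- risk
    selected[step] <- best
  }

  structure(
    list(family = family, nu = nu, mstop = mstop, offset = offset,
         fitted = f, risk_path = risk_path, riskred_per_learner = riskred,
         coef_per_learner = coefs, selection_path = selected,
         learners = learners,
         feature_names = colnames(X) %||% paste0("V", seq_len(m))),
    class = "boost_model"
  )
}

#' Per-column variable importance of a boosting fit
#'
#' The accumulated in-bag risk reduction credited to each design column
#' over the boosting path.  Importances are nonnegative, zero for columns
#' never selected, and sum to the total risk decrease.
#'
#' @param model a [fit_boosting()] fit.
#' @return named numeric vector, one entry per design column.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "boost_model"))
  setNames(model$riskred_per_learner, model$feature_names)
}

#' @export
print.boost_model <- function(x, ...) {
  cat(sprintf("Component-wise P-spline boosting (%s loss)\n", x$family))
  cat(sprintf("  %d columns, mstop = %d, nu = %g\n",
              length(x$riskred_per_learner), x$mstop, x$nu))
  cat(sprintf("  empirical risk: %.6g -> %.6g\n",
              x$risk_path[1], x$risk_path[length(x$risk_path)]))
  sel <- sum(x$riskred_per_learner > 0)
  cat(sprintf("  columns ever selected: %d\n", sel))
  invisible(x)
}
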