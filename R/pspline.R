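# P-spline base-learners: cubic B-spline basis with a difference penalty,
# ridge parameter calibrated so the penalized hat matrix has a fixed
# effective degrees of freedom.  These are the component-wise learners of
# the boosting engine and the basis used by the nonlinear screening step.

# B-spline basis on equally spaced knots spanning range(x), extended
# `degree` knots beyond each boundary (the Eilers-Marx convention: with
# uniform knots the Greville points are equally spaced, so polynomials up
# to the difference-penalty order lie in the penalty null space).
# Number of basis functions = n_knots + degree + 1.
bspline_basis <- function(x, n_knots = 20, degree = 3, boundary = range(x)) {
  if (boundary[2] <= boundary[1])
    stop("cannot build a spline basis on a constant column")
  h <- (boundary[2] - boundary[1]) / (n_knots + 1)
  knots <- seq(boundary[1] - degree * h, boundary[2] + degree * h,
               length.out = n_knots + 2 + 2 * degree)
  # clamp to the boundary so evaluation is defined for all x
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  splines::splineDesign(knots, xc, ord = degree + 1, outer.ok = TRUE)
}

# order-d difference penalty matrix t(D) %*% D for B basis functions
difference_penalty <- function(B, order = 2) {
  D <- diff(diag(B), differences = order)
  crossprod(D)
}

#' Build a penalized B-spline (P-spline) base-learner
#'
#' Constructs a cubic B-spline basis on equally spaced knots over the range
#' of `x`, a difference penalty of the given order, and solves (by a
#' monotone 1-D root-find on log-lambda) for the ridge parameter at which
#' the penalized hat matrix \eqn{B (B'B + \lambda P)^{-1} B'} has trace
#' equal to `target_df`.  A small target df makes every candidate learner
#' equally "weak", which is what keeps component-wise boosting's selection
#' of learners comparable across columns.
#'
#' @param x numeric vector (one design column), non-constant.
#' @param n_knots number of interior knots (equally spaced).
#' @param degree spline degree (3 = cubic).
#' @param penalty_order order of the difference penalty; its null space
#'   (polynomials of degree `penalty_order - 1`) is unpenalized, so the
#'   attainable df range is `(penalty_order, n_knots + degree + 1)`.
#' @param target_df target effective degrees of freedom.
#' @return object of class `pspline_learner`: basis matrix `basis`, penalty
#'   `penalty`, ridge parameter `ridge_lambda`, achieved `df`, and the
#'   Cholesky factor of `B'B + lambda P` used for fast fitting.
#' @export
build_pspline_learner <- function(x, n_knots = 20, degree = 3,
                                  penalty_order = 2, target_df = 4) {
  x <- as.numeric(x)
  if (sd(x) < .Machine$double.eps^0.5) stop("constant column")
  if (n_knots < penalty_order + 1)
    stop("need n_knots >= penalty_order + 1")
  B <- bspline_basis(x, n_knots, degree)
  nb <- ncol(B)
  if (target_df >= nb)
    stop("target_df (", target_df, ") must be below the basis dimension (",
         nb, ")")
  if (target_df <= penalty_order)
    stop("target_df must exceed the penalty null-space dimension (",
         penalty_order, ")")
  P <- difference_penalty(nb, penalty_order)
  BtB <- crossprod(B)
  eps <- 1e-8 * mean(diag(BtB))

  # Demmler-Reinsch: with R = chol(B'B + eps I) and d the eigenvalues of
  # R^{-T} P R^{-1}, df(lambda) = sum 1 / (1 + lambda d).  Monotone in
  # lambda and numerically stable even for ill-conditioned B'B.
  R <- chol(BtB + eps * diag(nb))
  Mid <- forwardsolve(t(R), t(forwardsolve(t(R), P)))
  d <- eigen((Mid + t(Mid)) / 2, symmetric = TRUE, only.values = TRUE)$values
  d <- pmax(d, 0)
  df_at <- function(loglam) sum(1 / (1 + exp(loglam) * d))
  f <- function(ll) df_at(ll) - target_df
  lo <- -30; hi <- 40
  if (f(lo) < 0) stop("basis too small for target_df even at lambda -> 0")
  if (f(hi) > 0) stop("target_df unreachable: penalty null space too rich")
  root <- uniroot(f, c(lo, hi), tol = 1e-10)
  lam <- exp(root$root)

  chol_fac <- chol(BtB + lam * P + eps * diag(nb))
  structure(
    list(basis = B, penalty = P, ridge_lambda = lam,
         df = df_at(root$root), n_knots = n_knots, degree = degree,
         penalty_order = penalty_order, boundary = range(x),
         chol = chol_fac),
    class = "pspline_learner"
  )
}

# penalized least-squares fit of the learner to a working response u;
# returns list(coef, fitted)
pspline_fit <- function(learner, u) {
  rhs <- crossprod(learner$basis, u)
  cf <- backsolve(learner$chol, forwardsolve(t(learner$chol), rhs))
  list(coef = drop(cf), fitted = drop(learner$basis %*% cf))
}

#' @export
print.pspline_learner <- function(x, ...) {
  cat(sprintf("P-spline learner: %d basis functions, df = %.3f, lambda = %.4g\n",
              ncol(x$basis), x$df, x$ridge_lambda))
  invisible(x)
}
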