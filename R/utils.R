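# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize the columns of a matrix
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation.  Constant columns are rejected: a zero-variance feature cannot
#' be standardized and carries no information for selection.
#'
#' @param X numeric matrix (samples in rows, features in columns).
#' @return matrix of the same dimensions with standardized columns;
#'   attributes `center` and `scale` hold the column means and sds.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  bad <- which(sdv < .Machine$double.eps^0.5)
  if (length(bad))
    stop("constant (zero-variance) column(s): ",
         paste(colname_or_index(X, bad), collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  attr(Xs, "center") <- mu
  attr(Xs, "scale") <- sdv
  Xs
}

colname_or_index <- function(X, idx) {
  if (is.null(colnames(X))) as.character(idx) else colnames(X)[idx]
}

# checked coercion of an outcome to its internal form:
# gaussian -> numeric vector; cox -> two-column matrix (time, event)
check_outcome <- function(y, family, n = NULL) {
  family <- match.arg(family, c("gaussian", "cox"))
  if (family == "gaussian") {
    y <- as.numeric(y)
    if (anyNA(y)) stop("outcome contains missing values")
  } else {
    if (inherits(y, "Surv")) y <- cbind(time = y[, "time"], event = y[, "status"])
    y <- as.matrix(y)
    if (ncol(y) != 2) stop("cox outcome must be a (time, event) pair")
    colnames(y) <- c("time", "event")
    if (anyNA(y)) stop("outcome contains missing values")
    if (any(y[, "time"] <= 0)) stop("survival times must be positive")
    if (!all(y[, "event"] %in% c(0, 1))) stop("event indicator must be 0/1")
    if (sum(y[, "event"]) == 0) stop("cox outcome has zero events")
  }
  if (!is.null(n) && NROW(y) != n)
    stop("outcome length (", NROW(y), ") does not match sample count (", n, ")")
  y
}
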