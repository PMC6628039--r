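# Second-order Gaussian (model-X) knockoff construction.
#
# Knockoff copies X~ of the covariates X are sampled so that (X, X~) has,
# in population, the same second moments as an exchangeable pair:
#   E[X~] = mu,  cov(X~) = Sigma,  cov(X_i, X~_j) = Sigma_ij - s_j 1{i=j}.
# The knockoffs never see the outcome; they act as negative controls
# against which the importance of each original feature is calibrated.

#' Estimate a second-moment Gaussian model for the covariates
#'
#' Fits the mean vector and a shrunken, positive-definite covariance matrix
#' used to sample second-order Gaussian knockoffs.  Shrinkage operates on
#' the correlation scale: the sample correlation matrix is replaced by the
#' convex combination \eqn{(1-\gamma) R + \gamma I}, after which the minimum
#' eigenvalue is floored at `1e-6` times the mean diagonal of the covariance.
#' With `shrinkage = "auto"` the intensity is chosen analytically
#' (Ledoit-Wolf style, using the large-sample variance approximation
#' \eqn{(1-r^2)^2/n} for each off-diagonal correlation), which keeps the
#' estimate well-conditioned when p approaches or exceeds n.
#'
#' @param X numeric matrix, samples in rows.  Columns must be non-constant
#'   and free of missing values.
#' @param shrinkage shrinkage intensity in `[0, 1]`, or `"auto"`.
#' @return an object of class `gaussian_knockoff_model` with components
#'   `mean`, `covariance`, `s` (equicorrelated knockoff decorrelation
#'   vector, see [solve_equicorrelated_s()]) and `shrinkage` (the intensity
#'   used).
#' @seealso [sample_knockoffs()]
#' @export
estimate_gaussian_model <- function(X, shrinkage = "auto") {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 samples to estimate a covariance")
  if (anyNA(X)) stop("covariate matrix contains missing values")
  sdv <- apply(X, 2, sd)
  bad <- which(sdv < .Machine$double.eps^0.5)
  if (length(bad))
    stop("constant (zero-variance) column(s): ",
         paste(colname_or_index(X, bad), collapse = ", "))

  mu <- colMeans(X)
  S <- cov(X)
  D <- sqrt(diag(S))
  R <- S / tcrossprod(D)
  diag(R) <- 1

  if (identical(shrinkage, "auto")) {
    r2 <- R[upper.tri(R)]^2
    num <- sum((1 - r2)^2) / n
    den <- sum(r2)
    gamma <- if (den <= 0) 0 else min(1, max(0, num / den))
  } else {
    gamma <- as.numeric(shrinkage)
    if (is.na(gamma) || gamma < 0 || gamma > 1)
      stop("shrinkage must be in [0, 1] or \"auto\"")
  }
  Rsh <- (1 - gamma) * R
  diag(Rsh) <- 1

  # floor the spectrum so downstream solves are stable
  floor_val <- 1e-6 * mean(diag(S)) / mean(D^2)
  ev <- eigen(Rsh, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < floor_val) {
    bump <- floor_val - min(ev)
    Rsh <- (Rsh + bump * diag(p)) / (1 + bump)
  }
  Sigma <- Rsh * tcrossprod(D)

  s <- solve_equicorrelated_s(Sigma)
  structure(
    list(mean = mu, covariance = Sigma, s = s, shrinkage = gamma,
         feature_names = colnames(X)),
    class = "gaussian_knockoff_model"
  )
}

#' @export
print.gaussian_knockoff_model <- function(x, ...) {
  p <- length(x$mean)
  cat("Second-moment Gaussian knockoff model\n")
  cat(sprintf("  features: %d;  shrinkage intensity: %.4g\n", p, x$shrinkage))
  cat(sprintf("  s range: [%.4g, %.4g] (covariance scale)\n",
              min(x$s), max(x$s)))
  invisible(x)
}

#' Equicorrelated knockoff decorrelation vector
#'
#' Computes the vector `s` of the equicorrelated knockoff construction: on
#' the correlation scale every coordinate gets
#' \eqn{s_j = \min(1, 2 \lambda_{\min}(R))}, the largest common value for
#' which the joint covariance of the pair (X, X~) remains positive
#' semidefinite.  Larger `s` means knockoffs less correlated with their
#' originals and hence more selection power.  The result is rescaled to the
#' covariance scale (multiplied by `diag(Sigma)`), and clipped downward by
#' the factor `1 - 1e-5` (at most 10 times) until
#' \eqn{2\,\mathrm{diag}(s) - \mathrm{diag}(s) R^{-1} \mathrm{diag}(s)}
#' passes a Cholesky check.
#'
#' @param Sigma positive-definite covariance matrix.
#' @return numeric vector `s` on the covariance scale.
#' @export
solve_equicorrelated_s <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  p <- ncol(Sigma)
  D <- sqrt(diag(Sigma))
  R <- Sigma / tcrossprod(D)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (lam_min <= 0)
    stop("Sigma is not positive-definite; apply shrinkage first ",
         "(see estimate_gaussian_model)")
  s_corr <- rep(min(1, 2 * lam_min), p)

  Rinv <- chol2inv(chol(R))
  ok <- function(s) {
    C <- 2 * diag(s, p) - diag(s, p) %*% Rinv %*% diag(s, p)
    inherits(try(chol(C + 1e-12 * mean(diag(C)) * diag(p)), silent = TRUE),
             "matrix")
  }
  for (i in 0:10) {
    if (ok(s_corr)) break
    if (i == 10) stop("could not make the knockoff conditional covariance PSD")
    s_corr <- s_corr * (1 - 1e-5)
  }
  s_corr * D^2
}

#' Sample second-order Gaussian knockoff copies
#'
#' Draws one knockoff row per sample from the Gaussian conditional
#' distribution
#' \deqn{\tilde x \mid x \sim N\big(x - \mathrm{diag}(s)\Sigma^{-1}(x-\mu),\;
#'   2\,\mathrm{diag}(s) - \mathrm{diag}(s)\Sigma^{-1}\mathrm{diag}(s)\big),}
#' which guarantees the population moment identities of a knockoff pair.
#' The interface deliberately accepts no outcome: knockoffs must be
#' constructed blind to y, which is what makes them valid negative controls.
#'
#' @param X numeric matrix of original covariates.
#' @param model a [estimate_gaussian_model()] fit of matching dimension.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an object of class `augmented_design`: the n x 2p matrix
#'   `[X, X~]` with knockoff columns named `<feature>_ko`, plus the
#'   original/knockoff pairing (column j pairs with column j + p) and the
#'   seed used.
#' @export
sample_knockoffs <- function(X, model, seed) {
  X <- as.matrix(X)
  if (!inherits(model, "gaussian_knockoff_model"))
    stop("model must come from estimate_gaussian_model()")
  p <- ncol(X)
  if (length(model$mean) != p)
    stop("model dimension (", length(model$mean),
         ") does not match X (", p, " columns)")
  seed <- as.integer(seed)

  Sigma <- model$covariance
  s <- model$s
  Sinv_ds <- solve(Sigma, diag(s, p))          # Sigma^{-1} diag(s)
  C <- 2 * diag(s, p) - diag(s, p) %*% Sinv_ds # conditional covariance
  C <- (C + t(C)) / 2
  ch <- try(chol(C), silent = TRUE)
  if (inherits(ch, "try-error")) {
    # tolerate roundoff-level indefiniteness only
    ev <- eigen(C, symmetric = TRUE)
    tol <- 1e-10 * max(ev$values, 0)
    if (min(ev$values) < -tol)
      stop("knockoff conditional covariance is not PSD; ",
           "reduce s (see solve_equicorrelated_s)")
    vals <- pmax(ev$values, 0)
    ch <- diag(sqrt(vals)) %*% t(ev$vectors)   # C = t(ch) %*% ch
  }

  Xc <- sweep(X, 2, model$mean, "-")
  M <- X - Xc %*% Sinv_ds                      # conditional means
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Z <- matrix(rnorm(nrow(X) * p), nrow(X), p)
  Xk <- M + Z %*% ch

  nm <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(Xk) <- paste0(nm, "_ko")
  out <- cbind(X, Xk)
  colnames(out)[seq_len(p)] <- nm
  structure(
    list(values = out, p = p,
         pairing = cbind(original = seq_len(p), knockoff = seq_len(p) + p),
         knockoff_seed = seed),
    class = "augmented_design"
  )
}

#' @export
print.augmented_design <- function(x, ...) {
  cat(sprintf("Augmented knockoff design: %d samples x %d columns (p = %d pairs), seed %d\n",
              nrow(x$values), ncol(x$values), x$p, x$knockoff_seed))
  invisible(x)
}

#' @export
dim.augmented_design <- function(x) dim(x$values)

#' Write an augmented design to a TSV file
#'
#' @param design an `augmented_design`.
#' @param path output path; knockoff columns carry the `_ko` suffix.
#' @export
write_augmented_design <- function(design, path) {
  stopifnot(inherits(design, "augmented_design"))
  write.table(design$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a covariate matrix from a delimited text file
#'
#' Expects a header row of feature names and one sample per row.  The
#' delimiter is inferred from the file extension (`.csv` vs tab-separated
#' otherwise) unless given explicitly.
#'
#' @param path file path.
#' @param sample_ids logical; if `TRUE` the first column holds sample
#'   identifiers and becomes the rownames.
#' @param sep field separator; default inferred from the extension.
#' @return numeric matrix with feature names as colnames.
#' @export
read_covariates <- function(path, sample_ids = FALSE, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (sample_ids) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else rn <- NULL
  X <- as.matrix(df)
  if (!is.numeric(X))
    stop("non-numeric entries in covariate file ", path)
  if (!is.null(rn)) rownames(X) <- rn
  X
}
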