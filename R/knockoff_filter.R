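#' Knockoff filter for FDR-controlled variable selection
#'
#' The main entry point: selects features associated with an outcome while
#' controlling the false discovery rate at a target level `q`, using
#' model-X knockoffs as negative controls.  The pipeline is
#'
#' 1. standardize the covariates;
#' 2. estimate a second-moment Gaussian model ([estimate_gaussian_model()])
#'    and sample knockoff copies ([sample_knockoffs()]) -- outcome-blind;
#' 3. if the augmented design has more columns than samples, screen to the
#'    top `n_keep` columns by the nonlinear B-spline criterion
#'    ([nonlinear_screen()]);
#' 4. compute an antisymmetric importance statistic W: `"rrb"`
#'    (component-wise P-spline boosting, the recommended model-free
#'    default), `"lcd"` (cross-validated lasso coefficient difference) or
#'    `"drs"` (difference in R-squared under kernel ridge regression);
#' 5. select `{j : W_j >= tau}` at the knockoff(+) threshold for level `q`.
#'
#' No linearity assumption is made anywhere in the `"rrb"` path, which is
#' what lets the same call discover linear, nonlinear and survival
#' associations.
#'
#' @param X numeric covariate matrix (samples x features) with column
#'   names, or a path readable by [read_covariates()].
#' @param y outcome: numeric vector (`family = "gaussian"`; binary 0/1
#'   outcomes are handled through the same squared-error machinery) or a
#'   (time, event) pair / `survival::Surv` (`family = "cox"`).
#' @param q target FDR level in (0, 1); default 0.2.
#' @param statistic `"rrb"`, `"lcd"` or `"drs"`.
#' @param family `"gaussian"` or `"cox"` (`"drs"` requires gaussian).
#' @param variant `"knockoff_plus"` (offset 1, finite-sample guarantee;
#'   default) or `"knockoff"`.
#' @param seed integer seed controlling knockoff sampling and any CV fold
#'   assignment; a fixed seed makes the whole fit deterministic.
#' @param screen `TRUE` (screen whenever 2p > n, the default), `FALSE`
#'   (never), or an integer `n_keep`.
#' @param shrinkage covariance shrinkage, see [estimate_gaussian_model()].
#' @param mstop,nu boosting parameters for `statistic = "rrb"`.
#' @param n_folds CV folds for `statistic = "lcd"`.
#' @return object of class `knockoff_filter` with components `selected`
#'   (indices), `names`, `threshold`, `W` (the `knockoff_stats`),
#'   `screening` (or `NULL`), `q`, `variant`, `statistic`, `seed` and the
#'   fitted ingredients (`model`, and for RRB the `boosting` fit).
#'   Methods: [print.knockoff_filter()], [summary.knockoff_filter()],
#'   [coef.knockoff_filter()] (the W vector), [plot.knockoff_filter()].
#'
#' @examples
#' cfg <- simulation_config(n = 150, p = 40, k = 6, amplitudes = 2.5,
#'                          reps = 1, seed = 7)
#' dat <- simulate_dataset(cfg)
#' fit <- knockoff_filter(dat$X, dat$y, q = 0.2, seed = 7)
#' print(fit)
#' sort(dat$true_set)
#' @export
knockoff_filter <- function(X, y, q = 0.2,
                            statistic = c("rrb", "lcd", "drs"),
                            family = c("gaussian", "cox"),
                            variant = c("knockoff_plus", "knockoff"),
                            seed = 1, screen = TRUE, shrinkage = "auto",
                            mstop = 100, nu = 0.1, n_folds = 5) {
  statistic <- match.arg(statistic)
  family <- match.arg(family)
  variant <- match.arg(variant)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (is.character(X) && length(X) == 1) X <- read_covariates(X)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (statistic == "drs" && family != "gaussian")
    stop("the DRS statistic requires a gaussian-type outcome")
  y <- check_outcome(y, family, n)

  Xs <- standardize_columns(X)
  model <- estimate_gaussian_model(Xs, shrinkage = shrinkage)
  aug <- sample_knockoffs(Xs, model, seed = seed)

  m <- ncol(aug$values)
  screening <- NULL
  if (isTRUE(screen)) {
    n_keep <- if (m > n) n else m
  } else if (is.numeric(screen)) {
    n_keep <- min(as.integer(screen), m)
  } else n_keep <- m
  if (n_keep < m) {
    screening <- nonlinear_screen(aug, y, n_keep = n_keep, family = family)
    kept <- screening$kept_columns
  } else kept <- seq_len(m)
  design_kept <- aug$values[, kept, drop = FALSE]

  boosting <- NULL
  if (statistic == "rrb") {
    boosting <- fit_boosting(design_kept, y, family = family,
                             nu = nu, mstop = mstop)
    W <- rrb_statistic(boosting, aug$pairing, col_ids = kept)
  } else if (statistic == "lcd") {
    W <- lcd_statistic(design_kept, y, family = family, n_folds = n_folds,
                       seed = seed, pairing = aug$pairing, col_ids = kept)
  } else {
    W <- drs_statistic(design_kept, y, pairing = aug$pairing,
                       col_ids = kept)
  }
  names(W$w) <- colnames(X) %||% paste0("V", seq_len(p))

  sel <- knockoff_select(W, q, variant)
  structure(
    list(selected = sel$selected,
         names = (colnames(X) %||% paste0("V", seq_len(p)))[sel$selected],
         threshold = sel$threshold, W = W, screening = screening,
         q = q, variant = variant, statistic = toupper(statistic),
         family = family, seed = as.integer(seed), n = n, p = p,
         model = model, boosting = boosting, call = match.call()),
    class = "knockoff_filter"
  )
}

#' @export
print.knockoff_filter <- function(x, ...) {
  cat(sprintf("Knockoff filter (%s statistic, %s family, %s)\n",
              x$statistic, x$family, x$variant))
  cat(sprintf("  n = %d samples, p = %d features, q = %g, seed = %d\n",
              x$n, x$p, x$q, x$seed))
  if (!is.null(x$screening))
    cat(sprintf("  screened %d design columns down to %d\n",
                length(x$screening$scores),
                length(x$screening$kept_columns)))
  cat(sprintf("  threshold: %s\n",
              if (is.infinite(x$threshold)) "Inf (no selection)" else
                format(x$threshold, digits = 4)))
  cat(sprintf("  selected %d feature(s)", length(x$selected)))
  if (length(x$selected))
    cat(": ", paste(x$names, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Summarize a knockoff filter fit
#'
#' @param object a `knockoff_filter`.
#' @param ... unused.
#' @return data frame of all features with nonzero W (or all selected),
#'   ordered by decreasing W, with a `selected` flag.
#' @export
summary.knockoff_filter <- function(object, ...) {
  w <- object$W$w
  keep <- which(w != 0)
  df <- data.frame(feature = names(w)[keep], W = as.numeric(w[keep]),
                   selected = keep %in% object$selected)
  df <- df[order(-df$W), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(table = df, fit = object), class = "summary.knockoff_filter")
}

#' @export
print.summary.knockoff_filter <- function(x, ...) {
  print(x$fit)
  cat("\nFeatures with nonzero W (decreasing):\n")
  print(head(x$table, 20), row.names = FALSE)
  if (nrow(x$table) > 20)
    cat("  ... (", nrow(x$table) - 20, " more)\n", sep = "")
  invisible(x)
}

#' W statistics of a knockoff filter fit
#'
#' @param object a `knockoff_filter`.
#' @param ... unused.
#' @return named numeric vector of per-feature W statistics.
#' @export
coef.knockoff_filter <- function(object, ...) object$W$w

#' Plot the W statistics of a knockoff filter fit
#'
#' Features are plotted against their W statistic with the selection
#' threshold marked; selected features are highlighted.  Under the null,
#' W is symmetric about zero, so an excess of large positive values is the
#' visual signature of real signal.
#'
#' @param x a `knockoff_filter`.
#' @param ... passed to [plot()].
#' @export
plot.knockoff_filter <- function(x, ...) {
  w <- x$W$w
  plot(seq_along(w), w, pch = 16,
       col = ifelse(seq_along(w) %in% x$selected, 2, 1),
       xlab = "feature index", ylab = "W statistic",
       main = sprintf("%s knockoff statistics (q = %g)", x$statistic, x$q),
       ...)
  abline(h = 0, lty = 1, col = "grey")
  if (is.finite(x$threshold)) {
    abline(h = x$threshold, lty = 2, col = 2)
    abline(h = -x$threshold, lty = 3, col = 2)
  }
  invisible(x)
}
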