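#' l1-penalized logistic regression
#'
#' Minimizes `sum_j log(1 + exp(-y_j (x' f_j + c))) + lambda * sum_i
#' pen_i |x_i|` with an unpenalized intercept `c`, labels encoded internally
#' as +1 (positive/poor outcome) and -1. With `penalty = 1/W` this is the
#' adaptive form in which a larger penalty falls on features with a small
#' composite weight; solving the plain problem on the weighted matrix and
#' rescaling `z_i = W_i * x_i` attains the same optimum. The solver is
#' accelerated proximal gradient (FISTA) with backtracking and
#' soft-thresholding.
#'
#' @param X numeric matrix (samples x features), typically weighted z-scores.
#' @param y binary labels (0/1 or -1/+1); both classes must be present.
#' @param lambda regularization parameter, `>= 0`.
#' @param penalty optional per-feature penalty factors (default all 1).
#' @param tol relative-objective convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `l1_logistic_fit`: named `coefficients`,
#'   `intercept`, `lambda`, `objective`, `converged`, `support` (feature ids
#'   with `|x| > 1e-9`).
#' @export
fit_l1_logistic <- function(X, y, lambda, penalty = NULL,
                            tol = 1e-8, max_iter = 10000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in X", call. = FALSE)
  ypm <- encode_labels(y)
  if (length(unique(ypm)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0)
    stop("lambda must be >= 0", call. = FALSE)
  if (is.null(penalty)) penalty <- rep(1, ncol(X))
  stopifnot(length(penalty) == ncol(X), all(penalty >= 0))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- .l1_logistic_cpp(X, ypm, lambda, penalty, tol, as.integer(max_iter),
                          rep(0, ncol(X)), 0)
  coefs <- drop(fit$x)
  names(coefs) <- colnames(X)
  structure(list(coefficients = coefs, intercept = fit$intercept,
                 lambda = lambda, objective = fit$objective,
                 converged = fit$converged,
                 support = names(coefs)[abs(coefs) > ZERO_TOL]),
            class = "l1_logistic_fit")
}

#' @keywords internal
encode_labels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) return(ifelse(y == 1, 1, -1))
  if (all(y %in% c(-1, 1))) return(y)
  stop("labels must be 0/1 or -1/+1", call. = FALSE)
}

# objective of the adaptive problem, used by tests and the path machinery
#' @keywords internal
l1_objective <- function(X, y, x, intercept, lambda, penalty = NULL) {
  if (is.null(penalty)) penalty <- rep(1, ncol(X))
  eta <- drop(X %*% x) + intercept
  m <- -encode_labels(y) * eta
  loss <- sum(ifelse(m > 0, m + log1p(exp(-m)), log1p(exp(m))))
  loss + lambda * sum(penalty * abs(x))
}

#' Regularization grid from the closed-form lambda_max
#'
#' At the intercept-only fit the gradient of the logistic loss for feature i
#' is `sum_j f_ij (y'_j - pi)` with `y'` in 0/1 and `pi = n_pos/m`; the
#' smallest lambda whose solution is all-zero (the KKT boundary) is the
#' largest absolute gradient, divided by the feature's penalty factor. The
#' grid is log-spaced from `lambda_max` down to `ratio * lambda_max`.
#'
#' @inheritParams fit_l1_logistic
#' @param n_values grid length (default 10).
#' @param ratio smallest/largest lambda (default 0.01).
#' @return numeric vector, strictly decreasing, length `n_values`.
#' @export
lambda_grid <- function(X, y, n_values = 10L, ratio = 0.01, penalty = NULL) {
  X <- as.matrix(X)
  y01 <- (encode_labels(y) + 1) / 2
  g <- abs(drop(crossprod(X, y01 - mean(y01))))
  if (!is.null(penalty)) {
    stopifnot(length(penalty) == ncol(X))
    g <- ifelse(penalty > 0, g / penalty, 0)
  }
  lmax <- max(g)
  if (!(lmax > 0))
    stop("degenerate matrix: lambda_max is zero", call. = FALSE)
  # lmax times scale-free multipliers: rescaling X rescales the whole grid
  # exactly, which keeps the solver scale-equivariant (collapse-to-M0)
  lmax * exp(seq(0, log(ratio), length.out = n_values))
}

#' Stability selection over bootstraps and a lambda grid
#'
#' Repeatedly resamples the cohort (bootstrap with replacement at full size,
#' stratified by class, or Meinshausen-Buhlmann half-subsampling) and fits
#' the sparse logistic path over the lambda grid on each resample. One "run
#' of the algorithm" is one (bootstrap, lambda) fit; under the default rule
#' a feature's selection frequency is the fraction of all
#' `n_bootstraps * length(grid)` runs in which its coefficient is nonzero,
#' and the stable set contains the features selected in strictly more than
#' `threshold` of the runs. The alternative `"min_hits"` rule counts a
#' bootstrap as a selection when the feature is nonzero at at least
#' `min_lambda_hits` grid values and divides by `n_bootstraps`.
#'
#' @param X numeric matrix of (weighted) feature values.
#' @param y binary labels.
#' @param grid descending lambda values; computed by [lambda_grid()] on
#'   `(X, y)` when `NULL`.
#' @param n_bootstraps number of resamples (default 100).
#' @param threshold selection-frequency threshold; strict inequality
#'   (exactly 50% is not selected, default 0.5).
#' @param seed integer seed; the profile is fully reproducible from it.
#' @param selection_rule `"lambda_average"` (default) or `"min_hits"`, see
#'   above.
#' @param min_lambda_hits hit count for the `"min_hits"` rule (default 1).
#' @param subsample `FALSE` (default) for class-stratified full-size
#'   bootstrap; `TRUE` for half-subsampling without replacement.
#' @param n_lambda,lambda_ratio grid parameters when `grid` is `NULL`.
#' @param tol,max_iter solver controls for the inner fits.
#' @return object of class `stability_profile`: `frequency` (named, in
#'   \[0,1\]), `grid`, `n_bootstraps`, `threshold`, `selected`.
#' @export
stability_select <- function(X, y, grid = NULL, n_bootstraps = 100L,
                             threshold = 0.5, seed = NULL,
                             selection_rule = c("lambda_average", "min_hits"),
                             min_lambda_hits = 1L, subsample = FALSE,
                             n_lambda = 10L, lambda_ratio = 0.1,
                             tol = 1e-7, max_iter = 5000L) {
  selection_rule <- match.arg(selection_rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  ypm <- encode_labels(y)
  if (length(unique(ypm)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (is.null(grid)) grid <- lambda_grid(X, y, n_lambda, lambda_ratio)
  pos <- which(ypm > 0); neg <- which(ypm < 0)
  n_draw <- if (subsample)
    max(1L, floor(length(pos) / 2)) + max(1L, floor(length(neg) / 2))
  else length(ypm)
  idx <- with_seed(seed, {
    vapply(seq_len(n_bootstraps), function(b) {
      if (subsample)
        c(sample(pos, max(1L, floor(length(pos) / 2))),
          sample(neg, max(1L, floor(length(neg) / 2))))
      else
        c(sample(pos, length(pos), replace = TRUE),
          sample(neg, length(neg), replace = TRUE))
    }, integer(n_draw))
  })
  hits <- .stability_hits_cpp(X, ypm, grid, rep(1, ncol(X)), idx,
                              tol, as.integer(max_iter), ZERO_TOL)
  freq <- if (selection_rule == "lambda_average")
    rowSums(hits) / (n_bootstraps * length(grid))
  else rowSums(hits >= min_lambda_hits) / n_bootstraps
  names(freq) <- colnames(X)
  structure(list(frequency = freq, grid = grid,
                 n_bootstraps = n_bootstraps, threshold = threshold,
                 selection_rule = selection_rule,
                 selected = names(freq)[freq > threshold]),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "stability_profile: %d features, %d bootstraps, %d selected (> %.0f%%)\n",
    length(x$frequency), x$n_bootstraps, length(x$selected),
    100 * x$threshold))
  invisible(x)
}
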