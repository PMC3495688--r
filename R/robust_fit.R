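#' Robust line fit of shadow count on read count
#'
#' Fits s = alpha + beta * n by Huber M-estimation (iteratively reweighted
#' least squares, tuning constant 1.345 on the MAD residual scale), via
#' [MASS::rlm()]. Robustness matters because some points carry legitimate
#' shadows — genuinely distinct reads that happen to lie within the edit
#' neighborhood — whose counts do not scale with n; those points must not
#' drive the slope.
#'
#' When the bulk of the points lies exactly on a line the MAD residual scale
#' degenerates to zero and IRLS weights are undefined; in that case the fit
#' falls back to ordinary least squares restricted to the points with zero
#' residual, which reproduces the exact line regardless of how the remaining
#' (outlying) points are placed.
#'
#' @param n numeric vector of read counts (regressors), or a two-column
#'   matrix/data.frame of (n, s) pairs.
#' @param s numeric vector of shadow counts (response); omit if `n` holds both.
#' @param maxit,acc IRLS iteration cap and convergence tolerance on
#'   coefficients.
#' @return An object of class `robust_fit`: list with `intercept`, `slope`,
#'   `slope_se`, `n_points`, `converged`, `iterations`, `scale`, `fitted`,
#'   `residuals`, `weights`, and the data (`n`, `s`).
#' @examples
#' f <- fit_robust_line(1:100, 2 + 3 * (1:100))
#' coef(f)
#' @export
fit_robust_line <- function(n, s = NULL, maxit = 50, acc = 1e-8) {
  if (is.null(s)) {
    m <- as.matrix(n)
    stopifnot(ncol(m) == 2)
    s <- m[, 2]
    n <- m[, 1]
  }
  n <- as.numeric(n)
  s <- as.numeric(s)
  stopifnot(length(n) == length(s))
  if (length(n) < 3) stop("at least 3 points are required for a robust fit")
  if (length(unique(n)) < 2) stop("degenerate design: all read counts identical")

  ols <- lm(s ~ n)
  r <- resid(ols)
  sc <- mad(r)
  yscale <- max(abs(s), 1)
  if (sc < 1e-10 * yscale) {
    # Majority of points exactly on a line: refit OLS on the zero-residual set.
    on_line <- abs(r) <= 1e-9 * yscale
    fit <- if (all(on_line)) ols else lm(s ~ n, subset = on_line)
    # summary.lm warns about zero residual variance; that is exactly this case
    sm <- suppressWarnings(summary(fit)$coefficients)
    res_all <- s - (coef(fit)[1] + coef(fit)[2] * n)
    return(new_robust_fit(coef(fit)[1], coef(fit)[2],
                          slope_se = if (nrow(sm) > 1) sm[2, 2] else 0,
                          n_points = length(n), converged = TRUE, iterations = 0L,
                          scale = 0, fitted = coef(fit)[1] + coef(fit)[2] * n,
                          residuals = res_all,
                          weights = as.numeric(abs(res_all) <= 1e-9 * yscale),
                          n = n, s = s))
  }

  fit <- withCallingHandlers(
    MASS::rlm(s ~ n, psi = MASS::psi.huber, k = 1.345, scale.est = "MAD",
              maxit = maxit, acc = acc),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  new_robust_fit(coef(fit)[1], coef(fit)[2], slope_se = sm[2, 2],
                 n_points = length(n), converged = fit$converged,
                 iterations = length(fit$conv), scale = fit$s,
                 fitted = fitted(fit), residuals = resid(fit),
                 weights = fit$w, n = n, s = s)
}

new_robust_fit <- function(intercept, slope, slope_se, n_points, converged,
                           iterations, scale, fitted, residuals, weights, n, s) {
  structure(list(intercept = unname(intercept), slope = unname(slope),
                 slope_se = unname(slope_se), n_points = n_points,
                 converged = converged, iterations = iterations,
                 scale = unname(scale), fitted = unname(fitted),
                 residuals = unname(residuals), weights = unname(weights),
                 n = n, s = s),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("Robust line fit (Huber M-estimation):\n")
  cat(sprintf("  intercept %.6g   slope %.6g (SE %.3g)\n",
              x$intercept, x$slope, x$slope_se))
  cat(sprintf("  %d points, residual scale %.4g, %s after %d iterations\n",
              x$n_points, x$scale,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.robust_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.robust_fit <- function(object, ...) object$residuals

#' Slope to error rate transform
#'
#' The fitted slope beta is the number of additional error shadows per
#' additional correctly sequenced copy of a read, Delta e / Delta n. The
#' per-read error rate — errored reads over all reads — is then
#' Delta e / (Delta n + Delta e) = beta / (1 + beta).
#'
#' @param beta fitted slope (finite, != -1). Negative slopes, which can arise
#'   on essentially error-free data, are truncated to 0 with a warning.
#' @return Error rate in `[0, 1)`.
#' @examples
#' slope_to_error_rate(0.25)  # 0.2
#' @export
slope_to_error_rate <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1)
  if (!is.finite(beta)) stop("slope must be finite")
  if (beta == -1) stop("slope -1 has no defined error rate")
  if (beta < 0) {
    warning("negative fitted slope (", signif(beta, 3), ") truncated to 0")
    beta <- 0
  }
  beta / (1 + beta)
}

#' Delta-method standard error of the estimated error rate
#'
#' Propagates the slope standard error through the transform
#' `rate = beta/(1+beta)`: `SE(rate) = SE(beta) / (1 + beta)^2`. The robust
#' regression's own printed standard error lives on the slope scale; this is
#' the first-order approximation on the rate scale.
#'
#' @param fit a `robust_fit` object.
#' @return Nonnegative standard error.
#' @export
error_rate_se <- function(fit) {
  stopifnot(inherits(fit, "robust_fit"))
  beta <- max(fit$slope, 0)
  fit$slope_se / (1 + beta)^2
}
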