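# Storey pi0/pi1 estimation used for "true positive rate" enrichment
# summaries. pi1 = 1 - pi0 estimates the proportion of tests drawn from
# the alternative.

#' Estimate Storey's pi0 (and pi1 = 1 - pi0)
#'
#' pi0_hat(lambda) = #\{p > lambda\} / (m (1 - lambda)) over a tuning grid.
#' The `smoother` method fits a cubic smoothing spline (3 effective df) to
#' pi0_hat(lambda) and evaluates it at the largest lambda; `fixed` uses a
#' single lambda (default 0.5), for which the estimate has the closed form
#' #\{p > lambda\} / (m (1 - lambda)). `auto` (the default) uses the
#' smoother for m >= 500 and falls back to fixed for smaller inputs, where
#' the smoother is unstable.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @param lambda_grid tuning grid for the smoother (default 0.05..0.95 by
#'   0.05).
#' @param method "auto", "smoother" or "fixed".
#' @param lambda_fixed the single lambda for the fixed method.
#' @return object of class `pi1_estimate`: list with `pi0`, `pi1`,
#'   `lambda_grid`, `pi0_lambda`, `method`, `m`.
#' @export
estimate_pi0 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                         method = c("auto", "smoother", "fixed"),
                         lambda_fixed = 0.5) {
  method <- match.arg(method)
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) stopf("glucoMR_data_error", "no p-values supplied")
  if (any(p < 0 | p > 1)) {
    stopf("glucoMR_data_error", "p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (method == "auto") method <- if (m >= 500L) "smoother" else "fixed"
  if (method == "smoother" && m < 50L) {
    warning("fewer than 50 p-values; falling back to fixed lambda")
    method <- "fixed"
  }
  if (method == "fixed") {
    check_prob(lambda_fixed, "lambda_fixed")
    pi0 <- sum(p > lambda_fixed) / (m * (1 - lambda_fixed))
    grid <- lambda_fixed
    pi0_lambda <- pi0
  } else {
    grid <- sort(lambda_grid)
    pi0_lambda <- vapply(grid, function(l) sum(p > l) / (m * (1 - l)),
                         numeric(1))
    # cubic smoothing spline over the grid, evaluated at the largest
    # lambda -- the standard Storey smoother
    fit <- stats::smooth.spline(grid, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(grid))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda_grid = grid,
                 pi0_lambda = pi0_lambda, method = method, m = m),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("<pi1_estimate> pi1 = %.3f (pi0 = %.3f, method = %s, m = %d)\n",
              x$pi1, x$pi0, x$method, x$m))
  invisible(x)
}
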