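#' Construct a Hill-plus-shift fit object
#'
#' The model is \deqn{y(x) = \frac{A}{1 + (k_a/x)^n} + C,} so `y(0) = C`
#' (baseline), `y(Inf) = A + C` (asymptote), `y(ka) = A/2 + C`
#' (half-response), and `n` sets the steepness. `A` may be negative for a
#' decreasing response (mutation rate falling with repair induction).
#'
#' @param A amplitude (signed).
#' @param ka half-response concentration (> 0).
#' @param n Hill coefficient (> 0).
#' @param C baseline shift.
#' @param rss residual sum of squares of the fit (linear scale), if known.
#' @param scale `"linear"` or `"log"`, the scale the fit minimized on.
#' @param flags character vector of fit diagnostics.
#' @return object of class `hill_fit`.
#' @export
hill_fit <- function(A, ka, n, C, rss = NA_real_, scale = "linear",
                     flags = character(0)) {
  if (!is.na(ka) && ka <= 0) stop("'ka' must be positive")
  if (!is.na(n) && n <= 0) stop("'n' must be positive")
  structure(list(A = A, ka = ka, n = n, C = C, rss = rss,
                 scale = scale, flags = flags),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill-plus-shift fit: A =", format(x$A, digits = 3),
      " ka =", format(x$ka, digits = 3),
      " n =", format(x$n, digits = 3),
      " C =", format(x$C, digits = 3), "\n")
  if (is.finite(x$rss)) cat("  rss:", format(x$rss, digits = 3), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a Hill-plus-shift curve
#'
#' At `x = 0` the value is exactly `C` (the `(ka/x)^n` term diverges); the
#' curve is monotone in `x` with the sign of `A`.
#'
#' @param fit a [hill_fit()].
#' @param x non-negative concentration(s).
#' @return numeric vector of responses.
#' @examples
#' f <- hill_fit(A = 0.22, ka = 42, n = 1.6, C = 1.6e-3)
#' eval_hill(f, c(0, 42))  # C and A/2 + C
#' @export
eval_hill <- function(fit, x) {
  if (any(x < 0)) stop("'x' must be non-negative")
  y <- rep(fit$C, length(x))
  pos <- x > 0
  y[pos] <- fit$A / (1 + (fit$ka / x[pos])^fit$n) + fit$C
  y
}

#' Fit a Hill function plus shift by least squares
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of
#' `y = A/(1 + (ka/x)^n) + C`. For mutation-rate series (`kind = "rate"`)
#' the default objective is squared error of `ln y`, because rates span
#' orders of magnitude and linear-scale least squares would ignore the
#' low-rate regime; set `scale = "linear"` to match fits performed on the
#' raw scale. Starting values come from the data extremes: `C` from the
#' response at the smallest x, `A` from the signed range, `ka` from the x
#' nearest half-range, `n = 1`. Bounds keep `ka` in (0, 1e4] and `n` in
#' (0, 10].
#'
#' @param x non-negative concentrations (>= 4 distinct values).
#' @param y responses (positive when fitting on the log scale).
#' @param kind `"expression"` or `"rate"`; sets the default `scale`.
#' @param scale `"linear"` or `"log"` objective.
#' @param weights optional per-point weights (linear scale only).
#' @return a [hill_fit()] with `rss` (residual sum of squares on the fit
#'   scale). A constant series returns `A = 0`, `C = mean(y)` flagged
#'   `"degenerate"` (`ka`, `n` unidentifiable, set to `NA`).
#' @examples
#' truth <- hill_fit(A = 0.22, ka = 42, n = 1.6, C = 1.6e-3)
#' x <- c(0, 1, 2, 5, 10, 20, 42, 100, 200)
#' fit_hill(x, eval_hill(truth, x))
#' @export
fit_hill <- function(x, y, kind = c("expression", "rate"),
                     scale = NULL, weights = NULL) {
  kind <- match.arg(kind)
  if (is.null(scale)) scale <- if (kind == "rate") "log" else "linear"
  scale <- match.arg(scale, c("linear", "log"))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4)
    stop("at least 4 distinct x values are required to fit (A, ka, n, C)")
  if (any(x < 0)) stop("'x' must be non-negative")
  if (scale == "log" && any(y <= 0))
    stop("log-scale fitting requires positive y")

  if (sd(y) < 1e-12 * max(abs(mean(y)), 1e-300)) {
    return(hill_fit(A = 0, ka = NA_real_, n = NA_real_, C = mean(y),
                    rss = 0, scale = scale, flags = "degenerate"))
  }

  C0 <- y[which.min(x)]
  A0 <- y[which.max(x)] - C0
  if (A0 == 0) A0 <- diff(range(y))
  half <- C0 + A0 / 2
  xp <- x[x > 0]
  ka0 <- if (length(xp)) xp[which.min(abs(y[x > 0] - half))] else 1
  if (!is.finite(ka0) || ka0 <= 0) ka0 <- max(stats::median(xp), 1e-3)
  start <- c(A = A0, ka = ka0, n = 1, C = C0)
  lower <- c(-Inf, 1e-8, 1e-2, -Inf)
  upper <- c(Inf, 1e4, 10, Inf)

  resid_fun <- function(par) {
    f <- hill_fit(par[1], par[2], par[3], par[4])
    pred <- eval_hill(f, x)
    if (scale == "log") {
      if (any(pred <= 0)) return(rep(1e6, length(y)))
      log(pred) - log(y)
    } else if (is.null(weights)) pred - y else sqrt(weights) * (pred - y)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5) {
    best <- hill_fit(fit$par[1], fit$par[2], fit$par[3], fit$par[4],
                     rss = fit$deviance, scale = scale,
                     flags = "not_converged")
    stop("Hill fit did not converge (", fit$message,
         "); best iterate: A=", format(best$A), " ka=", format(best$ka),
         " n=", format(best$n), " C=", format(best$C))
  }
  flags <- character(0)
  if (fit$par[2] >= upper[2] * (1 - 1e-6) || fit$par[3] >= upper[3] * (1 - 1e-6))
    flags <- c(flags, "at_bound")
  hill_fit(unname(fit$par[1]), unname(fit$par[2]), unname(fit$par[3]),
           unname(fit$par[4]), rss = fit$deviance, scale = scale,
           flags = flags)
}

#' Compose expression and rate dose-response fits
#'
#' Pairs the fitted mean expression and fitted mutation rate at each
#' inducer concentration on a grid: the parametric curve of mutation rate
#' vs repair-protein expression. With an increasing expression fit
#' (`A > 0`) and a decreasing rate fit (`A < 0`) the returned rate is
#' monotone non-increasing in expression.
#'
#' @param expr_fit Hill fit of expression vs inducer.
#' @param rate_fit Hill fit of mutation rate vs inducer.
#' @param atc_grid ascending non-negative inducer concentrations.
#' @return data.frame with columns `inducer`, `expression`, `rate`.
#' @export
compose_rate_vs_expression <- function(expr_fit, rate_fit, atc_grid) {
  if (is.unsorted(atc_grid)) stop("'atc_grid' must be sorted ascending")
  data.frame(inducer = atc_grid,
             expression = eval_hill(expr_fit, atc_grid),
             rate = eval_hill(rate_fit, atc_grid))
}
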