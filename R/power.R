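#' Asymptotic relative efficiency of the Wilcoxon-Mann-Whitney test
#'
#' ARE of WMW relative to the two-sample t test, by parent distribution:
#' the distribution-free minimum 0.864, normal 3/pi, logistic pi^2/9,
#' Laplace 1.5.
#'
#' @param parent one of "min", "normal", "logistic", "laplace".
#' @return the ARE as a unitless scalar.
#' @export
wmw_are <- function(parent = c("normal", "min", "logistic", "laplace")) {
  parent <- match.arg(parent)
  switch(parent,
         min = 0.864,
         normal = 3 / pi,
         logistic = pi^2 / 9,
         laplace = 1.5)
}

#' Minimal detectable correlation (sensitivity analysis)
#'
#' Fisher-z approximation: the smallest population correlation a test of
#' H0: rho = 0 can detect at the given alpha and power is
#' r = tanh((z_crit + z_power) / sqrt(n - 3)).
#'
#' @param n sample size (>= 4).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @return A `sensitivity_result` with `minimal_detectable` on the r scale.
#' @examples
#' detectable_r(72)   # rounds to 0.4
#' detectable_r(296)  # rounds to 0.2
#' @export
detectable_r <- function(n, alpha = 0.05, power = 0.95, tails = 2) {
  check_sensitivity_query(alpha, power, tails)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  zc <- stats::qnorm(1 - alpha / tails)
  zp <- stats::qnorm(power)
  r <- tanh((zc + zp) / sqrt(n - 3))
  sensitivity_result(r, "correlation (Fisher z)",
                     list(n = n, alpha = alpha, power = power, tails = tails))
}

#' Minimal detectable Cohen's d for the Wilcoxon-Mann-Whitney test
#'
#' Normal-approximation two-sample sensitivity with ARE-deflated effective
#' sample sizes: d = (z_crit + z_power) * sqrt(1/n1' + 1/n2') with
#' ni' = ni * ARE(parent). `are` overrides the parent lookup (1 recovers the
#' plain t-test formula).
#'
#' @param n1,n2 group sizes (>= 4).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @param parent parent-distribution label for the ARE (see [wmw_are()]).
#' @param are optional explicit ARE, overriding `parent`.
#' @return A `sensitivity_result` with `minimal_detectable` on the d scale.
#' @export
detectable_d_wmw <- function(n1, n2, alpha = 0.05, power = 0.95, tails = 2,
                             parent = "normal", are = NULL) {
  check_sensitivity_query(alpha, power, tails)
  if (n1 < 4 || n2 < 4) stop("group sizes must be >= 4", call. = FALSE)
  eff <- if (is.null(are)) wmw_are(parent) else are
  zc <- stats::qnorm(1 - alpha / tails)
  zp <- stats::qnorm(power)
  d <- (zc + zp) * sqrt(1 / (n1 * eff) + 1 / (n2 * eff))
  sensitivity_result(d, sprintf("WMW normal approximation (ARE %.4f)", eff),
                     list(n1 = n1, n2 = n2, alpha = alpha, power = power,
                          tails = tails, parent = if (is.null(are)) parent else "custom"))
}

#' Minimal detectable f-squared for a multiple-regression F test
#'
#' The smallest Cohen's f^2 whose noncentral-F power (numerator df = number
#' of predictors, denominator df = n - k - 1, noncentrality lambda = f^2 * n)
#' reaches the requested power, solved by bisection to 1e-6.
#'
#' @param n sample size (> n_predictors + 1).
#' @param n_predictors number of predictors tested (numerator df).
#' @param alpha significance level.
#' @param power target power.
#' @return A `sensitivity_result` with `minimal_detectable` on the f^2 scale.
#' @export
detectable_f2 <- function(n, n_predictors, alpha = 0.05, power = 0.80) {
  check_sensitivity_query(alpha, power, tails = 2)
  if (n <= n_predictors + 1) stop("need n > n_predictors + 1", call. = FALSE)
  df1 <- n_predictors
  df2 <- n - n_predictors - 1
  crit <- stats::qf(1 - alpha, df1, df2)
  pow <- function(f2) 1 - stats::pf(crit, df1, df2, ncp = f2 * n)
  lo <- 0; hi <- 1
  while (pow(hi) < power) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pow(mid) < power) lo <- mid else hi <- mid
  }
  sensitivity_result((lo + hi) / 2, "regression F (noncentral)",
                     list(n = n, n_predictors = n_predictors, alpha = alpha,
                          power = power))
}

check_sensitivity_query <- function(alpha, power, tails) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
}

sensitivity_result <- function(value, method, query) {
  structure(list(minimal_detectable = value, method = method, query = query),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  q <- paste(names(x$query), unlist(x$query), sep = "=", collapse = ", ")
  cat(sprintf("minimal detectable effect %.4f [%s; %s]\n",
              x$minimal_detectable, x$method, q))
  invisible(x)
}
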