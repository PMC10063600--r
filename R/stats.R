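#' Spearman rank correlation with t-approximation p value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-tailed p value comes from the t approximation with n - 2 degrees
#' of freedom, the convention common statistical packages print for samples
#' of this size. Pairs with a missing value in either variable are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return A `correlation_result` list with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman needs >= 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("spearman undefined: a variable has zero rank variance", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(rho = rho, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g, n = %d\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Mann-Whitney U comparison with tie-corrected z
#'
#' U is reported as min(U1, U2), computed from mid-rank sums. z comes from
#' the normal approximation with the tie-corrected variance and no continuity
#' correction, and carries the sign of (mean rank of `a` - mean rank of `b`):
#' a negative z means `a` tends to rank lower. When every pooled value is
#' tied the variance is zero and z = 0, p = 1 by convention. With
#' `exact = TRUE` (tie-free data only) the two-tailed p is
#' min(1, 2 * P(U <= observed U)) from the exact null distribution.
#'
#' @param a,b numeric samples.
#' @param exact use the exact U distribution for p (requires no ties).
#' @return A `group_comparison` list with `U`, `z`, `p`, `n1`, `n2`, plus
#'   `r` and `d` filled by [effect_size_from_z()].
#' @export
mann_whitney <- function(a, b, exact = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)

  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  varU <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (varU <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U1 - n1 * n2 / 2) / sqrt(varU)
    p <- 2 * stats::pnorm(-abs(z))
  }
  if (exact) {
    if (tie_term > 0) stop("exact p requires tie-free data", call. = FALSE)
    p <- min(1, 2 * stats::pwilcox(U, n1, n2))
  }
  es <- effect_size_from_z(z, n1, n2)
  structure(list(U = U, z = z, p = p, n1 = n1, n2 = n2, r = es$r, d = es$d),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, z = %.2f, p = %.4g (n1 = %d, n2 = %d), r = %.3f, d = %.3f\n",
              x$U, x$z, x$p, x$n1, x$n2, x$r, x$d))
  invisible(x)
}

#' Convert a z statistic to effect sizes r and Cohen's d
#'
#' r = |z| / sqrt(n1 + n2) (the rank-biserial-scale effect magnitude) and
#' d = 2r / sqrt(1 - r^2), the standard r-to-d conversion. Both are reported
#' as magnitudes; the direction lives in the sign of z.
#'
#' @param z standard-normal deviate from a rank test.
#' @param n1,n2 group sizes.
#' @return list with `r` and `d`.
#' @export
effect_size_from_z <- function(z, n1, n2) {
  N <- n1 + n2
  if (N < 2L) stop("need n1 + n2 >= 2", call. = FALSE)
  r <- abs(z) / sqrt(N)
  if (r >= 1) stop("effect r >= 1: z is not a valid rank-test deviate for this N",
                   call. = FALSE)
  list(r = r, d = 2 * r / sqrt(1 - r^2))
}

#' Lilliefors-type Kolmogorov-Smirnov normality screen
#'
#' D is the supremum distance between the sample ECDF and the normal
#' distribution with the sample's estimated mean and SD. Because the
#' parameters are estimated, the classical KS null distribution does not
#' apply; the p value is calibrated by seeded Monte Carlo: `n_sim` standard
#' normal samples of the same size are drawn, D is recomputed with estimated
#' parameters for each, and p is the fraction at least as large as the
#' observed D (with the +1 continuity convention).
#'
#' @param x numeric sample, n >= 3.
#' @param n_sim Monte-Carlo replicates for the p value.
#' @param seed integer seed for the calibration draw.
#' @return A `normality_result` list with `D`, `p`, `n`.
#' @export
ks_normality <- function(x, n_sim = 2000, seed = 1L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("ks_normality needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("ks_normality undefined: zero variance", call. = FALSE)
  }
  D <- lilliefors_D(x)
  sims <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(seq_len(n_sim), function(i) lilliefors_D(stats::rnorm(n)), numeric(1))
  })
  p <- (sum(sims >= D) + 1) / (n_sim + 1)
  structure(list(D = D, p = p, n = n), class = "normality_result")
}

lilliefors_D <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Lilliefors KS: D = %.4f, Monte-Carlo p = %.4g, n = %d\n",
              x$D, x$p, x$n))
  invisible(x)
}

#' Multiple linear regression with bias-corrected bootstrap CIs
#'
#' Point estimates come from ordinary least squares on the full sample.
#' Confidence intervals come from a case-resampling bootstrap with the
#' bias-corrected (BC) percentile method: for each coefficient the bias
#' constant z0 = qnorm(fraction of bootstrap estimates below the full-sample
#' estimate) shifts the percentile endpoints to pnorm(2*z0 +/- z_(1-alpha/2)).
#' Rank-deficient resamples are redrawn (and counted). Classical t statistics
#' and two-tailed p values are reported per coefficient alongside the
#' semipartial correlation sr = t * sqrt(1 - R^2) / sqrt(df_res); a bootstrap
#' p (the smallest alpha at which the BC interval excludes 0) is also given.
#'
#' @param y numeric outcome.
#' @param predictors data frame or matrix of predictors (listwise-complete
#'   with y).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for resampling.
#' @param conf confidence level (default 0.95).
#' @return A `regression_table` list: `coef` data frame (term, B, ci_low,
#'   ci_high, t, p, p_boot, sr), `r2`, `adj_r2`, `n`, `n_boot`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_ols <- function(y, predictors, n_boot = 1000, seed = 1L,
                          conf = 0.95) {
  X0 <- as.data.frame(predictors)
  keep <- stats::complete.cases(y, X0)
  y <- y[keep]; X0 <- X0[keep, , drop = FALSE]
  n <- length(y)
  k <- ncol(X0)
  if (n <= k + 1) stop("need n > number of predictors + 1", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(X0))
  qr0 <- qr(X)
  if (qr0$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)

  fit <- stats::lm.fit(X, y)
  B <- fit$coefficients
  res <- fit$residuals
  df_res <- n - ncol(X)
  sigma2 <- sum(res^2) / df_res
  XtXinv <- chol2inv(qr.R(qr0))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- B / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  sr <- tval * sqrt(1 - r2) / sqrt(df_res)

  boots <- matrix(NA_real_, n_boot, ncol(X))
  n_redrawn <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    qb <- qr(Xb)
    if (qb$rank < ncol(X)) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    boots[b, ] <- qr.coef(qb, y[idx])
    b <- b + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- t(vapply(seq_len(ncol(X)), function(j) {
    bc_interval(boots[, j], B[j], zq)
  }, numeric(2)))
  p_boot <- vapply(seq_len(ncol(X)), function(j) {
    bc_boot_p(boots[, j], B[j])
  }, numeric(1))

  structure(list(
    coef = data.frame(term = colnames(X), B = unname(B),
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      t = unname(tval), p = unname(pval),
                      p_boot = p_boot, sr = unname(sr),
                      stringsAsFactors = FALSE, row.names = NULL),
    r2 = r2, adj_r2 = adjusted_r2(r2, n, k),
    n = n, n_boot = n_boot, seed = seed, n_redrawn = n_redrawn
  ), class = "regression_table")
}

# BC percentile interval: percentile endpoints shifted by the bias constant
# z0 (the normal quantile of the fraction of bootstrap draws below the
# full-sample estimate).
bc_interval <- function(draws, est, zq) {
  prop <- mean(draws < est)
  # all draws on one side of the estimate: fall back to plain percentiles
  if (prop <= 0 || prop >= 1) {
    return(unname(stats::quantile(draws, stats::pnorm(c(-zq, zq)), type = 6)))
  }
  z0 <- stats::qnorm(prop)
  probs <- stats::pnorm(c(2 * z0 - zq, 2 * z0 + zq))
  unname(stats::quantile(draws, probs, type = 6))
}

# smallest alpha at which the BC interval excludes zero
bc_boot_p <- function(draws, est) {
  prop <- mean(draws < est)
  z0 <- if (prop <= 0 || prop >= 1) 0 else stats::qnorm(prop)
  # fraction of the BC-adjusted distribution on the far side of 0
  pl <- mean(draws <= 0)
  if (pl <= 0 || pl >= 1) return(1 / (length(draws) + 1))
  # alpha solving the one-sided endpoint = 0, doubled
  zl <- stats::qnorm(pl)
  min(1, 2 * stats::pnorm(-abs(zl - 2 * z0)))
}

#' @export
print.regression_table <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrapped OLS (n = %d, %d resamples, seed %d)\n",
              x$n, x$n_boot, x$seed))
  print(format(x$coef, digits = digits), row.names = FALSE)
  cat(sprintf("R2 = %.3f, adj. R2 = %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' Semipartial correlation from a regression t statistic
#'
#' sr = t * sqrt(1 - R^2) / sqrt(df_res): the correlation between the outcome
#' and the unique part of one predictor, recoverable from the printed t, the
#' model R^2 and the residual degrees of freedom.
#'
#' @param t coefficient t statistic.
#' @param r2 model R squared, in \[0, 1).
#' @param df_res residual degrees of freedom (> 0).
#' @return semipartial (part) correlation.
#' @export
semipartial_from_t <- function(t, r2, df_res) {
  if (df_res <= 0) stop("df_res must be positive", call. = FALSE)
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)", call. = FALSE)
  t * sqrt(1 - r2) / sqrt(df_res)
}

#' Adjusted R squared
#'
#' 1 - (1 - R^2) * (n - 1) / (n - k - 1) for n observations and k predictors.
#'
#' @param r2 model R squared.
#' @param n number of observations (> k + 1).
#' @param k number of predictors.
#' @return adjusted R squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}
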