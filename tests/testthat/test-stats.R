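test_that("spearman matches hand values and the rank-then-Pearson oracle", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  expect_equal(spearman(1:4, c(1, 3, 2, 4))$rho, 0.8, tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:40) {
    n <- sample(5:15, 1)
    x <- sample(1:8, n, replace = TRUE)  # ties likely
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    s <- spearman(x, y)
    expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "zero rank variance")
  expect_error(spearman(1:2, 2:1), ">= 3")
})

test_that("spearman drops incomplete pairs", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, 1, 3, NA, 5)
  s <- spearman(x, y)
  expect_equal(s$n, 3)
  expect_equal(s$rho, cor(rank(c(1, 2, 5)), rank(c(2, 1, 5))), tolerance = 1e-12)
})

test_that("Mann-Whitney U and z follow the tie-corrected rank-sum convention", {
  # exchangeable samples: U = n1*n2/2, z = 0
  m0 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$U, 4.5)
  expect_equal(m0$z, 0)

  # complete separation on tiny samples: exact p by enumeration is 2/6
  m1 <- mann_whitney(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(m1$U, 0)
  expect_equal(m1$p, 1 / 3, tolerance = 1e-12)

  # all pooled values tied: zero variance -> z = 0, p = 1
  mt <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(mt$z, 0)
  expect_equal(mt$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("U matches brute-force pair counting and U1 + U2 = n1*n2", {
  set.seed(31)
  for (rep in 1:60) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    a <- sample(1:6, n1, replace = TRUE)
    b <- sample(1:6, n2, replace = TRUE)
    m <- mann_whitney(a, b)
    expect_equal(m$U, brute_force_U(a, b))
    expect_lte(m$U, n1 * n2 / 2)  # reported U is min(U1, U2)
    # invariance under a strictly monotone transform of the pooled data
    m2 <- mann_whitney(exp(a / 2), exp(b / 2))
    expect_equal(m2$U, m$U)
    expect_equal(m2$z, m$z, tolerance = 1e-12)
  }
})

test_that("z carries the sign of group 1's rank advantage", {
  lo <- c(1, 2, 3, 4); hi <- c(5, 6, 7, 8)
  expect_lt(mann_whitney(lo, hi)$z, 0)
  expect_gt(mann_whitney(hi, lo)$z, 0)
})

test_that("normal-approximation and exact p agree in rejection decision", {
  set.seed(41)
  agree <- 0; total <- 0; disagreements <- character(0)
  for (rep in 1:150) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = sample(c(0, 1.5), 1))
    p_approx <- mann_whitney(a, b)$p
    p_exact <- enumerate_exact_p(a, b)
    total <- total + 1
    if ((p_approx < 0.05) == (p_exact < 0.05)) agree <- agree + 1
    else disagreements <- c(disagreements,
                            sprintf("n1=%d n2=%d approx=%.3f exact=%.3f",
                                    n1, n2, p_approx, p_exact))
  }
  if (length(disagreements)) message("rejection disagreements: ",
                                     paste(disagreements, collapse = "; "))
  expect_gte(agree / total, 0.95)
})

test_that("z-to-d conversion is null at z = 0 and errors on impossible r", {
  es <- effect_size_from_z(0, 10, 10)
  expect_equal(es$r, 0)
  expect_equal(es$d, 0)
  expect_error(effect_size_from_z(5, 2, 2), "r >= 1")
})

test_that("Lilliefors D matches a hand ECDF maximisation and nortest", {
  # x = (-1, 0, 1): fitted mean 0, sd 1; max gap at x = -1: 1/3 - pnorm(-1)
  r <- ks_normality(c(-1, 0, 1), n_sim = 50, seed = 1)
  expect_equal(r$D, 1 / 3 - pnorm(-1), tolerance = 1e-9)

  set.seed(51)
  x <- rnorm(40)
  expect_equal(ks_normality(x, n_sim = 50, seed = 1)$D,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-9)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
})

test_that("Monte-Carlo normality p is calibrated under the null and powerful for skew", {
  # null calibration: rejection rate near alpha
  set.seed(61)
  rej <- vapply(1:200, function(i) {
    ks_normality(rnorm(50), n_sim = 400, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)

  # strongly right-skewed samples are rejected essentially always
  set.seed(62)
  small_p <- vapply(1:20, function(i) {
    ks_normality(rexp(200), n_sim = 1000, seed = i)$p < 0.01
  }, logical(1))
  expect_gte(mean(small_p), 0.95)
})

test_that("bootstrap OLS recovers exact and simulated generating models", {
  # perfect linear fit: B = 2, R2 = 1, interval collapses
  x <- 1:20
  fit <- bootstrap_ols(2 * x, data.frame(x = x), n_boot = 200, seed = 3)
  expect_equal(fit$coef$B[2], 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$coef$ci_high[2] - fit$coef$ci_low[2], 1e-8)

  # known generating slope is covered in the vast majority of draws
  covered <- vapply(1:10, function(s) {
    set.seed(700 + s)
    x <- rnorm(500); y <- 1 + 0.5 * x + rnorm(500)
    f <- bootstrap_ols(y, data.frame(x = x), n_boot = 400, seed = s)
    f$coef$ci_low[2] < 0.5 && f$coef$ci_high[2] > 0.5
  }, logical(1))
  expect_gte(sum(covered), 8)

  set.seed(71)
  x <- rnorm(500); y <- 1 + 0.5 * x + rnorm(500)
  fit2 <- bootstrap_ols(y, data.frame(x = x), n_boot = 500, seed = 5)
  expect_equal(fit2$coef$sr,
               fit2$coef$t * sqrt(1 - fit2$r2) / sqrt(500 - 2),
               tolerance = 1e-12)

  # determinism: same seed, identical intervals
  fit3 <- bootstrap_ols(y, data.frame(x = x), n_boot = 500, seed = 5)
  expect_identical(fit2$coef, fit3$coef)

  expect_error(bootstrap_ols(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "rank deficient")
})

test_that("classical t/p match summary.lm on a multi-predictor fit", {
  set.seed(81)
  X <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- 1 + 0.3 * X$a - 0.2 * X$c + rnorm(60)
  fit <- bootstrap_ols(y, X, n_boot = 50, seed = 1)
  ref <- summary(lm(y ~ a + b + c, data = X))
  expect_equal(fit$coef$t, unname(ref$coefficients[, "t value"]), tolerance = 1e-9)
  expect_equal(fit$coef$p, unname(ref$coefficients[, "Pr(>|t|)"]), tolerance = 1e-9)
  expect_equal(fit$r2, ref$r.squared, tolerance = 1e-12)
  expect_equal(fit$adj_r2, ref$adj.r.squared, tolerance = 1e-12)
})

test_that("semipartial and adjusted R2 helpers follow their formulas", {
  expect_equal(semipartial_from_t(0, 0.3, 100), 0)
  expect_equal(semipartial_from_t(2, 0.19, 81), 2 * 0.9 / 9, tolerance = 1e-12)
  expect_error(semipartial_from_t(1, 1, 10), "r2")
  expect_equal(adjusted_r2(1, 100, 3), 1)
  expect_equal(adjusted_r2(0.5, 12, 2), 1 - 0.5 * 11 / 9, tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 4, 3), "n > k")
})
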