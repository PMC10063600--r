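test_that("TAS-20 scoring reproduces hand-computed totals and subscales", {
  # 3 is the fixed point of the reverse map, so no item moves
  s <- score_tas(rep(3, 20))
  expect_equal(s$total, 60)
  expect_equal(s$dif, 21)
  expect_equal(s$ddf, 15)
  expect_equal(s$eot, 24)

  # all 5s: the five reverse-keyed items (4,5,10,18,19) map to 1
  s5 <- score_tas(rep(5, 20))
  expect_equal(s5$total, 80)
  expect_equal(s5$dif, 35)   # no DIF item is reverse-keyed
  expect_equal(s5$ddf, 21)   # item 4 reversed: 4*5 + 1
  expect_equal(s5$eot, 24)   # items 5,10,18,19 reversed: 4*5 + 4*1
})

test_that("TAS scoring rejects out-of-range and incomplete input, naming the item", {
  items <- rep(3, 20); items[7] <- 0
  expect_error(score_tas(items), "item 7")
  expect_error(score_tas(rep(3, 19)), "expected 20")
  items[7] <- 2.5
  expect_error(score_tas(items), "item 7")
})

test_that("subscale additivity and reversal involution hold for random items", {
  set.seed(42)
  for (rep in 1:50) {
    items <- sample(1:5, 20, replace = TRUE)
    s <- score_tas(items)
    expect_equal(s$total, s$dif + s$ddf + s$eot)
    expect_true(s$total >= 20 && s$total <= 100)
    expect_true(s$dif >= 7 && s$dif <= 35)
    expect_true(s$ddf >= 5 && s$ddf <= 25)
    expect_true(s$eot >= 8 && s$eot <= 40)
    expect_identical(reverse_items(reverse_items(items)), items)
  }
})

test_that("AI and CRT scoring follow their keyed-sum definitions", {
  expect_equal(score_ai(rep(1, 5)), 5)
  expect_equal(score_ai(rep(4, 5)), 20)
  expect_equal(score_ai(c(1, 4, 2, 3, 1), reverse = 2), 8)
  expect_error(score_ai(c(1, 1, 1, 1, 5)), "item 5")
  expect_equal(score_crt(c(TRUE, FALSE, TRUE)), 2)
  expect_equal(score_crt(c(1, 1, 1)), 3)
  expect_equal(score_crt(c(0, 0, 0)), 0)
  expect_error(score_crt(c(TRUE, FALSE)), "expected 3")
})

test_that("Cronbach's alpha matches the variance-ratio formula", {
  # two parallel items (perfectly correlated, equal variance) attain the bound
  m <- cbind(1:6, (1:6) + 3)
  expect_equal(cronbach_alpha(m)$alpha, 1)

  # hand computation: k=2, item vars 1 and 1/3, total var 7/3
  m2 <- matrix(c(1, 1, 2, 1, 3, 2), ncol = 2, byrow = TRUE)
  expect_equal(cronbach_alpha(m2)$alpha, 6 / 7, tolerance = 1e-12)

  expect_error(cronbach_alpha(matrix(1:5, ncol = 1)), "2 items")
  expect_error(cronbach_alpha(matrix(c(1, 2, 2, 1), 2)), "zero total-score variance")
})

test_that("alpha is invariant to adding a constant to every response", {
  set.seed(7)
  m <- matrix(sample(1:5, 60, replace = TRUE), ncol = 6)
  a0 <- cronbach_alpha(m)$alpha
  expect_equal(cronbach_alpha(m + 3)$alpha, a0, tolerance = 1e-12)
})

test_that("alpha on dichotomous items equals KR-20", {
  set.seed(11)
  m <- matrix(rbinom(90, 1, 0.5), ncol = 3)
  k <- ncol(m); n <- nrow(m)
  pq <- colMeans(m) * (1 - colMeans(m)) * n / (n - 1)  # sample item variances
  kr20 <- k / (k - 1) * (1 - sum(pq) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m)$alpha, kr20, tolerance = 1e-12)
})

test_that("attention filter reproduces the exclusion bookkeeping", {
  mk <- function(n, fail_idx) {
    data.frame(pid = sprintf("P%03d", 1:n),
               attn = replace(rep(5, n), fail_idx, 2))
  }
  # 151 records, 3 failures -> 148 retained
  f1 <- filter_attention(mk(151, c(5, 60, 150)))
  expect_equal(nrow(f1$cohort), 148)
  expect_equal(nrow(f1$log), 3)
  expect_true(all(f1$log$reason == "attention_check_failed"))

  # 301 records, 4 failures + 1 manual exclusion -> 296 retained
  f2 <- filter_attention(mk(301, c(2, 30, 200, 301)),
                         manual_exclusions = "P100")
  expect_equal(nrow(f2$cohort), 296)
  expect_setequal(f2$log$reason,
                  c("attention_check_failed", "manual_exclusion"))

  # zero failures: identity
  f3 <- filter_attention(mk(10, integer(0)))
  expect_identical(f3$cohort, mk(10, integer(0)))
  expect_equal(nrow(f3$log), 0)
})

test_that("group assignment uses strict cutoffs and partitions every total", {
  expect_equal(as.character(assign_group(61)), "high")
  expect_equal(as.character(assign_group(51)), "low")
  expect_equal(as.character(assign_group(52)), "unclassified")
  expect_equal(as.character(assign_group(60)), "unclassified")
  g <- assign_group(20:100)
  expect_false(anyNA(g))
  expect_equal(sum(g == "high"), 40)         # 61..100
  expect_equal(sum(g == "low"), 32)          # 20..51
  expect_equal(sum(g == "unclassified"), 9)  # 52..60
})
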