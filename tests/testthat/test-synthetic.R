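test_that("cohort generation is deterministic and prefix-stable in n", {
  g1 <- generate_cohort(tiny_config(n = 40, seed = 5))
  g2 <- generate_cohort(tiny_config(n = 40, seed = 5))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$participants, g2$truth$participants)

  # per-participant streams: growing the cohort never reshuffles the prefix
  g3 <- generate_cohort(tiny_config(n = 80, seed = 5))
  expect_identical(g1$cohort, g3$cohort[1:40, , drop = FALSE])

  g4 <- generate_cohort(tiny_config(n = 40, seed = 6))
  expect_false(identical(g1$cohort, g4$cohort))
})

test_that("exactly the configured number of attention failures is injected", {
  g <- generate_cohort(tiny_config(n = 151, seed = 9,
                                   n_attention_failures = 3))
  expect_equal(sum(g$cohort$attn != 5), 3)
  expect_true(all(g$cohort$attn %in% 1:5))
  g0 <- generate_cohort(tiny_config(n = 25, seed = 9))
  expect_true(all(g0$cohort$attn == 5))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(-1), "n_participants")
  expect_error(cohort_config(10, n_attention_failures = 11), "n_attention_failures")
  expect_error(cohort_config(10, rating_scale_max = 0), "rating_scale_max")
  expect_error(cohort_config(10, target_tas_mean = 110), "target_tas_mean")
  expect_error(cohort_config(10, tas_ai_rho = 1.2), "tas_ai_rho")
  expect_error(cohort_config(10, conditions = "both"), "conditions")
  expect_error(cohort_config(10, base_offtarget_rating = 80), "base_target_rating")
})

test_that("rating blocks have the design's shape and base profile", {
  cfg <- tiny_config(n = 5)
  b <- generate_rating_block(0.3, cfg, stream_seed = 77)
  expect_equal(dim(b), c(12, 4))
  expect_equal(table(attr(b, "target_category")),
               table(rep(c("fear", "anger", "disgust", "sadness"), each = 3)))

  # noise-free, fully decoupled: every picture equals the fixed base profile
  cfg0 <- tiny_config(n = 5, trait_coupling = 0, rating_noise_sd = 0,
                      crt_diff_rho = 0)
  b0 <- generate_rating_block(1.7, cfg0, stream_seed = 1)
  cats <- rep(1:4, each = 3)
  for (i in 1:12) {
    expect_equal(unname(b0[i, cats[i]]), 75)
    off <- b0[i, -cats[i]]
    expect_true(all(off == off[1]))
    expect_lt(off[1], 75)
  }
  # same base profile regardless of trait when decoupled
  expect_identical(unclass(b0), unclass(generate_rating_block(-2.4, cfg0, 1)),
                   ignore_attr = TRUE)
})

test_that("high trait blunts the rating profile under positive coupling", {
  cfg <- tiny_config(n = 5, trait_coupling = 1.5)
  d_low <- differentiation_index(generate_rating_block(-3, cfg, 42))$index
  d_high <- differentiation_index(generate_rating_block(3, cfg, 42))$index
  expect_lt(d_high, d_low)
})

test_that("generated values never leave their declared ranges", {
  set.seed(91)
  for (rep in 1:5) {
    smax <- sample(c(10, 100), 1)
    cfg <- cohort_config(n_participants = 25,
                         n_categories = sample(2:5, 1),
                         pictures_per_category = sample(1:4, 1),
                         rating_scale_max = smax,
                         base_target_rating = 0.75 * smax,
                         base_offtarget_rating = 0.1 * smax,
                         trait_coupling = runif(1, 0, 3),
                         rating_noise_sd = runif(1, 0, 40),
                         target_tas_mean = runif(1, 30, 70),
                         n_attention_failures = sample(0:5, 1),
                         master_seed = sample.int(1000, 1))
    g <- generate_cohort(cfg)$cohort
    tas <- as.matrix(g[paste0("tas_", 1:20)])
    expect_true(all(tas >= 1 & tas <= 5 & tas == round(tas)))
    expect_true(all(g$attn %in% 1:5))
    ai <- as.matrix(g[paste0("ai_", 1:5)])
    expect_true(all(ai >= 1 & ai <= 4))
    crt <- as.matrix(g[paste0("crt_", 1:3)])
    expect_true(all(crt %in% c(0, 1)))
    ratings <- as.matrix(g[grep("^rating_", names(g))])
    expect_true(all(ratings >= 0 & ratings <= cfg$rating_scale_max))
  }
})

test_that("mean differentiation decreases across trait quartiles when coupled", {
  g <- generate_cohort(tiny_config(n = 1200, seed = 13, trait_coupling = 1))
  d <- cohort_differentiation(g$cohort)$diff_index
  q <- cut(g$truth$participants$trait,
           quantile(g$truth$participants$trait, probs = seq(0, 1, 0.25)),
           include.lowest = TRUE)
  means <- tapply(d, q, mean)
  expect_true(all(diff(means) < 0))
})

test_that("cohort moments track the configured targets", {
  g <- generate_cohort(tiny_config(n = 3000, seed = 17))
  sc <- score_cohort_tas(g$cohort)
  expect_lt(abs(mean(sc$tas_total) - 45), 2)
  expect_gt(sd(sc$tas_total), 11.5)
  expect_lt(sd(sc$tas_total), 14.5)
  d <- cohort_differentiation(g$cohort)$diff_index
  expect_lt(abs(spearman(sc$tas_total, sc$ai_total)$rho - 0.5), 0.05)
  expect_lt(abs(spearman(sc$tas_total, sc$crt_total)$rho), 0.06)
  expect_lt(abs(spearman(sc$crt_total, d)$rho - 0.17), 0.05)
})
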