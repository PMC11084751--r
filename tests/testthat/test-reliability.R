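make_table <- function(ids, ...) {
  vals <- list(...)
  df <- data.frame(image_id = ids, stringsAsFactors = FALSE)
  for (v in names(vals)) df[[v]] <- vals[[v]]
  df
}

test_that("paired_errors matches on image_id and counts exclusions", {
  t1 <- make_table(c("a", "b", "c", "d"), ARA = c(10, 12, 14, 16))
  es <- paired_errors(t1, t1, "ARA")
  expect_equal(es$errors, rep(0, 4))
  expect_equal(es$n_pairs, 4)
  expect_equal(es$n_excluded, 0)

  t2 <- t1
  t2$ARA[2] <- NA
  es2 <- paired_errors(t1, t2, "ARA")
  expect_equal(es2$n_pairs, 3)
  expect_equal(es2$n_excluded, 1)

  # shuffled rows give the same series (id-matched, not positional)
  t3 <- t1[c(3, 1, 4, 2), ]
  es3 <- paired_errors(t1, t3, "ARA")
  expect_equal(es3$errors[order(es3$image_ids)],
               es$errors[order(es$image_ids)])
  expect_equal(sort(es3$image_ids), sort(es$image_ids))

  expect_error(paired_errors(t1, make_table("a", ARA = 1), "ARA"),
               class = "cervimetrics_insufficient_data")
})

test_that("error_summary computes RMSE/SD with the exact decomposition", {
  t1 <- make_table(c("a", "b"), V = c(3, 0))
  t2 <- make_table(c("a", "b"), V = c(0, 4))
  es <- paired_errors(t1, t2, "V")   # errors 3, -4
  sm <- error_summary(es)
  expect_equal(sm$rmse, sqrt(12.5))
  expect_equal(sm$mean_signed_err, -0.5)
  expect_equal(sm$mean_abs_err, 3.5)

  # constant errors: rmse = |c|, sd = 0
  tc1 <- make_table(letters[1:5], V = 1:5)
  tc2 <- make_table(letters[1:5], V = 1:5 - 2.5)
  smc <- error_summary(paired_errors(tc1, tc2, "V"))
  expect_equal(smc$rmse, 2.5)
  expect_equal(smc$std_err, 0)

  # rmse^2 = mean^2 + ((n-1)/n) sd^2 on random series
  for (i in 1:25) {
    e <- with_seed_helper(i, stats::rnorm(20, 1, 3))
    ta <- make_table(as.character(1:20), V = e)
    tb <- make_table(as.character(1:20), V = rep(0, 20))
    sm <- error_summary(paired_errors(ta, tb, "V"))
    n <- 20
    expect_equal(sm$rmse^2,
                 sm$mean_signed_err^2 + (n - 1) / n * sm$std_err^2,
                 tolerance = 1e-9)
  }
})

test_that("ICC mean squares match a two-way ANOVA oracle", {
  for (i in 1:20) {
    x1 <- with_seed_helper(i, stats::rnorm(30, 10, 3))
    x2 <- x1 + with_seed_helper(i + 100, stats::rnorm(30, 0.5, 1))
    # oracle: mean squares from base aov on the long layout
    long <- data.frame(y = c(x1, x2),
                       subj = factor(rep(1:30, 2)),
                       rater = factor(rep(1:2, each = 30)))
    tab <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]
    rn <- trimws(rownames(tab))
    msr <- tab[rn == "subj", "Mean Sq"]
    msc <- tab[rn == "rater", "Mean Sq"]
    mse <- tab[rn == "Residuals", "Mean Sq"]
    n <- 30; k <- 2
    oracle_a1 <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    oracle_c1 <- (msr - mse) / (msr + (k - 1) * mse)
    expect_equal(icc(x1, x2)$estimate, oracle_a1, tolerance = 1e-9)
    expect_equal(icc(x1, x2, "two_way_mixed_consistency")$estimate,
                 oracle_c1, tolerance = 1e-9)
  }
})

test_that("ICC hand fixtures and degenerate cases", {
  x <- c(4, 9, 2, 7, 11)
  r <- icc(x, x)
  expect_equal(r$estimate, 1)

  # hand mean squares: (1,2,3) vs (2,3,4) -> agreement 2/3, consistency 1
  r2 <- icc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$estimate, 2 / 3, tolerance = 1e-12)
  r3 <- icc(c(1, 2, 3), c(2, 3, 4), "two_way_mixed_consistency")
  expect_equal(r3$estimate, 1)

  expect_error(icc(rep(1, 5), rep(1, 5)),
               class = "cervimetrics_undefined_statistic")
  expect_error(icc(c(1, 2), c(1, 2)),
               class = "cervimetrics_insufficient_data")
})

test_that("ICC(2,1) is affine-invariant jointly, offset-sensitive singly", {
  x1 <- with_seed_helper(11, stats::rnorm(40, 20, 5))
  x2 <- x1 + with_seed_helper(12, stats::rnorm(40, 0, 2))
  base_a <- icc(x1, x2)$estimate
  base_c <- icc(x1, x2, "two_way_mixed_consistency")$estimate

  # common affine rescaling of both trials
  expect_equal(icc(3 * x1 - 7, 3 * x2 - 7)$estimate, base_a,
               tolerance = 1e-9)

  # constant offset on one trial lowers agreement but not consistency
  off_a <- icc(x1, x2 + 4)$estimate
  off_c <- icc(x1, x2 + 4, "two_way_mixed_consistency")$estimate
  expect_lt(off_a, base_a)
  expect_equal(off_c, base_c, tolerance = 1e-9)
})

test_that("ICC estimate recovers the variance ratio in simulation", {
  # tau^2 = 9, sigma^2 = 1 -> true ICC = 0.9; modest replicate count here,
  # the full-scale recovery experiment lives in the acceptance suite
  est <- with_seed_helper(2024, replicate(50, {
    mu <- stats::rnorm(100, 0, 3)
    icc(mu + stats::rnorm(100), mu + stats::rnorm(100))$estimate
  }))
  expect_lt(abs(mean(est) - 0.9), 0.03)

  # CI brackets the truth most of the time and is ordered
  one <- with_seed_helper(7, {
    mu <- stats::rnorm(200, 0, 3)
    icc(mu + stats::rnorm(200), mu + stats::rnorm(200))
  })
  expect_lt(one$ci_low, one$estimate)
  expect_gt(one$ci_high, one$estimate)
})

test_that("r_squared equals the OLS coefficient of determination", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(r_squared(x, 2 * x + 3), 1)
  expect_equal(r_squared(x, x), 1)

  # orthogonal construction: exactly zero sample correlation
  a <- c(-1, 0, 1, 0)
  b <- c(0, 1, 0, -1)
  expect_equal(r_squared(a, b), 0)

  for (i in 1:20) {
    x1 <- with_seed_helper(i, stats::rnorm(25))
    x2 <- 0.5 * x1 + with_seed_helper(i + 50, stats::rnorm(25, 0, 0.7))
    oracle <- summary(stats::lm(x2 ~ x1))$r.squared
    expect_equal(r_squared(x1, x2), oracle, tolerance = 1e-12)
    expect_equal(r_squared(x1, x2), r_squared(x2, x1), tolerance = 1e-12)
  }

  expect_error(r_squared(rep(2, 5), 1:5),
               class = "cervimetrics_undefined_statistic")
})

test_that("R-squared bands and effect-size labels", {
  expect_equal(classify_r2(0.93), "super-clean")
  expect_equal(classify_r2(0.86), "clean")
  expect_equal(classify_r2(0.64), "semi-clean")
  expect_equal(classify_r2(0.3), "unreliable")
  expect_equal(classify_r2(c(0.90, 0.75, 0.50, 0.499)),
               c("super-clean", "clean", "semi-clean", "unreliable"))
  expect_error(classify_r2(1.2), class = "cervimetrics_validation_error")

  expect_equal(effect_size_label(1.0), "perfect")
  expect_equal(effect_size_label(0.6), "moderate")
  expect_equal(effect_size_label(0.29), "none/very-weak")
  expect_equal(effect_size_label(c(0.7, 0.3, 0.5)),
               c("strong", "weak", "moderate"))
  expect_error(effect_size_label(-0.1),
               class = "cervimetrics_validation_error")
})

test_that("reliability_report produces one row per variable with strata partition", {
  cfg <- generator_config(n_images = 24, seed = 5)
  sim <- simulate_study(cfg, noise_model(sigma = 0.2))
  m1 <- measure_study(sim$trials$US1)
  m2 <- measure_study(sim$trials$US2)

  rep0 <- reliability_report(m1, m2, "US vs US")
  expect_equal(nrow(rep0), 18)
  expect_setequal(rep0$variable,
                  c("ARA", "C1H", "TR",
                    paste0("KA", c("23", "34", "45", "56", "67")),
                    paste0("RRA", c("23", "34", "45", "56", "67")),
                    paste0("ST", c("23", "34", "45", "56", "67"))))
  expect_true(all(rep0$icc > 0 & rep0$icc <= 1))
  expect_true(all(rep0$rmse > 0))

  # identical tables: exact identity statistics
  repid <- reliability_report(m1, m1, "self")
  expect_true(all(repid$icc == 1))
  expect_true(all(repid$rmse == 0))
  expect_true(all(repid$r2 == 1))

  # strata rows partition the pooled pairs
  m1$sex <- rep(c("F", "M"), length.out = nrow(m1))
  reps <- reliability_report(m1, m2, "US vs US", strata = "sex")
  ara <- reps[reps$variable == "ARA", ]
  expect_equal(sum(ara$n_pairs[ara$stratum != "all"]),
               ara$n_pairs[ara$stratum == "all"])

  expect_error(reliability_report(m1[0, ], m2, "x"),
               class = "cervimetrics_insufficient_data")
})
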