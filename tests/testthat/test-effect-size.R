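test_that("effect sizes follow the log response ratio definition", {
  recs <- make_records(c(2.0, 2.216, 4.0), c(2.0, 2.518, 2.0))
  eff <- trial_effects(recs)
  expect_equal(eff$effect_size[1], 0)
  expect_equal(eff$response_pct[1], 0)
  expect_equal(eff$response_pct[2], 13.63, tolerance = 5e-3)
  expect_equal(eff$effect_size[3], -log(2))
  # order preserved, one row per record
  expect_equal(eff$site_id, recs$site_id)
  expect_error(trial_effects(make_records(c(2, 0), c(2, 2))), "non-positive")
})

test_that("back-transform is consistent for random positive yield pairs", {
  withr::local_seed(1)
  u <- runif(500, 0.1, 12)
  t <- runif(500, 0.1, 15)
  eff <- trial_effects(make_records(u, t))
  expect_equal(eff$response_pct, (exp(eff$effect_size) - 1) * 100,
               tolerance = 1e-12)
  expect_equal(eff$response_pct, (t / u - 1) * 100, tolerance = 1e-12)
})

test_that("bootstrap degenerates gracefully on zero-variance input", {
  res <- bootstrap_mean_effect(rep(0.07, 20), n_boot = 1000, seed = 1)
  expect_equal(res$mean_effect, 0.07)
  expect_equal(res$ci_low, 0.07)
  expect_equal(res$ci_high, 0.07)
})

test_that("bootstrap input contracts are enforced", {
  expect_error(bootstrap_mean_effect(0.1), "at least 2")
  expect_error(bootstrap_mean_effect(c(0.1, 0.2), n_boot = 10), "1000")
  expect_error(bootstrap_mean_effect(c(0.1, 0.2), conf = 1.2), "conf")
})

test_that("normal-interval half-width matches the closed form on iid data", {
  withr::local_seed(42)
  x <- rnorm(10000, mean = 0.1, sd = 0.05)
  res <- bootstrap_mean_effect(x, n_boot = 2000, conf = 0.95, seed = 8)
  half <- (res$ci_high - res$ci_low) / 2
  theory <- qnorm(0.975) * 0.05 / sqrt(10000)
  expect_lt(abs(half - theory) / theory, 0.10)
})

test_that("norm interval agrees with the boot package convention", {
  skip_if_not_installed("boot")
  withr::local_seed(99)
  x <- log(runif(60, 0.9, 1.4))
  res <- bootstrap_mean_effect(x, n_boot = 5000, conf = 0.95, seed = 12)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 5000)
  ci <- boot::boot.ci(b, conf = 0.95, type = "norm")$normal
  # two independent resampling runs: intervals agree to Monte Carlo error
  expect_equal(res$ci_low, ci[2], tolerance = 5e-3)
  expect_equal(res$ci_high, ci[3], tolerance = 5e-3)
})

test_that("bootstrap is reproducible under a fixed seed and CI covers sanely", {
  x <- log(runif(80, 0.95, 1.35))
  a <- bootstrap_mean_effect(x, n_boot = 1000, seed = 5)
  b <- bootstrap_mean_effect(x, n_boot = 1000, seed = 5)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$mean_effect)
  expect_gte(a$ci_high, a$mean_effect)
  p <- bootstrap_mean_effect(x, n_boot = 1000, seed = 5, type = "perc")
  expect_lt(p$ci_low, p$ci_high)
})

test_that("CI width shrinks like 1/sqrt(n)", {
  withr::local_seed(17)
  x1 <- rnorm(400, 0.1, 0.12)
  x2 <- c(x1, rnorm(400, 0.1, 0.12))
  w1 <- with(bootstrap_mean_effect(x1, n_boot = 4000, seed = 1),
             ci_high - ci_low)
  w2 <- with(bootstrap_mean_effect(x2, n_boot = 4000, seed = 2),
             ci_high - ci_low)
  expect_lt(abs(w1 / w2 - sqrt(2)) / sqrt(2), 0.15)
})

test_that("effectiveness counts strict exceedances", {
  expect_equal(unname(effectiveness(c(-5, 0, 5, 15), c(0, 10))),
               c(50, 25))
  expect_equal(unname(effectiveness(rep(20, 4), c(0, 10))), c(100, 100))
  expect_equal(unname(effectiveness(rep(0, 4), c(0, 10))), c(0, 0))
  expect_error(effectiveness(numeric(0)), "no effects")
})

test_that("effectiveness is non-increasing in the threshold", {
  withr::local_seed(3)
  for (i in 1:20) {
    r <- rnorm(50, mean = 8, sd = 12)
    th <- sort(runif(5, -10, 30))
    e <- effectiveness(r, th)
    expect_true(all(diff(e) <= 0))
  }
})

test_that("summarize_crop assembles means, CIs and both response scales", {
  recs <- make_records(c(1.0, 2.0), c(1.1, 2.2))
  s <- summarize_crop(recs, n_boot = 1000, seed = 4)
  expect_equal(s$mean_untreated, 1.5)
  expect_equal(s$response_pct, 10)                 # equal per-trial ratios
  expect_equal(s$response_pct_ratio_of_means, 10)
  expect_equal(s$mean_effect, log(1.1))
  expect_equal(s$response_pct_log_scale, 10)

  expect_error(summarize_crop(recs[1, ]), "at least 2")
  mixed <- rbind(recs, make_records(3, 3.3, crop = "other"))
  expect_error(summarize_crop(mixed), "mix crops")
})

test_that("mean of per-trial responses differs from ratio of mean yields", {
  # log-scale example: maize-like mean effect back-transforms exactly
  expect_equal((exp(log(1.1573)) - 1) * 100, 15.73)
  # a sample with unequal ratios must expose both summaries, and they differ
  recs <- make_records(c(1, 4), c(1.5, 4.4))
  s <- summarize_crop(recs, n_boot = 1000, seed = 2)
  expect_equal(s$response_pct, (50 + 10) / 2)
  expect_equal(s$response_pct_ratio_of_means, (5.9 / 5 - 1) * 100)
  expect_false(isTRUE(all.equal(s$response_pct,
                                s$response_pct_ratio_of_means)))
})

test_that("summarize_crops handles several crops with derived seeds", {
  recs <- rbind(records_with_responses(c(5, 10, 20), crop = "a"),
                records_with_responses(c(-2, 8, 30), crop = "b"))
  s <- summarize_crops(recs, n_boot = 1000, seed = 1)
  expect_equal(nrow(s), 2)
  expect_equal(s$crop, c("a", "b"))
  s2 <- summarize_crops(recs, n_boot = 1000, seed = 1)
  expect_equal(s, s2)
})
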