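test_that("yield-difference ECDF counts with the <= convention", {
  d_t <- c(-100, 0, 100, 300) / 1000      # back to t/ha
  recs <- make_records(rep(4, 4), 4 + d_t)
  ec <- yield_diff_ecdf(recs)
  expect_equal(ec$n, 4)
  expect_equal(ec$diffs, sort(d_t * 1000))
  expect_equal(ec$F(0), 0.5)
  expect_equal(ec$F(299), 0.75)
  expect_equal(ec$F(300), 1)

  one <- yield_diff_ecdf(make_records(4, 4.25))
  expect_equal(one$F(249.9), 0)
  expect_equal(one$F(250), 1)
})

test_that("ECDF is non-decreasing on random inputs", {
  withr::local_seed(10)
  for (i in 1:10) {
    u <- runif(30, 1, 9)
    recs <- make_records(u, u * exp(rnorm(30, 0.1, 0.15)))
    ec <- yield_diff_ecdf(recs)
    x <- seq(min(ec$diffs) - 50, max(ec$diffs) + 50, length.out = 200)
    expect_true(all(diff(ec$F(x)) >= 0))
  }
})

test_that("break-even yield follows cost / price", {
  expect_equal(break_even_yield(price = 384.2, total_cost = 24), 62.47,
               tolerance = 1e-4)
  expect_equal(break_even_yield(price = 260.5, total_cost = 24), 92.13,
               tolerance = 1e-4)
  expect_equal(break_even_yield(price = 200, total_cost = 0), 0)
  expect_error(break_even_yield(price = 0, total_cost = 24), "price")
  # round trip: selling the break-even mass pays exactly the cost
  be <- break_even_yield(price = 215.2, total_cost = 31)
  expect_equal(be * 215.2 / 1000, 31, tolerance = 1e-12)
})

test_that("chance to exceed cost is a strict exceedance percentage", {
  recs <- make_records(rep(4, 4), 4 + c(50, 150, 250, 350) / 1000)
  ec <- yield_diff_ecdf(recs)
  expect_equal(chance_exceed_cost(ec, 100), 75)
  expect_equal(chance_exceed_cost(ec, 10), 100)   # below the minimum
  expect_equal(chance_exceed_cost(ec, 350), 0)    # at the maximum, <= counts
  expect_equal(chance_exceed_cost(ec, 50), 75)    # tie: not an exceedance
})

test_that("chance_exceed_cost equals a brute-force strict count", {
  withr::local_seed(77)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    u <- runif(n, 1, 10)
    recs <- make_records(u, u * exp(rnorm(n, 0.08, 0.2)))
    ec <- yield_diff_ecdf(recs)
    be <- runif(1, -300, 800)
    brute <- 100 * sum((recs$treated_yield - recs$untreated_yield) * 1000 > be) / n
    expect_equal(chance_exceed_cost(ec, be), brute)
    # include an exact tie
    be_tie <- ec$diffs[sample(n, 1)]
    brute_tie <- 100 * sum(ec$diffs > be_tie) / n
    expect_equal(chance_exceed_cost(ec, be_tie), brute_tie)
  }
})

test_that("net return matches the partial-budget formula and units", {
  expect_equal(net_return(2.216, 2.518, price = 384.2, total_cost = 24),
               92.0, tolerance = 0.05)
  expect_equal(net_return(4.470, 5.181, price = 215.2, total_cost = 31),
               122.0, tolerance = 0.05)
  expect_equal(net_return(3, 3, price = 250, total_cost = 27), -27)
  expect_error(net_return(0, 2, price = 200, total_cost = 24), "> 0")
  # kg & USD/kg computation agrees with t & USD/t to machine precision
  expect_equal(net_return(2.216, 2.518, price = 384.2, total_cost = 24),
               (2518 - 2216) * (384.2 / 1000) - 24, tolerance = 1e-12)
})

test_that("scenario table implements the three-scenario assumptions", {
  pc <- price_cost("soybean", mean_price = 384.2, price_sd = 79.35,
                   product_cost = 14, application_cost = 10)
  sc <- scenario_table(pc)
  expect_equal(sc$scenario, c("unfavorable", "normal", "favorable"))
  expect_equal(sc$price, c(304.85, 384.2, 463.55))
  expect_equal(round(sc$price[1], 1), 304.9)
  expect_equal(sc$total_cost, c(24 * 1.045, 24, 24))
  expect_equal(round(sc$total_cost[1], 1), 25.1)

  flat <- scenario_table(price_cost("x", 200, price_sd = 0,
                                    product_cost = 14,
                                    application_cost = 10))
  expect_equal(flat$price, rep(200, 3))
})

test_that("explicit scenario prices override the mean±SD derivation", {
  pc <- uruguay_price_costs()$wheat
  sc <- scenario_table(pc)
  expect_equal(sc$price, c(169.8, 215.2, 260.5))
  expect_equal(sc$total_cost[2], 24)
})

test_that("break-even is monotone in price; chance monotone in break-even", {
  withr::local_seed(31)
  prices <- sort(runif(10, 100, 500))
  be <- break_even_yield(price = prices, total_cost = 24)
  expect_true(all(diff(be) < 0))
  u <- runif(40, 2, 8)
  ec <- yield_diff_ecdf(make_records(u, u * exp(rnorm(40, 0.1, 0.12))))
  ch <- chance_exceed_cost(ec, sort(runif(20, -100, 1200)))
  expect_true(all(diff(ch) <= 0))
})

test_that("scenario ordering of profitability chances holds on random data", {
  withr::local_seed(19)
  pc <- price_cost("any", mean_price = 220, price_sd = 40,
                   product_cost = 14, application_cost = 10)
  sc <- scenario_table(pc)
  be <- break_even_yield(sc)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    u <- runif(n, 1, 10)
    recs <- make_records(u, u * exp(rnorm(n, 0.1, 0.15)))
    ch <- chance_exceed_cost(yield_diff_ecdf(recs), be)
    expect_true(ch[1] <= ch[2] && ch[2] <= ch[3])
  }
})

test_that("break_even_table assembles the per-crop sensitivity analysis", {
  recs <- simulate_crop(uruguay_grain_profiles()$wheat, seed = 6)
  tab <- break_even_table(recs, uruguay_price_costs()$wheat)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$break_even_yield, tab$total_cost / tab$price * 1000)
  expect_true(all(tab$chance_exceed_cost >= 0 &
                  tab$chance_exceed_cost <= 100))
  mixed <- rbind(recs, make_records(3, 3.2, crop = "other"))
  expect_error(break_even_table(mixed, uruguay_price_costs()$wheat),
               "single crop")
})

test_that("price_cost rejects negative figures", {
  expect_error(price_cost("x", -1, 0, 14, 10), "finite and >= 0")
  expect_error(price_cost("x", 200, 0, 14, 10, scenario_prices = c(1, 2)),
               "scenario_prices")
})
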