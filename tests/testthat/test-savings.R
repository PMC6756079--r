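test_that("short-term savings scale the variable share of each category", {
  us <- us_cost_table()
  s <- short_term_savings(us, const_reduction(0.0355))
  cats <- s$categories
  # fully-variable prescribed medicines: 36.1 * 0.0355
  expect_equal(cats$mean[cats$category == "Prescribed medicines"],
               36.1 * 0.0355)
  # hospital inpatient at the 0.165 short-run variable share
  expect_equal(cats$mean[cats$category == "Hospital inpatient stays"],
               101 * 0.0355 * 0.165)
  zero <- short_term_savings(us, const_reduction(0))
  expect_true(all(zero$categories$mean == 0))
  expect_true(all(zero$subtotals$mean == 0))

  broken <- us_cost_table()
  broken$categories$variable_share[2] <- NA
  expect_error(short_term_savings(broken, const_reduction(0.01)),
               "variable share")
})

test_that("per-category savings are comonotone multiples of the draw", {
  us <- us_cost_table()
  set.seed(33)
  R <- runif(400, 0, 0.2)
  red <- incidence_reduction("mc", R)
  s <- short_term_savings(us, red)
  # oracle: every summary entry is base_c times the same moment of R
  base <- us$categories$amount_2017 * us$categories$variable_share
  q <- quantile(R, c(0.025, 0.975), type = 7, names = FALSE)
  expect_equal(s$categories$mean, base * mean(R))
  expect_equal(s$categories$ci_low, base * q[1])
  expect_equal(s$categories$ci_high, base * q[2])
  # so the ratio of any two categories' savings is constant across draws
  expect_equal(s$categories$mean[1] / s$categories$mean[2],
               s$categories$ci_high[1] / s$categories$ci_high[2])
})

test_that("category means sum to subtotals and the total before rounding", {
  set.seed(12)
  red <- incidence_reduction("mc", runif(300, 0, 0.3))
  for (tb in list(us_cost_table(), canada_cost_table())) {
    for (s in list(short_term_savings(tb, red),
                   long_term_savings(tb, red))) {
      direct <- s$categories$kind == "direct"
      sub <- s$subtotals
      expect_equal(sum(s$categories$mean[direct]),
                   sub$mean[sub$level == "direct"])
      expect_equal(sum(s$categories$mean[!direct]),
                   sub$mean[sub$level == "indirect"])
      expect_equal(sum(s$categories$mean), sub$mean[sub$level == "total"])
      expect_true(all(sub$ci_low <= sub$mean & sub$mean <= sub$ci_high))
    }
  }
})

test_that("savings are linear in the reduction draws", {
  us <- us_cost_table()
  set.seed(5)
  R <- runif(200, 0, 0.2)
  s1 <- short_term_savings(us, incidence_reduction("r", R))
  s2 <- short_term_savings(us, incidence_reduction("r", 2 * R))
  expect_equal(s2$categories$mean, 2 * s1$categories$mean)
  expect_equal(s2$categories$ci_low, 2 * s1$categories$ci_low)
  expect_equal(s2$subtotals$ci_high, 2 * s1$subtotals$ci_high)
})

test_that("the annuity factor matches the year-by-year oracle", {
  expect_equal(annuity_factor(projection_spec(0.0354, 0.018, 10)), 11.99,
               tolerance = 1e-3)
  expect_equal(annuity_factor(projection_spec(0.013, 0.018, 10)), 10.73,
               tolerance = 1e-3)
  expect_equal(annuity_factor(projection_spec(0.02, 0.02, 10)), 11)

  loop_sum <- function(g, d, H) {
    total <- 0
    for (t in 0:H) total <- total + ((1 + g) / (1 + d))^t
    total
  }
  set.seed(8)
  for (i in 1:25) {
    g <- runif(1, -0.02, 0.08)
    d <- runif(1, 0, 0.06)
    H <- sample(0:30, 1)
    expect_equal(annuity_factor(projection_spec(g, d, H)), loop_sum(g, d, H),
                 tolerance = 1e-12)
  }
})

test_that("long-term savings discount an all-variable growing stream", {
  us <- us_cost_table()
  red <- const_reduction(0.03554)
  spec <- projection_spec(0.0354, 0.018, 10)
  s <- long_term_savings(us, red, spec)
  tot <- s$subtotals$mean[s$subtotals$level == "total"]
  expect_equal(tot, 368.5 * 0.03554 * annuity_factor(spec))
  # categories apportioned by 2017 cost share
  shares <- us$categories$amount_2017 / sum(us$categories$amount_2017)
  expect_equal(s$categories$mean, shares * tot)

  # H = 0 with all shares variable collapses to one year of all-variable
  # short-term savings (table whose printed total equals its category sum)
  allvar <- generate_cost_table(5, total = 200, seed = 2)$table
  allvar$categories$variable_share <- 1
  short <- short_term_savings(allvar, red)
  h0 <- long_term_savings(allvar, red, projection_spec(0.1, 0.018, 0))
  expect_equal(h0$subtotals$mean, short$subtotals$mean)
  expect_equal(h0$categories$mean, short$categories$mean)
})

test_that("total cost projections compound at the growth rate", {
  us <- us_cost_table()
  expect_equal(project_total_cost(us), 368.5 * 1.0354^10)
  expect_identical(
    project_total_cost(us, projection_spec(0, 0.018, 10)), 368.5)
})

test_that("percent decrease relates mean savings to the 2017 total", {
  us <- us_cost_table()
  s <- short_term_savings(us, const_reduction(0.0355))
  expect_equal(percent_decrease(s, us),
               100 * s$subtotals$mean[s$subtotals$level == "total"] / 368.5)
  expect_identical(percent_decrease(short_term_savings(us, const_reduction(0)), us), 0)

  empty <- cost_table("void", "$", "billion", 2017L,
                      data.frame(category = "a", kind = "direct",
                                 amount_base = 0, amount_2017 = 0,
                                 variable_share = 1),
                      cpi_factor = 1, annual_growth = 0)
  s0 <- short_term_savings(empty, const_reduction(0.1))
  expect_error(percent_decrease(s0, empty), "zero")
})
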