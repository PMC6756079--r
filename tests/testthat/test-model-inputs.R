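test_that("standard errors derive from confidence intervals", {
  z <- qnorm(0.975)
  # interval width / (2z): checked against direct arithmetic
  expect_equal(se_from_ci(0.61, 0.86), 0.25 / (2 * z))
  expect_equal(se_from_ci(0.61, 0.86), 0.0638, tolerance = 1e-3)
  expect_equal(se_from_ci(0.62, 0.82), 0.0510, tolerance = 1e-3)
  expect_identical(se_from_ci(0.70, 0.70), 0)
  # 90% interval uses the 1.645 quantile
  expect_equal(se_from_ci(0.5, 1.0, level = 0.90), 0.5 / (2 * qnorm(0.95)))
  expect_error(se_from_ci(-0.1, 0.5), "positive")
  expect_error(se_from_ci(0.9, 0.5), "reversed")
  expect_error(se_from_ci(0.5, 0.9, level = 1.2), "level")
})

test_that("bundled risk studies have valid derived standard errors", {
  rs <- cvd_risk_studies()
  expect_true(all(rs$se_lm > 0))
  expect_true(all(rs$se_lh > 0))
  expect_true(all(rs$se_lm < rs$rr_lm))
  expect_true(all(rs$se_lh < rs$rr_lh))
})

test_that("input validation names the offending study and field", {
  adh <- as.data.frame(us_adherence_studies())
  adh$low[2] <- 80
  expect_error(adherence_studies(adh), "row 2.*sum to")
  adh <- as.data.frame(us_adherence_studies())
  adh$scale[1] <- "7-point"
  expect_error(adherence_studies(adh), "scale")
  expect_error(adherence_studies(adh[, -2]), "missing column.*n")

  rs <- as.data.frame(cvd_risk_studies())
  rs$lo_lh[3] <- rs$hi_lh[3] + 0.1
  expect_error(risk_studies(rs), "row 3.*lower <= point <= upper")
  expect_error(risk_studies(rs[0, ]), "empty")
})

test_that("cost table validation enforces shares, kinds and totals", {
  cats <- us_cost_table()$categories
  expect_error(cost_table("x", "$", "billion", 2013L, cats[0, ], 1.1, 0.03),
               "empty")
  bad <- cats; bad$variable_share[1] <- 1.5
  expect_error(cost_table("x", "$", "billion", 2013L, bad, 1.1, 0.03),
               "variable_share")
  bad <- cats; bad$kind[2] <- "capital"
  expect_error(cost_table("x", "$", "billion", 2013L, bad, 1.1, 0.03),
               "direct.*indirect")
  expect_error(cost_table("x", "$", "billion", 2013L, cats, 0.9, 0.03),
               "cpi_factor")
  expect_error(
    cost_table("x", "$", "billion", 2013L, cats, 1.1, 0.03, total_2017 = 500),
    "differs from category sum")
})

test_that("bundled cost tables reproduce the printed totals", {
  us <- us_cost_table()
  expect_printed(sum(us$categories$amount_2017), 368.5, 0.1)
  expect_identical(us$total_2017, 368.5)
  expect_equal(sum(us$categories$amount_base), 329.6)

  ca <- canada_cost_table()
  expect_printed(sum(ca$categories$amount_2017), 14326, 1)
  direct <- ca$categories$kind == "direct"
  expect_printed(sum(ca$categories$amount_2017[direct]), 13650, 1)
  expect_printed(sum(ca$categories$amount_2017[!direct]), 676.4, 0.1)
})

test_that("CPI inflation reproduces the printed 2017 columns", {
  us <- inflate_costs(us_cost_table())
  # every re-inflated category within one unit of the last printed digit
  printed <- c(101, 11.9, 51.8, 21.9, 36.1, 145.9)
  steps <- c(1, 0.1, 0.1, 0.1, 0.1, 0.1)
  for (i in seq_along(printed))
    expect_printed(us$categories$amount_2017[i], printed[i], steps[i])

  ca <- inflate_costs(canada_cost_table())
  expect_printed(ca$categories$amount_2017[1], 6434, 1)

  ident <- us_cost_table()
  ident$cpi_factor <- 1
  expect_equal(inflate_costs(ident)$categories$amount_2017,
               ident$categories$amount_base)

  broken <- us_cost_table()
  broken$cpi_factor <- -2
  expect_error(inflate_costs(broken), "negative")
})

test_that("write/load round-trips an input set exactly", {
  dir <- withr::local_tempdir()
  a <- load_model_inputs()
  write_model_inputs(a, dir)
  b <- load_model_inputs(dir)
  expect_identical(as.data.frame(a$adherence), as.data.frame(b$adherence))
  expect_identical(as.data.frame(a$risk), as.data.frame(b$risk))
  for (id in names(a$costs)) {
    expect_identical(a$costs[[id]]$categories, b$costs[[id]]$categories)
    expect_identical(a$costs[[id]]$cpi_factor, b$costs[[id]]$cpi_factor)
    expect_identical(a$costs[[id]]$annual_growth, b$costs[[id]]$annual_growth)
    expect_identical(a$costs[[id]]$total_2017, b$costs[[id]]$total_2017)
  }
  expect_identical(a$config$n_draws, b$config$n_draws)
  expect_identical(a$config$scenarios[[1]]$mean_reduction,
                   b$config$scenarios[[1]]$mean_reduction)
})

test_that("the installed extdata input set matches the bundled fixtures", {
  dir <- system.file("extdata", package = "medcoi")
  b <- load_model_inputs(dir)
  a <- load_model_inputs()
  expect_identical(as.data.frame(a$risk), as.data.frame(b$risk))
  expect_identical(a$costs$us$categories, b$costs$us$categories)
  expect_identical(a$costs$canada$total_2017, b$costs$canada$total_2017)
})

test_that("loading reports missing files and directories", {
  expect_error(load_model_inputs(file.path(tempdir(), "nope-xyz")), "does not exist")
  dir <- withr::local_tempdir()
  write_model_inputs(load_model_inputs(), dir)
  unlink(file.path(dir, "risk_studies.csv"))
  expect_error(load_model_inputs(dir), "risk_studies.csv")
})

test_that("the JSON provenance dump carries derived fields", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "inputs.json")
  model_inputs_json(load_model_inputs(), path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$risk_studies$se_lh[1], se_from_ci(0.61, 0.86))
  expect_equal(j$cost_tables$us$total_2017, 368.5)
  expect_equal(j$config$n_draws, 10000)
})
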