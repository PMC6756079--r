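test_that("mixture weights follow the chosen weighting scheme", {
  rs <- cvd_risk_studies()
  eq <- build_mixture(rs, weighting = "equal")
  expect_equal(eq$components$weight, rep(0.2, 5))
  sz <- build_mixture(rs, weighting = "size")
  expect_equal(sz$components$weight,
               c(0.2699, 0.0370, 0.6624, 0.0162, 0.0145), tolerance = 1e-3)
  expect_equal(sum(sz$components$weight), 1, tolerance = 1e-12)
  # size-weighted mean of the low-to-high ratios
  expect_equal(sum(sz$components$weight * sz$components$mean_lh), 0.769,
               tolerance = 1e-3)

  one <- build_mixture(rs[1, ])
  expect_identical(one$components$weight, 1)
})

test_that("degenerate mixtures return their component means exactly", {
  one <- risk_studies(data.frame(
    name = "pt", n = 10L, rr_lm = 0.8, lo_lm = 0.8, hi_lm = 0.8,
    rr_lh = 0.75, lo_lh = 0.75, hi_lh = 0.75))
  d <- sample_mixture(build_mixture(one), 500, seed = 4)
  expect_identical(unique(d$rr_lh), 0.75)
  expect_identical(unique(d$rr_lm), 0.8)
})

test_that("sample moments converge to the closed-form mixture moments", {
  rs <- cvd_risk_studies()
  n <- 10000
  # independent oracle: moments computed directly from the study table
  mu <- rs$rr_lh
  sg <- rs$se_lh
  for (weighting in c("equal", "size")) {
    w <- if (weighting == "size") rs$n / sum(rs$n) else rep(0.2, 5)
    for (mode in c("select", "average")) {
      m_true <- sum(w * mu)
      v_true <- if (mode == "select") sum(w * (sg^2 + mu^2)) - m_true^2
                else sum(w^2 * sg^2)
      mix <- build_mixture(rs, weighting = weighting, spread_mode = mode)
      mm <- mixture_moments(mix)
      expect_equal(mm["lh", "mean"], m_true)
      expect_equal(mm["lh", "sd"], sqrt(v_true))
      d <- sample_mixture(mix, n, seed = 99)
      mc_se <- sqrt(v_true / n)
      expect_lt(abs(mean(d$rr_lh) - m_true), 4 * mc_se)
      expect_lt(abs(sd(d$rr_lh) - sqrt(v_true)), 4 * sqrt(v_true) / sqrt(n))
    }
  }
})

test_that("equal-weight select draws centre on a 25% reduction with sd 0.086", {
  d <- sample_mixture(build_mixture(cvd_risk_studies()), 10000, seed = 5)
  expect_equal(mean(1 - d$rr_lh), 0.25, tolerance = 0.005)
  expect_equal(sd(d$rr_lh), 0.0859, tolerance = 0.01)
})

test_that("contrasts are paired by study but independent within it", {
  rs <- cvd_risk_studies()
  d <- sample_mixture(build_mixture(rs), 10000, seed = 21)
  expect_identical(length(d$study_index), length(d$rr_lh))
  # within one fixed study the two contrasts are independent normals
  for (i in c(1, 3)) {
    sel <- d$study_index == i
    expect_gt(sum(sel), 500)
    expect_lt(abs(cor(d$rr_lm[sel], d$rr_lh[sel])), 4 / sqrt(sum(sel)))
    # and both centre on that study's published ratios
    expect_equal(mean(d$rr_lh[sel]), rs$rr_lh[i],
                 tolerance = 4 * rs$se_lh[i] / sqrt(sum(sel)) / rs$rr_lh[i])
  }
})

test_that("a fixed seed reproduces draw sequences bit-identically", {
  mix <- build_mixture(cvd_risk_studies())
  a <- sample_mixture(mix, 2000, seed = 123)
  b <- sample_mixture(mix, 2000, seed = 123)
  expect_identical(a, b)
  c <- sample_mixture(mix, 2000, seed = 124)
  expect_false(identical(a$rr_lh, c$rr_lh))
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(sample_mixture(build_mixture(cvd_risk_studies()), 100, seed = 5))
  expect_identical(runif(1), before)
})

test_that("raw-scale draws are truncated at zero by rejection", {
  wide <- risk_studies(data.frame(
    name = "wide", n = 50L,
    rr_lm = 0.3, lo_lm = 0.01, hi_lm = 0.59,
    rr_lh = 0.2, lo_lh = 0.01, hi_lh = 0.39))
  d <- sample_mixture(build_mixture(wide), 20000, seed = 9)
  expect_true(all(d$rr_lh > 0))
  expect_true(all(d$rr_lm > 0))
})

test_that("log-scale sampling matches lognormal mixture moments", {
  rs <- cvd_risk_studies()
  mix <- build_mixture(rs, rr_scale = "log")
  mm <- mixture_moments(mix)
  d <- sample_mixture(mix, 10000, seed = 31)
  expect_true(all(d$rr_lh > 0))
  expect_lt(abs(mean(d$rr_lh) - mm["lh", "mean"]),
            4 * mm["lh", "sd"] / sqrt(10000))
})

test_that("component means are recovered from draws grouped by study", {
  syn <- generate_risk_studies(k = 3, rr_range = c(0.6, 0.9),
                               rel_se_range = c(0.04, 0.08), seed = 14)
  d <- sample_mixture(build_mixture(syn$studies), 15000, seed = 15)
  for (i in 1:3) {
    sel <- d$study_index == i
    n_i <- sum(sel)
    expect_lt(abs(mean(d$rr_lh[sel]) - syn$truth$rr_lh[i]),
              3 * syn$truth$se_lh[i] / sqrt(n_i))
  }
})

test_that("draw summaries report reduction-scale moments and percentiles", {
  one <- risk_studies(data.frame(
    name = "pt", n = 10L, rr_lm = 0.8, lo_lm = 0.8, hi_lm = 0.8,
    rr_lh = 0.75, lo_lh = 0.75, hi_lh = 0.75))
  s <- summarize_draws(sample_mixture(build_mixture(one), 100, seed = 2))
  expect_equal(s["lh", "mean"], 0.25)
  expect_identical(s["lh", "sd"], 0)
  expect_true(all(s["lh", grep("^p", names(s))] == 0.25))

  d <- sample_mixture(build_mixture(cvd_risk_studies()), 5000, seed = 8)
  s <- summarize_draws(d)
  # type-7 percentile convention
  expect_equal(s["lh", "p2.5"],
               unname(quantile(1 - d$rr_lh, 0.025, type = 7)))
  expect_equal(s["lh", "mean"], mean(1 - d$rr_lh))
})

test_that("draw sets export to CSV at full precision", {
  d <- sample_mixture(build_mixture(cvd_risk_studies()), 200, seed = 3)
  path <- file.path(withr::local_tempdir(), "draws.csv")
  write_draws_csv(d, path)
  back <- read.csv(path)
  expect_identical(back$rr_lh, d$rr_lh)
  expect_identical(back$study, d$study_index)
})
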