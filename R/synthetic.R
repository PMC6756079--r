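# Synthetic-data generators: emulate the shapes of the adherence, risk
# and cost input tables with known ground truth, so every pipeline stage
# is testable independently of the bundled published tables. All
# generators are seed-deterministic and their outputs pass the same
# validation as real inputs.

#' Generate synthetic risk studies
#'
#' Draws \code{k} cohort studies with known true ratios. Each study gets
#' two contrasts with \code{rr_lh <= rr_lm} (high adherence at least as
#' protective as medium), standard errors proportional to the point
#' estimate, and confidence intervals reconstructed as \code{point +/- z
#' * se} (symmetric on the raw scale, or on the log scale with
#' \code{log_scale = TRUE}) so that [se_from_ci()] round-trips exactly.
#'
#' @param k Number of studies.
#' @param rr_range Interval the true ratios are drawn from (positive).
#' @param rel_se_range Interval of the relative standard error
#'   \code{se / rr}; \code{c(0, 0)} gives degenerate (point-mass)
#'   studies.
#' @param n_range Interval of cohort sizes.
#' @param seed Integer RNG seed.
#' @param log_scale Build CIs symmetric on the log scale instead.
#' @return A list with elements \code{studies} (a [risk_studies()]
#'   table) and \code{truth} (true means, SEs and size weights).
#' @export
generate_risk_studies <- function(k, rr_range = c(0.6, 0.95),
                                  rel_se_range = c(0.03, 0.12),
                                  n_range = c(1000, 60000),
                                  seed = 1, log_scale = FALSE) {
  if (!is_count(k)) stopf("`k` must be a positive integer")
  ok_range <- function(r, lo_min) length(r) == 2 && r[1] <= r[2] && r[1] >= lo_min
  if (!ok_range(rr_range, .Machine$double.eps) || !ok_range(rel_se_range, 0) ||
      !ok_range(n_range, 1))
    stopf("invalid generator range")
  with_seed(seed, {
    a <- stats::runif(k, rr_range[1], rr_range[2])
    b <- stats::runif(k, rr_range[1], rr_range[2])
    rr_lm <- pmax(a, b)
    rr_lh <- pmin(a, b)
    rel_lm <- stats::runif(k, rel_se_range[1], rel_se_range[2])
    rel_lh <- stats::runif(k, rel_se_range[1], rel_se_range[2])
    n <- round(stats::runif(k, n_range[1], n_range[2]))
    z <- stats::qnorm(0.975)
    # raw mode: se = rel * rr, CI = rr +/- z se, so se_from_ci round-trips
    # exactly; log mode: se is on the log scale (rel itself, delta-method
    # scale), CI = rr exp(+/- z se), so build_mixture's log-scale SE
    # round-trips exactly instead.
    if (log_scale) {
      se_lm <- rel_lm
      se_lh <- rel_lh
      ci <- function(rr, se) list(lo = rr * exp(-z * se), hi = rr * exp(z * se))
    } else {
      se_lm <- rel_lm * rr_lm
      se_lh <- rel_lh * rr_lh
      ci <- function(rr, se) list(lo = rr - z * se, hi = rr + z * se)
    }
    ci_lm <- ci(rr_lm, se_lm)
    ci_lh <- ci(rr_lh, se_lh)
    if (any(ci_lm$lo <= 0) || any(ci_lh$lo <= 0))
      stopf("generated interval crosses zero; narrow `rel_se_range`")
    studies <- risk_studies(data.frame(
      name = sprintf("synthetic-%02d", seq_len(k)), n = n,
      rr_lm = rr_lm, lo_lm = ci_lm$lo, hi_lm = ci_lm$hi,
      rr_lh = rr_lh, lo_lh = ci_lh$lo, hi_lh = ci_lh$hi))
    list(studies = studies,
         truth = list(rr_lm = rr_lm, se_lm = se_lm,
                      rr_lh = rr_lh, se_lh = se_lh,
                      n = n, size_weights = n / sum(n), seed = seed))
  })
}

#' Generate synthetic adherence studies
#'
#' Draws \code{k} studies whose tertile percentages jitter around a true
#' population distribution and are renormalised to sum to 100.
#'
#' @param k Number of studies.
#' @param true_dist Length-3 vector of true tertile percentages
#'   (low, medium, high) summing to 100.
#' @param noise_sd Standard deviation of the per-study jitter
#'   (percentage points).
#' @param seed Integer RNG seed.
#' @return A list with \code{studies} (an [adherence_studies()] table)
#'   and \code{truth}.
#' @export
generate_adherence_studies <- function(k, true_dist = c(36, 36, 28),
                                       noise_sd = 2, seed = 1) {
  if (!is_count(k)) stopf("`k` must be a positive integer")
  if (length(true_dist) != 3 || abs(sum(true_dist) - 100) > 1e-8)
    stopf("`true_dist` must be 3 percentages summing to 100")
  with_seed(seed, {
    pct <- matrix(NA_real_, k, 3)
    for (i in seq_len(k)) {
      p <- pmax(true_dist + stats::rnorm(3, 0, noise_sd), 0.5)
      pct[i, ] <- 100 * p / sum(p)
    }
    studies <- adherence_studies(data.frame(
      name = sprintf("synthetic-%02d", seq_len(k)),
      n = round(stats::runif(k, 1000, 30000)),
      scale = sample(c("5-point", "9-point"), k, replace = TRUE),
      low = pct[, 1], medium = pct[, 2], high = pct[, 3]))
    list(studies = studies, truth = list(dist = true_dist, seed = seed))
  })
}

#' Generate a synthetic cost table
#'
#' Random positive category amounts summing exactly to \code{total},
#' with variable shares drawn from {1, 0.165} (the fully-variable and
#' hospital-type conventions) and a random direct/indirect split.
#'
#' @param n_categories Number of cost categories (>= 1).
#' @param total Total 2017 cost (> 0).
#' @param seed Integer RNG seed.
#' @param cpi_factor Base-year to 2017 multiplier (>= 1).
#' @param annual_growth Forward growth rate.
#' @return A list with \code{table} (a [cost_table()]) and \code{truth}.
#' @export
generate_cost_table <- function(n_categories, total, seed = 1,
                                cpi_factor = 1.05, annual_growth = 0.02) {
  if (!is_count(n_categories)) stopf("`n_categories` must be a positive integer")
  if (!is_number(total) || total <= 0) stopf("`total` must be positive")
  with_seed(seed, {
    w <- stats::runif(n_categories, 0.2, 1)
    amount_2017 <- total * w / sum(w)
    shares <- sample(c(1, 0.165), n_categories, replace = TRUE)
    kind <- sample(c("direct", "indirect"), n_categories, replace = TRUE)
    kind[1] <- "direct" # at least one direct category
    tbl <- cost_table(
      country = "synthetic", currency = "S$", units = "billion",
      base_year = 2013L,
      categories = data.frame(
        category = sprintf("category-%02d", seq_len(n_categories)),
        kind = kind,
        amount_base = amount_2017 / cpi_factor,
        amount_2017 = amount_2017,
        variable_share = shares),
      cpi_factor = cpi_factor, annual_growth = annual_growth,
      total_2017 = total)
    list(table = tbl,
         truth = list(amount_2017 = amount_2017, variable_share = shares,
                      total = total, g = annual_growth, seed = seed))
  })
}
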