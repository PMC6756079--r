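#' Standard error from a 95\% (or other level) confidence interval
#'
#' Converts a reported confidence interval on a hazard ratio or relative
#' risk into the standard error of a normal sampling distribution,
#' \code{(upper - lower) / (2 z)} with \code{z} the standard-normal
#' quantile at \code{(1 + level) / 2} (1.95996 for 95\%).
#'
#' @param lower,upper Numeric vectors of interval bounds, \code{0 < lower
#'   <= upper}.
#' @param level Confidence level of the reported interval, in (0, 1).
#' @return Numeric vector of standard errors (0 for a degenerate
#'   interval with \code{lower == upper}).
#' @examples
#' se_from_ci(0.61, 0.86)  # 0.0638
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != length(upper))
    stopf("`lower` and `upper` must be numeric vectors of equal length")
  if (!is_number(level) || level <= 0 || level >= 1)
    stopf("`level` must be a single number in (0, 1)")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stopf("confidence bounds must be finite")
  if (any(lower <= 0))
    stopf("lower confidence bound must be positive (got %g)", min(lower))
  if (any(upper < lower))
    stopf("reversed confidence interval: upper < lower")
  z <- stats::qnorm((1 + level) / 2)
  (upper - lower) / (2 * z)
}

#' Adherence study table
#'
#' Validates a table of Mediterranean-diet adherence studies: one row per
#' cohort with its size, score scale and the percentage of participants in
#' the low / medium / high adherence tertiles.
#'
#' @param x A data.frame with columns \code{name}, \code{n}, \code{scale}
#'   (one of \code{"5-point"}, \code{"9-point"}), \code{low},
#'   \code{medium}, \code{high} (percentages summing to 100 within 0.5).
#' @return The validated data.frame with class \code{adherence_studies}.
#' @export
adherence_studies <- function(x) {
  need <- c("name", "n", "scale", "low", "medium", "high")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("adherence studies: missing column(s) %s", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (nrow(x) == 0L) stopf("adherence studies: table is empty")
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    who <- sprintf("adherence study '%s' (row %d)", row$name, i)
    if (!is_number(row$n) || row$n <= 0 || row$n != round(row$n))
      stopf("%s: `n` must be a positive integer", who)
    if (!row$scale %in% c("5-point", "9-point"))
      stopf("%s: `scale` must be '5-point' or '9-point'", who)
    pct <- c(row$low, row$medium, row$high)
    if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
      stopf("%s: tertile percentages must lie in [0, 100]", who)
    if (abs(sum(pct) - 100) > 0.5)
      stopf("%s: tertile percentages sum to %.2f, not 100 +/- 0.5", who, sum(pct))
  }
  class(x) <- c("adherence_studies", "data.frame")
  x
}

#' Risk study table
#'
#' Validates a table of cohort studies reporting CVD hazard ratios or
#' relative risks for the low-to-medium and low-to-high adherence
#' contrasts, and derives the standard error of each contrast from its
#' 95\% confidence interval via [se_from_ci()].
#'
#' @param x A data.frame with columns \code{name}, \code{n},
#'   \code{rr_lm}, \code{lo_lm}, \code{hi_lm}, \code{rr_lh},
#'   \code{lo_lh}, \code{hi_lh}.
#' @return The validated data.frame with derived columns \code{se_lm},
#'   \code{se_lh} and class \code{risk_studies}.
#' @export
risk_studies <- function(x) {
  need <- c("name", "n", "rr_lm", "lo_lm", "hi_lm", "rr_lh", "lo_lh", "hi_lh")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("risk studies: missing column(s) %s", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (nrow(x) == 0L) stopf("risk studies: table is empty")
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    who <- sprintf("risk study '%s' (row %d)", row$name, i)
    if (!is_number(row$n) || row$n <= 0 || row$n != round(row$n))
      stopf("%s: `n` must be a positive integer", who)
    for (ct in c("lm", "lh")) {
      pt <- row[[paste0("rr_", ct)]]
      lo <- row[[paste0("lo_", ct)]]
      hi <- row[[paste0("hi_", ct)]]
      if (any(!is.finite(c(pt, lo, hi))))
        stopf("%s: non-finite value in contrast '%s'", who, ct)
      if (lo <= 0 || lo > pt || pt > hi)
        stopf("%s: contrast '%s' must satisfy 0 < lower <= point <= upper", who, ct)
    }
  }
  x$se_lm <- se_from_ci(x$lo_lm, x$hi_lm)
  x$se_lh <- se_from_ci(x$lo_lh, x$hi_lh)
  class(x) <- c("risk_studies", "data.frame")
  x
}

#' Country cost table
#'
#' Bundles per-category direct and indirect CVD costs for one country,
#' with the base-year to 2017 CPI inflation factor, the forward annual
#' healthcare cost growth rate, and each category's short-run variable
#' share (the fraction of the category that scales with incidence in the
#' short run; hospital costs are largely fixed short-term).
#'
#' @param country,currency,units Labels; \code{units} is the monetary
#'   unit amounts are held in (e.g. \code{"billion"} or \code{"million"}).
#'   Amounts are never converted across currencies.
#' @param base_year Year of the \code{amount_base} column.
#' @param categories A data.frame with columns \code{category},
#'   \code{kind} (\code{"direct"} or \code{"indirect"}),
#'   \code{amount_base}, \code{amount_2017}, \code{variable_share}.
#' @param cpi_factor Base-year to 2017 health-care CPI multiplier
#'   (>= 1).
#' @param annual_growth Forward annual cost growth rate (fraction per
#'   year), used for 10-year projections.
#' @param total_2017 Total 2017 cost as printed in the source table;
#'   defaults to the category sum. Must agree with the category sum
#'   within \code{max(0.1, 1e-4 * total)} to absorb printed rounding.
#' @return A list with class \code{cost_table}.
#' @export
cost_table <- function(country, currency, units, base_year, categories,
                       cpi_factor, annual_growth, total_2017 = NULL) {
  need <- c("category", "kind", "amount_base", "amount_2017", "variable_share")
  miss <- setdiff(need, names(categories))
  if (length(miss))
    stopf("cost table '%s': categories missing column(s) %s",
          country, paste(miss, collapse = ", "))
  categories <- as.data.frame(categories)[need]
  if (nrow(categories) == 0L)
    stopf("cost table '%s': category list is empty", country)
  for (i in seq_len(nrow(categories))) {
    row <- categories[i, ]
    who <- sprintf("cost table '%s', category '%s' (row %d)", country, row$category, i)
    if (!row$kind %in% c("direct", "indirect"))
      stopf("%s: `kind` must be 'direct' or 'indirect'", who)
    if (!is_number(row$amount_base) || row$amount_base < 0)
      stopf("%s: `amount_base` must be a non-negative number", who)
    if (!is_number(row$amount_2017) || row$amount_2017 < 0)
      stopf("%s: `amount_2017` must be a non-negative number", who)
    if (!is_number(row$variable_share) || row$variable_share < 0 || row$variable_share > 1)
      stopf("%s: `variable_share` must lie in [0, 1]", who)
  }
  if (!is_number(cpi_factor) || cpi_factor < 1)
    stopf("cost table '%s': `cpi_factor` must be >= 1", country)
  if (!is_number(annual_growth))
    stopf("cost table '%s': `annual_growth` must be a number", country)
  cat_sum <- sum(categories$amount_2017)
  total_2017 <- total_2017 %||% cat_sum
  tol <- max(0.1, 1e-4 * total_2017) + 1e-9  # epsilon absorbs float noise at the boundary
  if (abs(total_2017 - cat_sum) > tol)
    stopf("cost table '%s': total_2017 (%g) differs from category sum (%g) by more than %g",
          country, total_2017, cat_sum, tol)
  structure(
    list(country = country, currency = currency, units = units,
         base_year = base_year, categories = categories,
         cpi_factor = cpi_factor, annual_growth = annual_growth,
         total_2017 = total_2017),
    class = "cost_table")
}

#' @export
print.cost_table <- function(x, ...) {
  cat(sprintf("CVD cost table: %s (%s %s, base year %d -> 2017)\n",
              x$country, x$currency, x$units, x$base_year))
  cat(sprintf("  CPI factor %.4f, forward growth %.2f%%/yr, 2017 total %s %s\n",
              x$cpi_factor, 100 * x$annual_growth,
              format(x$total_2017, big.mark = ","), x$units))
  print(x$categories, row.names = FALSE)
  invisible(x)
}

#' Re-inflate base-year amounts to 2017 dollars
#'
#' Recomputes every category's 2017 amount as \code{amount_base *
#' cpi_factor} (full precision; rounding happens only in report
#' rendering) and refreshes the table total.
#'
#' @param table A [cost_table()].
#' @return The table with recomputed \code{amount_2017} and
#'   \code{total_2017}.
#' @export
inflate_costs <- function(table) {
  stopifnot(inherits(table, "cost_table"))
  if (table$cpi_factor < 0) stopf("negative CPI factor")
  table$categories$amount_2017 <- table$categories$amount_base * table$cpi_factor
  table$total_2017 <- sum(table$categories$amount_2017)
  table
}

#' Scenario shift in adherence tertiles
#'
#' An adherence scenario is expressed as percentage points of the total
#' population moving low-to-medium (\code{f_lm}) and medium-to-high
#' (\code{f_mh}). In \code{"calibrated"} mode the scenario's mean
#' incidence reduction is supplied directly and per-draw reductions are
#' rescaled low-to-high reduction draws; in \code{"additive_transitions"}
#' mode the reduction is assembled from the two transition terms.
#'
#' @param label Scenario label, e.g. \code{"20%"}.
#' @param f_lm,f_mh Non-negative shifts in percentage points of the total
#'   population.
#' @param mode \code{"calibrated"} or \code{"additive_transitions"}.
#' @param mean_reduction Target mean fractional incidence reduction
#'   (required in calibrated mode).
#' @return A list with class \code{scenario_shift}.
#' @export
scenario_shift <- function(label, f_lm, f_mh,
                           mode = c("calibrated", "additive_transitions"),
                           mean_reduction = NULL) {
  mode <- match.arg(mode)
  if (!is_number(f_lm) || f_lm < 0 || !is_number(f_mh) || f_mh < 0)
    stopf("scenario '%s': shift fractions must be non-negative", label)
  if (mode == "calibrated") {
    if (!is_number(mean_reduction) || mean_reduction < 0 || mean_reduction >= 1)
      stopf("scenario '%s': calibrated mode needs `mean_reduction` in [0, 1)", label)
  }
  structure(list(label = label, f_lm = f_lm, f_mh = f_mh, mode = mode,
                 mean_reduction = mean_reduction),
            class = "scenario_shift")
}

#' Projection specification for long-term savings
#'
#' @param annual_growth Annual cost growth rate (fraction per year).
#' @param discount_rate Annual discount rate (default 1.8\%).
#' @param horizon Projection horizon in years (default 10). Present
#'   values are summed over \code{horizon + 1} annual terms, base year
#'   included.
#' @param base_year First year of the projection (default 2017).
#' @return A list with class \code{projection_spec}.
#' @export
projection_spec <- function(annual_growth, discount_rate = 0.018,
                            horizon = 10, base_year = 2017) {
  if (!is_number(annual_growth)) stopf("`annual_growth` must be a number")
  if (!is_number(discount_rate) || 1 + discount_rate <= 0)
    stopf("`discount_rate` must satisfy 1 + d > 0")
  if (!is_number(horizon) || horizon < 0 || horizon != round(horizon))
    stopf("`horizon` must be a non-negative integer")
  structure(list(annual_growth = annual_growth, discount_rate = discount_rate,
                 horizon = as.integer(horizon), base_year = base_year),
            class = "projection_spec")
}

#' Model configuration
#'
#' Collects the Monte Carlo and evidence-synthesis settings: number of
#' draws, RNG seed, study weighting (\code{"equal"} reproduces the
#' published 25\% mean reduction; \code{"size"} weights by cohort size as
#' the methods text states), the scale on which within-study normals are
#' placed, and how the across-study spread enters each draw
#' (\code{"select"}: pick one study per draw; \code{"average"}: weighted
#' average of all studies per draw).
#'
#' @param n_draws Number of Monte Carlo draws (default 10,000).
#' @param seed Integer RNG seed.
#' @param weighting \code{"equal"} or \code{"size"}.
#' @param rr_scale \code{"raw"} or \code{"log"}.
#' @param spread_mode \code{"select"} or \code{"average"}.
#' @param discount_rate,horizon Long-term projection settings (1.8\%, 10
#'   years).
#' @param scenarios List of [scenario_shift()] objects.
#' @return A list with class \code{coi_config}.
#' @export
coi_config <- function(n_draws = 10000, seed = 42,
                       weighting = c("equal", "size"),
                       rr_scale = c("raw", "log"),
                       spread_mode = c("select", "average"),
                       discount_rate = 0.018, horizon = 10,
                       scenarios = meddiet_scenarios()) {
  if (!is_count(n_draws)) stopf("`n_draws` must be a positive integer")
  if (!is_number(seed)) stopf("`seed` must be a number")
  if (!is_number(discount_rate) || discount_rate < 0)
    stopf("`discount_rate` must be >= 0")
  if (!is_number(horizon) || horizon < 0)
    stopf("`horizon` must be >= 0")
  stopifnot(is.list(scenarios))
  for (s in scenarios) stopifnot(inherits(s, "scenario_shift"))
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         weighting = match.arg(weighting), rr_scale = match.arg(rr_scale),
         spread_mode = match.arg(spread_mode),
         discount_rate = discount_rate, horizon = as.integer(horizon),
         scenarios = scenarios),
    class = "coi_config")
}
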