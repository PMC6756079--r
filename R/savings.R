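#' Per-draw incidence reductions for a scenario
#'
#' @param label Scenario label.
#' @param draws Numeric vector of fractional reductions, all in [0, 1).
#' @param mode Provenance: \code{"calibrated"}, \code{"additive_transitions"}
#'   or \code{"fixed"}.
#' @param seed Seed the draws descend from (NA for deterministic input).
#' @return A list with class \code{incidence_reduction}.
#' @export
incidence_reduction <- function(label, draws, mode = "fixed", seed = NA_integer_) {
  if (!is.numeric(draws) || !length(draws))
    stopf("`draws` must be a non-empty numeric vector")
  if (any(!is.finite(draws)) || any(draws < 0) || any(draws >= 1))
    stopf("incidence reductions must lie in [0, 1)")
  structure(list(label = label, draws = as.numeric(draws),
                 mode = mode, seed = seed),
            class = "incidence_reduction")
}

# Shared summariser: every category's per-draw saving is base_c * R_i, so
# means and percentile bounds factor through the moments of R
# (comonotonicity). `base` is the vector of per-category multipliers.
summarize_savings <- function(table, base, reduction, horizon) {
  R <- reduction$draws
  q <- stats::quantile(R, c(0.025, 0.975), type = 7, names = FALSE)
  m <- mean(R)
  cats <- data.frame(
    category = table$categories$category,
    kind = table$categories$kind,
    mean = base * m,
    ci_low = base * q[1],
    ci_high = base * q[2])
  direct <- table$categories$kind == "direct"
  subtotals <- data.frame(
    level = c("direct", "indirect", "total"),
    mean = c(sum(base[direct]) * m, sum(base[!direct]) * m, sum(base) * m),
    ci_low = c(sum(base[direct]), sum(base[!direct]), sum(base)) * q[1],
    ci_high = c(sum(base[direct]), sum(base[!direct]), sum(base)) * q[2])
  structure(
    list(scenario = reduction$label, horizon = horizon,
         country = table$country, currency = table$currency,
         units = table$units, categories = cats, subtotals = subtotals,
         total_draws = sum(base) * R,
         percent_decrease = 100 * sum(base) * m / table$total_2017),
    class = "savings_summary")
}

#' Short-term (annual) cost savings
#'
#' For each draw \code{i} and category \code{c}, the saving is
#' \code{amount_2017(c) * R_i * variable_share(c)}: in the short run only
#' the variable share of a category scales with incidence. Summaries are
#' the Monte Carlo mean and empirical 2.5/97.5 percentile bounds.
#'
#' @param table A [cost_table()] with 2017 amounts.
#' @param reduction An [incidence_reduction()].
#' @return A \code{savings_summary}: per-category and
#'   direct/indirect/total records of (mean, ci_low, ci_high) in the
#'   table's currency and units, plus the total draw vector and the mean
#'   percent decrease in total 2017 cost.
#' @export
short_term_savings <- function(table, reduction) {
  stopifnot(inherits(table, "cost_table"), inherits(reduction, "incidence_reduction"))
  if (any(is.na(table$categories$variable_share)))
    stopf("cost table '%s': missing variable share", table$country)
  base <- table$categories$amount_2017 * table$categories$variable_share
  summarize_savings(table, base, reduction, horizon = "short")
}

#' Present-value annuity factor of a growing cost stream
#'
#' Closed-form geometric series \code{sum_{t=0}^{H} ((1+g)/(1+d))^t} with
#' \code{H + 1} annual terms (base year included), the factor that turns
#' a base-year saving into the discounted value of savings growing at
#' \code{g} over the horizon.
#'
#' @param spec A [projection_spec()].
#' @return The scalar factor.
#' @examples
#' annuity_factor(projection_spec(0.0354, 0.018, 10))  # 11.99
#' @export
annuity_factor <- function(spec) {
  stopifnot(inherits(spec, "projection_spec"))
  r <- (1 + spec$annual_growth) / (1 + spec$discount_rate)
  H <- spec$horizon
  if (abs(r - 1) < 1e-12) return(as.numeric(H) + 1)
  (r^(H + 1) - 1) / (r - 1)
}

#' Long-term (10-year discounted) cost savings
#'
#' In the long run all costs are variable: a 1\% fall in incidence cuts
#' every cost category by 1\%. Per draw, the discounted 10-year total is
#' \code{total_2017 * R_i * annuity_factor(spec)}; per-category figures
#' are apportioned by each category's share of the 2017 total (shares
#' normalised over the category sum, so category means add exactly to the
#' total).
#'
#' @param table A [cost_table()].
#' @param reduction An [incidence_reduction()].
#' @param spec A [projection_spec()]; defaults to the table's own growth
#'   rate with a 1.8\% discount rate over 10 years.
#' @return A \code{savings_summary} (see [short_term_savings()]).
#' @export
long_term_savings <- function(table, reduction,
                              spec = projection_spec(table$annual_growth)) {
  stopifnot(inherits(table, "cost_table"), inherits(reduction, "incidence_reduction"))
  af <- annuity_factor(spec)
  shares <- table$categories$amount_2017 / sum(table$categories$amount_2017)
  base <- shares * table$total_2017 * af
  summarize_savings(table, base, reduction, horizon = "long")
}

#' Projected total CVD cost at the end of the horizon
#'
#' Compound growth of the 2017 total at the table's (or spec's) annual
#' rate: \code{total_2017 * (1 + g)^H}.
#'
#' @param table A [cost_table()].
#' @param spec A [projection_spec()].
#' @return Projected total in the table's units.
#' @export
project_total_cost <- function(table, spec = projection_spec(table$annual_growth)) {
  stopifnot(inherits(table, "cost_table"), inherits(spec, "projection_spec"))
  table$total_2017 * (1 + spec$annual_growth)^spec$horizon
}

#' Mean savings as a percent of total 2017 cost
#'
#' @param summary A \code{savings_summary}.
#' @param table The [cost_table()] it was computed from.
#' @return Percent decrease (full precision; round to 1 decimal for
#'   reporting).
#' @export
percent_decrease <- function(summary, table) {
  stopifnot(inherits(summary, "savings_summary"), inherits(table, "cost_table"))
  if (table$total_2017 == 0) stopf("total 2017 cost is zero")
  total_mean <- summary$subtotals$mean[summary$subtotals$level == "total"]
  100 * total_mean / table$total_2017
}

#' @export
print.savings_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%s-term CVD cost savings, %s, scenario %s (%s %s)\n",
              if (x$horizon == "short") "Short" else "Long",
              x$country, x$scenario, x$currency, x$units))
  df <- rbind(
    data.frame(category = x$categories$category, kind = x$categories$kind,
               mean = x$categories$mean, ci_low = x$categories$ci_low,
               ci_high = x$categories$ci_high),
    data.frame(category = c("Total direct", "Total indirect", "Total savings"),
               kind = "",
               mean = x$subtotals$mean, ci_low = x$subtotals$ci_low,
               ci_high = x$subtotals$ci_high))
  df$mean <- round(df$mean, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Mean decrease in total 2017 CVD cost: %.1f%%\n", x$percent_decrease))
  invisible(x)
}
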