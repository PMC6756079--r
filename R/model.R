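#' Fit the Mediterranean-diet cost-of-illness model
#'
#' Runs the full three-step model: (1) average the adherence studies into
#' a baseline tertile distribution and apply each scenario's shifts; (2)
#' build the across-study mixture of CVD risk ratios and draw from it;
#' (3) propagate per-draw incidence reductions through every cost table
#' to short-term (annual, fixed-vs-variable shares) and long-term
#' (10-year discounted, all costs variable) savings.
#'
#' In the default calibrated mode, per-draw scenario reductions are
#' \code{scale * (1 - rr_lh)} with the scale chosen so the closed-form
#' mean equals the scenario's calibrated mean reduction; in
#' additive-transitions mode they are assembled from the population
#' shift fractions and both risk contrasts (see
#' [scenario_incidence_reduction()]).
#'
#' @param adherence An [adherence_studies()] table (default: bundled US
#'   studies).
#' @param risk A [risk_studies()] table (default: bundled CVD cohort
#'   studies).
#' @param costs Named list of [cost_table()]s (default: bundled US and
#'   Canada tables).
#' @param scenarios List of [scenario_shift()]s (default:
#'   [meddiet_scenarios()]).
#' @param n_draws,seed,weighting,rr_scale,spread_mode,discount_rate,horizon
#'   Passed to [coi_config()].
#' @return An object of class \code{meddiet_coi} with elements
#'   \code{baseline} (adherence distribution), \code{mixture},
#'   \code{draws}, \code{reductions} (per scenario),
#'   \code{results[[scenario]][[country]]$short / $long}
#'   (savings summaries), \code{projections} (10-year total cost per
#'   country), \code{config}, and the inputs.
#' @examples
#' fit <- meddiet_coi(n_draws = 2000, seed = 1)
#' fit
#' @export
meddiet_coi <- function(adherence = us_adherence_studies(),
                        risk = cvd_risk_studies(),
                        costs = list(us = us_cost_table(),
                                     canada = canada_cost_table()),
                        scenarios = meddiet_scenarios(),
                        n_draws = 10000, seed = 42,
                        weighting = c("equal", "size"),
                        rr_scale = c("raw", "log"),
                        spread_mode = c("select", "average"),
                        discount_rate = 0.018, horizon = 10) {
  config <- coi_config(n_draws = n_draws, seed = seed,
                       weighting = match.arg(weighting),
                       rr_scale = match.arg(rr_scale),
                       spread_mode = match.arg(spread_mode),
                       discount_rate = discount_rate, horizon = horizon,
                       scenarios = scenarios)
  adherence <- adherence_studies(adherence)
  risk <- risk_studies(risk)
  stopifnot(is.list(costs), length(costs) >= 1)
  for (tb in costs) stopifnot(inherits(tb, "cost_table"))
  if (is.null(names(costs))) names(costs) <- vapply(costs, `[[`, "", "country")

  baseline <- baseline_adherence(adherence)
  mixture <- build_mixture(risk, weighting = config$weighting,
                           rr_scale = config$rr_scale,
                           spread_mode = config$spread_mode)
  draws <- sample_mixture(mixture, config$n_draws, config$seed)
  mom <- mixture_moments(mixture)
  mean_reduction_lh <- 1 - mom["lh", "mean"]

  reductions <- list()
  results <- list()
  for (sc in config$scenarios) {
    if (sc$mode == "calibrated") {
      scale <- sc$mean_reduction / mean_reduction_lh
      r <- scenario_incidence_reduction(sc, draws$rr_lm, draws$rr_lh,
                                        mode = "calibrated",
                                        calibrated_scale = scale)
    } else {
      r <- scenario_incidence_reduction(sc, draws$rr_lm, draws$rr_lh)
    }
    # a draw with a sampled ratio above 1 implies harm; it contributes no
    # savings rather than a negative reduction
    red <- incidence_reduction(sc$label, pmax(r, 0), mode = sc$mode,
                               seed = config$seed)
    reductions[[sc$label]] <- red
    results[[sc$label]] <- lapply(costs, function(tb) {
      spec <- projection_spec(tb$annual_growth,
                              discount_rate = config$discount_rate,
                              horizon = config$horizon)
      list(short = short_term_savings(tb, red),
           long = long_term_savings(tb, red, spec))
    })
  }
  projections <- vapply(costs, function(tb)
    project_total_cost(tb, projection_spec(tb$annual_growth,
                                           discount_rate = config$discount_rate,
                                           horizon = config$horizon)),
    numeric(1))

  structure(
    list(baseline = baseline, mixture = mixture, draws = draws,
         reductions = reductions, results = results,
         projections = projections, config = config,
         inputs = list(adherence = adherence, risk = risk, costs = costs)),
    class = "meddiet_coi")
}

#' @export
print.meddiet_coi <- function(x, ...) {
  cat("Mediterranean-diet cost-of-illness model\n")
  cat(sprintf("  %d Monte Carlo draws (seed %d), %s study weights, %s scale, %s mode\n",
              x$config$n_draws, x$config$seed, x$mixture$weighting,
              x$mixture$rr_scale, x$mixture$spread_mode))
  print(x$baseline)
  s <- summarize_draws(x$draws)
  cat(sprintf("  Mean low-to-high CVD reduction: %.1f%% (sd %.1f pp)\n",
              100 * s["lh", "mean"], 100 * s["lh", "sd"]))
  for (lab in names(x$results)) {
    for (cn in names(x$results[[lab]])) {
      st <- x$results[[lab]][[cn]]$short
      tot <- st$subtotals[st$subtotals$level == "total", ]
      cat(sprintf("  %s scenario, %s: annual savings %s %.2f %s (95%% CI %.2f-%.2f), %.1f%% of total CVD cost\n",
                  lab, st$country, st$currency, tot$mean, st$units,
                  tot$ci_low, tot$ci_high, st$percent_decrease))
    }
  }
  invisible(x)
}

#' Summarise a fitted cost-of-illness model
#'
#' @param object A [meddiet_coi()] fit.
#' @param ... Unused.
#' @return A \code{summary.meddiet_coi} object: draw summary, shifted
#'   adherence distributions, per-scenario/country savings summaries and
#'   projected totals; printing renders the full set of savings tables.
#' @export
summary.meddiet_coi <- function(object, ...) {
  shifted <- lapply(object$config$scenarios, function(sc)
    apply_scenario_shift(object$baseline, sc))
  names(shifted) <- vapply(object$config$scenarios, `[[`, "", "label")
  structure(
    list(baseline = object$baseline, shifted = shifted,
         draw_summary = summarize_draws(object$draws),
         moments = mixture_moments(object$mixture),
         results = object$results, projections = object$projections,
         config = object$config),
    class = "summary.meddiet_coi")
}

#' @export
print.summary.meddiet_coi <- function(x, ...) {
  cat("Mediterranean-diet cost-of-illness model: summary\n\n")
  print(x$baseline)
  for (lab in names(x$shifted)) {
    cat(sprintf("After %s scenario shift: ", lab))
    print(x$shifted[[lab]])
  }
  cat("\nCVD reduction draws (fraction, by contrast):\n")
  print(round(x$draw_summary, 4))
  cat("\n")
  for (lab in names(x$results)) {
    for (cn in names(x$results[[lab]])) {
      print(x$results[[lab]][[cn]]$short)
      cat("\n")
      print(x$results[[lab]][[cn]]$long)
      cat("\n")
    }
  }
  cat("Projected total CVD cost at horizon end:\n")
  print(round(x$projections, 1))
  invisible(x)
}

#' Mixture component parameters of a fitted model
#'
#' @param object A [meddiet_coi()] fit.
#' @param ... Unused.
#' @return Matrix of per-study weights, means and standard errors (one
#'   row per study, on the configured sampling scale).
#' @export
coef.meddiet_coi <- function(object, ...) {
  comp <- object$mixture$components
  m <- as.matrix(comp[c("weight", "mean_lm", "se_lm", "mean_lh", "se_lh")])
  rownames(m) <- comp$name
  m
}

#' Simulate new risk-ratio draws from a fitted model
#'
#' @param object A [meddiet_coi()] fit.
#' @param nsim Number of draws per replicate.
#' @param seed Integer seed (defaults to the fitted seed).
#' @param ... Unused.
#' @return A data.frame with columns \code{draw}, \code{study},
#'   \code{rr_lm}, \code{rr_lh}.
#' @export
simulate.meddiet_coi <- function(object, nsim = object$config$n_draws,
                                 seed = object$config$seed, ...) {
  d <- sample_mixture(object$mixture, nsim, seed)
  data.frame(draw = seq_len(nsim), study = d$study_index,
             rr_lm = d$rr_lm, rr_lh = d$rr_lh)
}

#' Savings for a new cost table under the fitted scenarios
#'
#' @param object A [meddiet_coi()] fit.
#' @param newdata A [cost_table()].
#' @param horizon \code{"short"}, \code{"long"} or both.
#' @param ... Unused.
#' @return Nested list \code{[[scenario]][[horizon]]} of savings
#'   summaries.
#' @export
predict.meddiet_coi <- function(object, newdata,
                                horizon = c("short", "long"), ...) {
  stopifnot(inherits(newdata, "cost_table"))
  horizon <- match.arg(horizon, several.ok = TRUE)
  spec <- projection_spec(newdata$annual_growth,
                          discount_rate = object$config$discount_rate,
                          horizon = object$config$horizon)
  lapply(object$reductions, function(red) {
    out <- list()
    if ("short" %in% horizon) out$short <- short_term_savings(newdata, red)
    if ("long" %in% horizon) out$long <- long_term_savings(newdata, red, spec)
    out
  })
}

#' Plot the distribution of total savings
#'
#' Histogram of the per-draw total savings for one scenario, country and
#' horizon, with the mean and 95\% percentile interval marked.
#'
#' @param x A [meddiet_coi()] fit.
#' @param scenario Scenario label or index (default first).
#' @param country Country name or index (default first).
#' @param horizon \code{"short"} or \code{"long"}.
#' @param ... Passed to [graphics::hist()].
#' @return The savings summary plotted, invisibly.
#' @export
plot.meddiet_coi <- function(x, scenario = 1, country = 1,
                             horizon = c("short", "long"), ...) {
  horizon <- match.arg(horizon)
  s <- x$results[[scenario]][[country]][[horizon]]
  tot <- s$subtotals[s$subtotals$level == "total", ]
  graphics::hist(s$total_draws, breaks = 50, freq = FALSE,
                 main = sprintf("%s, %s scenario (%s-term)",
                                s$country, s$scenario, s$horizon),
                 xlab = sprintf("Total savings (%s %s)", s$currency, s$units),
                 col = "grey85", border = "grey50", ...)
  graphics::abline(v = tot$mean, lwd = 2)
  graphics::abline(v = c(tot$ci_low, tot$ci_high), lty = 2)
  invisible(s)
}
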