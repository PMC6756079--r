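# Bundled model inputs: the published adherence, risk and cost tables the
# reproduction runs on. Amounts are held exactly as printed (US$ billion,
# Can$ million); CPI factors are the table-implied base->2017 ratios.

#' Bundled US adherence studies
#'
#' Three US cohort studies reporting the percentage of participants in
#' low / medium / high Mediterranean-diet adherence tertiles.
#'
#' @return An [adherence_studies()] table.
#' @export
us_adherence_studies <- function() {
  adherence_studies(data.frame(
    name   = c("Ahmad 2018 (Women's Health Study)",
               "Park 2003 (NHANES III)",
               "Tsivgoulis 2015 (REGARDS)"),
    n      = c(25994L, 4700L, 20197L),
    scale  = c("9-point", "5-point", "9-point"),
    low    = c(39.0, 36.8, 32.8),
    medium = c(36.2, 31.9, 41.4),
    high   = c(24.8, 31.3, 25.8)))
}

#' Bundled CVD risk studies
#'
#' Five US cohort studies reporting adjusted hazard ratios or relative
#' risks (with 95\% CIs) of CVD for medium-vs-low and high-vs-low
#' Mediterranean-diet adherence. Standard errors are derived from the
#' intervals.
#'
#' @return A [risk_studies()] table.
#' @export
cvd_risk_studies <- function() {
  risk_studies(data.frame(
    name  = c("Ahmad 2018 (Women's Health Study)",
              "Shikany 2018 (REGARDS)",
              "George 2014 (WHI OS)",
              "Gardener 2011 (NOMAS)",
              "Fung 2009 (Nurses' Health)"),
    n     = c(25994L, 3562L, 63805L, 1559L, 1399L),
    rr_lm = c(0.77, 0.91, 0.82, 0.72, 0.87),
    lo_lm = c(0.67, 0.76, 0.70, 0.54, 0.77),
    hi_lm = c(0.90, 1.10, 0.97, 0.96, 0.99),
    rr_lh = c(0.72, 0.78, 0.79, 0.75, 0.71),
    lo_lh = c(0.61, 0.62, 0.67, 0.56, 0.62),
    hi_lh = c(0.86, 0.98, 0.94, 0.99, 0.82)))
}

# Short-run variable share of hospital-type cost categories, back-derived
# from the published short-term savings table: (0.6/101)/(1.3/36.1) = 0.165.
# Non-hospital categories are fully variable in the short run.
HOSPITAL_VARIABLE_SHARE <- 0.165

#' Bundled US cost table (US$ billion)
#'
#' Direct and indirect CVD costs for the United States, 2013--2014 base
#' year inflated to 2017 dollars by the US health-care CPI. Hospital-type
#' categories (inpatient, emergency, outpatient) carry the 0.165
#' short-run variable share; all other categories are fully variable.
#' The forward growth rate is 3.54\%/yr (US health-care CPI, 2007--2017).
#'
#' @return A [cost_table()].
#' @export
us_cost_table <- function() {
  cost_table(
    country = "United States", currency = "US$", units = "billion",
    base_year = 2013L,
    categories = data.frame(
      category = c("Hospital inpatient stays",
                   "Hospital emergency room visits",
                   "Hospital outpatient or office-based provider visits",
                   "Home healthcare",
                   "Prescribed medicines",
                   "Lost productivity/mortality"),
      kind = c(rep("direct", 5), "indirect"),
      amount_base = c(90.3, 10.6, 46.3, 19.6, 32.3, 130.5),
      amount_2017 = c(101, 11.9, 51.8, 21.9, 36.1, 145.9),
      variable_share = c(HOSPITAL_VARIABLE_SHARE, HOSPITAL_VARIABLE_SHARE,
                         HOSPITAL_VARIABLE_SHARE, 1, 1, 1)),
    cpi_factor = 368.5 / 329.6,
    annual_growth = 0.0354,
    total_2017 = 368.5)
}

#' Bundled Canada cost table (Can$ million)
#'
#' Direct and indirect CVD costs for Canada, 2010 base year inflated to
#' 2017 dollars by Statistics Canada's health-care CPI. Hospitals carry
#' the 0.165 short-run variable share; the forward growth rate is
#' 1.3\%/yr (2007--2017).
#'
#' @return A [cost_table()].
#' @export
canada_cost_table <- function() {
  cost_table(
    country = "Canada", currency = "Can$", units = "million",
    base_year = 2010L,
    categories = data.frame(
      category = c("Hospitals", "Drugs", "Physicians", "Formal caregiving",
                   "Mortality", "Morbidity and long-term caring"),
      kind = c(rep("direct", 4), rep("indirect", 2)),
      amount_base = c(6128, 4957, 1910, 5.1, 130.9, 513.3),
      amount_2017 = c(6434, 5205, 2005, 5.4, 137.4, 539),
      variable_share = c(HOSPITAL_VARIABLE_SHARE, 1, 1, 1, 1, 1)),
    cpi_factor = 14326 / 13644,
    annual_growth = 0.013,
    total_2017 = 14326)
}

#' Calibrated scenario mean incidence reductions
#'
#' Scenario-level mean fractional reductions in CVD incidence under the
#' 20\% and 80\% adherence-increase scenarios, back-calculated from the
#' published short-term savings tables (fully-variable rows: e.g.
#' prescribed medicines 1.3/36.1, lost productivity 5.2/145.9, total
#' 8.2/231.08 all imply ~0.0355 for the 20\% scenario). These are the
#' default calibration targets of [meddiet_scenarios()].
#'
#' @return Named numeric vector \code{c("20%" = 0.0355, "80%" = 0.1345)}.
#' @export
calibrated_reductions <- function() {
  c("20%" = 0.0355, "80%" = 0.1345)
}

#' Bundled adherence scenarios
#'
#' The 20\% and 80\% adherence-increase scenarios: percentage points of
#' the total population shifting low-to-medium and medium-to-high, with
#' calibrated scenario mean reductions (see [calibrated_reductions()]).
#'
#' @param mode Reduction mode for both scenarios, \code{"calibrated"}
#'   (reproduction default) or \code{"additive_transitions"} (assembled
#'   from the stated transition fractions and pooled risk ratios).
#' @return List of two [scenario_shift()] objects.
#' @export
meddiet_scenarios <- function(mode = c("calibrated", "additive_transitions")) {
  mode <- match.arg(mode)
  r <- calibrated_reductions()
  list(
    scenario_shift("20%", f_lm = 9.3, f_mh = 18.8, mode = mode,
                   mean_reduction = if (mode == "calibrated") r[["20%"]]),
    scenario_shift("80%", f_lm = 35.5, f_mh = 48.3, mode = mode,
                   mean_reduction = if (mode == "calibrated") r[["80%"]]))
}

# Published headline values used only to juxtapose computed results in
# rendered reports; never consumed by any computation.
published_reference <- function() {
  data.frame(
    country  = c("United States", "United States", "Canada", "Canada",
                 "United States", "United States", "Canada", "Canada"),
    scenario = rep(c("20%", "80%"), 4),
    horizon  = rep(c("short", "long"), each = 4),
    total    = c(8.2, 31.0, 0.32, 1.20, 157.1, 596, 5.5, 20.9),
    pct_decrease = c(2.2, 8.4, 2.2, 8.4, NA, NA, NA, NA),
    units    = c(rep("billion", 2), rep("billion", 2), rep("billion", 4)))
}
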