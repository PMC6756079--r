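# Shared test helpers.

# Agreement with a printed table cell: within one unit of its last
# printed digit (step), with a float-noise epsilon.
expect_printed <- function(computed, printed, step) {
  expect_lte(abs(computed - printed), step + 1e-9,
             label = sprintf("|%.4f - %g|", computed, printed))
}

# A deterministic reduction object: every draw equal to r.
const_reduction <- function(r, label = "fixed", n = 1L) {
  incidence_reduction(label, rep(r, n), mode = "fixed")
}

# Small hand-built risk-study table with convenient round numbers.
toy_risk_studies <- function() {
  z <- qnorm(0.975)
  risk_studies(data.frame(
    name = c("A", "B"), n = c(1000L, 3000L),
    rr_lm = c(0.8, 0.9), lo_lm = c(0.8 - z * 0.05, 0.9 - z * 0.02),
    hi_lm = c(0.8 + z * 0.05, 0.9 + z * 0.02),
    rr_lh = c(0.7, 0.8), lo_lh = c(0.7 - z * 0.04, 0.8 - z * 0.03),
    hi_lh = c(0.7 + z * 0.04, 0.8 + z * 0.03)))
}
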