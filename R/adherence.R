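#' Adherence tertile distribution
#'
#' Percent of the adult population in the low / medium / high
#' Mediterranean-diet adherence tertiles.
#'
#' @param low,medium,high Percentages in [0, 100] summing to 100 within
#'   0.1.
#' @return A named numeric vector with class \code{adherence_distribution}.
#' @export
adherence_distribution <- function(low, medium, high) {
  x <- c(low = low, medium = medium, high = high)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stopf("tertile percentages must lie in [0, 100]")
  if (abs(sum(x) - 100) > 0.1)
    stopf("tertile percentages sum to %.3f, not 100 +/- 0.1", sum(x))
  structure(x, class = "adherence_distribution")
}

#' @export
print.adherence_distribution <- function(x, ...) {
  cat(sprintf("Adherence tertiles (%% of population): low %.1f, medium %.1f, high %.1f\n",
              x[["low"]], x[["medium"]], x[["high"]]))
  invisible(x)
}

#' Baseline adherence distribution
#'
#' Unweighted arithmetic mean of each tertile percentage across the
#' supplied adherence studies.
#'
#' @param studies An [adherence_studies()] table.
#' @return An [adherence_distribution()].
#' @examples
#' baseline_adherence(us_adherence_studies())  # (36.2, 36.5, 27.3)
#' @export
baseline_adherence <- function(studies) {
  studies <- adherence_studies(studies)
  adherence_distribution(mean(studies$low), mean(studies$medium), mean(studies$high))
}

#' Apply an adherence scenario shift
#'
#' Moves \code{f_lm} percentage points of the total population from the
#' low to the medium tertile and \code{f_mh} from medium to high. The
#' tertile sum is preserved exactly.
#'
#' @param dist An [adherence_distribution()].
#' @param shift A [scenario_shift()].
#' @return The shifted [adherence_distribution()].
#' @export
apply_scenario_shift <- function(dist, shift) {
  stopifnot(inherits(dist, "adherence_distribution"),
            inherits(shift, "scenario_shift"))
  low <- dist[["low"]] - shift$f_lm
  med <- dist[["medium"]] + shift$f_lm - shift$f_mh
  high <- dist[["high"]] + shift$f_mh
  if (low < 0)
    stopf("scenario '%s': low tertile would fall below 0 (shift %.1f exceeds available %.1f)",
          shift$label, shift$f_lm, dist[["low"]])
  if (med < 0)
    stopf("scenario '%s': medium tertile would fall below 0", shift$label)
  adherence_distribution(low, med, high)
}

#' Scenario-level incidence reduction
#'
#' Converts an adherence scenario plus risk ratios into a fractional
#' reduction in CVD incidence. In \code{additive_transitions} mode the
#' reduction is \code{(f_lm/100) (1 - rr_lm) + (f_mh/100) (1 -
#' rr_lh/rr_lm)} — the medium-to-high contrast is the ratio of the two
#' published contrasts, since hazard ratios compose multiplicatively; a
#' negative medium-to-high term (rr_lh > rr_lm) is floored at 0 with a
#' warning. In \code{calibrated} mode the low-to-high reduction
#' \code{1 - rr_lh} is rescaled by \code{calibrated_scale} so that its
#' mean matches an externally supplied scenario mean.
#'
#' Vectorised over \code{rr_lm} / \code{rr_lh}, so it maps draw vectors
#' to per-draw reductions.
#'
#' @param shift A [scenario_shift()].
#' @param rr_lm,rr_lh Risk ratios (scalars or equal-length draw vectors).
#' @param mode \code{"additive_transitions"} or \code{"calibrated"};
#'   defaults to the shift's own mode.
#' @param calibrated_scale Scale applied to \code{1 - rr_lh} in
#'   calibrated mode.
#' @return Fractional incidence reduction(s), same length as the inputs.
#' @export
scenario_incidence_reduction <- function(shift, rr_lm, rr_lh,
                                         mode = shift$mode,
                                         calibrated_scale = NULL) {
  stopifnot(inherits(shift, "scenario_shift"))
  mode <- match.arg(mode, c("additive_transitions", "calibrated"))
  if (any(rr_lm <= 0) || any(rr_lh <= 0))
    stopf("risk ratios must be positive")
  if (mode == "calibrated") {
    if (!is_number(calibrated_scale))
      stopf("calibrated mode requires a `calibrated_scale`")
    return(calibrated_scale * (1 - rr_lh))
  }
  term_mh <- 1 - rr_lh / rr_lm
  if (any(term_mh < 0)) {
    warning(sprintf("scenario '%s': rr_lh > rr_lm in %d draw(s); medium-to-high term floored at 0",
                    shift$label, sum(term_mh < 0)), call. = FALSE)
    term_mh <- pmax(term_mh, 0)
  }
  (shift$f_lm / 100) * (1 - rr_lm) + (shift$f_mh / 100) * term_mh
}
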