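#' Dose-tiered infusion-duration rule
#'
#' Vancomycin is infused slowly to limit infusion reactions. The rule is a
#' step function of the dose: each tier maps doses up to an inclusive upper
#' bound (mg) to a fixed duration (min); doses above the last tier are infused
#' at a constant overflow rate. The default rule is the one both bundled
#' nomograms assume: 60 min up to 1000 mg, 90 min up to 1500 mg, 120 min up to
#' 2000 mg, and about 1 g/h above 2000 mg.
#'
#' @param tiers List of `c(dose_upper_bound_mg, duration_min)` pairs with
#'   strictly increasing bounds and durations.
#' @param overflow_rate_mg_per_h Infusion rate applied above the last tier.
#' @return An object of class `vanc_infusion_rule`.
#' @export
#' @examples
#' infusion_rule()
infusion_rule <- function(tiers = list(c(1000, 60), c(1500, 90), c(2000, 120)),
                          overflow_rate_mg_per_h = 1000) {
  if (!is.list(tiers) || length(tiers) == 0L) {
    stop_validation("tiers must be a non-empty list of (bound, duration) pairs")
  }
  ok <- vapply(tiers, function(t) {
    is.numeric(t) && length(t) == 2L && all(is.finite(t)) && all(t > 0)
  }, logical(1))
  if (!all(ok)) {
    stop_validation("each tier must be two positive numbers (bound_mg, duration_min)")
  }
  bounds <- vapply(tiers, `[`, numeric(1), 1L)
  durations <- vapply(tiers, `[`, numeric(1), 2L)
  if (is.unsorted(bounds, strictly = TRUE) ||
      is.unsorted(durations, strictly = TRUE)) {
    stop_validation("tier bounds and durations must be strictly increasing")
  }
  if (!is_scalar_number(overflow_rate_mg_per_h) || overflow_rate_mg_per_h <= 0) {
    stop_validation("overflow_rate_mg_per_h must be a positive number")
  }
  # every tier's implied rate must not exceed the overflow rate
  rate_cap <- overflow_rate_mg_per_h / 60
  bad <- which(bounds / durations > rate_cap + 1e-9)
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "tier %d implies %.3f mg/min, above the overflow rate %.3f mg/min",
      bad[1L], bounds[bad[1L]] / durations[bad[1L]], rate_cap
    ))
  }
  structure(
    list(bounds = bounds, durations = durations,
         overflow_rate_mg_per_h = overflow_rate_mg_per_h),
    class = "vanc_infusion_rule"
  )
}

#' @rdname infusion_rule
#' @export
default_infusion_rule <- function() infusion_rule()

round_half_up <- function(x) floor(x + 0.5)

#' Infusion duration for a dose
#'
#' Applies an [infusion_rule()] to a dose: the duration of the first tier
#' whose bound covers the dose, or, above the last tier, the time implied by
#' the overflow rate, rounded half-up to a whole minute (minutes are the
#' display unit).
#'
#' @param rule A `vanc_infusion_rule`.
#' @param dose_mg Positive dose in mg.
#' @return Duration in minutes.
#' @export
#' @examples
#' infusion_duration_min(default_infusion_rule(), 1250) # 90
#' infusion_duration_min(default_infusion_rule(), 2250) # 135
infusion_duration_min <- function(rule, dose_mg) {
  if (!inherits(rule, "vanc_infusion_rule")) {
    stop_validation("rule must be a vanc_infusion_rule")
  }
  if (!is_scalar_number(dose_mg) || dose_mg <= 0) {
    stop_validation("dose_mg must be a single positive number")
  }
  i <- which(dose_mg <= rule$bounds)
  if (length(i) > 0L) {
    return(rule$durations[i[1L]])
  }
  round_half_up(dose_mg * 60 / rule$overflow_rate_mg_per_h)
}

#' @export
print.vanc_infusion_rule <- function(x, ...) {
  cat("<infusion rule>\n")
  for (i in seq_along(x$bounds)) {
    cat(sprintf("  dose <= %g mg: %g min\n", x$bounds[i], x$durations[i]))
  }
  cat(sprintf("  above: %g mg/h\n", x$overflow_rate_mg_per_h))
  invisible(x)
}
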