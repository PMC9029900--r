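#' Validated patient input
#'
#' The engine's sole clinical input: the population (which selects the
#' nomogram screen, never inferred from weight), actual body weight in kg,
#' estimated creatinine clearance in mL/min, and — needed only when a
#' neonatal age-conditional maintenance cell is hit — postnatal age in days.
#'
#' @param population `"adult"` or `"pediatric"`; always explicit.
#' @param weight Actual body weight in kg (> 0).
#' @param crcl Estimated creatinine clearance in mL/min (>= 0). How it was
#'   estimated is out of scope; it is an input, not a computation.
#' @param postnatal_age_days Optional non-negative integer age in days.
#' @return An object of class `vanc_patient`.
#' @export
#' @examples
#' patient_input("adult", weight = 75, crcl = 65)
patient_input <- function(population = c("adult", "pediatric"),
                          weight, crcl, postnatal_age_days = NULL) {
  population <- match.arg(population)
  if (!is_scalar_number(weight) || weight <= 0) {
    stop_validation("weight must be a single positive number (kg)")
  }
  if (!is_scalar_number(crcl) || crcl < 0) {
    stop_validation("crcl must be a single non-negative number (mL/min)")
  }
  if (!is.null(postnatal_age_days)) {
    if (!is_scalar_number(postnatal_age_days) || postnatal_age_days < 0 ||
        postnatal_age_days %% 1 != 0) {
      stop_validation("postnatal_age_days must be a single non-negative integer")
    }
    postnatal_age_days <- as.integer(postnatal_age_days)
  }
  structure(
    list(population = population, weight = as.numeric(weight),
         crcl = as.numeric(crcl), postnatal_age_days = postnatal_age_days),
    class = "vanc_patient"
  )
}

#' Resolve a maintenance cell's dosing interval
#'
#' Unconditional cells return their interval unchanged; postnatal age is
#' ignored. Age-conditional (neonatal) cells resolve to the shorter interval
#' if postnatal age > 7 days and to the longer one if < 7 days. Age exactly 7
#' days is not covered by either branch of the rule; it resolves to the longer
#' (q12) interval with a warning attached, the conservative reading. A
#' conditional cell with no age supplied is an error, never a guess.
#'
#' @param entry A [dose_entry()].
#' @param postnatal_age_days Postnatal age in days, or `NULL`.
#' @return List with `interval_h` and a character vector `warnings`
#'   (zero-length when none apply).
#' @export
#' @examples
#' resolve_interval(dose_entry(25, conditional_interval = c(8, 12)), 10)
resolve_interval <- function(entry, postnatal_age_days = NULL) {
  if (!inherits(entry, "vanc_dose_entry")) {
    stop_validation("entry must be a vanc_dose_entry")
  }
  if (!is_conditional(entry)) {
    return(list(interval_h = entry$interval_h, warnings = character(0)))
  }
  ci <- entry$conditional_interval
  if (is.null(postnatal_age_days)) {
    stop_missing_age(paste0(
      "this maintenance cell's interval depends on postnatal age ",
      "(q", ci[["if_age_gt_7d_h"]], "h if > 7 days, q",
      ci[["if_age_le_7d_h"]], "h if < 7 days); supply postnatal_age_days"
    ))
  }
  if (!is_scalar_number(postnatal_age_days) || postnatal_age_days < 0) {
    stop_validation("postnatal_age_days must be a single non-negative number")
  }
  if (postnatal_age_days > 7) {
    list(interval_h = unname(ci[["if_age_gt_7d_h"]]), warnings = character(0))
  } else if (postnatal_age_days < 7) {
    list(interval_h = unname(ci[["if_age_le_7d_h"]]), warnings = character(0))
  } else {
    list(
      interval_h = unname(ci[["if_age_le_7d_h"]]),
      warnings = paste0(
        "postnatal age exactly 7 days is not covered by the interval rule; ",
        "the longer q", ci[["if_age_le_7d_h"]], "h interval was chosen"
      )
    )
  }
}

#' Compute a complete vancomycin regimen
#'
#' Resolves a patient against a nomogram table: the weight band selects the
#' loading dose and the maintenance row, the creatinine-clearance band selects
#' the maintenance cell, the interval rule resolves any age-conditional cell,
#' and the infusion rule converts both doses to infusion durations. The time
#' to first maintenance dose equals the resolved dosing interval. Inputs
#' outside the table's axes raise an out-of-range error; the nomogram is
#' never extrapolated.
#'
#' A creatinine clearance of exactly 0 mL/min (anuria/dialysis) resolves to
#' the lowest renal band, with a warning attached noting that mapping.
#'
#' @param patient A [patient_input()].
#' @param table A `vanc_nomogram`; defaults to the built-in table for the
#'   patient's population. Its population must match the patient's.
#' @param rule An [infusion_rule()]; defaults to the standard tiered rule.
#' @return An object of class `vanc_regimen` with fields `loading_dose_mg`,
#'   `loading_infusion_min`, `maintenance_dose_mg`, `interval_h`,
#'   `maintenance_infusion_min`, `first_maintenance_after_h`, `provenance`
#'   (table name and both band labels) and `warnings`.
#' @export
#' @examples
#' compute_regimen(patient_input("adult", 75, 65))
compute_regimen <- function(patient, table = NULL,
                            rule = default_infusion_rule()) {
  if (!inherits(patient, "vanc_patient")) {
    stop_validation("patient must be built with patient_input()")
  }
  if (is.null(table)) {
    table <- if (patient$population == "adult") {
      builtin_adult_table()
    } else {
      builtin_pediatric_table()
    }
  }
  if (!inherits(table, "vanc_nomogram")) {
    stop_validation("table must be a vanc_nomogram")
  }
  if (table$population != patient$population) {
    stop_validation(sprintf(
      "patient population '%s' does not match table population '%s'",
      patient$population, table$population
    ))
  }
  if (!inherits(rule, "vanc_infusion_rule")) {
    stop_validation("rule must be a vanc_infusion_rule")
  }

  warnings <- character(0)
  wband <- find_band(table$weight_axis, patient$weight)
  cband <- find_band(table$crcl_axis, patient$crcl)
  wi <- attr(wband, "index")
  ci <- attr(cband, "index")
  if (patient$crcl == 0) {
    warnings <- c(warnings, paste0(
      "creatinine clearance 0 mL/min (anuria/dialysis) was mapped to the ",
      "lowest renal band ('", cband$label, "'); the nomogram has no separate ",
      "dialysis logic"
    ))
  }

  entry <- table$maintenance[[wi]][[ci]]
  res <- resolve_interval(entry, patient$postnatal_age_days)
  warnings <- c(warnings, res$warnings)

  loading <- table$loading_mg[wi]
  structure(
    list(
      loading_dose_mg = loading,
      loading_infusion_min = infusion_duration_min(rule, loading),
      maintenance_dose_mg = entry$dose_mg,
      interval_h = res$interval_h,
      maintenance_infusion_min = infusion_duration_min(rule, entry$dose_mg),
      first_maintenance_after_h = res$interval_h,
      provenance = list(table = table$name,
                        weight_band = wband$label,
                        crcl_band = cband$label),
      warnings = warnings
    ),
    class = "vanc_regimen"
  )
}

regimen_labels <- function(lang = c("pt", "en")) {
  lang <- match.arg(lang)
  if (lang == "pt") {
    list(loading = "Dose de ataque", infusion = "Duração da infusão",
         maintenance = "Dose de manutenção",
         after = "Tempo após dose de ataque",
         interval = "Intervalo de dose",
         hours = "horas", minutes = "minutos", warning = "Aviso")
  } else {
    list(loading = "Loading dose", infusion = "Rate of infusion",
         maintenance = "Maintenance dose",
         after = "Time after loading dose",
         interval = "Dosing interval",
         hours = "hours", minutes = "minutes", warning = "Warning")
  }
}

#' Format a regimen as labelled text
#'
#' Renders the five output fields of the dosing screens, in Portuguese (the
#' tool's default language) or English.
#'
#' @param x A `vanc_regimen`.
#' @param lang `"pt"` or `"en"`.
#' @param ... Unused.
#' @return Character vector of lines.
#' @export
format.vanc_regimen <- function(x, lang = c("pt", "en"), ...) {
  L <- regimen_labels(lang)
  c(
    sprintf("%s: %g mg (%s: %g %s)", L$loading, x$loading_dose_mg,
            L$infusion, x$loading_infusion_min, L$minutes),
    sprintf("%s: %g mg", L$maintenance, x$maintenance_dose_mg),
    sprintf("%s: %g %s", L$after, x$first_maintenance_after_h, L$hours),
    sprintf("%s: %g %s", L$interval, x$interval_h, L$hours),
    sprintf("%s: %g %s", L$infusion, x$maintenance_infusion_min, L$minutes)
  )
}

#' @export
print.vanc_regimen <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  cat(sprintf("[%s | %s kg | %s mL/min]\n", x$provenance$table,
              x$provenance$weight_band, x$provenance$crcl_band))
  for (w in x$warnings) cat("Warning:", w, "\n")
  invisible(x)
}

#' Convert a regimen to a plain list
#'
#' Stable field order matching the JSON output of the CLI.
#'
#' @param x A `vanc_regimen`.
#' @param ... Unused.
#' @export
as.list.vanc_regimen <- function(x, ...) {
  list(
    loading_dose_mg = x$loading_dose_mg,
    loading_infusion_min = x$loading_infusion_min,
    maintenance_dose_mg = x$maintenance_dose_mg,
    interval_h = x$interval_h,
    maintenance_infusion_min = x$maintenance_infusion_min,
    first_maintenance_after_h = x$first_maintenance_after_h,
    provenance = x$provenance,
    warnings = x$warnings
  )
}
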