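#' Create a maintenance-dose cell
#'
#' A cell of the maintenance grid: a dose in mg together with either a fixed
#' dosing interval in hours, or — for the neonatal weight band — a pair of
#' intervals conditional on postnatal age (one interval if age > 7 days, the
#' other if age < 7 days). Exactly one of `interval_h` / `conditional_interval`
#' must be given.
#'
#' @param dose_mg Dose in mg; positive multiple of 25.
#' @param interval_h Fixed dosing interval in hours, or `NULL`.
#' @param conditional_interval Numeric pair
#'   `c(if_age_gt_7d_h, if_age_le_7d_h)`, or `NULL`.
#' @return An object of class `vanc_dose_entry`.
#' @export
#' @examples
#' dose_entry(1000, interval_h = 12)
#' dose_entry(25, conditional_interval = c(8, 12))
dose_entry <- function(dose_mg, interval_h = NULL, conditional_interval = NULL) {
  if (!is_scalar_number(dose_mg) || dose_mg <= 0 || dose_mg %% 25 != 0) {
    stop_validation("dose_mg must be a positive multiple of 25 mg")
  }
  has_fixed <- !is.null(interval_h)
  has_cond <- !is.null(conditional_interval)
  if (has_fixed == has_cond) {
    stop_validation("exactly one of interval_h / conditional_interval must be set")
  }
  if (has_fixed) {
    if (!is_scalar_number(interval_h) || interval_h <= 0) {
      stop_validation("interval_h must be a single positive number of hours")
    }
    entry <- list(dose_mg = as.numeric(dose_mg),
                  interval_h = as.numeric(interval_h),
                  conditional_interval = NULL)
  } else {
    ci <- as.numeric(conditional_interval)
    if (length(ci) != 2L || any(!is.finite(ci)) || any(ci <= 0)) {
      stop_validation("conditional_interval must be two positive hour values")
    }
    entry <- list(dose_mg = as.numeric(dose_mg),
                  interval_h = NULL,
                  conditional_interval = c(if_age_gt_7d_h = ci[1L],
                                           if_age_le_7d_h = ci[2L]))
  }
  structure(entry, class = "vanc_dose_entry")
}

is_conditional <- function(entry) !is.null(entry$conditional_interval)

#' Create a complete dosing nomogram table
#'
#' Assembles and validates one population's full dosing table: the weight and
#' creatinine-clearance axes, one loading dose per weight band, and a complete
#' maintenance grid with one [dose_entry()] per (weight band, CrCl band) pair.
#' All structural invariants are checked on construction; an invalid table can
#' never be built.
#'
#' @param name Table name (free text, recorded in regimen provenance).
#' @param population `"adult"` or `"pediatric"`.
#' @param weight_axis,crcl_axis [banded_axis()] objects.
#' @param loading_mg Numeric vector of loading doses, one per weight band.
#' @param maintenance List of rows (one per weight band), each a list of
#'   [dose_entry()] objects (one per CrCl band).
#' @param infusion_rule_id Identifier of the infusion rule the table assumes.
#' @param source Free-text citation for the table's values.
#' @return An object of class `vanc_nomogram`.
#' @export
nomogram_table <- function(name, population = c("adult", "pediatric"),
                           weight_axis, crcl_axis, loading_mg, maintenance,
                           infusion_rule_id = "vancomycin_tiered",
                           source = "") {
  population <- match.arg(population)
  if (!(is.character(name) && length(name) == 1L && nzchar(name))) {
    stop_validation("table name must be a non-empty string")
  }
  if (!inherits(weight_axis, "vanc_axis") || weight_axis$name != "weight_kg") {
    stop_validation("weight_axis must be a vanc_axis named 'weight_kg'")
  }
  if (!inherits(crcl_axis, "vanc_axis") || crcl_axis$name != "crcl_ml_min") {
    stop_validation("crcl_axis must be a vanc_axis named 'crcl_ml_min'")
  }
  nw <- length(weight_axis$bands)
  nc <- length(crcl_axis$bands)
  if (!is.numeric(loading_mg) || length(loading_mg) != nw) {
    stop_validation(sprintf(
      "loading_mg must have one dose per weight band (expected %d, found %d)",
      nw, length(loading_mg)
    ))
  }
  if (any(!is.finite(loading_mg)) || any(loading_mg <= 0) ||
      any(loading_mg %% 25 != 0)) {
    stop_validation("loading doses must be positive multiples of 25 mg")
  }
  if (!is.list(maintenance) || length(maintenance) != nw) {
    stop_validation(sprintf(
      "maintenance grid must have one row per weight band (expected %d, found %d)",
      nw, length(maintenance)
    ))
  }
  for (i in seq_len(nw)) {
    row <- maintenance[[i]]
    if (!is.list(row) || length(row) != nc) {
      stop_validation(sprintf(
        "maintenance row %d ('%s') must have one cell per CrCl band (expected %d, found %d)",
        i, weight_axis$labels[i], nc, length(row)
      ))
    }
    ok <- vapply(row, inherits, logical(1), "vanc_dose_entry")
    if (!all(ok)) {
      stop_validation(sprintf(
        "maintenance row %d ('%s'), cell %d is not a dose entry",
        i, weight_axis$labels[i], which(!ok)[1L]
      ))
    }
  }
  structure(
    list(name = name, population = population,
         weight_axis = weight_axis, crcl_axis = crcl_axis,
         loading_mg = as.numeric(loading_mg), maintenance = maintenance,
         infusion_rule_id = infusion_rule_id, source = source),
    class = "vanc_nomogram"
  )
}

#' @export
print.vanc_nomogram <- function(x, ...) {
  cat(sprintf("<vancomycin nomogram '%s' (%s): %d weight bands x %d CrCl bands>\n",
              x$name, x$population,
              length(x$weight_axis$bands), length(x$crcl_axis$bands)))
  cat(" weight bands:", paste(x$weight_axis$labels, collapse = " | "), "\n")
  cat(" CrCl bands:  ", paste(x$crcl_axis$labels, collapse = " | "), "\n")
  invisible(x)
}

make_axis <- function(lowers, uppers, labels, name) {
  banded_axis(Map(band, lowers, uppers, labels), name = name)
}

# en dash / >= sign in labels, as printed
EN <- "\u2013"
GE <- "\u2265 "

#' Built-in adult vancomycin nomogram
#'
#' The adult dosing table: 5 total-body-weight bands (50–100 kg) by 11
#' estimated-creatinine-clearance bands (<10 to >=120 mL/min), with one
#' loading dose per weight band and 55 maintenance cells. Band bounds follow
#' the contiguous half-open convention `[lower, next_lower)`, so e.g. the
#' "50–60" band covers [50, 61) kg. The published CrCl column header
#' "100–199" sits immediately before a ">= 120" column and is transcribed
#' here as 100–119 (see the package vignette).
#'
#' @return A validated `vanc_nomogram` for adults.
#' @export
#' @examples
#' builtin_adult_table()
builtin_adult_table <- function() {
  weight_axis <- make_axis(
    lowers = c(50, 61, 71, 81, 91),
    uppers = c(61, 71, 81, 91, 101),
    labels = paste0(c(50, 61, 71, 81, 91), EN, c(60, 70, 80, 90, 100)),
    name = "weight_kg"
  )
  crcl_axis <- make_axis(
    lowers = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 100, 120),
    uppers = c(10, 20, 30, 40, 50, 60, 70, 80, 100, 120, Inf),
    labels = c("< 10", paste0(c(10, 20, 30, 40, 50, 60, 70), EN,
                              c(19, 29, 39, 49, 59, 69, 79)),
               paste0(80, EN, 99), paste0(100, EN, 119), paste0(GE, 120)),
    name = "crcl_ml_min"
  )
  loading_mg <- c(1500, 1500, 2000, 2000, 2250)
  # 5 x 11 maintenance grid, row-major by weight band
  doses <- rbind(
    c(1000, 500,  750, 500,  500,  750,  750, 1000, 1250, 1750, 1750),
    c(1250, 500,  750, 500,  750,  750, 1000, 1250, 1000, 1750, 1250),
    c(1250, 500, 1000, 750,  750, 1000, 1000, 1500, 1000, 1250, 1000),
    c(1500, 750, 1250, 750, 1000, 1000, 1250, 1500, 1750, 1000, 1000),
    c(1750, 750, 1250, 750, 1000, 1250, 1500, 1500, 1000, 1000, 1000)
  )
  intervals <- rbind(
    c(96, 24, 24, 12, 12, 12, 12, 12, 12, 12, 12),
    c(96, 24, 24, 12, 12, 12, 12, 12,  8, 12,  8),
    c(96, 24, 24, 12, 12, 12, 12, 12,  8,  8,  6),
    c(96, 24, 24, 12, 12, 12, 12, 12, 12,  6,  6),
    c(96, 24, 24, 12, 12, 12, 12, 12,  6,  6,  6)
  )
  maintenance <- lapply(seq_len(nrow(doses)), function(i) {
    lapply(seq_len(ncol(doses)), function(j) {
      dose_entry(doses[i, j], interval_h = intervals[i, j])
    })
  })
  nomogram_table(
    name = "adult_builtin", population = "adult",
    weight_axis = weight_axis, crcl_axis = crcl_axis,
    loading_mg = loading_mg, maintenance = maintenance,
    source = "Adult vancomycin dosing nomogram (total body weight x renal function)"
  )
}

#' Built-in pediatric vancomycin nomogram
#'
#' The pediatric dosing table: 8 total-body-weight bands (2.5–70 kg) by 5
#' estimated-creatinine-clearance bands (<15 to >=90 mL/min). In the smallest
#' weight band (2.5–4.5 kg, neonates) all maintenance cells except the lowest
#' renal band carry an age-conditional interval: q8h if postnatal age > 7
#' days, q12h if < 7 days. Resolving those cells requires
#' `postnatal_age_days` in the patient input.
#'
#' @return A validated `vanc_nomogram` for pediatric patients.
#' @export
#' @examples
#' builtin_pediatric_table()
builtin_pediatric_table <- function() {
  w_lo <- c(2.5, 4.6, 12.1, 18.1, 30.1, 40.1, 50.1, 60.1)
  w_hi <- c(4.6, 12.1, 18.1, 30.1, 40.1, 50.1, 60.1, 70.1)
  w_lab <- c(paste0("2.5", EN, "4.5"), paste0("4.6", EN, "12.0"),
             paste0("12.1", EN, "18.0"), paste0("18.1", EN, "30.0"),
             paste0("30.1", EN, "40.0"), paste0("40.1", EN, "50.0"),
             paste0("50.1", EN, "60.0"), paste0("60.1", EN, "70.0"))
  weight_axis <- make_axis(w_lo, w_hi, w_lab, "weight_kg")
  crcl_axis <- make_axis(
    lowers = c(0, 15, 30, 60, 90),
    uppers = c(15, 30, 60, 90, Inf),
    labels = c("< 15", paste0(15, EN, 29), paste0(30, EN, 59),
               paste0(60, EN, 89), paste0(GE, 90)),
    name = "crcl_ml_min"
  )
  loading_mg <- c(100, 250, 500, 750, 1000, 1250, 1500, 2000)
  doses <- rbind(
    c(25,   25,   25,  50,  50),
    c(100, 150,  150, 150, 150),
    c(150, 250,  250, 250, 250),
    c(250, 250,  250, 250, 500),
    c(500, 500,  500, 500, 500),
    c(500, 750,  750, 750, 750),
    c(500, 750,  750, 750, 750),
    c(500, 1000, 1000, 750, 750)
  )
  # NA interval marks an age-conditional (q8 or q12) cell
  intervals <- rbind(
    c(168, NA, NA, NA, NA),
    c(168, 24, 12, 8, 6),
    c(168, 24, 12, 8, 6),
    c(168, 24, 12, 8, 6),
    c(168, 24, 12, 8, 6),
    c(168, 24, 12, 8, 6),
    c(168, 24, 12, 8, 6),
    c(168, 24, 12, 8, 6)
  )
  maintenance <- lapply(seq_len(nrow(doses)), function(i) {
    lapply(seq_len(ncol(doses)), function(j) {
      if (is.na(intervals[i, j])) {
        dose_entry(doses[i, j], conditional_interval = c(8, 12))
      } else {
        dose_entry(doses[i, j], interval_h = intervals[i, j])
      }
    })
  })
  nomogram_table(
    name = "pediatric_builtin", population = "pediatric",
    weight_axis = weight_axis, crcl_axis = crcl_axis,
    loading_mg = loading_mg, maintenance = maintenance,
    source = "Pediatric vancomycin dosing nomogram (total body weight x renal function)"
  )
}
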