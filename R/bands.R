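#' Create a nomogram band
#'
#' A band is one half-open numeric interval `[lower, upper)` of a nomogram
#' axis, together with the label printed in the source table (for example
#' `"50-60"` or `">= 90"`). The half-open convention means non-integer values
#' such as 60.5 kg resolve to exactly one band without rounding, even though
#' the printed labels are integer-gapped (`50-60`, `61-70`, ...).
#'
#' @param lower Inclusive lower bound (finite number).
#' @param upper Exclusive upper bound; may be `Inf` for the last band of an
#'   axis.
#' @param label Printed label for the band.
#' @return An object of class `vanc_band`.
#' @export
#' @examples
#' band(50, 61, "50–60")
band <- function(lower, upper, label) {
  if (!is_scalar_number(lower)) {
    stop_validation("band lower bound must be a single finite number")
  }
  if (!(is.numeric(upper) && length(upper) == 1L && !is.na(upper))) {
    stop_validation("band upper bound must be a single number (may be Inf)")
  }
  if (!(is.character(label) && length(label) == 1L && nzchar(label))) {
    stop_validation("band label must be a non-empty string")
  }
  if (lower >= upper) {
    stop_validation(sprintf(
      "band '%s': lower bound (%g) must be strictly below upper bound (%g)",
      label, lower, upper
    ))
  }
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper), label = label),
    class = "vanc_band"
  )
}

#' Create a banded nomogram axis
#'
#' An axis is an ordered list of contiguous, disjoint half-open bands covering
#' `[first$lower, last$upper)`. Contiguity (each band's upper bound equals the
#' next band's lower bound) is enforced so that every in-range value resolves
#' to exactly one band.
#'
#' @param bands List of [band()] objects, sorted by lower bound.
#' @param name Axis name, `"weight_kg"` or `"crcl_ml_min"`.
#' @return An object of class `vanc_axis`.
#' @export
banded_axis <- function(bands, name = c("weight_kg", "crcl_ml_min")) {
  name <- match.arg(name)
  if (!is.list(bands) || length(bands) == 0L ||
      !all(vapply(bands, inherits, logical(1), "vanc_band"))) {
    stop_validation("bands must be a non-empty list of vanc_band objects")
  }
  lowers <- vapply(bands, `[[`, numeric(1), "lower")
  uppers <- vapply(bands, `[[`, numeric(1), "upper")
  labels <- vapply(bands, `[[`, character(1), "label")
  if (is.unsorted(lowers, strictly = TRUE)) {
    stop_validation(sprintf("axis '%s': bands must be sorted by lower bound", name))
  }
  n <- length(bands)
  if (n > 1L) {
    gap <- which(uppers[-n] != lowers[-1L])
    if (length(gap) > 0L) {
      i <- gap[1L]
      stop_validation(sprintf(
        "axis '%s': bands '%s' and '%s' are not contiguous (upper %g != lower %g)",
        name, labels[i], labels[i + 1L], uppers[i], lowers[i + 1L]
      ))
    }
  }
  if (any(!is.finite(uppers[-n]))) {
    stop_validation(sprintf("axis '%s': only the last band may be unbounded", name))
  }
  structure(
    list(bands = bands, name = name,
         lowers = lowers, uppers = uppers, labels = labels),
    class = "vanc_axis"
  )
}

#' Resolve a value to its axis band
#'
#' Returns the unique band with `lower <= value < upper`. Values outside the
#' axis range raise an out-of-range error naming the axis, the value, and the
#' covered range; the nomograms are never extrapolated.
#'
#' @param axis A [banded_axis()].
#' @param value Finite non-negative number.
#' @return The matching `vanc_band`, with attribute `index` giving its
#'   1-based position on the axis.
#' @export
#' @examples
#' ax <- builtin_adult_table()$weight_axis
#' find_band(ax, 60.5)$label
find_band <- function(axis, value) {
  if (!inherits(axis, "vanc_axis")) {
    stop_validation("axis must be a vanc_axis")
  }
  if (!is_scalar_number(value) || value < 0) {
    stop_validation(sprintf(
      "lookup value for axis '%s' must be a single finite non-negative number",
      axis$name
    ))
  }
  n <- length(axis$bands)
  if (value < axis$lowers[1L] || value >= axis$uppers[n]) {
    upper_txt <- if (is.finite(axis$uppers[n])) sprintf("%g", axis$uppers[n]) else "Inf"
    stop_out_of_range(sprintf(
      "value %g is outside axis '%s' (covered range [%g, %s))",
      value, axis$name, axis$lowers[1L], upper_txt
    ), axis = axis$name, value = value)
  }
  idx <- findInterval(value, axis$lowers)
  out <- axis$bands[[idx]]
  attr(out, "index") <- idx
  out
}

#' @export
print.vanc_band <- function(x, ...) {
  upper_txt <- if (is.finite(x$upper)) sprintf("%g", x$upper) else "Inf"
  cat(sprintf("<band '%s' [%g, %s)>\n", x$label, x$lower, upper_txt))
  invisible(x)
}

#' @export
print.vanc_axis <- function(x, ...) {
  cat(sprintf("<axis %s: %d bands: %s>\n", x$name, length(x$bands),
              paste(x$labels, collapse = " | ")))
  invisible(x)
}
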