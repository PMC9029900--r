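#' @importFrom jsonlite toJSON fromJSON
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

SCHEMA_VERSION <- "1"

band_to_doc <- function(b) {
  list(lower = b$lower,
       upper = if (is.finite(b$upper)) b$upper else NULL,
       label = b$label)
}

entry_to_doc <- function(e) {
  if (is_conditional(e)) {
    list(dose_mg = e$dose_mg,
         conditional_interval = list(
           if_age_gt_7d_h = unname(e$conditional_interval[["if_age_gt_7d_h"]]),
           if_age_le_7d_h = unname(e$conditional_interval[["if_age_le_7d_h"]])))
  } else {
    list(dose_mg = e$dose_mg, interval_h = e$interval_h)
  }
}

#' Serialize a nomogram table to JSON
#'
#' Renders a complete, human-auditable JSON document: schema version, both
#' band axes (an unbounded upper edge is an explicit `null`), the loading
#' doses, the maintenance grid in row-major order, and the infusion rule.
#' Key order and number formatting are fixed, so repeated dumps of the same
#' table are byte-identical and documents diff cleanly.
#'
#' @param table A `vanc_nomogram`.
#' @param rule The [infusion_rule()] to embed; defaults to the rule attached
#'   by [load_nomogram()], or the standard tiered rule.
#' @return A single JSON string (class `json`).
#' @export
#' @examples
#' txt <- dump_nomogram(builtin_pediatric_table())
dump_nomogram <- function(table, rule = NULL) {
  if (!inherits(table, "vanc_nomogram")) {
    stop_validation("table must be a vanc_nomogram")
  }
  rule <- rule %||% attr(table, "infusion_rule") %||% default_infusion_rule()
  doc <- list(
    schema_version = SCHEMA_VERSION,
    name = table$name,
    population = table$population,
    source = table$source,
    weight_bands = lapply(table$weight_axis$bands, band_to_doc),
    crcl_bands = lapply(table$crcl_axis$bands, band_to_doc),
    loading_mg = table$loading_mg,
    maintenance = unlist(lapply(table$maintenance, function(row) {
      lapply(row, entry_to_doc)
    }), recursive = FALSE),
    infusion_rule = list(
      tiers = lapply(seq_along(rule$bounds), function(i) {
        list(dose_upper_bound_mg = rule$bounds[i],
             duration_min = rule$durations[i])
      }),
      overflow_rate_mg_per_h = rule$overflow_rate_mg_per_h
    )
  )
  toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA, null = "null")
}

#' Write a nomogram table to a JSON file
#'
#' @param table A `vanc_nomogram`.
#' @param path Output file path.
#' @param rule Infusion rule to embed (see [dump_nomogram()]).
#' @return `path`, invisibly.
#' @export
write_nomogram <- function(table, path, rule = NULL) {
  writeLines(dump_nomogram(table, rule), path, useBytes = TRUE)
  invisible(path)
}

need <- function(x, key, path, type = NULL) {
  if (!(key %in% names(x))) {
    stop_schema(sprintf("missing required field at %s.%s", path, key))
  }
  v <- x[[key]]
  if (!is.null(type)) {
    ok <- switch(type,
      string = is.character(v) && length(v) == 1L,
      number = is.numeric(v) && length(v) == 1L,
      list = is.list(v),
      stop("unknown type spec"))
    if (!ok) {
      stop_schema(sprintf("field %s.%s must be a %s", path, key, type))
    }
  }
  v
}

doc_to_band <- function(b, path) {
  if (!is.list(b)) stop_schema(sprintf("band at %s must be an object", path))
  lower <- need(b, "lower", path, "number")
  label <- need(b, "label", path, "string")
  if (!("upper" %in% names(b))) {
    stop_schema(sprintf("missing required field at %s.upper", path))
  }
  upper <- b[["upper"]]
  if (is.null(upper)) {
    upper <- Inf
  } else if (!(is.numeric(upper) && length(upper) == 1L)) {
    stop_schema(sprintf("field %s.upper must be a number or null", path))
  }
  band(lower, upper, label)
}

doc_to_entry <- function(cell, path) {
  if (!is.list(cell)) stop_schema(sprintf("cell at %s must be an object", path))
  dose <- need(cell, "dose_mg", path, "number")
  has_fixed <- "interval_h" %in% names(cell)
  has_cond <- "conditional_interval" %in% names(cell)
  if (has_fixed == has_cond) {
    stop_schema(sprintf(
      "cell at %s must have exactly one of interval_h / conditional_interval",
      path
    ))
  }
  if (has_fixed) {
    iv <- need(cell, "interval_h", path, "number")
    dose_entry(dose, interval_h = iv)
  } else {
    ci <- need(cell, "conditional_interval", path, "list")
    gt <- need(ci, "if_age_gt_7d_h", paste0(path, ".conditional_interval"),
               "number")
    le <- need(ci, "if_age_le_7d_h", paste0(path, ".conditional_interval"),
               "number")
    dose_entry(dose, conditional_interval = c(gt, le))
  }
}

#' Load a nomogram table from a JSON document
#'
#' Parses and validates a nomogram document (as produced by
#' [dump_nomogram()]), rebuilding a `vanc_nomogram` through the same
#' constructors as the built-in tables, so every structural invariant —
#' contiguous half-open bands, complete maintenance grid, dose granularity —
#' is re-checked after parsing. Schema violations name the JSON path of the
#' offending field; grid-size errors name the expected and found counts;
#' band gaps name the two bands involved. Documents with an unknown
#' `schema_version` are rejected, not coerced.
#'
#' @param path Path to a JSON file, or a literal JSON string.
#' @return A validated `vanc_nomogram`, with the document's infusion rule
#'   attached as attribute `"infusion_rule"`.
#' @export
#' @examples
#' t <- load_nomogram(dump_nomogram(builtin_adult_table()))
load_nomogram <- function(path) {
  if (!(is.character(path) && length(path) == 1L)) {
    stop_validation("path must be a single file path or JSON string")
  }
  txt <- if (grepl("^\\s*\\{", path)) {
    path
  } else {
    if (!file.exists(path)) {
      stop_vanc("vancnomo_io_error", sprintf("cannot read nomogram file '%s'", path))
    }
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  doc <- tryCatch(
    fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop_schema(sprintf("not valid JSON: %s", conditionMessage(e)))
    }
  )
  if (!is.list(doc)) stop_schema("document root must be a JSON object")

  ver <- need(doc, "schema_version", "$", "string")
  if (ver != SCHEMA_VERSION) {
    stop_schema(sprintf(
      "unsupported schema_version '%s' at $.schema_version (supported: '%s')",
      ver, SCHEMA_VERSION
    ))
  }
  name <- need(doc, "name", "$", "string")
  population <- need(doc, "population", "$", "string")
  if (!population %in% c("adult", "pediatric")) {
    stop_schema("field $.population must be 'adult' or 'pediatric'")
  }
  source <- need(doc, "source", "$", "string")

  wb <- need(doc, "weight_bands", "$", "list")
  cb <- need(doc, "crcl_bands", "$", "list")
  if (length(wb) == 0L) stop_schema("field $.weight_bands must be non-empty")
  if (length(cb) == 0L) stop_schema("field $.crcl_bands must be non-empty")
  weight_axis <- banded_axis(
    lapply(seq_along(wb), function(i) {
      doc_to_band(wb[[i]], sprintf("$.weight_bands[%d]", i))
    }), name = "weight_kg")
  crcl_axis <- banded_axis(
    lapply(seq_along(cb), function(i) {
      doc_to_band(cb[[i]], sprintf("$.crcl_bands[%d]", i))
    }), name = "crcl_ml_min")

  loading <- need(doc, "loading_mg", "$")
  loading <- vapply(loading, function(x) {
    if (!(is.numeric(x) && length(x) == 1L)) {
      stop_schema("field $.loading_mg must be a list of numbers")
    }
    as.numeric(x)
  }, numeric(1))

  cells <- need(doc, "maintenance", "$", "list")
  nw <- length(wb)
  nc <- length(cb)
  if (length(cells) != nw * nc) {
    stop_schema(sprintf(
      "maintenance grid at $.maintenance has %d cells but the axes imply %d (%d weight bands x %d CrCl bands)",
      length(cells), nw * nc, nw, nc
    ))
  }
  maintenance <- lapply(seq_len(nw), function(i) {
    lapply(seq_len(nc), function(j) {
      k <- (i - 1L) * nc + j
      doc_to_entry(cells[[k]], sprintf("$.maintenance[%d]", k))
    })
  })

  ir <- need(doc, "infusion_rule", "$", "list")
  tiers <- need(ir, "tiers", "$.infusion_rule", "list")
  tiers <- lapply(seq_along(tiers), function(i) {
    t <- tiers[[i]]
    p <- sprintf("$.infusion_rule.tiers[%d]", i)
    c(need(t, "dose_upper_bound_mg", p, "number"),
      need(t, "duration_min", p, "number"))
  })
  overflow <- need(ir, "overflow_rate_mg_per_h", "$.infusion_rule", "number")
  rule <- infusion_rule(tiers = tiers, overflow_rate_mg_per_h = overflow)

  table <- nomogram_table(
    name = name, population = population,
    weight_axis = weight_axis, crcl_axis = crcl_axis,
    loading_mg = loading, maintenance = maintenance,
    source = source
  )
  attr(table, "infusion_rule") <- rule
  table
}

band_probe <- function(b) {
  if (is.finite(b$upper)) (b$lower + b$upper) / 2 else b$lower + 1
}

#' Generate exhaustive grid fixtures for a nomogram
#'
#' Emits one test fixture per (weight band, CrCl band) cell: a probe patient
#' at the band midpoints (or lower bound + 1 for an unbounded band) together
#' with the expected regimen read directly off the table — loading dose,
#' maintenance dose, and interval. Age-conditional cells emit two fixtures
#' (postnatal age 3 and 10 days), one per branch of the interval rule.
#' Replaying every fixture through [compute_regimen()] exercises the full
#' lookup surface of a table.
#'
#' @param table A `vanc_nomogram`.
#' @return A data frame with one row per fixture: probe inputs (`weight`,
#'   `crcl`, `postnatal_age_days`), band labels, and expected
#'   `loading_dose_mg`, `maintenance_dose_mg`, `interval_h`.
#' @export
#' @examples
#' nrow(generate_grid_fixtures(builtin_adult_table())) # 55
generate_grid_fixtures <- function(table) {
  if (!inherits(table, "vanc_nomogram")) {
    stop_validation("table must be a vanc_nomogram")
  }
  rows <- list()
  for (i in seq_along(table$weight_axis$bands)) {
    wb <- table$weight_axis$bands[[i]]
    for (j in seq_along(table$crcl_axis$bands)) {
      cbd <- table$crcl_axis$bands[[j]]
      entry <- table$maintenance[[i]][[j]]
      base <- list(
        population = table$population,
        weight = band_probe(wb), crcl = band_probe(cbd),
        weight_band = wb$label, crcl_band = cbd$label,
        loading_dose_mg = table$loading_mg[i],
        maintenance_dose_mg = entry$dose_mg
      )
      if (is_conditional(entry)) {
        ci <- entry$conditional_interval
        rows[[length(rows) + 1L]] <- c(base, list(
          postnatal_age_days = 10,
          interval_h = unname(ci[["if_age_gt_7d_h"]])))
        rows[[length(rows) + 1L]] <- c(base, list(
          postnatal_age_days = 3,
          interval_h = unname(ci[["if_age_le_7d_h"]])))
      } else {
        rows[[length(rows) + 1L]] <- c(base, list(
          postnatal_age_days = NA_real_,
          interval_h = entry$interval_h))
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Export a maintenance grid as CSV text
#'
#' Read-only convenience view of a table: a header row of CrCl band labels
#' and one row per weight band, each cell rendered as `"DOSEmg qINTERVALh"`
#' (age-conditional cells as `"DOSEmg q8or12h"`).
#'
#' @param table A `vanc_nomogram`.
#' @param path Optional file path; when given the CSV is written there.
#' @return Character vector of CSV lines, invisibly when `path` is given.
#' @export
nomogram_csv <- function(table, path = NULL) {
  if (!inherits(table, "vanc_nomogram")) {
    stop_validation("table must be a vanc_nomogram")
  }
  fmt_cell <- function(e) {
    if (is_conditional(e)) {
      ci <- e$conditional_interval
      sprintf("%gmg q%gor%gh", e$dose_mg,
              ci[["if_age_gt_7d_h"]], ci[["if_age_le_7d_h"]])
    } else {
      sprintf("%gmg q%gh", e$dose_mg, e$interval_h)
    }
  }
  quote_csv <- function(x) paste0('"', gsub('"', '""', x), '"')
  header <- paste(c(quote_csv("weight_kg"), quote_csv("loading_mg"),
                    quote_csv(table$crcl_axis$labels)), collapse = ",")
  body <- vapply(seq_along(table$weight_axis$bands), function(i) {
    cells <- vapply(table$maintenance[[i]], fmt_cell, character(1))
    paste(c(quote_csv(table$weight_axis$labels[i]),
            sprintf("%g", table$loading_mg[i]), quote_csv(cells)),
          collapse = ",")
  }, character(1))
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
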