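test_that("band lookup follows the half-open [lower, upper) convention", {
  ax <- builtin_adult_table()$weight_axis
  expect_equal(find_band(ax, 55)$label, "50–60")
  expect_equal(find_band(ax, 60.5)$label, "50–60")  # no rounding to 61-70
  expect_equal(find_band(ax, 61)$label, "61–70")    # lower bound inclusive
  expect_equal(find_band(ax, 100.9)$label, "91–100")

  crcl <- builtin_pediatric_table()$crcl_axis
  expect_equal(find_band(crcl, 90)$label, "≥ 90")
  expect_equal(find_band(crcl, 0)$label, "< 15")
})

test_that("out-of-range values raise an error naming axis, value and range", {
  ax <- builtin_adult_table()$weight_axis
  expect_error(find_band(ax, 49.9), class = "vancnomo_out_of_range")
  expect_error(find_band(ax, 101), class = "vancnomo_out_of_range")
  err <- tryCatch(find_band(ax, 40), vancnomo_out_of_range = function(e) e)
  expect_match(conditionMessage(err), "40")
  expect_match(conditionMessage(err), "weight_kg")
  expect_match(conditionMessage(err), "\\[50, 101\\)")
})

test_that("boundary probes resolve coherently on every axis of both tables", {
  eps <- 1e-9
  for (table in both_tables()) {
    for (axis in list(table$weight_axis, table$crcl_axis)) {
      n <- length(axis$bands)
      for (i in seq_len(n)) {
        b <- axis$bands[[i]]
        expect_identical(find_band(axis, b$lower)$label, b$label)
        expect_identical(find_band(axis, b$lower + eps)$label, b$label)
        if (is.finite(b$upper)) {
          expect_identical(find_band(axis, b$upper - eps)$label, b$label)
          if (i < n) {
            expect_identical(find_band(axis, b$upper)$label,
                             axis$bands[[i + 1L]]$label)
          }
        }
      }
    }
  }
})

test_that("axis construction rejects gaps, overlaps and misordered bands", {
  expect_error(band(61, 61, "x"), class = "vancnomo_validation_error")
  expect_error(
    banded_axis(list(band(50, 60, "50-59"), band(62, 70, "62-69")),
                name = "weight_kg"),
    "not contiguous", class = "vancnomo_validation_error")
  expect_error(
    banded_axis(list(band(60, 70, "b"), band(50, 60, "a")),
                name = "weight_kg"),
    "sorted", class = "vancnomo_validation_error")
  expect_error(
    banded_axis(list(band(0, Inf, "all"), band(5, 10, "x")),
                name = "crcl_ml_min"),
    class = "vancnomo_validation_error")
})
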