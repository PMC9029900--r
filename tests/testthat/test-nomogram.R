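test_that("bundled tables have the published dimensions and pass construction", {
  adult <- builtin_adult_table()
  ped <- builtin_pediatric_table()
  expect_length(adult$weight_axis$bands, 5)
  expect_length(adult$crcl_axis$bands, 11)
  expect_length(ped$weight_axis$bands, 8)
  expect_length(ped$crcl_axis$bands, 5)
  expect_length(adult$loading_mg, 5)
  expect_length(ped$loading_mg, 8)
  for (t in list(adult, ped)) {
    for (row in t$maintenance) {
      expect_length(row, length(t$crcl_axis$bands))
    }
  }
})

test_that("published spot cells are reproduced exactly", {
  adult <- builtin_adult_table()
  expect_equal(adult$loading_mg[1], 1500)          # 50-60 kg row
  cell <- adult$maintenance[[4]][[11]]             # 81-90 kg, >=120 mL/min
  expect_equal(cell$dose_mg, 1000)
  expect_equal(cell$interval_h, 6)

  ped <- builtin_pediatric_table()
  expect_equal(ped$loading_mg[1], 100)             # 2.5-4.5 kg row
  low <- ped$maintenance[[1]][[1]]                 # 2.5-4.5 kg, <15 mL/min
  expect_equal(low$dose_mg, 25)
  expect_equal(low$interval_h, 168)
  cond <- ped$maintenance[[1]][[2]]                # 2.5-4.5 kg, 15-29 mL/min
  expect_equal(cond$dose_mg, 25)
  expect_null(cond$interval_h)
  expect_equal(unname(cond$conditional_interval), c(8, 12))
})

test_that("dose granularity holds: adult multiples of 250 mg, pediatric of 25 mg", {
  tabs <- both_tables()
  for (d in reachable_doses(tabs$adult)) expect_equal(d %% 250, 0)
  for (d in reachable_doses(tabs$pediatric)) expect_equal(d %% 25, 0)
})

test_that("loading dose is non-decreasing with weight band", {
  for (t in both_tables()) {
    expect_false(is.unsorted(t$loading_mg))
  }
})

test_that("total daily maintenance dose is monotone along both axes", {
  for (t in both_tables()) {
    dd <- vapply(t$maintenance, function(row) {
      vapply(row, daily_dose, numeric(1))
    }, numeric(length(t$crcl_axis$bands)))
    # dd is [crcl band, weight band]
    for (i in seq_len(ncol(dd))) {
      expect_false(is.unsorted(dd[, i]),
                   label = sprintf("daily dose across CrCl, weight band %d", i))
    }
    for (j in seq_len(nrow(dd))) {
      expect_false(is.unsorted(dd[j, ]),
                   label = sprintf("daily dose across weight, CrCl band %d", j))
    }
  }
})

test_that("table construction rejects inconsistent components", {
  adult <- builtin_adult_table()
  expect_error(
    nomogram_table("bad", "adult", adult$weight_axis, adult$crcl_axis,
                   loading_mg = adult$loading_mg[-1],
                   maintenance = adult$maintenance),
    "expected 5, found 4", class = "vancnomo_validation_error")
  short <- adult$maintenance
  short[[2]] <- short[[2]][-1]
  expect_error(
    nomogram_table("bad", "adult", adult$weight_axis, adult$crcl_axis,
                   loading_mg = adult$loading_mg, maintenance = short),
    "expected 11, found 10", class = "vancnomo_validation_error")
  expect_error(dose_entry(130, interval_h = 12),
               "multiple of 25", class = "vancnomo_validation_error")
  expect_error(dose_entry(250, interval_h = 12, conditional_interval = c(8, 12)),
               class = "vancnomo_validation_error")
  expect_error(dose_entry(250),
               class = "vancnomo_validation_error")
})
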