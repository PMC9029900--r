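test_that("interval resolution applies the postnatal-age rule", {
  fixed <- dose_entry(250, interval_h = 12)
  cond <- dose_entry(25, conditional_interval = c(8, 12))

  expect_equal(resolve_interval(fixed)$interval_h, 12)
  expect_equal(resolve_interval(fixed, 3)$interval_h, 12)  # age ignored

  expect_equal(resolve_interval(cond, 10)$interval_h, 8)
  expect_equal(resolve_interval(cond, 8)$interval_h, 8)
  expect_equal(resolve_interval(cond, 3)$interval_h, 12)
  expect_equal(resolve_interval(cond, 0)$interval_h, 12)

  # age exactly 7 days: conservative longer interval, flagged
  at7 <- resolve_interval(cond, 7)
  expect_equal(at7$interval_h, 12)
  expect_length(at7$warnings, 1)
  expect_match(at7$warnings, "7 days")

  expect_error(resolve_interval(cond), class = "vancnomo_missing_age")
})

test_that("worked regimens match the published tables", {
  adult <- compute_regimen(patient_input("adult", 75, 65))
  expect_equal(adult$loading_dose_mg, 2000)
  expect_equal(adult$loading_infusion_min, 120)
  expect_equal(adult$maintenance_dose_mg, 1000)
  expect_equal(adult$interval_h, 12)
  expect_equal(adult$maintenance_infusion_min, 60)
  expect_equal(adult$first_maintenance_after_h, 12)
  expect_equal(adult$provenance$weight_band, "71–80")
  expect_equal(adult$provenance$crcl_band, "60–69")

  anuric <- compute_regimen(patient_input("adult", 55, 5))
  expect_equal(anuric$maintenance_dose_mg, 1000)
  expect_equal(anuric$interval_h, 96)

  ped <- compute_regimen(patient_input("pediatric", 15, 45))
  expect_equal(ped$loading_dose_mg, 500)
  expect_equal(ped$loading_infusion_min, 60)
  expect_equal(ped$maintenance_dose_mg, 250)
  expect_equal(ped$interval_h, 12)

  neonate <- compute_regimen(patient_input("pediatric", 3, 40,
                                           postnatal_age_days = 5))
  expect_equal(neonate$maintenance_dose_mg, 25)
  expect_equal(neonate$interval_h, 12)
  older <- compute_regimen(patient_input("pediatric", 3, 40,
                                         postnatal_age_days = 10))
  expect_equal(older$interval_h, 8)
})

test_that("every grid fixture replays through compute_regimen exactly", {
  for (t in both_tables()) {
    fx <- generate_grid_fixtures(t)
    for (k in seq_len(nrow(fx))) {
      age <- if (is.na(fx$postnatal_age_days[k])) NULL else fx$postnatal_age_days[k]
      r <- compute_regimen(
        patient_input(fx$population[k], fx$weight[k], fx$crcl[k],
                      postnatal_age_days = age), t)
      expect_equal(r$loading_dose_mg, fx$loading_dose_mg[k])
      expect_equal(r$maintenance_dose_mg, fx$maintenance_dose_mg[k])
      expect_equal(r$interval_h, fx$interval_h[k])
      expect_equal(r$provenance$weight_band, fx$weight_band[k])
      expect_equal(r$provenance$crcl_band, fx$crcl_band[k])
    }
  }
})

test_that("identical inputs always produce identical regimens", {
  p <- patient_input("pediatric", 3.2, 25, postnatal_age_days = 10)
  expect_identical(compute_regimen(p), compute_regimen(p))
})

test_that("engine errors are specific and never extrapolate the tables", {
  expect_error(compute_regimen(patient_input("adult", 40, 65)),
               class = "vancnomo_out_of_range")
  expect_error(compute_regimen(patient_input("pediatric", 80, 65)),
               class = "vancnomo_out_of_range")
  # conditional cell hit without an age: error, never a guess
  expect_error(compute_regimen(patient_input("pediatric", 3, 40)),
               class = "vancnomo_missing_age")
  # population routing is explicit: a 55 kg patient fits both tables
  expect_error(
    compute_regimen(patient_input("adult", 55, 50), builtin_pediatric_table()),
    "population", class = "vancnomo_validation_error")
  expect_error(patient_input("adult", -3, 50),
               class = "vancnomo_validation_error")
  expect_error(patient_input("adult", 75, -1),
               class = "vancnomo_validation_error")
})

test_that("anuric patients map to the lowest renal band with a warning", {
  r <- compute_regimen(patient_input("adult", 75, 0))
  expect_equal(r$provenance$crcl_band, "< 10")
  expect_equal(r$maintenance_dose_mg, 1250)
  expect_equal(r$interval_h, 96)
  expect_length(r$warnings, 1)
  expect_match(r$warnings, "dialysis")
})
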