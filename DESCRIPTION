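Package: vancnomo
Title: Vancomycin Dosing Nomogram Calculator for Adult and Pediatric Patients
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline calculator for empiric intravenous vancomycin dosage
    regimens in severe MRSA infection, driven by banded dosing nomograms
    indexed by actual body weight and estimated creatinine clearance.
    Bundles validated adult and pediatric nomogram tables, resolves a
    complete regimen (loading dose, maintenance dose, dosing interval,
    infusion durations, time to first maintenance dose), applies the
    dose-tiered infusion-duration rule and the neonatal postnatal-age
    interval rule, and supports loading custom nomograms from an audited
    JSON format. Includes a command-line interface with Portuguese and
    English output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
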