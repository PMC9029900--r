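# vancnomo

Offline vancomycin dosing calculator for adult and pediatric inpatients
with severe MRSA infection, for pharmacists and physicians doing empiric
dosing before (or in the absence of) therapeutic drug monitoring.

Vancomycin dosing is individualized on two covariates: actual body weight
and estimated creatinine clearance (CrCl, mL/min). `vancnomo` implements
nomogram dosing — a banded lookup in which the weight band selects the
loading dose and the CrCl band selects the maintenance dose and interval
(q6h–q168h) — plus the dose-tiered infusion rule (60 min ≤ 1.0 g, 90 min
for 1.1–1.5 g, 120 min for 1.6–2.0 g, ~1 g/h above 2.0 g, capping the
rate at 1000/60 mg/min) and the neonatal postnatal-age interval rule
(q8h if > 7 days, q12h if < 7 days) for the 2.5–4.5 kg band. Two validated
tables are bundled (adult: 5 weight × 11 CrCl bands; pediatric: 8 × 5);
custom tables load from an audited JSON format. Band bounds are contiguous
half-open intervals `[lower, next_lower)`, out-of-range inputs are hard
errors, and the engine is fully deterministic.

## Worked example

```r
library(vancnomo)
compute_regimen(patient_input("adult", weight = 75, crcl = 65))
```

```
Dose de ataque: 2000 mg (Duração da infusão: 120 minutos)
Dose de manutenção: 1000 mg
Tempo após dose de ataque: 12 horas
Intervalo de dose: 12 horas
Duração da infusão: 60 minutos
[adult_builtin | 71–80 kg | 60–69 mL/min]
```

A 75 kg adult falls in the 71–80 kg band (loading dose 2000 mg, infused
over 120 min because it sits in the 1.6–2.0 g tier); CrCl 65 mL/min falls
in the 60–69 band, giving 1000 mg every 12 h, each dose infused over
60 min, with the first maintenance dose 12 h after the load.

The same computation from a shell, as JSON (labels default to Portuguese,
`--lang en` for English; `--format json` for machines; exit codes: 0
success, 2 validation/out-of-range/missing-age, 1 unreadable nomogram
file):

```sh
Rscript exec/vancnomo --population adult --weight 75 --crcl 65 --format json
Rscript exec/vancnomo --population pediatric --weight 3 --crcl 40 --postnatal-days 5
```

Other entry points: `builtin_adult_table()` / `builtin_pediatric_table()`
(the validated tables), `infusion_duration_min()`, `resolve_interval()`,
`dump_nomogram()` / `load_nomogram()` / `nomogram_csv()` (byte-stable JSON
round trip, CSV view), and `generate_grid_fixtures()` (one probe patient
per table cell with the expected regimen read directly off the table).

See `vignettes/vancomycin-dosing.Rmd` for the band conventions (including
the 100–119 CrCl transcription), edge-case decisions (postnatal age
exactly 7 days, CrCl 0, loading-dose infusion), and limitations.

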