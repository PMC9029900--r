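---
title: "Nomogram-based vancomycin dosing: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nomogram-based vancomycin dosing: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancnomo)
```

## The dosing model

Vancomycin has a narrow therapeutic index, and empiric dosing for severe
MRSA infection is commonly individualized on two covariates: actual body
weight and estimated creatinine clearance (CrCl), a surrogate for
glomerular filtration. Rather than fitting a pharmacokinetic model per
patient, nomogram dosing precomputes a regimen for every combination of a
weight band and a renal-function band. `vancnomo` implements that lookup
exactly:

* the **weight band** selects the loading dose ("dose de ataque") and the
  row of the maintenance grid;
* the **CrCl band** selects the maintenance cell — a dose in mg and a
  dosing interval in hours (q6h … q168h; q168 is once weekly, used at the
  lowest renal function);
* a **dose-tiered infusion rule** converts each dose to an infusion
  duration: 60 min for doses up to 1.0 g, 90 min for 1.1–1.5 g, 120 min
  for 1.6–2.0 g, and a constant rate of about 1 g/h above 2.0 g. The cap
  of 1000/60 mg/min limits infusion reactions ("red man" syndrome);
* the **time to first maintenance dose** is reported equal to the resolved
  dosing interval.

Two tables are bundled: an adult table (5 weight bands from 50 to 100 kg ×
11 CrCl bands from < 10 to ≥ 120 mL/min, 55 maintenance cells) and a
pediatric table (8 weight bands from 2.5 to 70 kg × 5 CrCl bands from
< 15 to ≥ 90 mL/min, 40 cells). In the smallest pediatric band
(2.5–4.5 kg, neonates) every cell except the lowest renal band carries an
age-conditional interval: q8h if postnatal age is over 7 days, q12h if
under 7 days.

```{r}
builtin_adult_table()
compute_regimen(patient_input("adult", weight = 75, crcl = 65))
```

## Band conventions

The published band labels are integer-gapped ("50–60", "61–70", …), which
leaves values such as 60.5 kg formally unassigned. We interpret every axis
as **contiguous half-open intervals** `[lower, next_lower)`: the adult
weight bands are `[50, 61)`, `[61, 71)`, `[71, 81)`, `[81, 91)`,
`[91, 101)`, so any in-range measurement resolves to exactly one band
without rounding. The constructors enforce contiguity, disjointness and
ordering, so a table with a gap or overlap cannot be built or loaded.

Two transcription decisions deserve prominence:

* The adult CrCl column printed as **"100–199"** is immediately followed
  by a "≥ 120" column. We treat the printed 199 as a typographical
  artifact and transcribe the band as **100–119** (`[100, 120)`); the
  alternative reading would make the axis overlap. The bundled label says
  "100–119" for honesty about what the engine does.
* The adult "80–99" column is the interval `[80, 100)` under the same
  convention.

**Out-of-range inputs are hard errors.** The tables give no guidance below
50 kg (adult), below 2.5 kg or above 70 kg (pediatric), so the engine
refuses to extrapolate rather than silently clamping. Population routing
is likewise explicit — weights of 50–70 kg exist in both tables, so the
caller must select the table, mirroring the two separate calculator
screens of the original tool.

## Edge-case decisions

These were genuinely open points; the choices and their rationale:

* **Postnatal age exactly 7 days.** The neonatal rule covers "> 7 days"
  and "< 7 days" only. We resolve age = 7 to the *longer* (q12h) interval
  — the conservative choice for an immature kidney — and attach a warning
  so the user sees the gap was bridged by convention, not by the source
  table.
* **Conditional cell without an age.** If a neonatal age-conditional cell
  is hit and `postnatal_age_days` was not supplied, the engine raises a
  `vancnomo_missing_age` error. Guessing either branch would silently
  halve or extend the daily dose.
* **CrCl = 0 (anuria/dialysis).** Zero clearance falls inside the lowest
  renal band under the half-open convention, and that is where it
  resolves, with a warning attached: the nomogram has no separate dialysis
  logic, and the mapping should be visible to the clinician.
* **Loading-dose infusion duration.** No separate loading rule is stated;
  the same dose-tiered rule is applied to the loading dose, which is
  consistent with the worked adult example (a 2000 mg loading dose infused
  over 2 h).
* **Overflow durations** (doses above 2.0 g) are reported in whole
  minutes, rounding half-up, because "about 1 g/h" is approximate and
  minutes are the display unit; e.g. 2250 mg → 135 min.
* **Time after the loading dose.** The output field exists in the original
  tool but no rule is printed for it; we set it equal to the resolved
  maintenance interval. This is an assumption of this package, not a fact
  of the source tables.
* **Pediatric CrCl units.** The pediatric table header says mL/min only;
  the engine documents and uses mL/min, without assuming normalization to
  1.73 m² body surface area.

## The JSON nomogram format

Custom tables load from a JSON document (`load_nomogram()`) and the
bundled tables can be audited bit-exactly (`dump_nomogram()`,
`nomogram_csv()`). Design points: key order and number formatting are
fixed so repeated dumps are byte-identical and diff cleanly; an unbounded
upper band edge is an explicit `null`, never a sentinel number;
`schema_version` is `"1"` and unknown versions are rejected, not coerced;
en-dash band labels are preserved verbatim in UTF-8. Every document is
rebuilt through the same validating constructors as the built-in tables,
so all structural invariants are re-checked after parsing, and error
messages name the JSON path of the offending field.

## What the tests cover — and what they cannot show

The test surface is exhaustive for a finite lookup: every one of the
55 + 40 grid cells is probed at its band midpoint (plus both postnatal-age
branches for conditional cells, and lower + 1 for unbounded bands), every
band boundary is probed on both sides at machine-epsilon offsets, the
infusion-rate cap is checked over every reachable dose, and dump/load
round trips are compared byte for byte. Grid fixtures are generated
programmatically by `generate_grid_fixtures()`, whose expected values come
from a direct cell read, independent of the engine's lookup path. Daily
maintenance dose (dose × 24 / interval, conditional cells resolved at
q8h) was verified non-decreasing across CrCl bands within every weight
band and across weight bands within every CrCl band, for both tables; no
exception had to be documented.

None of this is a clinical claim. Passing tests show the engine reproduces
the published tables exactly and applies their footnote rules
deterministically; they say nothing about attainment of target trough
concentrations (15–20 mg/L) or AUC~24h~/MIC ≥ 400 in real patients, which
the underlying tables were designed around but which this package does not
model.

## Known limitations

* CrCl is an input, never estimated: no Cockcroft–Gault, no Schwartz. The
  quality of the regimen is bounded by the quality of that estimate.
* No therapeutic drug monitoring, Bayesian individualization, AUC/MIC
  computation, dose capping, or redosing after measured troughs.
* No adjusted-body-weight logic for obesity; the tables are indexed on
  actual weight and stop at 100 kg (adult) / 70 kg (pediatric).
* Intended for severe MRSA infection dosing only; not for *C. difficile*
  (oral route), skin/soft-tissue infection, or surgical prophylaxis.
* A decision-support aid, not a prescriber: outputs should be reviewed by
  a clinician, and warnings (age = 7 days, CrCl = 0) exist precisely to
  surface the engine's conventions at the bedside.
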