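# spiroqc

Automatic quality assessment of forced-spirometry maneuvers from curve
morphology.

Forced spirometry measures expired volume and flow during a maximal
exhalation; its indices (FVC, FEV1, PEF) are diagnostic only when the
maneuver itself was technically adequate. Outside specialist labs nobody is
watching the curve, so quality control has to be automatic. `spiroqc`
grades each maneuver **0** (reject — bad morphology), **1** (acceptable) or
**2** (needs expert review) by evaluating a battery of shape criteria on
the volume–time, flow–time and flow–volume representations of the
recording, alongside the four traditional ATS/ERS acceptability rules.

## Method at a glance

For a maneuver with flow $F(t)$ and cumulative volume $V(t)$:

* **Indices.** The time origin $T_0$ is the back-extrapolation point: the
  tangent to $V(t)$ at its steepest slope, extended to $V = 0$. From it:
  $\mathrm{FVC} = \max V$, $\mathrm{FEV1} = V(T_0+1) - V(T_0)$,
  $\mathrm{BEV} = V(T_0)$, $\mathrm{PEF} = \max F$ (and its time
  $\mathrm{PEFT}$), $\mathrm{EOTV}$ = volume range over the final second,
  $\mathrm{FET100}$ = time from $T_0$ to reaching FVC, and $T_{ex}$ = time
  until the per-second volume gain drops below 25 mL.
* **Zones.** The curve is segmented into the ascent to the peak (Z1), the
  peak band above 80 % of PEF (Z2), the descent (Z3), the final second
  (Z4) and the whole curve (Z5).
* **Criteria.** Per zone, 23 shape criteria (C1–C12b) measure derivative
  regularity, peak timing and shape (flat, bimodal, slow), descent-slope
  statistics in the FV plane, the printed back-extrapolation and plateau
  rules (BEV ≤ max(0.15 L, 5 % FVC); EOTV < 0.025 L; FET ≥ 6 s), a family
  of end-of-test refinements, end-of-test oscillation, and single-peak
  checks. Session repeatability requires three acceptable maneuvers, two
  agreeing in FVC and FEV1 within 0.15 L.
* **Grading.** A configurable policy routes criterion failures to
  rejection (grade 0) or expert review (grade 2); a clean battery is
  grade 1. Predictions are scored against expert labels by sensitivity
  (expert-0 curves predicted 0) and specificity (expert-1 predicted 1),
  with grade-2 predictions counted separately.

A synthetic-maneuver generator with nine injectable, severity-scaled
defects (delayed start, cough, bimodal/flat/slow peak, early termination,
end oscillation, irregular ascent/descent) makes the whole battery
testable without patient data. See the methods vignette
(`vignettes/spiroqc-methods.Rmd`) for the models, thresholds and design
rationale.

## Worked example

```r
library(spiroqc)

m <- generate_clean(fvc = 4, pef = 8, rise_time = 0.1, duration = 10, seed = 7)
report <- assess_maneuver(m)
report
#> <quality_report> grade: 1  (config 0e2a74d8)
#>   FVC 4.00 L  FEV1 3.29 L  PEF 8.01 L/s  FET100 9.96 s
#>   failed criteria: none

bad <- inject_defect(m, "delayed_start", severity = 1)
assess_maneuver(bad)
#> <quality_report> grade: 0  (config 0e2a74d8)
#>   FVC 4.50 L  FEV1 3.32 L  PEF 8.01 L/s  FET100 10.03 s
#>   failed criteria: C2b C8

compute_indices(bad)$BEV
#> [1] 0.4991
```

The clean maneuver passes the full battery (grade 1). Prepending a slow
0.5-L leak before the blast shifts the back-extrapolated origin late and
inflates the back-extrapolated volume to 0.50 L, beyond both the 0.15-L
and the 5 %-of-FVC allowance, so C8 fails and the maneuver is rejected
(grade 0). `report_table(report)` tabulates every criterion with its
metric values; `write_report(report, format = "json")` serializes the
report.

A command-line wrapper is installed at `inst/cli/spiroqc` with
`assess`, `batch`, `simulate` and `evaluate` subcommands, e.g.
`spiroqc assess --in curve.tsv` or `spiroqc --print-default-config`.

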