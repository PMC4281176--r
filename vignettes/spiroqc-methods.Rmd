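---
title: "Automatic quality grading of forced spirometry: models and methods"
author: "spiroqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic quality grading of forced spirometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiroqc)
```

## The problem

Forced spirometry asks a subject to inhale fully and then exhale as hard and
as long as possible. The clinically used indices — forced vital capacity
(FVC, in litres), the volume expired in the first second (FEV1), peak
expiratory flow (PEF) — are only meaningful when the maneuver itself was
technically adequate: an explosive start, a single sharp peak, a smooth
descent, a full exhalation ending in a volume plateau. In specialist labs a
trained technician judges this by eye. When testing moves into primary care,
that judgment has to be automated.

`spiroqc` grades a recorded maneuver into three classes from its curve
morphology alone:

* **grade 0** — reject: the shape is decisively bad;
* **grade 1** — acceptable morphology;
* **grade 2** — borderline findings that deserve an expert's look.

The decision is built from a battery of per-zone shape criteria evaluated on
the volume–time (VT), flow–time (FT) and flow–volume (FV) representations of
the same recording, combined with the four classical ATS/ERS acceptability
rules (back-extrapolated volume, end-of-test plateau, expiratory time,
session repeatability).

## Indices and conventions

All timed indices use the standard back-extrapolation origin
$T_0$: the tangent to the VT curve at its steepest point, extended down to
zero volume; its axis crossing is the effective start of the blast. The
slope estimate uses the flow signal (which *is* $dV/dt$) after a 50-ms
local-quadratic (Savitzky–Golay) smooth; ties in the maximum are broken to
the earliest sample, and all sub-sample evaluation is by linear
interpolation.

* $\mathrm{FVC} = \max_t V(t)$ (earliest attainment).
* $\mathrm{BEV} = V(T_0)$, the back-extrapolated volume; a hesitant start
  expires volume before the blast and inflates it.
* $\mathrm{FEV1} = V(T_0 + 1\,\mathrm{s}) - V(T_0)$, reported `NA` with a
  reason code when the record ends within a second of $T_0$.
* $\mathrm{PEF} = \max_t F(t)$ on the raw samples (so it bounds every
  sampled flow); $\mathrm{PEFT}$ is its time relative to $T_0$.
* $\mathrm{EOTV}$ = max minus min volume over the final 1.0 s of the
  record; a true plateau makes it small.
* $T_{ex}$ = time from $T_0$ until the volume accumulated over the trailing
  1-s window first drops below the 25-mL plateau allowance (or the end of
  the record). The trailing-anchored sliding window is a deliberate choice;
  the window length and threshold are configurable.
* $\mathrm{FET100}$ = time from $T_0$ to the first sample at which the VT
  curve reaches FVC. The end of exhalation is the last recorded sample; no
  automatic tail trimming is done.

Input curves may carry flow, volume, or both; the missing series is
completed by cumulative trapezoidal integration or central finite
differences. Non-uniform sampling is resampled to 100 Hz by linear
interpolation on ingest — ample for the 1-s and 25-mL scales the criteria
work at, while keeping derivative estimates cheap and stable.

## The five zones

The FV curve is split into five analysis zones on a common sample-index
base: Z1, the ascent from expiration onset (first flow above 2% of PEF) to
the PEF sample; Z2, the peak region where flow stays above 80% of PEF; Z3,
the descent from the right edge of Z2; Z4, the final second of the record;
and Z5, the whole curve. The 80% band and the 2% onset fraction are package
defaults, not published constants, and both are configurable. Zones may
overlap; together Z1–Z4 cover everything from onset to the end.

## The criterion battery

Each criterion compares one or two named metrics against thresholds from a
flat configuration (`default_config()`, round-trippable through
`read_config()`/`write_config()`). Outcomes are `pass`, `fail` or
`not_applicable` (a zone too short to analyse never causes rejection, but
is reported). Comparison conventions follow the printed rules: "less than"
is strict, "reaches" is inclusive — in particular an expiratory time of
exactly 6 s passes.

**Z1 (ascent).** C1 counts sign changes of the second derivative of flow
with respect to volume on a uniform volume grid (normalized by PEF and the
Z1 span), above a relative amplitude floor. C2a gates on the standard
deviation of the high-frequency flow residual — raw flow minus a 70-ms
local-quadratic smooth — over Z1, normalized by PEF; the samples within
half a smoothing window of the PEF corner are excluded because the slope
kink leaks into the residual there. C2b caps the maximum normalized
curvature excursion. The exact published forms of these ascent-regularity
metrics are proprietary, so the statistics here are this package's own
surrogates; the first-derivative coefficient of variation is reported
alongside C2a but is not gated on, because on an 8–15-sample rise its value
is dominated by discretization of the cosine-like ramp (measured range on
clean curves: 0.44–0.74).

**Z2 (peak).** C3/C4 bound PEFT above and below (defaults 0.20 s and
0.02 s; clean synthetic rises peak at 0.05–0.10 s after $T_0$, while a
stretched "slow peak" lands beyond 0.2 s). C5a/C5b measure the time spent
at or above 90% of PEF (contiguous band through the peak, and total)
against a 0.3-s cap. C5c finds local maxima of the smoothed flow with
topographic prominence of at least 10% of PEF and fails when two or more
lie within the hull of the 80%-of-PEF band; prominence is computed on the
whole curve because a genuine second mode's descent continues below the
band, and the *hull* is used because a bimodal peak breaks the band's
contiguity by construction. C6 interprets the "peak too low" check as the
ratio PEF/FVC falling below 1.0 s$^{-1}$ — a size-independent reading of a
slow, blunted peak; this interpretation is flagged here because the
original wording is ambiguous between flow and volume at the peak.

**Z3 (descent).** All four criteria work on the FV-plane slope
$dF/dV = (dF/dt)/F$, evaluated only where flow exceeds 10% of PEF (the
ratio is numerically unstable near zero flow). A smooth one-compartment
descent has nearly constant $dF/dV = -1/\tau$, so C7a caps its maximum
magnitude (12 (L/s)/L), C7b its variance (30), C7c the variance inside any
sliding 0.5-L volume window (40), and C7d a chord-deviation-weighted count
of slope sign changes (score above 1.0 fails): flips of $dF/dV$ count only
insofar as the curve also departs from the straight FV chord across Z3.

**Z4 (start and end of test).** C8 is the printed back-extrapolation rule:
fail iff $\mathrm{BEV} > \max(0.15\,\mathrm{L},\ 0.05\,\mathrm{FVC})$. The
parenthetical form of this rule in the literature reads as an "or" between
the two allowances; following the ATS convention it is implemented as
acceptable when BEV is within *either* allowance. C9 is the plateau rule:
fail iff $\mathrm{EOTV} \ge 0.025$ L over the final second. The C10 family
refines the end-of-test decision as a parameterized threshold curve, since
the five published variants are named but their constants are not public:
C10a fails when the plateau test fails *and* $T_{ex} < 6$ s; C10b applies
the plateau threshold to a shorter 0.5-s window when $T_{ex} \ge 6$ s;
C10c applies a relaxed 0.04-L threshold; C10d and C10e compare EOTV
against $thr(T_{ex}) = 0.025\,(1 + 0.5\max(0, 6 - T_{ex}))$ L, linear in
the $T_{ex}$ deficit. C11 detects end-of-test oscillation: sign changes of
the smoothed FT derivative in Z4 whose flow swing between successive
extrema reaches 0.06 L/s, four or more failing.

**Z5 (whole curve).** C12a fails when the smoothed flow has two or more
maxima with prominence of at least 10% of PEF anywhere — the cough
signature. C12b applies the same test restricted to secondary peaks whose
expired volume lies within 0.5 L of the FEV1 point.

**Traditional session rules.** FET fails when FET100 is under 6 s (adult
rule, inclusive boundary). REP passes when at least three maneuvers in a
session are individually acceptable and some pair agrees in both FVC and
FEV1 to strictly within 0.15 L.

### Threshold provenance

The printed ATS/ERS constants (0.15 L / 5% FVC, 0.025 L / 1 s, 6 s,
0.15 L repeatability) are taken as-is. Every other threshold is a
**calibration artifact of this package**: it was placed by sweeping the
synthetic generator's study conditions (below) and choosing a value with
clean-curve false-positive rates near zero and decisive separation from
high-severity defects, then frozen. They are defaults to be tuned against
real device data, not published values.

## Grading policy

A failed *rejecting* criterion forces grade 0; otherwise a failed *warning*
criterion yields grade 2; otherwise grade 1. The default rejecting set is
`{C2a, C3, C5a, C5c, C7b, C8, C10a, C11, C12a, FET}` — exactly the
criteria that are each the designated detector of one decisively bad
defect pattern (hesitant start, late peak, flat peak, bimodal peak,
irregular ascent/descent, end oscillation, cough, short exhalation, failed
end-of-test). C10a rather than C9 carries the end-of-test rejection
because C10a only fails when the plateau test fails *with* a short
$T_{ex}$ — a missing plateau after a long exhalation is a warning, not a
rejection. The remaining morphology criteria warn. Routing every
designated detector to rejection is what lets a high-severity defect be
rejected automatically instead of piling into grade 2; with rejection
limited to the traditional criteria alone, five of the nine defect
patterns could at best reach grade 2, defeating the point of automatic
classification. The policy is fully configurable in the same flat file as
the thresholds, and every report records the configuration fingerprint
that produced it.

## The synthetic generator

No patient recordings ship with the package; the entire battery is
validated on synthetic maneuvers with known ground truth.

**Clean model.** Flow rises as a quarter sine to PEF over the rise time,
then decays as a two-compartment exponential: a fast compartment whose
decay constant is solved (bisection on the discretely integrated volume,
1e-4 L tolerance) so total expired volume equals the requested FVC at the
requested duration, plus a small slow compartment (decay constant a third
of the exhalation) sized to leave about 8 mL/s of flow at the last sample.
The slow tail matters: a single exponential sized for a 10-s record
empties in about 3 s, after which the volume plateau is exactly flat and
both FVC attainment and the expiratory time become artifacts of sensor
noise. Real complete exhalations keep a slow measurable dribble to the
end; with the two-compartment tail, volume rises monotonically to the last
sample while the final-second volume stays near 10 mL, well inside the
25-mL plateau allowance. White flow noise (default sd 0.02 L/s, a typical
pneumotach resolution scale) is added last and volume is re-integrated.

**Study conditions.** Labeled datasets draw FVC uniformly on 2–6 L, rise
time on 0.08–0.15 s, duration on 8–11 s, and PEF near twice FVC (jittered
±20%, clamped to 4–12 L/s). The coupling reflects the strong physiological
association between vital capacity and attainable peak flow; uncoupled
corners (PEF 12 L/s with FVC 2 L) produce curves no healthy subject
generates and whose back-extrapolated volume violates the 0.15-L allowance
even when executed perfectly. Clean curves carry expert label 1; defect
curves (severity drawn uniformly on 0.8–1) carry label 0. Everything is
reproducible from one master seed, with per-curve seeds recorded in the
manifest.

**Defects.** Nine labeled transforms scale with a severity in [0, 1]
(severity 0 is the identity); magnitudes are anchored to the printed
thresholds so severity 1 violates the designated criterion decisively
while severity 0.2 stays within bounds: a delayed start prepends a 1-s
leak expiring up to 0.5 L; a cough multiplies flow by a narrow Gaussian
notch placed by flow level (default at 50% of PEF — a time-based placement
would land on the empty tail of fast exhalations); a bimodal peak is a
dip-and-recovery pair placed at the 90% and 75% PEF crossings so the
second mode stays inside the peak band at any decay rate; a flat peak
clips and holds the peak level forward over a widening plateau; a slow
peak stretches the rise up to five-fold; early termination truncates the
record at up to 60% of its duration; end oscillation adds a 4-Hz sinusoid
of up to 0.1 L/s over the final second; irregular ascent/descent add
band-limited noise of sd up to 5% of PEF, 15–30 Hz on the ascent and
8–12 Hz on the descent, with the realized in-window standard deviation
normalized exactly. The ascent band is higher-frequency than the descent
band deliberately: the ascent window is 0.08–0.15 s long, and a ripple
slower than ~15 Hz fits under a smooth monotone rise for less than one
cycle — it is then mathematically indistinguishable from a clean curve,
and no regularity statistic could (or should) flag it.

**What the generator does not emulate.** Real device artifacts (baseline
drift, BTPS correction, zero-flow offset), pediatric maneuvers, submaximal
but smooth efforts, inter-subject shape diversity beyond the
sine-rise/exponential-decay family, and inter-expert label variability.
Passing the synthetic battery therefore demonstrates that the metrics
measure what they claim and that the decision logic is wired correctly
under controlled conditions — not that the default thresholds transfer
unchanged to any particular spirometer or population.

## Numerical choices

Savitzky–Golay smoothing is quadratic with an odd window of at least 3
samples; a zero window is the identity and constants and ramps pass
through unchanged. Derivatives are central differences with one-sided
endpoints. FV-plane work interpolates flow onto a strictly increasing
volume subsequence (sensor noise can make sampled volume locally
non-monotone near zero flow). Peak prominence uses the standard
topographic definition with ties to the earliest sample. Degenerate
inputs — all-zero flow, records shorter than the end-of-test window, a Z1
or Z3 with fewer than 5 usable samples — raise typed errors or yield
`not_applicable` outcomes rather than fabricated metrics.

## Validation problem sizes

The shipped test suite checks index computations against brute-force
oracles (exhaustive-tangent search, dense-grid window extrema) on 200
random maneuvers; closed-form recovery of the timed-volume ratio of an
exponential volume curve sampled at 1 kHz; exact decision flips on
constructed curves straddling the 0.15-L, 0.025-L and 6-s boundaries;
severity monotonicity of each defect's headline metric over a 5-point
grid by 20 seeds; bit-level determinism under fixed seeds; and the
operating point on a 280-curve labeled dataset (100 clean + 20 per
defect), requiring sensitivity and specificity of at least 0.95 with at
most 15% of curves routed to grade 2 and each defect detected by its
designated criterion in at least 95% of its curves. These sizes were
chosen so the whole suite runs in well under a minute per component while
keeping the binomial noise on a 95% rate below the margins being asserted.

## Known limitations

Thresholds for the novel shape criteria are calibrated on the synthetic
family only. The C6 interpretation (PEF/FVC) is one of two defensible
readings of the published wording. The C10 refinements implement a
plausible parameterized family, not published constants. Grade-2 routing
is conservative by construction and nearly empty under the synthetic
conditions; on real data its volume depends entirely on where the warning
thresholds sit relative to device noise.
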