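---
title: "Methods: a digital twin of a dynamic myocardial perfusion phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital twin of a dynamic myocardial perfusion phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpiphantom)
```

## What this package models

Hardware perfusion phantoms validate absolute myocardial perfusion imaging
(MPI) by pushing a radiotracer bolus through a physical "heart" at known
flow settings, so software-derived myocardial blood flow (MBF) can be
compared against a flow-sensor ground truth. `mpiphantom` is a software
twin of such a setup: a closed 5 L water circuit feeding a well-mixed
left-ventricular cavity (LVC) at 4 L/min, three parallel myocardial segment
lines at 40–125 mL/min each, sorbent-based tracer trapping in the segments,
recirculation filters in the return lines, and the complete dynamic-SPECT
analysis chain on top (frame binning, TAC processing, net-retention MBF
estimation, AHA territory reporting).

Everything downstream of the simulator treats its output the way clinical
software treats scanner data, so the estimation chain can be validated
against analytic ground truth under fully controlled conditions.

## The flow-circuit model

All compartments are well-mixed. With activities in MBq, volumes in mL and
flows converted to mL/s at the boundary, the states are the in-transit
bolus $D$, the LVC activity $A_L$, per-segment free and trapped activities
$F_i$, $T_i$, the reservoir $A_R$ and the filtered sink:

$$\dot D = u(t) - D/\tau, \qquad
  \dot A_L = Q\,C_R + D/\tau - Q\,C_L,$$
$$\dot F_i = Q_i C_L - Q_i C_i - k_{ads,i} V_i\, C_i + k_{des,i} T_i,
  \qquad \dot T_i = k_{ads,i} V_i\, C_i - k_{des,i} T_i,$$
$$\dot A_R = (1-\eta)\Big[(Q - \textstyle\sum_i Q_i) C_L
  + \sum_i Q_i C_i\Big] - Q\,C_R,$$

with concentrations $C_X = A_X / V_X$, arterial flow $Q$, segment flows
$Q_i$, and filter efficiency $\eta$ (the filtered fraction goes to a sink).
The bolus $u(t)$ is rectangular — 500 MBq over 1.5 s (1.5 mL at 1 mL/s) —
and the dispersion compartment with time constant $\tau = 5$ s stands in
for injector-to-LVC transport smearing; only injector settings are known,
so a single-exponential kernel is the simplest defensible choice.

Sorption is linear: trapping is a clearance $k_{ads} V$ (mL/min) out of
the segment's free water volume, release a first-order rate $k_{des}$.
Activated carbon is irreversible ($k_{des} = 0$), zeolite reversible
($k_{des} = 0.05$/min, an order-of-magnitude choice — reversibility is a
qualitative observation). For the well-mixed segment the first-pass
extraction has the closed form

$$E = \frac{k_{ads} V}{Q_i + k_{ads} V},$$

which the simulator reproduces exactly (it is also the independent oracle
in the tests). Defaults are calibrated so the optimised 7 g
activated-carbon filling gives $k_{ads}V = 120$ mL/min, i.e. $E = 0.60$ at
the normal 80 mL/min — inside the physiological 55–65% window for
Tc-99m-labelled MPI tracers. Free segment volume (30 mL) and the rate
constants are calibration choices, not measured values: the hardware
never reported them.

Numerical scheme: fixed-step classical RK4 at $dt = 0.05$ s. The system is
linear and non-stiff at these rates; the step resolves the fastest time
constant (LVC, $V_L/Q \approx 1.4$ s) by a factor ~30. The bolus enters as
a per-step constant (rate × overlap of the step with the bolus window), so
the integrator accounts for the injected mass exactly and the whole-system
mass balance holds to machine precision — the test suite enforces 0.1%
but observed errors are ~1e-15. Negative or non-finite states abort with
the offending compartment named; values below zero by less than 1e-6 of
the dose (floating-point dust) are clamped.

Physical decay of Tc-99m (half-life 6.01 h) is off by default — under
1.2% over a 6-minute scan and no decay correction is part of the analysis
chain — but available via `include_decay`.

Tubing transport delays are zero by default: no tubing lengths are known,
and a pure delay would be absorbed by the AIF peak alignment anyway.

## The acquisition model

`default_frame_schedule()` reproduces the clinical list-mode re-binning:
21 × 3 s, then 9, 15, 21, 27 s, then 7 × 30 s — 32 frames, 345 s. Frame
values are averages of the true concentration over the frame, stamped at
the frame midpoint (the vendor convention is unknown; midpoints make the
frame value an unbiased sample of a linear curve).

The measured tissue signal is
$P_{obs} = PV \cdot P_{true} + S_m \cdot C_a$ and the blood-pool signal
$C_{a,obs} = C_a + S_b \cdot P_{true}$, with forward defaults equal to the
correction constants used at estimation (PV = 0.63, $S_m$ = 0.4,
$S_b$ = 0): under matched assumptions the corrections invert the forward
model exactly, so any residual estimation error is attributable to the
physics (recirculation, windowing), not to model mismatch. Both knobs can
be mismatched deliberately to study bias.

Counting noise is Poisson on frame counts with mean
`sensitivity × value × duration` and a single global sensitivity of
10 counts per MBq·s — no count levels were ever reported, so this is a
realism knob; at the default it yields ~20–45 counts per tissue frame and
replicate-level MBF SDs of 0.2–0.3 mL/g/min, comparable to the large
spreads seen in real measurements. A constant per-segment
`background_level` models residual activity from earlier measurements
(slow washout is negligible over 6 minutes); the rest scan — acquired
without injection — measures exactly this baseline.

## TAC processing

The pipeline mirrors the clinical/offline analysis order: background
subtraction (rest from stress, pointwise, floored at zero with floor
events logged — activity cannot be negative), then normalisation of each
measurement to 500 MBq injected (doses are drawn from 468–551 MBq),
then linear resampling to a 0.5 s grid and cubic-spline AIF peak location
(resolution ≤ 0.01 s) for cross-measurement alignment to the mean peak
time. Alignment is used only for ensemble mean ± SD curves and AUC
statistics; per-measurement retention integration runs on the native scan
clock, as the clinical software's own estimates did. Ensemble statistics
use the sample (n−1) SD and are restricted to the common time span after
shifts — curves are never extrapolated. AUC windows are the
retention-model limits: [0, 60] s for AIFs, [60, 120] s for TRFs.

The "recirculation-corrected" TRF overlay sometimes drawn in such plots
(a linear rise from ~20 s) is deliberately not implemented as an input to
estimation; it is a visual suggestion, not a measurement.

## Net-retention MBF estimation

The retention rate is

$$R = \frac{\frac{1}{PV (t_3 - t_2)} \int_{t_2}^{t_3}
      \big(P(t) - S_m C_a(t)\big)\,dt}
     {CF \int_0^{t_1} \big(C_a(t) - S_b P(t)\big)\,dt},$$

with $t_1 = 60$ s (end of the blood-pool phase), $t_2 = 60$ s,
$t_3 = 120$ s, PV = 0.63, CF = 1, $S_m = 0.4$, $S_b = 0$. Integrals are
trapezoidal on the 0.5 s resampled grid (frames are coarse; after linear
resampling the curves are piecewise-linear, for which the trapezoid rule
is exact). The ratio has units 1/s and is multiplied by 60 to give
mL/g/min — the per-minute convention is this package's explicit choice,
with CF available to absorb any other calibration.

Under the retention model $R = \mathrm{MBF} \times E$. How clinical
software converts $R$ to MBF is vendor-internal, so the conversion is
explicit here: `mbf_from_retention(R, assumed_extraction)`, with the
assumed extraction defaulting to the simulator's configured closed-form
$E$ per segment, and both $R$ and MBF reported. An optional Renkin–Crone
hook (flow-dependent $E$) exists but is off by default.

Ground truth is flow over perfused mass:
$\mathrm{MBF}_{true} = \Phi / (\rho \cdot V_{VOI})$ with
$V_{VOI} = 53$ mL and $\rho = 1$ g/mL — 1.5 mL/g/min at 80 mL/min,
0.8 mL/g/min at 40 mL/min (values reported rounded half-away-from-zero to
one decimal, like all printed MBF values here).

Territory reporting uses the AHA 17-segment model with segments 1, 2, 7, 8
→ LAD, 3, 4, 9, 10 → RCA, 5, 6, 11, 12 → LCX. The phantom has three
homogeneous segments, so each maps its value uniformly onto its four AHA
segments; apical segments are excluded because the phantom has no apex.
(Protocols for this phantom list segments 14–17 as excluded while analysing
exactly twelve segments, leaving 13 unmentioned; this package excludes
13–17, the consistent reading.)

## The experiment harness and reproducibility

`run_experiment()` chains everything: simulate rest (no injection) and
stress truth once, then per replicate draw an injected dose, scale the
truth (tracer kinetics are linear), acquire noisy rest/stress TAC sets,
subtract background, normalise, estimate $R$ and MBF per segment, and
aggregate across replicates per territory. Per-replicate seeds derive
deterministically from the master seed; every CSV artifact carries the
MD5 hash of the YAML-serialised configuration, and a provenance log
records seeds and versions. Identical configurations produce
byte-identical outputs.

Default problem sizes — 360 s simulated at dt = 0.05 s (7200 RK4 steps),
20 replicates — were chosen so a full campaign is a few seconds of
compute; an end-to-end run is well under two minutes on one CPU.

## What the generator does and does not emulate

It emulates: closed-loop recirculation with imperfect filters (the leaky
default $\eta = 0.9$ reproduces the characteristic slowly rising TRF tail;
$\eta = 1$ is the ideal mode), dose-to-dose variation, residual background
between measurements, partial volume, spillover and counting noise at
clinically plausible levels.

It does not emulate: image formation (no projections, reconstruction or
contour detection — the twin operates at ROI/TAC level), heterogeneous
sorbent distribution within a segment, cardiac or respiratory motion,
pump pressure dynamics, or sorbent saturation (sorption is linear; no
saturation was observed over a single bolus). Consequently, passing tests
demonstrate correctness of the kinetic analysis chain under the stated
physics — they do not certify performance on real scanner data, where
contour misplacement and reconstruction effects add error modes this twin
does not contain.

## Numerical and degenerate-input choices

- Boundary-peak curves: `locate_peak()` warns and returns the boundary
  time rather than failing.
- Background subtraction floors at zero; the count of floored samples is
  kept in the curve metadata.
- `retention_rate()` extends curves as constant before the first sample
  (frame midpoints start at 1.5 s; a pre-bolus AIF is zero there anyway)
  and refuses curves that do not reach $t_3$, and AIF integrals ≤ 0.
- A single-curve ensemble reports SD 0 with an explicit flag.
- Zero injected activity short-circuits to exact zero curves.

## Known limitations

Recirculation biases the estimator upward by ~5–10% at the default
$\eta = 0.9$ (extra late-window tissue uptake outpaces the extra AIF
tail); this is faithful to the physical setup's main limitation, and the
ideal-filter mode isolates it. The retention estimator's accuracy also
degrades if the bolus is not fully through the LVC by $t_1$ — at the
default dispersion and flows it is. Extraction–flow coupling
($E$ falls as flow rises) means a fixed assumed extraction would bias
high-flow estimates; the per-segment closed-form default avoids this in
the twin but real analyses must model it explicitly.
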