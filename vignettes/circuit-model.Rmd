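---
title: "An RC-circuit view of mitochondrial ATP synthesis in mitosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An RC-circuit view of mitochondrial ATP synthesis in mitosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`mitovolt` treats the inner mitochondrial membrane as a one-capacitor
electrical circuit. The electron transport chain (ETC) is a battery of
effective electromotive force $E$ charging the membrane capacitance $C$
through a conductance $g_\mathrm{ETC}$; ATP synthase and proton leak are
parallel discharge conductances $g_\mathrm{ATP}$ and $g_\mathrm{leak}$.
With all conductances expressed per unit capacitance (units 1/min,
$C \equiv 1$):

$$\frac{dV}{dt} = g_\mathrm{ETC}(E - V) - (g_\mathrm{leak} + g_\mathrm{ATP})\,V$$

Within an epoch of constant conductances the solution is a single
exponential relaxation with time constant
$\tau = 1/(g_\mathrm{ETC}+g_\mathrm{leak}+g_\mathrm{ATP})$ toward
$V_{ss} = E\,g_\mathrm{ETC}/(g_\mathrm{ETC}+g_\mathrm{leak}+g_\mathrm{ATP})$.
CDK1 activity switches the conductance set at mitotic entry (G2/M) and
back at the metaphase–anaphase (M/A) transition; because the biochemical
switch is fast but not instantaneous, conductances interpolate linearly
over a short transition ramp (default 4 min, two sampling intervals)
around each switch, and samples inside a ramp are excluded from epoch
fitting.

Membrane potential is stored as a positive magnitude in mV
(hyperpolarization = larger value), which keeps Ohm's-law currents
positive. The cationic dye (TMRE at non-quenching concentration) is
assumed to partition Nernstianly, so after mass normalization (dividing
fluorescence by buoyant mass) and baseline normalization (dividing by
the median over the 3 h preceding abscission), the signal $s(t)$ maps to

$$V(t) = V_\mathrm{baseline} + \frac{RT}{F}\,\ln s(t)$$

with $RT/F \approx 26.73$ mV at 310.15 K. Volume-fraction and
plasma-membrane-potential corrections are deliberately omitted: the
pipeline's conclusions are expressed as *relative* rates, and the
sensitivity scan (below) quantifies how little they depend on the
conversion constants.

Key identifying assumptions, recorded in output metadata:

* capacitance is equal across conditions and CDK1 states ($C \equiv 1$);
* control and oligomycin-treated cells share the same non-ATP
  conductances, so the difference in their relaxation rate constants
  $1/\tau$ is the ATP-synthase conductance
  $\kappa_\mathrm{ATP} = g_\mathrm{ATP}/C$ of that state (oligomycin
  takes $R_\mathrm{ATP}\to\infty$);
* only relative ATP currents are identifiable; every profile is reported
  as a fraction of the cell's own G2 reference rate
  $I_{G2} = V_{G2}\,\kappa_\mathrm{off}$.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `sampling_interval` | 2 | min | temporal resolution of the measurement system emulated |
| `noise_cv` | 0.02 | – | multiplicative optical noise floor of the fluorescence readout |
| `v_baseline` | 130 | mV | typical literature G2 magnitude; swept 100–180 mV by the sensitivity scan |
| `temperature` | 310.15 | K | 37 °C assay temperature, sets $RT/F$ |
| `window` | 180 | min | baseline-normalization window before abscission |
| `slope_tolerance` | 0.02 | /h | steady-baseline QC threshold, at the optical noise floor |
| `ramp` | 4 | min | CDK1 transition ramp; samples inside are excluded from fits |
| `tau_bounds` | (0.1, 500) | min | physically plausible relaxation range for the bounded fit |
| anaphase window | 15 | min | from the M/A transition, clipped at abscission |

The G2 reference potential $V_{G2}$ is the median over
$[t_\mathrm{G2/M}-60,\,t_\mathrm{G2/M}-10]$ min; the 10-min standoff
avoids any pre-prophase drift near the switch.

## What the synthetic generator emulates

`simulate_cohort()` draws per-cell conductances log-normally (CV 0.1 by
default) around a cohort-level truth, solves the switched circuit
exactly (closed form within epochs, RK4 across ramps), and emits
fluorescence as $m(t)\,e^{V(t)/(RT/F)}$ times unit-mean log-normal noise,
with exponential mass growth (4%/h from 50 pg). Each simulated cell
spans late G2 (255 min at the off-state steady state) through a 30-min
mitosis and 45-min cytokinesis to abscission at 330 min; division is not
simulated within a trace. The cytokinesis span was chosen so the
CDK1-off fit window covers about four off-state time constants.

Default circuit truth: CDK1-off $g_\mathrm{ETC}=0.04$,
$g_\mathrm{leak}=0.01$, $g_\mathrm{ATP}=0.05$ min⁻¹
($\tau_\mathrm{off}=10$ min), with $E$ derived so the off steady state
equals `v_baseline`; CDK1-on $g_\mathrm{ETC}=0.07$,
$g_\mathrm{leak}=0.06$ min⁻¹, and $g_\mathrm{ATP,on}$ *calibrated by
root-finding* so that the generative time-averaged ATP current over
early mitosis is exactly half the G2 rate (a designed 50% decrease,
$g_\mathrm{ATP,on}\approx 0.021$ min⁻¹). This parameter set
hyperpolarizes by ~20 mV (about a two-fold dye signal at the M/A peak),
keeps the anaphase rate near G2 levels, and makes the non-ATP
conductance rise in mitosis — the regime the analysis is designed for.

What it does **not** emulate: voltage-dependent (nonlinear) proton leak
— a consequence is that simulated oligomycin cells reach an
unrealistically high baseline steady state and *depolarize* during
mitosis, whereas real oligomycin-treated cells hyperpolarize mildly;
this is harmless to the pipeline because only their time constants enter
the inference and those are offset-invariant. Also not emulated: dye
quenching and diffusion kinetics, plasma-membrane-potential shifts,
mitochondrial volume changes, mass measurement noise (sub-0.2%,
negligible), or event-time annotation error. Passing recovery tests on
these cohorts therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artifact of real traces.

## Numerical choices

* **Forward solver.** Exact exponentials within constant-parameter
  epochs; classical RK4 at step 0.01 min across ramps. Tests verify
  agreement with stitched closed forms ($<10^{-9}$ mV, instant switch)
  and with an independent adaptive integrator (`deSolve::lsoda`,
  $<10^{-6}$ mV with a ramp).
* **Epoch fitting.** Bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`) of $v_\infty + (v_0-v_\infty)e^{-t/\tau}$, with
  a deterministic three-point $\tau$ multi-start (span/10, span/3, span);
  the start with the lowest RMSE wins. Flat segments are declared
  unidentifiable (`flat_segment`) rather than fitted; optimizer failure
  returns the initialization with `converged = FALSE`.
* **Conductance subtraction.** The arm location of the per-cell rate
  constants $1/\hat\tau$ is the **median** (the mean is available via
  `aggregate = "mean"`). $1/\hat\tau$ is a convex transform of a noisy
  estimate, so its distribution is right-skewed; with 2% optical noise a
  few control on-segments fit with badly underestimated $\tau$, and an
  arm mean inherits those outliers while the median does not. Negative
  conductance differences are clamped to zero with a warning, raw value
  retained.
* **Window averaging.** Relative-rate window means are trapezoidal
  time-averages with endpoint interpolation; with an instantaneous
  switch the CDK1-on interval is closed at the M/A transition (left
  limit at the peak).
* **QC.** The spec of a "steady baseline prior to division" is
  evaluated on the pre-mitotic part of the baseline window (the window
  itself extends through mitosis, where any slope would only measure the
  mitotic spike): least-squares slope $\le 2\%$/h of baseline, at least
  5 samples and 60 min of pre-mitotic coverage. Cells whose converted
  potential magnitude is non-positive under the assumed baseline (only
  possible when sweeping the conversion far from the truth) are excluded
  with reason `voltage_conversion_failure`.
* **Error model.** Cohort summaries report the analytic SEM and a
  seeded bootstrap-over-cells SEM side by side. The per-cell decrease
  is the mean of per-cell ratios (the `ratio_of_means` convention is a
  config flag).

## Design choices made where the design was open

* The on-state is fit as a rising single exponential toward a fixed
  asymptote (no moving-target or double-exponential variant), matching
  the single-RC interpretation of each epoch.
* The anaphase window is anchored at the M/A transition (15 min,
  clipped at abscission), and the anaphase summary is the time-average,
  not the peak.
* Oligomycin cells contribute only to conductance extraction; their
  implied ATP current is identically zero and they never enter profile
  summaries.
* The transition-exclusion ramp applies to both fit windows
  (`[t_{G2/M}+r, t_{M/A}]` and `[t_{M/A}+r, t_\mathrm{abscission}]`).

## Problem sizes and reproducibility

The shipped tests and the acceptance script use cohorts of 40 + 40 cells
at 2-min sampling (166 samples/cell), 500-replicate Monte-Carlo checks
for fit-noise properties, and a six-point baseline-potential sweep —
sizes chosen so the full suite exercises every stage in a couple of
minutes on a laptop. At those design conditions the cohort-to-cohort
sampling SD of the estimated decrease is roughly 7 percentage points,
dominated by fit noise in the control on-state time constant (a
three-parameter exponential on 13 points with ~0.5 mV effective noise is
close to its information limit). Every random draw descends from
explicit seeds; rerunning any configuration reproduces results
bit-for-bit.

## Known limitations

* Per-cell fits are independent; no hierarchical pooling across cells.
* The subtraction estimator assumes control and oligomycin arms are
  exchangeable in their non-ATP conductances; systematic differences
  (e.g. drug effects on the ETC) would bias $\kappa_\mathrm{ATP}$.
* Absolute fluxes are unidentifiable without the capacitance and the
  dye-to-potential proportionality; all outputs are relative.
* The linear leak makes extreme-voltage behavior (notably the simulated
  oligomycin baseline) unphysical, as discussed above.
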