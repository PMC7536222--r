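# mitovolt

Circuit-model inference of mitochondrial ATP synthesis rates through
mitosis, from single-cell membrane-potential dye traces.

## The problem

Proliferating suspension cells (e.g. L1210 lymphocytic leukemia cells)
transiently hyperpolarize their mitochondria during mitosis: the
mass-normalized TMRE signal rises from the G2/M transition, peaks at the
metaphase–anaphase (M/A) transition, and recovers during cytokinesis, in
step with switch-like CDK1 activity. Whether ATP *synthesis* rises or
falls during that window cannot be read off the dye signal directly —
membrane potential reflects the balance of the electron transport chain
(ETC) charging the membrane and the ATP-synthase plus proton-leak paths
discharging it.

`mitovolt` is for experimentalists and modelers who have (or want to
simulate) single-cell time series of buoyant mass and potentiometric dye
fluorescence with per-cell mitotic event annotations, and who want
relative mitochondrial ATP synthesis rates through division with honest
uncertainties.

## The model

The inner mitochondrial membrane is treated as an RC circuit: an ETC
battery with electromotive force *E* charges the membrane capacitance *C*
through conductance *g*<sub>ETC</sub>, while ATP synthase
(*g*<sub>ATP</sub>) and proton leak (*g*<sub>leak</sub>) discharge it:

    C dV/dt = g_ETC (E − V) − (g_leak + g_ATP) V

Within a fixed CDK1 state the solution is a single exponential with

    τ = C / (g_ETC + g_leak + g_ATP),   V_ss = E g_ETC / (g_ETC + g_leak + g_ATP)

Conductances switch between CDK1-on (G2/M → M/A) and CDK1-off (G2,
cytokinesis) parameter sets, interpolating linearly over a short
transition ramp. The pipeline:

1. converts mass-normalized, baseline-normalized TMRE signal to an
   approximate potential magnitude via the Nernst relation
   *V*(*t*) = *V*<sub>baseline</sub> + (*RT/F*) ln *s*(*t*);
2. fits the exponential relaxation of each CDK1 epoch per cell, giving
   state-specific time constants τ<sub>on</sub>, τ<sub>off</sub>;
3. extracts the ATP-synthase conductance per state from the shift in
   rate constants when oligomycin blocks the synthase
   (κ<sub>ATP</sub> = median<sub>control</sub> 1/τ −
   median<sub>oligomycin</sub> 1/τ, since oligomycin takes
   *R*<sub>ATP</sub> → ∞);
4. derives the ATP synthesis current by Ohm's law,
   *I*<sub>ATP</sub>(*t*) = *V*(*t*) κ<sub>ATP</sub>(*t*), reported
   relative to each cell's G2 rate *V*<sub>G2</sub> κ<sub>off</sub>.

Only relative rates are identifiable (C ≡ 1 by convention). A synthetic
trace generator with the same circuit (plus multiplicative log-normal
optical noise and log-normal inter-cell parameter variability) makes
every stage testable without instrument data, and population-level
utilities cover synchrony-corrected flux unmixing, oligomycin-sensitive
oxygen-consumption decomposition and lactate efflux slopes.

## Worked example

Simulate the default study: 40 control + 40 oligomycin-treated cells,
2-min sampling, 2% optical noise, 10% inter-cell conductance variability,
with the generator calibrated so the true early-mitosis ATP synthesis
decrease is exactly 50%; then run the full analysis:

```r
library(mitovolt)
bundle <- run_pipeline(pipeline_config(seed = 1, infer = list(n_boot = 500)))
print(bundle)
#> <report_bundle>
#>   cells passing QC: 80 of 80
#>   kappa_atp (CDK1 on):  0.0228 +- 0.0062 1/min
#>   kappa_atp (CDK1 off): 0.0504 +- 0.0074 1/min
#>   early-mitosis ATP synthesis decrease: 46.1% +- 0.5% (mean +- SEM, n = 40)
#>   anaphase ATP synthesis change: +0.3% +- 0.8%
#>   total ATP ratio, early mitosis: 0.54; anaphase: 1.00
```

Reading the output: the ATP-synthase conductance drops from
0.050 min⁻¹ in the CDK1-off state to 0.023 min⁻¹ in the CDK1-on state
(the generating truth is 0.050 and 0.021), so despite the mitotic
hyperpolarization the inferred ATP synthesis rate falls by ~46% (truth:
50%) between mitotic entry and the M/A transition, and mitochondria
synthesize only ~0.54× the ATP a constant-G2-rate null would give over
that window. During anaphase the rate is back near G2 levels. The
quoted SEM is the spread over cells at the shared cohort conductances;
cohort-to-cohort sampling variability of the decrease at these design
conditions is ~7 percentage points (see the methods vignette).

`render_report(bundle, "out/")` writes the summary, a per-cell fit
table, bundle JSON, τ boxplots, a fit-overlay figure and a per-cell
*I*<sub>ATP</sub> fan chart centered on the M/A transition.

External cohorts in the documented CSV dialect load with
`read_cohort()`, and `pipeline_config(paths = list(traces = ...,
annotations = ...))` runs the identical analysis on them.

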