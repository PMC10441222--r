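---
title: "Methods: kLa-based scale-up analysis and the synthetic chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kLa-based scale-up analysis and the synthetic chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscale)
```

## The problem

Aerobic cultivations of the thermoacidophilic archaeon *Sulfolobus
acidocaldarius* (75 °C, pH 3) are oxygen-fragile in a specific way: the
organism needs sufficient dissolved oxygen (DO), but raising the oxygen
fraction of the inlet gas to compensate for poor transfer harms viability.
That rules out the common fix for under-aerated large vessels and makes the
*volumetric oxygen mass transfer coefficient* kLa — rather than the aerated
power input Pg/VL — the natural scale-up criterion: hold kLa constant across
scales and the culture never needs oxygen-enriched gas.

`chemoscale` implements the complete computational side of such a scale-up
campaign: estimating kLa from dynamic gassing-out experiments,
characterizing stirred-tank power input, translating an operating point to a
new scale at constant kLa, and evaluating the full chemostat physiology
(rates, yields, off-gas balances, carbon closure) with steady-state
statistics. A synthetic cultivation generator with known ground truth closes
the loop: every estimator in the package can be exercised against data whose
true values are known exactly.

## kLa from dynamic gassing-out

The experiment sparges nitrogen until DO ≈ 0 %, switches to air, and records
the DO rise. With a step change in the saturation driving force the oxygen
balance gives

$$C(t) = C^\*\bigl(1 - e^{-k_La\,t}\bigr),$$

so the *oxygen deficit* is log-linear in time:
$\ln(1 - C/C^\*) = -k_La\,t$. `fit_kla()` estimates kLa as minus the slope
of that regression.

Numerical choices:

* **Fit window 10–90 %DO** (configurable). Near saturation the deficit
  $1 - C/C^\*$ approaches zero and its logarithm amplifies probe noise
  without bound; below ~10 % the switch transient and gas-phase washout
  distort the response. The window keeps the regression in the
  well-conditioned middle of the curve.
* **Probe lag off by default.** `simulate_do_step()` can convolve the
  response with a first-order probe time constant (the analytic
  two-exponential solution, with the confluent limit handled explicitly at
  $k_La\,\tau = 1$), but the estimator does not model lag by default: probes
  are calibrated at the operating point and the lag of a modern optical DO
  probe is small against 1/kLa ≈ 90 s at kLa ≈ 40 h⁻¹.
* **Optional nonlinear refinement** (`refine = TRUE`) re-fits the
  exponential model directly; with heavy noise the log transform carries a
  small downward bias that the refinement removes. The log-linear estimate
  is exact on noiseless data.

A seed-swept simulation (100 replicates at 1 %DO probe noise; run by the
test suite and the acceptance script) characterizes the estimator's
dispersion; its relative standard deviation stays within the few-percent
reproducibility that gassing-out measurements typically show.

## Power input and operating-point translation

Ungassed power is the standard turbulent-regime draw
$P = \sum N_p\,\rho\,n^3 d^5$ over the mounted impellers; a warning fires
when the impeller Reynolds number drops below $10^4$, where a constant
power number no longer applies. Sparging reduces the draw; the default
correction is the Michel–Miller correlation
$P_g = c\,(P^2 n d^3 / Q^{0.56})^{0.45}$ (SI units, $c = 0.72$), capped at
the ungassed power so the zero-gas limit is exact. The correlation choice is
configurable — vendor-specific cavity behaviour can deviate substantially —
and impeller characteristics (diameter, power number, count) must come from
the user: they are vendor data.

Scale translation uses the standard power-law correlation
$k_La = \alpha\,(P_g/V_L)^a\,v_s^b$ fitted on logs to measured operating
points (`fit_kla_correlation()`), where $v_s$ is the superficial gas
velocity. `solve_operating_point()` root-solves the correlation for the
stirrer speed that reaches a target kLa at fixed gas flow, within an
admissible 50–1500 rpm range (configurable) and a default 1 % tolerance.
Since predicted kLa rises monotonically with stirrer speed, a sign-changing
bracket guarantees the root; an unreachable target reports the achievable
kLa interval instead.

All correlations are evaluated in SI internally; rpm→s⁻¹ conversion happens
in exactly one place per formula.

## The chemostat physiology calculus

For each pair of consecutive sampling points the package evaluates:

* dilution rate $D = (F_{feed} + F_{acid})/V$ — acid counts toward dilution
  but carries no substrate;
* bleed-corrected specific growth rate
  $\mu = (\Delta X + \Delta V_{bleed}\,\bar{x}) / (\bar{X}\,\Delta t)$ with
  $X = x V$ total biomass; at steady state the broth term vanishes and the
  bleed term recovers $\mu = D$;
* specific substrate rates
  $q_S = (\Delta S_{reactor} + S_{in} - S_{out}) / (\Delta t\,\bar{X})$,
  *consumption-positive* ($\Delta S_{reactor}$ as previous − current), and
  the product rate production-positive — yields and the carbon balance are
  only meaningful with positive rates;
* gas rates from the simple difference form
  $CER = (Q_g/V)\,(1/V_m)\,(y_{CO_2,out} - y_{CO_2,in})\cdot 1000$ with
  $V_m = 22.414$ L/mol, and OUR as $(y_{O_2,in} - y_{O_2,out})$ — the inlet
  minus outlet ordering makes OUR positive for consumption so that
  $RQ = CER/OUR$ is positive. The specific oxygen rate is $OUR/x$ and the
  specific CO₂ rate $CER/x$;
* C-mol yields via the shipped compound table (glucose 180.16 g/mol, 6 C;
  anhydrous MSG 169.11 g/mol, 5 C; trehalose 342.30 g/mol, 12 C) and the
  carbon balance $Y_{X/S} + Y_{CO_2/S} + Y_{Tre/S}$ in C-mol/C-mol.

Conventions worth stating explicitly:

* **Bleed-discharged substrate/product** uses the mean of the two bounding
  broth concentrations times the bleed volume. Samples are ~24 h apart and
  no finer concentration trace exists; at steady state the approximation is
  exact.
* **Off-gas alignment**: gas signals are linearly interpolated to the
  sampling-interval midpoints. Off-gas analyzers log far more densely than
  broth sampling, so interpolation error is negligible against measurement
  noise.
* **Irregular intervals** (weekend gaps) need no resampling — every formula
  is interval-wise in $\Delta t$.
* **Glutamate vs MSG**: photometric assays report glutamic acid; the fixed
  factor 1.15 (the anhydrous-MSG/glutamic-acid molar-mass ratio,
  169.11/147.13 = 1.149) converts to MSG equivalents on data entry.
* **Biomass elemental composition** is not measured by typical campaigns;
  the C-mol biomass yield uses the standard microbial formula
  CH₁.₈O₀.₅N₀.₂ (0.488 g C/g DCW), overridable wherever a
  `biomass_composition` is accepted. An organism-specific measured
  composition would shift $Y_{X/S}$ (C-mol) and the carbon balance
  proportionally.
* **OD540 → DCW** uses the published correlation factor 0.586 g/L.

Steady state is declared four theoretical dwell times ($4/D$) after the
chemostat start; all rates and yields are evaluated per interval and then
averaged over the steady-state intervals, with spread reported as
STD% = 100 · sample SD / mean (undefined, and reported as missing, when the
mean is zero).

Group comparison of steady-state scalars (viability across sparger/kLa
conditions) uses classical one-way ANOVA followed by pooled-variance
two-sample t tests with a Bonferroni-adjusted threshold (family α divided by
the number of pairs; 0.05 over three pairs gates at p < 0.0167). The pooled
variance choice is the classical post-hoc-after-ANOVA convention; with the
small, similar group sizes of steady-state campaigns the distinction from
per-pair variance is minor.

## The synthetic cultivation generator

`simulate_cultivation()` integrates a three-phase process — batch,
exponential fed-batch, chemostat — as ODEs on total amounts (biomass,
glucose, MSG, trehalose, volume, cumulative flows and gas) with
`deSolve::lsoda` (rtol = atol = 1e-8, 0.25 h output grid; phase ends located
by root-finding).

**Kinetics.** Growth follows dual-substrate multiplicative Monod kinetics,
$\mu = \mu_{max} \frac{G}{K_G + G}\frac{M}{K_M + M}$, with uptake
$q_i = \mu / Y_{X/S,i}$ per substrate and a small constant specific
trehalose formation rate. Defaults: $\mu_{max} = 0.08$ h⁻¹ (comfortably
above the 0.03–0.035 h⁻¹ operating range, so the chemostat is
substrate-limited), $K = 0.05$ g/L each, yields 0.933 g/g (glucose) and
0.442 g/g (MSG). The yield split fixes the glucose:MSG consumption ratio at
the feed ratio (4.5 : 9.5), so both substrates are drawn down together —
the overall yield of ~0.30 g/g then puts steady-state biomass near 4 g/L on
the 14 g/L total feed carbon load, the titer class the benchtop process
produces. $q_{Tre} = 0.002$ g/g/h leaves a ~0.27 g/L extracellular
trehalose pool at D = 0.03 h⁻¹.

**Gas phase.** The generator does not posit independent gas stoichiometry:
CO₂ carbon is defined as consumed substrate carbon minus biomass and
trehalose carbon, and O₂ consumption as CO₂ divided by a fixed true RQ
(default 1.0, the complete-carbohydrate-oxidation value). Carbon is thereby
conserved *by construction* — the test suite verifies the closure against an
independent cumulative bookkeeping oracle to within 0.1 % — which is exactly
the property the analysis pipeline's C-balance is supposed to detect. A
kinetic-parameter set for which the generated data would *not* close carbon
is impossible, so a pipeline C-balance away from 1.0 always indicates an
analysis defect, not a generator artifact. For this reason the generator
has no free oxygen-per-biomass parameter: with carbon-closed CO₂ and a
fixed RQ, the gas phase is fully determined, and an independent O₂ constant
would over-determine it.

**Process schedule.** Defaults mirror the benchtop campaign: 1.5 L batch on
2 g/L MSG + 1 g/L glucose, exponential feed ramp starting at 14.8 g/h with
$\mu_{set} = 0.035$ h⁻¹ until 2 L, then chemostat at D = 0.03 h⁻¹ on
9.5 g/L MSG + 4.5 g/L glucose feed, 24 h sampling (optionally with weekend
gaps), hourly off-gas logging, and an acid stream at 2 % of the feed flow so
the dilution rate genuinely has two terms. The 20 L and 200 L presets scale
the vessel, the gas flow and the feed ramp (148 g/h, 1.4 kg/h).

One schedule parameter deserves its own paragraph: the **inoculation
density** defaults to 0.3 g/L. The feed-ramp start, the batch carbon load
and $\mu_{set}$ jointly determine the biomass a *consistent* exponential
fed-batch must begin with ($F_0 \approx \mu_{set} X_0 / (Y_{tot}
S_{feed})$); with the published ramp start of 14.8 g/h and the ~0.9 g/L of
biomass the batch medium can add, the batch must hand over ≈1.8 g — hence
the 0.3 g/L inoculum. A sparser inoculum (the OD range typical of such
campaigns corresponds to ~0.02–0.05 g/L) would make the early ramp overfeed
and the realized growth rate exceed the setpoint for most of the short
fed-batch; the real organism's batch physiology (extra complex-medium
components the simulator does not track) closes that gap in practice. We
chose consistency of the generator over literalism on the inoculum.

**Measurement model.** Multiplicative Gaussian noise with a configurable CV
is applied to the measured concentrations (DCW, OD, glucose, MSG,
trehalose, viability) and to the off-gas in/out concentration *differences*
(applying it to the raw mole fractions would make the noise on the
difference — the physically measured quantity class — explode).
Balance-derived quantities (volume, cumulative feed/acid/bleed) are treated
as exact: integrating pumps report these far more precisely than any assay.
Every stochastic element is seeded explicitly; a fixed seed reproduces the
fixture files byte-identically, and `resample_measurements()` redraws only
the measurement layer on a fixed true trajectory for seed-sweep studies of
estimator precision.

**Washout** (D above the achievable growth rate) is flagged — realized µ
pinned below 0.95 D at the end of the run — but still returns a valid,
analyzable output.

**Dissolved oxygen** during cultivation is reported diagnostically from the
quasi-steady balance $DO = 100\,(1 - OUR/(k_La\,c^\*))$ with a configurable
solubility $c^\*$ (default 0.25 mmol/L; not a literature value for this
medium). DO does not feed back on growth: the simulated process is assumed
oxygen-sufficient — which is precisely what a correctly executed
constant-kLa scale-up guarantees, and modeling oxygen toxicity is out of
scope.

### What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis assumes:
interval sampling of a smooth single-compartment process, carbon-conserving
gas generation, multiplicative assay noise, irregular sampling. It does not
emulate spatial gradients, probe drift, correlated analyzer error,
substrate-specific maintenance, oxygen limitation or toxicity, or batch
growth on untracked complex-medium components (NZ-amine is omitted from the
carbon bookkeeping). Estimator properties demonstrated on it — recovery of
µ, q's, RQ, carbon closure under noise — therefore validate the *calculus*,
not the biology: on real data the same pipeline can be biased by exactly
the effects the generator excludes.

## Problem sizes

The shipped test suite and the acceptance script run the benchtop-scale
scenario (about 18 h batch + 22 h fed-batch + 300 h chemostat at 0.25 h
integration output), 100-replicate kLa noise sweeps, and a 50-seed
measurement-noise recovery study — sizes chosen so the full suite completes
in seconds while leaving ≥ 6 steady-state sampling intervals, ~200 regression
points per kLa fit, and enough replicates for stable dispersion estimates.

## Known limitations

* The power-input module predicts, it does not measure: absolute kW/m³
  values depend on vendor impeller characteristics and the chosen gassed
  correlation, and reported values should be treated as estimates with the
  correlation's (substantial) literature spread.
* The kLa correlation is an interpolator; extrapolating it far outside the
  fitted Pg/VL–vs envelope is not protected against beyond the rpm-range
  guard.
* C-mol yields inherit the assumed biomass elemental composition.
* The simulator's trehalose kinetics (constant specific rate) are a
  placeholder for unknown formation kinetics; only the rate *calculus* on
  top of them is validated.
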