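---
title: "Modelling gas exchange against rubisco kinetics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gas exchange against rubisco kinetics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycogas)
library(dplyr)
```

## The scientific question

Acidophilic, thermophilic red microalgae live in water where inorganic carbon
is scarce: at pH ~2 essentially all dissolved inorganic carbon (Ci) is CO2(aq),
which outgasses readily, and at 40 °C both CO2 solubility and rubisco's CO2
affinity and specificity are poor. A carbon-concentrating mechanism (CCM) —
cellular machinery that raises the CO2 concentration around rubisco — would
explain how such an alga photosynthesises efficiently anyway. Because a CCM
suppresses rubisco oxygenation, its signature in gas-exchange data is a CO2
compensation point (Γ, the dissolved CO2 at which net assimilation is zero)
that is *lower*, and *less oxygen-sensitive*, than rubisco kinetics alone
permit.

`phycogas` implements that comparison quantitatively. It models the
compensation point permitted by published rubisco kinetics of thermophilic
Cyanidialean red algae, reduces aquatic-chamber gas-exchange data to the
physiological parameters the model predicts (Γ, apparent K~m~(CO2), A~max~,
respiration in the light R~L~), and provides the carbonate-speciation layer
needed to interpret pH-manipulation experiments that test whether cells can
take up bicarbonate.

## The compensation-point model

For rubisco-limited photosynthesis with day respiration R~L~, the compensation
point in liquid-phase units is

$$\Gamma = \frac{0.5/S_{c/o} + K_c r / K_o}{1 - r}\,O \;+\; \frac{K_c r}{1 - r},
\qquad r = R_L/V_{cmax},$$

with S~c/o~ the CO2/O2 specificity (molar/molar), K~c~, K~o~ the Michaelis
constants for CO2 and O2 (µM), and O the dissolved O2 (µM). Γ is exactly
linear in O, so the model's oxygen sensitivity is the closed-form slope
coefficient; `gamma_grid()` nevertheless also fits an ordinary least-squares
line through the (O, Γ) points and cross-asserts the two routes (they agree to
10⁻⁹ relative), because the measured-data pipeline extracts the same quantity
by regression.

Cellular V~cmax~ is taken as comparable to the measured maximal assimilation
rate A~max~, so the model consumes the ratio r = R~L~/V~cmax~ directly
(defaults 0.13 at 40 °C, 0.07 at 30 °C, from light-response measurements)
rather than computing V~cmax~ internally.

Because the kinetics of the study organism itself are unpublished, the model
is evaluated over *all* S~c/o~ × K~c~ cross-combinations of the packaged
parameter sets (three species; the single published K~o~ is shared), giving a
range rather than a point prediction. The slope extrema separate over the two
factors — the maximum slope pairs the lowest specificity with the highest
K~c~ — so the 9-combination cross and the 3 species-paired sets yield the same
range; the cross is the default and each row records its parameter provenance.

```{r grid}
grid <- gamma_grid(rubisco_cyanidiales(), temperature_c = 40,
                   o_levels = c(20, 209, 398), rl_ratio = 0.13)
glance(grid)
```

A measured slope (e.g. mean ± 2 SE over replicates) is compared against this
range with `classify_measurement()`: a measurement wholly below the calculated
minimum is the CCM signature.

`hypothetical_gamma()` runs the model's stress test: even with a specificity
double the highest temperature-adjusted value and a K~c~ half the lowest —
kinetics better than any measured rubisco — the model floor at 40 °C, 21% O2
is ~1.3 µM, so a measured Γ at or below that level cannot be explained by
plausible kinetics without a CCM.

## Temperature adjustment (Q10)

Published kinetics refer to 25 °C; measurements are made at 30–40 °C. Each
parameter is adjusted by the Q10 rule
Parameter(T) = Parameter(25 °C) · Q10^((T−25)/10), with two conventions that
matter:

* **Specificity (liquid phase)** has two published Q10 values at different
  base temperatures (0.60 at 25 °C, 0.62 at 35 °C). We apply them piecewise:
  0.60 over 25→35 °C, then 0.62 for the remainder, e.g.
  S(40) = S(25) · 0.60 · 0.62^0.5. The source tabulation does not spell out
  the intended composition; this reading reproduces the published slope range
  to < 1%, which is the only available evidence for it, and is flagged as an
  interpretation rather than a stated rule.
* **Michaelis constants** have Q10 values defined on gas-phase (µbar/mbar)
  forms. The adjustment therefore converts µM → partial pressure with Henry's
  law at 25 °C, applies Q10^((T−25)/10), and converts back at the target
  temperature, so the returned liquid-phase constant embeds the temperature
  dependence of solubility as well. Both forms are returned and are mutually
  consistent through Henry's law at T to 10⁻⁹ relative.

Adjustment below 25 °C errors deliberately: the coefficients describe the
warming direction and nothing in the framework needs cooling.

## Gas solubility and unit bridging

Henry's law C = H·P with H(T) = H₂₉₈.₁₅ exp[B(1/T − 1/298.15)]
(CO2: 0.035 mol/(kg·bar), B = 2400 K; O2: 0.0012 mol/(kg·bar), B = 1700 K)
links headspace and dissolved quantities. Partial pressure is mole fraction ×
total pressure (101,325 Pa default), with no water-vapour displacement or
fugacity correction — the simplest reading of C = H·P — and no
solute/ionic-strength corrections, whose partially non-additive effects are
conventionally neglected in this literature. Concentrations are computed in
mol/kg and reported in µM after multiplying by the density of pure water (a
quadratic in °C fitted once to a packaged 0–50 °C table; 0.99706 kg/L at
25 °C). The density step changes results by < 1% but keeps the units honest.

**Canonical dissolved O2.** Direct computation gives ≈18.5, 193, 387 and
232 µM for the four tabulated atmosphere/temperature combinations, while the
canonical published values are 20, 209, 398 and 251 µM (up to ~8% higher); how
the latter were derived is not recorded. Since the headline results (the slope
range and the 1.3 µM floor) are tied to the canonical values, `dissolved_o2()`
returns them by default (`mode = "canonical"`) and recomputes from Henry's law in
`mode = "physics"`. We deliberately do not guess the original derivation.

## Carbonate speciation and the accessible-Ci construct

`speciate_from_pco2()` models fresh water in equilibrium with a fixed
headspace pCO2: CO2(aq) = K0·pCO2 is pH-independent, HCO3⁻ = CO2(aq)·K1/[H⁺],
CO3²⁻ = HCO3⁻·K2/[H⁺], on the mol/kg scale with unit activity coefficients
and free-scale pH. Two K1/K2 formulations are shipped:

* `formulation = "plummer"`: Plummer & Busenberg (1982) zero-ionic-strength
  constants (pK1 = 6.35 at 25 °C, 6.30 at 40 °C) — the rigorous choice for
  pure water, cross-checked in the tests against the independent Harned &
  Davis equation.
* `formulation = "lueker"` (default): Lueker et al. (2000) evaluated at
  salinity 0 (pK1 = 6.11 at 25 °C, 6.00 at 40 °C). This is the default
  constant set of the carbonate-chemistry packages commonly used in this
  field, extrapolated outside their salinity calibration; it is what produces
  the familiar "bicarbonate is about half the Ci pool at pH 6 (40 °C)"
  statement (HCO3⁻/DIC = 0.499, versus 0.335 with the freshwater constants).

The default is the `"lueker"` set because the package's pH 2/pH 6
interpretation layer — in particular the "accessible pool doubles at pH 6 for
a bicarbonate user" expectation — is calibrated against results computed that
way; users doing de novo freshwater chemistry should prefer `"plummer"`
and expect the pH 6 bicarbonate share to be nearer a third than a half. This
~0.3-unit pK1 discrepancy is a real ambiguity in the upstream convention, not
a numerical issue.

`accessible_ci()` formalises the uptake question: a CO2-only organism sees
CO2(aq); a bicarbonate-capable one sees CO2(aq) + HCO3⁻ (carbonate never).
At pH 2 the two coincide to < 1%; at pH 6 (Lueker constants) they differ
two-fold, which is what makes the paired-pH experiment diagnostic.

## The gas-exchange pipeline

* **Headspace correction** (`headspace_co2()`): the instrument's
  subsample-loop arithmetic ΔC_sub = (µᵢ/µᵢ_sub)·ΔC, with headspace =
  (reference − ΔC) − ΔC_sub. The sign convention (ΔC = reference − sample,
  positive under CO2 drawdown) is the unique linear reading of the stated
  ordering assumption. Negative values are clamped to zero, flagged per
  record, and counted.
* **Michaelis–Menten fit** (`fit_michaelis_menten()`): two-parameter
  A = A~max~C/(K~m~+C) by Levenberg–Marquardt, with 95% CIs from the
  linearised covariance at the optimum (not profile likelihood — matching how
  such fits are conventionally reported). An optional strict `max_driver`
  cutoff (e.g. < 700 ppm) drops high-CO2 points that depart from saturation
  kinetics.
* **Compensation point** (`fit_compensation_point()`): OLS on points at or
  below 100 ppm (inclusive), Γ = −intercept/slope; a nonpositive slope is a
  degenerate-fit error rather than a silently negative Γ.
* **Kok respiration** (`fit_kok()`): OLS over the 10–30 µmol m⁻² s⁻¹
  *incident*-light window (the stated convention; absorbed-light conversion is
  out of scope), R~L~ = −intercept.
* **Oxygen response** (`oxygen_response_analysis()`): per-replicate OLS slopes
  of Γ vs dissolved O2, aggregated as mean ± 2 SE across replicates.
* **pH comparison** (`ph_comparison_tests()`): two one-sided Welch tests — the
  "half-mean" test of H0: µ₆ = µ₂/2 vs H1: µ₆ < µ₂/2, computed on the pH 6
  sample against the pH 2 sample scaled by 0.5 (variances scaled by 0.25), and
  the plain "pH 2 greater" test. The half-mean construction is one of several
  defensible formalisations of the verbal hypothesis (a ratio test on logs
  is another); the scaled-sample Welch form was chosen for transparency and
  is stated explicitly in the output.

Whether compensation points are fitted in ppm and converted, or fitted on
converted curves, changes Γ by < 0.5% over the ≤100 ppm window (the Henry
mapping is near-linear there); the tests assert that bound, so the choice is
immaterial.

## The synthetic-data generator

No raw instrument data are distributed, so every pipeline stage is exercised
against generated data with known ground truth, written into a `truth`
attribute so tests never re-derive it.

* **CO2 response**: the offset saturation model
  A(C) = (A~max~+R~L~)·C/(K~m~+C) − R~L~ + ε, ε ~ N(0, σ²). The offset form
  gives one curve meaningful targets for both fits: it saturates at A~max~ and
  crosses zero at the closed-form compensation point Γ = K~m~R~L~/A~max~.
  Defaults (K~m~ 150 ppm, A~max~ 35 pmol µg Chl a⁻¹ s⁻¹, R~L~ = 0.13·A~max~,
  3 replicates, σ = 5% of A~max~) mirror typical 40 °C cellular values; the
  noise level is a package choice — the instrument's noise magnitude is not
  published — stated here, not a claim about any instrument.
* **Light response**: exactly linear (φI − R~L~) below a break point, then a
  C¹ exponential approach to A~max~; the Kok window sits in the linear
  segment so noise-free recovery is exact.
* **Oxygen response**: linear Γ(O) per replicate; slopes either specified or
  drawn from the kinetic grid, with an `attenuation` factor in (0, 1]
  emulating a CCM damping the oxygen sensitivity.
* **Paired pH experiment**: the physiological driver is `accessible_ci()` at
  each record's pH, so a bicarbonate-capable simulated organism shows an
  apparent headspace-ppm K~m~ at pH 6 of about half its pH 2 value and a
  CO2-only one shows equal K~m~ — the diagnostic contrast the pipeline must
  resolve. Note one deliberate realism: the generator includes the R~L~
  offset, while the two-parameter fit (like the real pipeline) omits it, so
  fitted K~m~ carries a small (~6%) bias common to both pH groups; exactness
  tests therefore use the β = 0 (ratio exactly 1) configuration, and the
  β = 1 ratio is asserted within 0.05 of the analytic value.

Seeding: a master seed expands to per-replicate streams by a fixed affine
rule, so increasing the replicate count appends replicates without
reshuffling earlier ones, and identical configurations are byte-identical.

What the generator does *not* emulate: chamber mixing/equilibration
transients, analyzer matching and averaging, instrument drift or
heteroscedastic noise, photoinhibition, or any mechanistic CCM physiology.
Passing tests demonstrate that the estimators recover known parameters under
the stated noise model — not that real instrument data are this well-behaved.

## Numerical and statistical choices

* Nonlinear fits start from heuristics (A~max~ ≈ max response, K~m~ ≈ driver
  at half-max) with Levenberg–Marquardt damping; non-convergence is a hard
  error carrying the optimiser message, never a silent NA.
* Coverage expectations for "within 2 SE" checks are set from t-theory, not
  from the normal 95.4%: a pooled 9-point OLS slope has P(|t₇| < 2) = 0.914,
  and a 6-replicate mean has P(|t₅| < 2) = 0.898; the property tests assert
  coverage at those rates minus Monte-Carlo slack. The 95% CI coverage of
  K~m~ in the acceptance check comfortably exceeds its 90% floor (measured
  0.96 over 500 simulations).
* Problem sizes in the suite (500–1000 seeded simulations, 10⁴ fuzzed
  records) were chosen so the full suite runs in about a minute while keeping
  Monte-Carlo error well below the asserted margins.
* Degenerate inputs error early with the violated bound named: temperatures
  outside 0–50 °C (density) or 273.15–333.15 K (solubility), r ≥ 1
  (singular compensation point), nonpositive flows, fewer than the minimum
  points per fit window.

## Known limitations

* The Q10 piecewise rule for specificity and the canonical-O2 override are
  reproductions of an upstream convention, not first-principles choices; both
  have physics-mode alternatives exposed.
* The speciation layer is qualitative at the curve level: without knowing the
  upstream constant set and pH scale exactly, only the pH 2 scarcity and
  pH 6 ≈ half statements are reproducible, and those only under the `"lueker"`
  formulation.
* Liquid-phase only: gas-phase (µbar) compensation points for leaves, salinity
  corrections, borate chemistry and CO2-hydration kinetics are out of scope.
* Printed replicate-level statistics of the original experiments (measured
  slope, measured Γ, p-values) are *inputs* for classification here — the raw
  replicate data needed to recompute them are not public.
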