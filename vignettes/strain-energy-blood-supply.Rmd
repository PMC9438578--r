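---
title: "Arterial strain energy and blood supply: model, calibration, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial strain energy and blood supply: model, calibration, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## The model and its assumptions

The elastic aorta is modelled as a thin-walled cylinder (diameter-to-wall
ratio well above 10) whose circumferential behaviour over the physiological
pressure range is linear-elastic with secant modulus $E$. Axial deformation
is ignored: the axial modulus is much larger, the vessel is tethered by
surrounding tissue, and in vivo longitudinal stretching is small. The
surrounding tissue also limits free radial dilation; the fraction of the
free Laplace response that survives is the expansion constraint coefficient
$\varphi \in (0, 1]$, giving the constrained hoop stress
$\sigma_i = \varphi p_i D_i / 2h_i$ and the lumen area strain
$\varepsilon_A(p) = \varphi p D / (E h)$.

Between diastole ($p_d$) and systole ($p_s$) the wall stores the strain
energy density increment

$$\Delta u \;=\; \tfrac12(\sigma_s-\sigma_d)(\varepsilon_s-\varepsilon_d)
\;=\; \frac{\varphi^2(\alpha_s p_s - \alpha_d p_d)^2}{8E},
\qquad \alpha_i = D_i/h_i - 2 .$$

The two forms are not identical term by term: under equal wall ratios and
linear-elastic strains the stress–strain form equals the pressure form
times $((\alpha+2)/\alpha)^2$ (about 1.2 for the ascending aorta). The
pressure form is treated as authoritative whenever the input is a pressure
pair, because it is the expression written directly in the clinical
variables; the identity is pinned by a property test.

Treating blood flow as laminar (aortic Reynolds numbers are
$\sim 1000\text{–}2000$, below the critical 2100), a Hamilton-principle
balance of stored energy, kinetic energy and wall-shear dissipation yields
a characteristic velocity — the flow distance per pulse through the cross
section —

$$V = \frac{\varphi h (\alpha_s p_s - \alpha_d p_d)}{D\,\gamma\,(1+\beta)},
\qquad \beta = \frac{4 E \lambda (h_d - h_s)}{D (p_s - p_d)\varphi},
\qquad \lambda = 64/\mathrm{Re},$$

and the mean flow per minute at pulse rate $n$ through lumen area $A_f$:

$$\bar Q = n\left(1 + \frac{\varphi D p}{E h}\right) A_f V,
\qquad p = \tfrac13(2p_d + p_s).$$

$\beta$ folds the friction loss into the velocity solution; it vanishes if
the wall does not thin in systole and is negative (with a warning) if the
wall thickens, which would contradict incompressibility of a distending
wall.

## Conventions that the published form leaves open

The source equations are typeset with collapsed fractions and omit several
conventions. The package fixes them once (see also `CALIBRATION.md` at the
repository root):

* **Bare $D$ and $A_f$** use the reference *inner* diameter
  $D_o - 2h$. This is not arbitrary: the printed constraint coefficients
  $\varphi = 0.0439/0.0565$ for the resting and normal states reproduce the
  quoted 3 %/4 % area dilations *exactly* via
  $\varepsilon_A = \varphi \bar p D_{in}/(Eh)$ at mean pressure — with the
  outer diameter they do not.
* **State geometry.** A vessel quoted by its unstressed diameter $D_o$ and
  wall $h$ is distended to each pressure by the area strain at that
  pressure: $D_i = D_o\sqrt{1+\varepsilon_A(p_i)}$, with thicknesses from
  wall incompressibility $h_i D_i = h D_o$. The same verification as above
  shows the quoted dilations are strains *at pressure* relative to the
  unstressed state, so one uniform rule serves every example and sweep
  (`distend_geometry()`).
* **Weight convention.** $\gamma$ defaults to the kilogram-force
  convention (numerically equal to $\rho = 1050$). The SI convention
  $\rho g$ is selectable but yields flows an order of magnitude below any
  physiological value at the reference inputs, so the calibration selects
  kilogram-force.
* **Pulse rate** for the reference examples, unprinted in the source, is
  60 min$^{-1}$ — the standard clinical resting pulse.
* **Residual constant.** One dimensionless constant $c_0$ multiplies all
  flows. It is anchored so that the resting-state reference
  (110/80 mmHg, $\varphi = 0.0439$, $\beta = 0.375$) yields exactly
  5.23 L/min, the canonical resting cardiac output; this gives
  $c_0 = 0.979$. `flow_calibration()` derives it at run time from the
  package's own uncalibrated evaluation, so code and documentation cannot
  drift apart.

## Why several published figures cannot be matched

With the calibration frozen on the resting state, the remaining published
worked-example figures deviate: the normal state computes to
$\approx 9.88$ L/min (published 7.95), the 160/75-vs-160/95 comparison to
$+29\,\%$ (published $+23\,\%$), the 120/95-vs-120/80 case to $-36.8\,\%$
(published $-18.2\,\%$), and the equal-flow diastolic inversion to
$\approx 106$ mmHg (published 94.3). Only the severe-hypertension lower
bound ($\geq 31\,\%$; computed $+84.8\,\%$) is met.

These are not tuning failures but a property of the published numbers: a
log-linear solve over the published anchors requires
$\bar Q \propto \mathrm{PP}^{0.11}\,\mathrm{MBP}^{-1.46}\,\mathrm{SBP}^{1.42}$,
a dependence that *no* placement of the collapsed fractions in the printed
equations can produce (every consistent reading is, to first order, linear
in pulse pressure with a weak positive mean-pressure correction). The
package therefore reports its computed values and their deviations
(`run_worked_examples()`) rather than adjusting parameters case by case.
For the diastolic inversion specifically, the root is insensitive to the
absolute scale of the compliance-derived $\varphi$ (it moves only between
105 and 112 mmHg over a 20-fold scale range); matching 94.3 mmHg would
require scaling $\varphi$ by $\mathrm{MBP}^{-0.7}$, an exponent with no
basis in the model's own linear relations, so it is not done.

## Compliance and the constraint coefficient

Integrating $\mathrm dA/\mathrm dp = \varphi A D/(Eh)$ along a segment of
length $L$ gives the volumetric compliance $C = L A \varphi D/(Eh)$, hence
`phi_from_compliance()`: $\varphi = C E h/(L A D)$. Attributing a *total*
arterial compliance (1.78 ml/mmHg for the healthy reference cohort) to a
single segment forces $L \gtrsim 0.4$ m for $\varphi < 1$; a half-metre
effective aortic length is used where an absolute value is needed. For
cohort comparisons only the compliance *ratio* matters, so
`solve_diastolic_pressure()` anchors the reference cohort at the one
printed human coefficient ($\varphi = 0.0565$, normal state) and scales
each cohort by $C_i/C_{\mathrm{ref}}$.

## Numerical choices

* **$\beta$–$V$ circularity.** Three modes: `fixed_beta` (worked-example
  default; the source prints $\beta$ directly), `fixed_Re` ($\lambda =
  64/\mathrm{Re}$, $\beta$ from the wall-thinning relation), and
  `self_consistent`. In the last, $\mathrm{Re}$ is formed from $V$ by
  converting flow distance per pulse to m/s through $n/60$; since
  $\beta(V) \propto 1/V$, the fixed point collapses to the closed form
  $V = c - b$ with $c$ the driving term and $b$ velocity-independent. A
  negative $c - b$ means dissipation exceeds the driving term and raises a
  model-regime error (classed condition, CLI exit code 2). The closed form
  is pinned against a fixed-point iteration oracle at $10^{-10}$ relative.
* **Diastolic inversion.** Plain bisection on the flow mismatch over
  $[1, p_s - 1]$ mmHg to $10^{-3}$ mmHg, at most 200 iterations; a missing
  sign change reports the mismatch at both bracket ends. Bisection (rather
  than derivative-based root finding) because each evaluation is cheap and
  the mismatch can be nearly flat in pathological corners.
* **Exponential fits.** $\sigma = a(e^{b\varepsilon}-1)$ by
  Levenberg–Marquardt with deterministic starts: $b_0$ from the log-stress
  slope over the upper third of the strain range, $a_0$ through the last
  point. In the near-linear limit $a$ and $b$ are individually weakly
  identified while their product (the slope) is stable — tested as such.
* **Integration.** Composite trapezoid on tabulated curves with
  interpolated window endpoints; the exact antiderivative for fitted
  exponentials. Agreement is within 0.1 % at 200 panels and $10^{-6}$
  relative at $10^5$ panels.
* **Interpolation** of measured curves is monotone piecewise-linear and
  never extrapolates; out-of-range pressures are errors.
* **Degenerate inputs.** A zero-pulse state ($p_s = p_d$) is a valid
  degenerate input with zero flow; a closed lumen ($D \le 2h$), crossed
  stresses, or an undeformed vessel in the secant-modulus inversion are
  domain errors; $D_o/h < 10$ triggers a thin-wall warning, and
  $\mathrm{Re} > 2100$ a laminar-assumption warning.

## Synthetic data: what it emulates, and what it does not

`sim_pressure_diameter()` generates the saturating dilation of an
expansion test as a bounded monotone sigmoid
$D(p) = D_o + (D_{max}-D_o)/(1+e^{-(p-p_{half})/s})$, with per-segment
parameter sets (`aorta_segment_params()`) whose sizes and axial stretches
(1.2/1.3/1.4 for ascending, proximal and distal descending) mirror the
qualitative anatomy; the parameters are illustrative, not measurements.
`sim_stress_strain()` generates the convex exponential response on a
$[0, 0.4]$ strain grid, the physiological strain range of the wall. Noise
is truncated-normal and kept monotone by rejection (cap 100 resamples, then
a loud error); because the sigmoid's tails are nearly flat, usable noise
levels are bounded by the local pressure-step increments — about 0.02 mm
at the default 40-point grid. `sim_cohort()` draws bounded parameter sets
with a forced systolic–diastolic gap.

Passing tests on these generators shows the estimators recover known
ground truth under idealised, in-model conditions — exact functional
forms, independent truncated noise, no hysteresis, no viscoelastic creep,
no inter-segment coupling. It does not validate the model against real
arterial measurements, which the underlying study did not publish as raw
data.

Test problem sizes were chosen to keep the whole suite within seconds
while leaving estimation error far below the asserted tolerances: 100
seeded replicates for fit recovery and inversion round-trips, 20 draws for
the velocity fixed point, $10^4$ subjects for the cohort moment check,
$10^4$-point grids for the bisection cross-check.

## Known limitations

* Per-pulse averaged: no time-resolved waveforms, no wave reflection, no
  Windkessel parameter fitting, no 3-D fluid–structure simulation.
* Linear-elastic circumferential response only; no Fung/GOH-type
  anisotropic hyperelasticity, no viscoelasticity.
* The calibration constant and weight convention absorb unit ambiguities
  of the published relation; absolute flows inherit that uncertainty,
  while ratios between states (the clinically interesting quantities) are
  independent of it.
* The published worked-example figures are mutually inconsistent under any
  single reading of the flow relation; this package prioritises internal
  consistency and transparent reporting over case-by-case agreement.
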