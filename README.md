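# aortaflow

Arterial strain energy and the blood supply it sustains.

The classical Windkessel picture treats the arterial tree as a passive
elastic buffer with the heart as the only power source. `aortaflow`
implements the alternative view in which the aortic wall, stretched between
diastole and systole, stores strain energy that is converted back into
mechanical work on the blood. The package is aimed at cardiovascular
biomechanics researchers who want to relate clinically measurable
parameters — systolic/diastolic pressure, aortic diameter and wall
thickness, circumferential stiffness, pulse rate — to the stored wall
energy and to an estimate of mean blood supply, and at modellers who need a
tested, scriptable implementation of the underlying closed-form relations.

## The model

For a thin-walled aorta constrained by surrounding tissue (expansion
constraint coefficient φ ∈ (0, 1]), with outer diameters D_i and wall
thicknesses h_i in diastole (i = d) and systole (i = s), wall ratios
α_i = D_i/h_i − 2 and circumferential modulus E:

* **Strain energy density increment** (energy stored per unit wall volume
  over one pulse):

      Δu = (σ_s − σ_d)(ε_s − ε_d)/2  =  φ²(α_s p_s − α_d p_d)² / (8E)

  with constrained Laplace stresses σ_i = φ p_i D_i/(2 h_i).

* **Characteristic velocity** (flow distance per pulse through the cross
  section), from a Hamilton-principle coupling of wall and blood with
  laminar wall-shear dissipation folded into a coupling coefficient
  β = 4Eλ(h_d − h_s)/(D(p_s − p_d)φ), λ = 64/Re:

      V = φ h (α_s p_s − α_d p_d) / (D γ (1 + β))

* **Mean blood flow** through the lumen area A_f at pulse rate n, with the
  distension increment governed by the area strain ε_A = φpD/(Eh) at mean
  pressure p = (2p_d + p_s)/3:

      Q̄ = n (1 + φDp/(Eh)) A_f V

The β–V circularity (λ depends on Re, Re on V) is handled in three modes:
`fixed_beta` (β supplied), `fixed_Re` (Re supplied), and `self_consistent`
(closed form V = c − b, since β(V) ∝ 1/V). Conventions and the one
dimensionless calibration constant are frozen once and documented in
[CALIBRATION.md](CALIBRATION.md); residual deviations from published worked
examples are reported by `run_worked_examples()`, not hidden.

Around the core model the package processes expansion-test
(pressure–diameter) and circumferential stress–strain curves (exponential
fit σ = a(e^{bε} − 1), linear-window fits, strain-energy integration),
generates seeded synthetic curves and cohorts, inverts the flow relation
for diastolic pressure under an equal-flow matching rule, and runs
sensitivity sweeps.

## Worked example

The normal-state ascending aorta (120/80 mmHg, E = 3.5×10⁵ Pa,
D = 32.0 mm, h = 1.46 mm, φ = 0.0565, β = 0.290, 60 pulses/min):

```r
library(aortaflow)
p <- example_parameters("normal")
fl <- aortic_flow(p$geometry, p$material, p$pressure, p$blood,
                  n = p$n, beta = p$beta)
fl
#> Aortic mean flow: 9.882 L/min  (n = 60 /min, mode = fixed_beta)
#>   V = 0.2434 m/pulse, beta = 0.29, Re = 2124, lambda = 0.03014
#>   Q0 = 158.4 ml/pulse, dQ = 6.336 ml/pulse (area strain at MBP 0.04)

sedi_pressure_form(p$material, fl$alpha_s, fl$alpha_d, p$pressure)
#> [1] 15.40467
```

The mean flow is 9.88 L/min: the base per-pulse flow `Q0` is the lumen area
times the characteristic velocity, and the 4 % distension of the lumen at
mean pressure adds `dQ`. The second call gives the strain energy density
increment stored by the wall over one pulse, 15.4 J/m³. The full
worked-example table (resting and normal flows, the diastolic-pressure
inversion, and the three relative-flow comparisons, each next to its
published reference value and the relative deviation) comes from:

```r
run_worked_examples()
```

A thin command-line interface wraps the same functions
(`inst/cli/aortaflow.R`; subcommands `flow`, `sedi`, `fit-curves`,
`invert-dbp`, `sweep`, `examples`, `synth`).

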