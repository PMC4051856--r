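# neuritaxis

Mechanistic modelling and quantification of neurite outgrowth under
chemogradients in microfluidic hydrogel chambers.

During development (and after injury), growing neurites are steered by
diffusible cues sensed by the growth cone at their tip. In a standard
microfluidic assay, cortical neurons are embedded in a 3D scaffold
(collagen I at 1 or 2 mg/mL, or matrigel) spanning a gel region of length
*l* = 5 mm; a cue (IGF-1 or BDNF) held at concentration *c₀* in the channel
at *x* = 0 diffuses across the gel and biases outgrowth and turning toward
the source over a 48 h culture. This package implements the quantitative
machinery for that system, for modellers and experimentalists who want to
fit or predict per-condition outgrowth:

* **Cue field.** The diffusion problem *∂c/∂t = D_c ∂²c/∂x²* with
  *c(0,t) = c₀*, zero flux at *x = l* and *c(x,0) = 0* has the exact series
  solution

  *c(x,t) = c₀ [1 − Σₙ 4/((2n−1)π) · sin((2n−1)πx/2l) ·
  exp(−(2n−1)²π²D_c t / 4l²)]*,

  with helpers for the establishment time *τ = l²/(4π²D_c)*, local gradient
  steepness across a 10 µm growth-cone width, Stokes–Einstein mass scaling
  of *D_c*, and least-squares recovery of *D_c* from time-stamped intensity
  profiles.

* **Growth-cone dynamics.** A Keller–Segel density equation
  *∂g/∂t = D_g ∂²g/∂x² − ∂/∂x[χ(c) g ∂c/∂x]* with receptor-saturating
  sensitivity *χ(c) = k/(1 + mc)²* (so *χ(0) = k*, *χ(1/m) = k/4*), solved
  by a conservative finite-volume scheme. The readout is the displacement
  *d = |x₁ − x₀|* of the density peak — the model counterpart of mean
  treated-minus-control outgrowth.

* **Staged estimation.** *k* is fitted from the displacement observed at
  *c₀* = 0.1 µg/mL (where *χ ≈ k*), then *m* from *c₀* = 1 µg/mL, alternating
  to a fixed point so the estimator exactly inverts the forward model.

* **Morphometry.** Trace-table outgrowth summaries (10 µm histogram bins,
  fold changes with propagated sd), wind-rose quadrant turning analysis
  (toward quadrant Q1: 135°–225°, away quadrant Q3: <45° or >315°, source at
  180°), Welch/Mann–Whitney group comparisons, CSV and SWC input.

* **Synthetic experiments.** A seeded generator calibrated to the published
  per-condition length and turning distributions (21 scaffold × cue × dose
  conditions), so the whole pipeline is testable end-to-end without
  microscopy data.

## Worked example

```r
library(neuritaxis)

## IGF-1 (17 kDa) diffusing through 2 mg/mL collagen
dom <- gel_domain(length_um = 5000, Dc_m2_s = 8e-12)
seconds_to_hours(diffusion_time(dom))
#> [1] 22            # hours for the gradient to establish across 5 mm

## forward simulation with the fitted collagen parameter set
sim <- simulate_growth_cones(dom, chemotaxis_law(k = 9, m = 15), c0 = 1)
sim
#> <ks_simulation> c0 = 1 ug/mL, k = 9, m = 15, t = 48 h
#>   d = 29.049 um (x0 = 2500.0 -> x1 = 2471.0 um); mass error 2.22e-16; 121 steps (dt = 1428 s)

## staged round trip: displacements at the two calibration doses -> (k, m)
cfg <- fit_config(dom)
d_low <- simulate_growth_cones(dom, chemotaxis_law(9, 15), 0.1, gc = cfg$gc)$d_final
fit_staged(d_low, sim$d_final, config = cfg)
#> <ks_fit> k = 9 um^2 mL/(ug s), m = 15 mL/ug
#>   4 iteration(s), converged; residuals (low, high) = (-5.15e-06, 0.00266) um

## synthetic morphometry for IGF-1 at 1 ug/mL in 2 mg/mL collagen
ctrl <- generate_lengths(get_calibration("collagen_2mg", "none"), 1e4, seed = 1)
igf  <- generate_lengths(get_calibration("collagen_2mg", "IGF1", 1), 1e4, seed = 2)
summarize_outgrowth(igf, control = ctrl)
#> <outgrowth_summary> n = 10000, length 44.41 +/- 56.24 um
#>   fold vs control: 2.96 +/- 3.79
turning_summary(generate_angles(get_calibration("collagen_2mg", "IGF1", 1), 1e4, seed = 3))
#> <turning_summary> n = 10000: Q1 (toward) 48.8%, Q3 (away) 7.8%, other 43.4%
```

The simulated 48 h displacement of ~29 µm at 1 µg/mL sits on top of the
~15 µm control outgrowth, i.e. the 3-fold increase reported for that
condition; the staged fit recovers the generating parameters to well under
a percent; and the calibrated generator reproduces the per-condition mean
(~45 µm), its long-tailed distribution (large sd), and the ~49%
toward-gradient quadrant mass.

The angle convention (wind-rose):

```
            90°
             |
   Q1  180° -+- 0°/360°  Q3
 (toward     |          (away
  source)   270°         from source)
```

Q1 = 135°–225° (red, toward the source channel on the left), Q3 = <45° or
>315° (away); boundary angles count as neither.

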