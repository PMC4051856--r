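---
title: "Modelling neurite outgrowth under chemogradients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neurite outgrowth under chemogradients: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the numerical choices, what the synthetic
generator does and does not emulate, and the design decisions taken where
the problem left genuine freedom.

## The experimental system

Embryonic cortical neurons are embedded in a 3D hydrogel (collagen I at 1
or 2 mg/mL, or matrigel) inside a microfluidic chamber. A guidance cue
(IGF-1 or BDNF) is supplied at constant concentration `c0` in the channel
on one side of the gel and diffuses across it, forming a quasi-1D gradient
over the gel length `l = 5 mm`. After 48 h of culture, neurite outgrowth
(soma-to-growth-cone path length) and orientation are quantified per
neuron. The package works at the level of this readout: concentration
fields, growth-cone density dynamics, displacement, and trace tables.

## Cue field

With the source boundary held at `c0` at `x = 0`, zero flux at `x = l`,
and a cue-free initial gel, the diffusion problem
`dc/dt = Dc d2c/dx2` has the eigenfunction-series solution implemented in
`exact_concentration()`:

c(x,t) = c0 [ 1 - sum_{n>=1} 4/((2n-1)pi) sin((2n-1)pi x / (2l))
          exp(-(2n-1)^2 pi^2 Dc t / (4 l^2)) ].

Cue consumption by cells and matrix degradation are assumed to cancel (no
net reaction term). Truncation is adaptive: terms are added until the
bound of the next term falls below `1e-8 * c0`, with a 50-term floor
because convergence is slowest at small `t`; a user-supplied `n_terms`
that cannot reach the tolerance triggers a warning carrying the achieved
bound. The series is cross-checked in the test suite against an
independent finite-difference integration (deSolve, 2001 nodes) to within
0.5% relative L-infinity at 1, 21 and 48 h.

Two diagnostics follow directly: the establishment time
`tau = l^2/(4 pi^2 Dc)` (`diffusion_time()`; about 22 h for
`Dc = 8e-12 m^2/s` over 5 mm) and the local gradient steepness across a
10 um growth-cone width, `100 (c(x) - c(x+10))/c(x)` (`steepness()`). The
average steepness over the culture window is not reproduced as a single
scalar because the averaging region is not uniquely defined; steepness is
exposed pointwise instead.

`scale_dc_by_mass()` carries the Stokes-Einstein argument: the
hydrodynamic radius of a globular molecule grows as the cube root of its
mass, so `D ~ M^(-1/3)`. The exponent 1/3 is a package choice; it
reproduces the quoted ~15% slowdown from a 17 kDa to a 27 kDa cue
(cube-root scaling gives 14.3%, rounded up in the usual reporting).
`estimate_dc_from_profiles()` inverts time-stamped fluorescence profiles
for `Dc` with a single free gain shared across time points (fluorescence
units are arbitrary); for each candidate `Dc` the gain is a closed-form
linear least-squares solution, leaving a 1D search over `log10 Dc`.

## Growth-cone density model

The growth-cone population is a density `g(x, t)` obeying a Keller-Segel
equation,

dg/dt = Dg d2g/dx2 - d/dx[ chi(c) g dc/dx ],

with no-flux walls and a Gaussian initial condition centred mid-domain
(`sigma = 25` um by default, FWHM ~ 59 um, far smaller than `l`; only the
"much smaller than the domain" property matters and the width is
configurable). The chemotactic sensitivity saturates with receptor
occupancy:

chi(c) = k / (1 + m c)^2,

so `chi(0) = k` and `chi(1/m) = k/4`; `m` acts as an inverse dissociation
constant. The flux convention `J_g = -Dg g_x + chi(c) g c_x` makes the
drift point up-gradient (toward the source at `x = 0`), which is the
stated physical behaviour of the attractants modelled. Because the
equation is linear in `g`, the density is normalised to unit mass
internally and the nominal peak value `g0` is metadata; the displacement
readout is invariant to it.

The readout is `d(t) = |x*(t) - x0|`, the travel of the density peak,
which corresponds to the mean treated-minus-control outgrowth in a
device. In all standard configurations `d` is tens of micrometres, much
smaller than `l`; the solver warns if `d` exceeds `0.1 l`.

### Numerics

Method of lines on the domain grid (default `dx = 5` um, 1001 nodes),
finite-volume form with half cells at the walls so the trapezoid-rule
mass is conserved exactly (observed relative drift < 1e-12 over 48 h).
Both operators advance explicitly: diffusion under the stability bound
`Dg dt/dx^2 <= 0.4` (cheap, since `Dg` is small), and advection by
first-order conservative upwind fluxes, which keeps `g` non-negative
under the advective CFL bound. The drift velocity `chi(c) c_x` is
evaluated analytically from the series at cell faces and at the temporal
midpoint of each step; the trigonometric factors are cached once per run
so each step costs two matrix-vector products.

The CFL bound deserves a note: at early times the velocity is enormous in
the thin boundary layer next to the source, where the density is
identically zero and always stays zero under an explicit update (the
support can grow only one cell per sub-step). The step size is therefore
set by `dt <= 0.8 dx / max|v|` taken over the *occupied* region of `g`
(plus a wide margin), with per-step sub-cycling of the advection wherever
the support's local velocities demand it; a global bound would shrink
`dt` by orders of magnitude for no physical reason. A resolution cap
`t_end/96` applies regardless. The peak is located to sub-grid accuracy
by fitting a parabola through the three nodes around the grid argmax —
exact for a quadratic peak, and accurate to a small fraction of `dx` for
the smooth profiles arising here; exact ties break toward smaller `x`
(the drift direction) with a warning. Runs whose peak reaches the source
wall (displacement saturated at `x0`, far beyond any observed outgrowth)
stop early with a warning.

First-order upwinding is deliberate: it is positivity-preserving at the
large `k` values (up to 350) that the matrigel parameter set requires,
where higher-order schemes need limiters. The price is first-order
spatial convergence of `d`; the test suite includes a refinement study
(`dx` = 20, 10, 5 um against a 2.5 um reference) confirming the expected
error decay, and an independent fully explicit fine-grid solve agrees
with the default configuration to better than 2%. Two analytic limits are
also enforced in tests: no displacement without chemotaxis (`k = 0` or
`c0 = 0`), and drift speed `k |s|` on a frozen linear profile of slope
`s` with `m = 0`.

## Staged parameter estimation

The two chemotaxis parameters are fitted from two displacement
observations: `k` from the displacement at `c0 = 0.1` ug/mL, where
`m c` is small and `chi ~ k`, then `m` from the displacement at
`c0 = 1` ug/mL, where saturation is informative. Displacement is
monotone increasing in `k` and decreasing in `m`, so each stage is a
bracketed Brent root-find on the forward model (`fit_k()`, `fit_m()`);
brackets grow geometrically from an initial guess and report the
boundary prediction when an observation is unreachable. `fit_staged()`
alternates the two stages to a fixed point (both residuals below
0.02 um by default). When `m c0` is large at both calibration
concentrations the two stages are strongly coupled and the alternation
converges only linearly; an Aitken delta-squared step taken every third
iterate extrapolates the geometric tail and cuts the iteration count by
roughly 4x without changing the fixed point. This makes the procedure an
exact inverse of the forward model: displacement pairs simulated from a known `(k, m)` are
recovered, in practice to a few tenths of a percent — the package's
round-trip verification for both published sets, `(k, m) = (9, 15)`
with `Dc = 8` um^2/s and `(350, 1100)` with `Dc = 4` um^2/s. Whether
the original two-stage fit was iterated is not documented; iterating is
the choice here because it makes the estimator self-consistent, and for
weakly coupled stages it converges in a handful of alternations. With
both observed displacements zero, `k = 0` and `m` is flagged
non-identifiable. Observation noise is taken at face value (the inputs
are already device-averaged means); uncertainty propagation is left to
resampling at the generator level.

`predict_dose_response()` and `parameter_sweep()` expose the forward
model's sensitivity structure: displacement rises with `c0` and then
saturates (no indefinite increase), rises near-linearly with `k`, falls
with `m` most strongly at high `c0`, is larger in shorter devices, and is
insensitive to `Dg` across its plausible range (1e-3 to 1e-1 um^2/s,
under 10% effect). One subtlety of the saturating law: the
shorter-device advantage is clean at low doses but not uniform in `c0`,
because a shorter gel also raises the absolute concentration everywhere
and the `(1 + m c)^2` suppression can outweigh the steeper gradient near
`c0 = 1` ug/mL; the package's length-effect check is therefore made in
the low-dose regime.

## Morphometry

Trace tables carry one neuron per row: path length and planar
orientation. The angle convention places the source channel on the left
at 180 degrees (the figures imply, but never state, the zero direction;
this is the package's documented choice). The toward-gradient quadrant Q1
is `135 < angle < 225` and the away quadrant Q3 is `angle < 45` or
`angle > 315`, with boundary angles excluded (strict inequalities as
printed); each quadrant covers a quarter of the circle, so uniform
orientations give 25% in each. Quadrant fractions are computed over
neurite-bearing traces. Length histograms use the standard bins
`[1, 10], (10, 20], ...`; sub-micron neurites (conditions reported as
"effectively zero outgrowth") are excluded from histograms but not from
means. Fold changes versus control propagate the two sds to first order.
`compare_groups()` applies Welch's t test or the Mann-Whitney test, with
an automatic Shapiro-Wilk screen (alpha = 0.05) choosing between them
and a rank-sum fallback for zero-variance degeneracies. SWC morphology
input is supported for single neurons; multi-branch trees use the
longest soma-to-tip path, since the traced structures are single
extensions.

## Synthetic experiment generator

The generator exists so that every analysis path is testable end-to-end
without microscopy data. It emulates, per condition (scaffold x cue x
dose): the mean and sd of neurite length, the long-tail length bins
observed at the highest attractant dose, and the toward-gradient quadrant
mass. It does **not** emulate: spatial position of somata, neurite
tortuosity, cue-receptor expression levels, cell viability, correlations
between length and angle, or time courses — so passing generator-based
tests validates the analysis arithmetic and the model round trips, not
biological variability beyond the calibrated moments.

Lengths are drawn from a gamma body moment-matched to the calibrated
`(mean, sd)` — gamma guarantees non-negativity for the small-mean, large-CV
controls — plus uniform tails over `(31, 100]` and `(101, 290]` um with
the calibrated tail fractions. The body alone is then rescaled so the
mixture's population mean equals the calibrated mean exactly; rescaling
the whole mixture instead would shift the tail ranges off the calibrated
bins. Angles are uniform for unbiased conditions and von Mises centred
at 180 degrees otherwise, with the concentration `kappa` solved by
root-finding so the expected Q1 mass equals the calibrated target (the
Q3 mass then follows from the shape of the distribution and is reported,
not enforced; targets below 0.25 would require a repulsive, away-biased
component and are rejected). The von Mises sampler is the Best-Fisher
rejection algorithm; the quadrant mass uses the exponentially scaled
Bessel-normalised integral, stable to `kappa = 500`.

`builtin_calibrations()` ships the full 21-condition grid. Every numeric
field is tagged in `provenance`: `"printed"` where the value is a
published per-condition summary, `"interpolated"` where only relative
statements constrain it. Interpolation rules, chosen once: sds of treated
groups preserve the control coefficient of variation; means stated only
as fold relations use those folds; turning targets described only as
"significantly biased" are set to 0.45 (between the unbiased 0.25-0.33
controls and the one quantified biased value, 0.49); unquantified
turning is uniform (0.25). `generate_experiment()` adds replicate-device
structure (6 devices per condition, 5% between-device CV as a unit-mean
lognormal factor on length) so that group comparisons see realistic
replication, and derives per-component child seeds from one master seed
by a documented counter scheme (`child_seed()`), making outputs
bit-for-bit reproducible.

The `model_driven` mode replaces the calibrated mean with
`control mean + d`, `d` simulated under the condition's published
`(Dc, k, m)` set — the bridge that lets generated experiments be pushed
through `fit_staged()` and recover the generating parameters (the
generator-to-estimation closure test, n = 500 neurons per condition).

## Problem sizes and runtimes

Default study configuration: `l = 5 mm`, `dx = 5` um (1001 nodes), 48 h
horizon, at most a few hundred time steps per run; one forward
simulation takes on the order of a second, and a full staged fit (a few
dozen forward runs) on the order of a minute. Unit tests use coarser
251-node grids where only self-consistency is being exercised, since
fits invert whatever configuration they are given; accuracy-sensitive
checks (oracle comparisons, refinement, published-set round trips) run
at the full configuration. Synthetic-data checks use n = 1e4 lengths
and n = 1e5 angles, sized so Monte-Carlo error is well inside the
asserted tolerances.

## Known limitations

* The model is strictly 1D; lateral and vertical structure of the
  chamber is outside scope (the gradient is effectively 1D over the gel).
* First-order upwinding underestimates sharp advective features; for the
  smooth, slowly drifting Gaussians here the effect on `d` is at the
  percent level (quantified by the refinement tests).
* Only two published `(Dc, k, m)` sets exist; model-driven generation is
  limited to those conditions.
* The two-observation staged fit is exactly determined and provides no
  goodness-of-fit measure; `fit_wls()` offers a multi-observation
  weighted least-squares extension (initialised from a staged fit), but
  the two-point scheme remains the canonical procedure.
* Angle and length are generated independently; any real covariation
  between outgrowth and turning is not represented.
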