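# lamellar

SAXS/WAXS analysis of multilamellar lipid bilayer phases in R.

Multilamellar vesicles diffract like one-dimensional powders: a stack with
repeat distance *d* produces Bragg reflections at *q* = 2πh/*d*
(h = 1, 2, 3, …), and the phase state of the membrane is written into that
pattern.  A rigid gel (L<sub>β′</sub>) stack gives three or more sharp
orders within a typical detector window plus a wide-angle chain-packing
peak near 1.5–1.6 Å⁻¹; a fluid (L<sub>α</sub>) stack gives only two broad
orders and no chain peak; gel/fluid coexistence shows two interleaved
series with distinct *d*.  This package implements the full analysis
chain that turns raw scattering into phase diagrams and bilayer
structure, for people who study lipid phase behaviour with synchrotron
or lab-source SAXS:

* **reduction** — azimuthal integration of 2D powder images (mean counts
  per uniform half-open *q* bin) and *q*-axis calibration against silver
  behenate (d<sub>001</sub> = 58.83 Å by default, overridable);
* **peakfit** — asymmetric-least-squares baseline estimation, robust peak
  detection, and (joint) nonlinear least-squares peak fitting with
  analytic integrated areas;
* **lamellar** — greedy indexing of fitted peaks into lamellar series
  (fundamental refined by weighted least squares through the origin),
  *d* = 2π/q₁, gel/fluid classification, coexistence detection, and
  phase-diagram assembly with per-composition transition temperatures;
* **edp** — relative electron-density profiles by truncated cosine
  synthesis, ρ(z) = Σ<sub>h</sub> α<sub>h</sub>|F<sub>h</sub>|cos(2πhz/d)
  with |F<sub>h</sub>| = √(I<sub>h</sub>h²) (powder Lorentz correction)
  and the centrosymmetric PC sign convention (−, −, +, …); the
  head-to-head distance d<sub>pp</sub> from the headgroup maxima, a
  +10 % truncation correction when only three orders are available, and
  the water layer d<sub>w</sub> = d − d<sub>pp</sub>;
* **geometry** — gel-phase chain tilt by reference-calibrated
  extrapolation, θ = arccos(d<sub>pp</sub>/L<sub>eff</sub>) with
  L<sub>eff</sub> = (d<sub>ref</sub> − d<sub>w,ref</sub>)/cos θ<sub>ref</sub>,
  and WAXS packing spacings d = 2π/q;
* **forward model** — a fully seeded simulator (Gaussian bilayer
  electron-density phantoms, analytic form factors, lamellar structure
  factors, Poisson counting noise, optional 16-bit TIFF powder images,
  rule-driven labelled phase grids) so every stage is testable against
  known ground truth without beamline data.

## Worked example

Simulate a coexistence sample (0.1 mol% guest lipid at 25 °C), classify
it, reconstruct the gel-fraction electron-density profile, and estimate
the chain tilt:

```r
library(lamellar)

inst <- instrument_config("SAXS", seed = 42)
profile <- synthesize_profile(
  list(list(edp = gel_bilayer_model(4.99),   stack = gel_stack(4.99, phi = 0.5)),
       list(edp = fluid_bilayer_model(7.00), stack = fluid_stack(7.00, phi = 0.5))),
  instrument = inst,
  meta = sample_meta(dha_molpercent = 0.1, temperature = 25))

point <- assess_point(profile)
point
#> <phase_point> state: coexistence
#> sample: <unlabelled>  (0.1 mol%, 25.0 degC)
#> <lamellar_series> d = 4.990 nm (q1 = 0.12592 A^-1), 3 orders, gel
#> <lamellar_series> d = 6.995 nm (q1 = 0.08982 A^-1), 2 orders, fluid

gel_series <- Filter(function(s) s$phase == "gel", point$series)[[1]]
edp <- edp_from_series(gel_series)
edp
#> <edp_profile> d = 4.990 nm, 3 orders, signs --+
#>   d_pp = 3.487 nm (raw 3.170 x factor 1.10), d_w = 1.503 nm

tilt_from_dpp(edp$d_pp)
#> <tilt_estimate> theta = 50.00 deg (d_pp = 3.487 nm, L_eff = 5.425 nm)
```

Reading the output: the two recovered series sit at the repeat distances
the simulator encoded (4.99 nm gel, 7.00 nm fluid), so the sample is in
gel/fluid coexistence.  The three gel orders give a raw head-to-head
distance of 3.17 nm; because a three-order Fourier synthesis
systematically underestimates d<sub>pp</sub>, the tabulated +10 %
correction lifts it to 3.49 nm, leaving a 1.50 nm water layer.  Against
the fully hydrated DPPC reference geometry (6.4 nm repeat, 1.83 nm water
layer, 32.6° tilt) that thickness implies a ~50° chain tilt.

A command-line front end over the same functions ships in
`inst/cli/lamellar.R` with subcommands `simulate`, `reduce`, `analyze`,
`edp` and `tilt`, a YAML run configuration, and exit codes 0/1/2
(success / partial / fatal).

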