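---
title: "Surface pressure-area isotherms from osmotic wall forces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface pressure-area isotherms from osmotic wall forces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The surface pressure-area (Pi-A) isotherm is the equation of state of a
surfactant monolayer at the air-water interface: the reduction Pi of the
clean-interface surface tension as a function of the area A available
per molecule.  Molecular-dynamics studies traditionally compute it by
the pressure-tensor (Kirkwood-Irving) route, which becomes unreliable at
low molecular areas.  An alternative confines the surfactants between
two semipermeable virtual walls -- planar flat-bottom restraints that
solvent crosses freely -- and reads the film pressure off the mean
restoring force the walls exert, like the barriers of a Langmuir trough.
`isopress` implements both routes, together with the semi-empirical
correction that rescales the wall-force pressure by the relative depth
of the interfacial zone, and a self-contained toy simulator that
generates all of its test data.

## The two routes

**Tensor route.**  For a slab with two interfaces normal to z,

    gamma = (L_z / 2) < P_zz - (P_xx + P_yy) / 2 >,

the Kirkwood-Irving surface tension; the 1/2 shares the integrated
anisotropy between the two interfaces.  The monolayer pressure is the
difference between a bare-interface run and a monolayer run,
Pi = gamma_w - gamma_m.  Two simulations are needed per isotherm point,
and the difference of two noisy tensions carries their combined error.

**Osmotic route.**  With walls at x = +-x_wall restraining only the
surfactants, every saved frame contributes the total restoring-force
magnitude on beads beyond a wall; the time average is the osmotic force
<F_wall>.  Both force laws act on the penetration depth d = |x| - x_wall:
quadratic, F = k d^2 (k in kcal mol^-1 A^-3, the default, matching the
plane-indenter convention) or linear, F = k d (the flat-bottom harmonic
restraint).  The estimator does not care which law generated the data.
The 2D film pressure is

    Pi_ideal = <F_wall> / (4 L_y),

the divisor 4 counting the four intersections of the two walls with the
two interfaces.  A per-species decomposition through the 3D osmotic
pressures Pi_os,a = <F_a> / (L_y tau_za) is also provided; the depths
tau_za cancel algebraically, and the implementation verifies at run time
that both routes coincide.

**The correction.**  Treating the surface zone as one molecule thick
overestimates the pressure once the film packs.  The corrected value is

    Pi_real = Pi_ideal * xi,      xi = L_ref / L_z;int(A),

where L_z;int is the 90-10 interfacial thickness -- the distance over
which the solvent density falls from 90% to 10% of its bulk value along
the interface normal -- and L_ref its infinite-dilution asymptote,
measured on a surfactant-free slab.  xi is close to 1 for a widely
spread film and drops below 1 as the inhomogeneous surface zone (solvent
plus head groups plus chain segments) deepens under compression.

## Numerical choices

* **Bulk reference density.**  The "maximum" solvent density in the
  90-10 rule is operationalized as the mean over the central 50% of the
  slab (the region where the density exceeds half its maximum), not the
  highest bin: a noisy maximum would bias the 90% crossing downward.
* **Crossing localization.**  Linear interpolation between adjacent
  bins, giving sub-bin resolution without assuming a profile shape.
  When a non-monotonic tail (vapour blobs) produces several crossings,
  the outermost one is used and a warning is emitted.
* **Two interfaces.**  The slab has a monolayer on both z-surfaces;
  L_z;int is measured per interface and the mean enters xi.  Profiles
  that plateau into a box edge (single-interface test fixtures)
  contribute only their decaying side.
* **Slab recentring.**  A Langevin thermostat does not conserve
  momentum, so the slab's centre of mass random-walks along z; averaging
  raw histograms over a long run smears both interfaces (we measured the
  apparent 90-10 width of a bare slab growing from 3.2 to 5.3 sigma over
  a 750 tau run).  `density_profile(center = TRUE)` shifts every frame
  by the circular-mean z of the solvent before binning, which removes
  the drift and leaves the interfacial structure untouched.  All
  thickness analyses use it.
* **Matched reference box.**  Capillary waves broaden the 90-10 width
  logarithmically with interfacial area, so comparing a monolayer
  thickness against a reference slab of a different cross-section
  biases xi.  The infinite-dilution reference is therefore always taken
  from a clean slab in the same box as the monolayer runs.
* **Bins.**  Default bin width 0.1 sigma (reduced) / 0.5 A (real):
  fine enough for 1% accuracy on analytic test profiles while keeping
  single-bin counting noise manageable at typical frame counts.
* **Uncertainties.**  Block averaging with 5 contiguous equal blocks by
  default (remainder frames dropped); the tension and pressure series
  are strongly autocorrelated and block means de-correlate them.
* **Burn-in and drift flags.**  Each per-area segment of a sweep
  discards its first 20% before analysis; a point whose first-half and
  second-half mean wall forces differ by more than 3x their combined
  block errors is flagged rather than silently kept.
* **Degenerate inputs.**  Parsers fail on malformed or truncated frames
  naming the line; empty selections, non-positive lengths and
  inconsistent particle counts are errors, not warnings.

## The toy simulator

The `toysim` module is a minimal Langevin-dynamics model whose only
purpose is to generate controlled test data and provide an independent
cross-check between the two pressure routes.  It is **not** a
coarse-grained lipid force field; it is a generic truncated-shifted
Lennard-Jones fluid.

* Geometry: a solvent slab centred at z = 0, periodic in x and y, with
  a vacuum region along z so the two film leaflets never interact
  through the boundary.  Surfactants (one head bead, two tail beads,
  harmonic bonds) sit on both slab surfaces with tails pointing into
  the vacuum.  Walls confine only surfactants; the solvent extends a
  clean margin (4.5 sigma, the analogue of 18 A at sigma = 4 A) beyond
  each wall so it exchanges freely across the barriers.
* Interactions (reduced units, all force-shifted at 2.5 sigma):
  eps_WW = 1, eps_WH = 1.3, eps_HH = 1, eps_HT = 0.8, eps_TT = 0.6 and
  eps_WT = 0.45.  The tails are mildly hydrophobic rather than hard-core
  repulsive: a compressed, thickening tail mat imbibes some solvent into
  its interstices.  That partial wetting is what reproduces, in this toy
  setting, the hallmark of real monolayers at low molecular area -- an
  inhomogeneous surface zone of solvent, head groups and chain segments
  that deepens as the film packs.  With hard-core (WCA) tail-solvent
  repulsion the film instead damps capillary waves and the apparent
  interfacial zone *thins* under compression; with much stronger
  tail-solvent attraction the film over-soaks and the thickness becomes
  erratic.  eps_WT = 0.45 sits in the regime where the thickening is
  gradual and monotone, and it was fixed as the model's study condition.
* Thermodynamic state: T* = 0.75 (between the triple and critical
  temperatures of the truncated LJ fluid, so the slab coexists with a
  dilute vapour), slab density 0.8 sigma^-3, friction 1/tau, timestep
  0.005 tau.
* Integrator: BAOAB Langevin splitting; with friction zero it reduces
  to velocity Verlet (used by the momentum-conservation test).  The RNG
  is a self-contained xoshiro256++ seeded per run, so every trajectory,
  wall-force log and pressure log is bitwise reproducible.
* Pressure tensor: kinetic term plus pair, bond and wall virials over
  the full box volume, sampled at the logging stride.  Force-shifted
  cutoffs make the logged tensor self-consistent with the dynamics, so
  no tail corrections are applied.
* Freshly built configurations pass through 200 displacement-capped
  steepest-descent iterations before dynamics, which defuses overlaps
  in deeply compressed packings; runs chained from a previous state
  skip this.
* Walls default to k = 50 eps/sigma^3 with the quadratic law.  The
  analysis is insensitive to k (checked against 2k in the test suite),
  mirroring the insensitivity reported for the real-units default
  k = 20 kcal mol^-1 A^-3.

### What the generator does and does not emulate

It reproduces the structural features the analysis relies on: a liquid
slab with one monolayer leaflet per interface, surfactants confined
between walls with a clean margin, solvent crossing the walls freely,
a 90-10 interfacial zone that deepens monotonically on compression, and
osmotic wall forces that grow as the area shrinks.  It does **not**
emulate real lipid chemistry: no electrostatics, no chain torsions, no
liquid-expanded/liquid-condensed coexistence plateau, and its absolute
tensions and pressures are in reduced units with no mapping to any
specific lipid.  Passing tests therefore demonstrate the correctness
and internal consistency of the estimators -- not that any particular
lipid isotherm is reproduced, which would require an external
coarse-grained force field and much longer simulations.

### Deep compression

Beyond roughly A = 2 sigma^2 per molecule the toy film buckles and
expels molecules from the surface layer -- the analogue of monolayer
collapse -- and the water surface under the collapsed crust sharpens
again.  Sweeps in the tests therefore stay at A >= 2.5 sigma^2, the
regime the method targets (real isotherms are likewise reported above
the equilibrium collapse area).

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen so the full suite runs on a single CPU in
well under half an hour while leaving the statistical checks
well-resolved:

* test-suite cross-method runs: the default 20 x 7.5 x 28 sigma box
  (~870 particles): a clean slab (150k steps) for gamma_w and the xi
  reference; a dilute walled monolayer at A = 20 sigma^2 (30k
  equilibration + 150k production) for the osmotic route, repeated
  with the doubled wall constant for the k-insensitivity check;
* tensor-route monolayer: fully covered periodic film at the same
  molecular area (16 x 7.5 x 28 box, no walls, 200k steps), matching
  the classical two-system protocol in which the pressure-tensor
  systems carry no walls;
* sweeps: the same default box with 4 surfactants per leaflet over
  A = 20, 10, 5, 2.5 sigma^2 (equivalently x_wall = 16/3 down to 2/3).
  Compression: 30k equilibration plus 120k steps per point with the
  first third discarded -- segments long enough that the burn-in covers
  the slow wetting of the compressed tail mat, the system's slowest
  mode; with much shorter segments the early points still carry their
  construction history.  Expansion: 80k steps per point, retracing the
  film from the compression's final state (a hysteresis loop, the way
  a trough expansion follows a compression; a fresh build at the most
  compressed area would start from an arbitrarily packed construction
  instead of a relaxed film);
* the acceptance script's headline runs use a larger 30 x 7.5 x 28 box
  (~1650 particles, 150k production) for the clean slab and the dilute
  monolayer;
* simulator sanity runs (equipartition, ideal gas): 400-500 particles,
  50k steps.

The cross-method comparison is made at the dilute end, where the
correction is small (xi near 1) and the two routes are expected to
coincide within their combined two-sigma block errors; under
compression the osmotic route remains well-behaved while the tensor
difference becomes noise-dominated -- which is precisely the situation
the osmotic method exists to address.

## Design decisions that were genuinely open

* **Force law of the wall.**  The printed force-constant units imply a
  force quadratic in the penetration depth, while the flat-bottom
  harmonic restraint of the underlying osmotic-pressure formalism is
  linear.  Both are implemented; quadratic is the default, and the
  estimator is agnostic.
* **Per-interface vs averaged xi.**  xi is formed from the mean of the
  two per-interface thicknesses (they differ at second order); the
  per-interface values are reported for inspection.
* **Reference from a clean slab, not extrapolation.**  The
  infinite-dilution thickness comes from a separate surfactant-free
  run under identical conditions rather than extrapolating a dilution
  series; it is cheaper, unambiguous, and matches the two-system
  protocol of the tension route.
* **Plateau detector.**  Coexistence plateaus are flagged from
  finite-difference slopes of adjacent points (the centred estimate at
  segment midpoints), requiring at least two consecutive flat segments.
  It is a convenience diagnostic with a configurable threshold, not an
  inference procedure.
* **Analysis resampling.**  Wall forces are logged at every sampling
  stride and all frames are weighted equally; coarser resampling for
  independence is available through the stride but block averaging
  already absorbs the autocorrelation.
* **Replicates.**  Repeat sweeps over the same area grid (different
  seeds) are merged per point by inverse-variance weighting of the
  pressures (`combine_isotherms()`); the combined xi is re-derived
  from the combined pressures so each stored point remains internally
  consistent.

## Known limitations

* The toy model's xi-correction regime was established for its specific
  parameter set; other parameterizations (e.g. strictly hydrophobic
  tails) show qualitatively different interfacial-thickness behaviour.
* Thickness estimates carry slow capillary-mode noise of a few percent
  at the run lengths used here; adjacent sweep points closer than that
  in thickness are not resolved.
* The tensor route over a partially covered walled box measures an
  x-averaged tension (covered strip plus clean margins); the package
  therefore uses a separate fully covered run for route comparisons,
  and the per-point `pi_tensor` column of a walled sweep should be read
  as a diagnostic only.
* Real-unit output is a fixed mapping (sigma = 4 A, eps = 0.3 kcal/mol,
  tau = 1 ps) provided to exercise unit conversions, not a calibration
  to any substance.

## A minimal session

```{r}
library(isopress)

# clean slab: reference thickness and gamma_w
clean <- generate_fixture("clean-slab", seed = 1, n_steps = 60000)
lz_ref <- reference_thickness(clean$trajectory)
gamma_w <- kirkwood_irving(clean$pressure, kind = "air-water")

# dilute monolayer: osmotic route
run <- generate_fixture("dilute-monolayer", seed = 1, n_steps = 60000)
rec <- wall_force(run$trajectory, run$spec$wall)
pid <- pi_ideal(rec, l_y = run$spec$box[2])
prof <- density_profile(run$trajectory, species = "W", bin_width = 0.1,
                        region = c(-1, 1) * run$spec$wall$x_wall,
                        center = TRUE)
xi <- xi_coefficient(interfacial_thickness(prof), lz_ref)
pi_real(pid, xi)

# a compression isotherm
iso <- sweep_isotherm(toy_spec(seed = 2), areas = c(20, 10, 5, 2.5),
                      direction = "compression", per_area_steps = 40000,
                      lz_ref = lz_ref$lz_int)
iso
plateau_detect(iso)
```
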