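---
title: "Field-cable models of epiretinal prosthesis stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-cable models of epiretinal prosthesis stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epiretinal prostheses drive arrays of small disc electrodes against the
inner retinal surface to evoke phosphenes in blind users. Electrodes vary
widely in how much current they need before a percept appears, and clinical
programming establishes that perceptual threshold electrode by electrode.
The geometry measured per electrode on OCT — the electrode-retina distance
(ERD), the local retinal thickness, and any fibrotic tissue on the array —
explains much of this variability. `fieldcable` implements the two-stage
"field-cable" model that turns those per-electrode measurements into
predicted neural activation thresholds and phosphene sizes:

1. a **volume-conductor stage** solves the quasi-static problem
   $\nabla\cdot(\sigma\nabla V)=0$ for the potential produced by the
   stimulating electrode in a layered tissue model, and
2. a **cable stage** drives multicompartment retinal ganglion cell (RGC)
   models with the extracellular potentials and finds, by bisection, the
   smallest stimulus amplitude that elicits a propagating action potential.

The per-electrode prediction is the *minimum* threshold over a population
of 250 RGCs placed beneath the electrode; phosphene size is the convex-hull
area of the activated somas, converted to squared degrees of visual angle
at 288 um per degree.

## Tissue model and field solve

Clinical models in this line of work are segmented from OCT and meshed for
commercial FEM solvers. This package replaces that path with a parametric
voxel slab per electrode site, which captures the same layered geometry
without any imaging input: choroid (bottom, grounded on its outer face), a
10 um / 0.001 S/m retinal-pigment-epithelium membrane treated as a thin
resistive interface, retina of the measured thickness (inner surface at
z = 0), the vitreous gap of height ERD − fibrosis, fibrotic tissue (if
measured) directly beneath the electrode, and the electrode plane — platinum
discs of 200 um diameter at 525 um pitch in an insulating substrate — with
vitreous above. Conductivities default to 0.503 (choroid), 0.100 (retina),
1.5 (vitreous), 0.15 (fibrosis) and 9.43e6 S/m (platinum); the retinal value
is exposed for sensitivity analyses.

The discretization is a conservative finite-volume scheme on a nonuniform
rectilinear grid (harmonic-mean face conductivities, so sharp conductivity
jumps are handled correctly), 15 um spacing within 500 um of the active
electrode and geometric coarsening outward. The active electrode is an
equipotential terminal carrying 1 A — its voxels are merged into a single
unknown — matching a FEM "current terminal" and the closed-form oracle below;
inactive electrodes are floating conductors (merged unknowns with zero net
current); the substrate and remaining outer boundaries are no-flux. The
symmetric positive-definite system is solved by Jacobi-preconditioned
conjugate gradients to a relative residual of 1e-8, at which point the
current collected at the ground boundary equals the injected current to well
under 1%.

Because the governing equation is linear, one unit-current solve per
electrode suffices: every stimulus amplitude is a scalar multiple.

```{r}
library(fieldcable)
site  <- electrode_site("C5", erd_um = 50, thickness_um = 200)
model <- build_slab_geometry(site)
field <- solve_unit_field(model)
field
```

**Default extents.** The desk-scale default domain is 4 x 4 mm laterally
with 2 mm of vitreous, against the full-scale 25 x 17 mm / 18 mm clinical
extents (available by argument). The near-field potential profile that
drives the neurons is insensitive to this choice — predicted thresholds for
the validation geometry move by under 7% between 4 mm and 16 mm extents —
although absolute terminal potentials do shift with the domain, as expected
when insulating lateral walls confine the return current.

**Validation oracle.** For an equipotential disc of radius $a$ on the
insulating boundary of a homogeneous half-space,
$V(r,z) = \frac{2V_0}{\pi}\arcsin\frac{2a}{\sqrt{(r-a)^2+z^2}+\sqrt{(r+a)^2+z^2}}$
with $V_0 = I/(4\sigma a)$ (the access-resistance form). The test suite
solves this configuration numerically with the analytic solution prescribed
on the remote boundaries — the standard way to emulate the semi-infinite
medium so the comparison isolates discretization error — and requires the
terminal potential within 3% and sampled near-field points within 5%.

## The RGC population

Somas are placed quasi-uniformly: 250 positions within a 700 um radius
beneath the electrode, relaxed by Lloyd's algorithm. We implement the
discrete (k-means style) variant — a fixed quasi-uniform sample of the disc
is repeatedly partitioned by nearest center and centers move to partition
centroids — which is deterministic per seed, keeps every soma inside the
disc, and monotonically decreases the Lloyd energy. Iteration stops after 30
rounds or when the mean centroid displacement falls below 1 um (the
algorithm's stopping rule is a design choice; published descriptions name
the algorithm only).

Axons follow the retinal nerve-fiber bundle model
$\phi(r) = \phi_0 + b(\phi_0)(r-r_0)^{c(\phi_0)}$ in polar coordinates about
the optic nerve head (ONH), with the published superior/inferior parameter
forms (see `?trajectory_params`) transcribed from the cited bundle-trajectory
literature; the disc-entry angle $\phi_0$ for a soma is found by root
solving. Temporal (macular) fibers come out nearly straight, nasal fibers
arc, and fibers never cross the horizontal raphe; somas exactly on the raphe
deterministically join the superior branch. The ONH sits 4 mm nasal and
0.6 mm superior to the array center by default — a typical implant position;
the value is configurable because it is not fixed by the measurement tables.

Each cell is an unbranched compartment chain: equivalent dendrite (500 um,
3 um diameter — standing in for a mammalian RGC dendritic field), 20 um
soma, axon hillock (40 um), sodium-channel band (60 um — the axon initial
segment), narrow segment (90 um, 0.5 um), then distal axon (1 um diameter,
25 um compartments) following the fiber trajectory for up to 2 mm. The soma
sits 55 um and the distal axon 15 um below the retinal surface, with the
initial sections ramping between the two depths; neurons whose local retina
is thinner than the soma depth are flagged unbuildable and excluded.

## Membrane dynamics

The membrane model is the five-channel RGC formulation of the
Fohlmeister–Miller lineage (Na, delayed-rectifier K, A-type K, Ca,
Ca-gated K, leak) with the classic rate functions, Q10-scaled from their
22 C reference to body temperature (Q10 = 2), and a mammalian regional
density profile peaking at 2 S/cm^2 Na in the sodium-channel band. Axonal
sodium channels (initial segment and beyond) carry a 5 mV hyperpolarizing
activation shift, standing in for the low-threshold Nav1.6 isoform that
concentrates there; this is what lets spikes initiate in the band at
realistic stimulus strengths. The leak reversal is solved per compartment so
the stated resting potential (−65 mV) is an exact equilibrium, and the
parameter file is chosen so that equilibrium is dynamically stable: the
suite verifies < 0.5 mV drift over 50 ms at zero stimulus. All densities
live in a bundled YAML file (`inst/extdata/membrane_rgc.yaml`) and can be
swapped wholesale.

The calibration logic, in order of authority: rate functions and channel
inventory are the published lineage; the regional densities, temperature
scaling and the initial-segment activation shift were fixed once, within
ranges reported for mammalian RGCs, such that the model's operating point
matches the published model-prediction scale for this stimulation geometry
(population-minimum thresholds of order 10 uA at 50 um ERD for 0.45 ms
pulses) while remaining stable at rest. They were not revisited afterwards.

Integration is semi-implicit: Rush–Larsen exponential updates for gating,
explicit Euler for the calcium pool, and a backward-Euler tridiagonal solve
for the voltages with channel conductances frozen over the step
(dt = 0.005 ms; halving dt moves thresholds by < 2%). The extracellular
potential enters through the axial coupling of $V_i = V_m + V_e$, with
$V_e(t) = s(t)\,A\,\hat V_e$ for waveform scale $s(t) \in \{-1,0,+1\}$
(cathodic-first biphasic, 0.45 ms per phase, zero net charge), amplitude $A$
in uA and unit potentials $\hat V_e$ from the field stage.

**Single pulse versus train.** Clinical thresholds use five-pulse 20 Hz
trains; the threshold simulation uses a single biphasic pulse over 3 ms.
With a deterministic cell and 50 ms between pulses the first pulse decides
activation, so the train adds cost without changing the threshold; train
mode remains available through `stimulus_waveform(n_pulses = 5)`.

A spike is a 0 mV upward crossing in at least three consecutive distal-axon
compartments — a propagation requirement that rejects depolarizations
confined to the initial segment. The detector is a package decision; the
source literature reports thresholds without specifying one.

## Thresholds, exclusion, phosphenes, statistics

Per-neuron thresholds use bisection with the bracket doubled from an
initial guess (cap 10,000 uA, sentinel `NA` beyond) and a 0.1 uA
convergence; the returned value is the upper bound of the final bracket.
Neurons whose soma sits where the retina has thinned below 100 um are
excluded — evaluated at the soma position, the simplest reading of removing
neurons "in regions" of degeneration (a whole-morphology variant would only
add exclusions) — and the electrode threshold is the minimum over what
remains. Electrodes enter analyses only if visible on OCT with perceptual
threshold strictly below 677 uA; rows without perceptual data are retained
for simulation-only runs.

Phosphene size: for amplitudes 1.2x to 6x threshold (13 evenly spaced
multiples — the range is from the source protocol, the grid density a
package choice), the activated set is every included neuron with threshold
at or below the amplitude (equivalent to re-simulating under a monotone
response, and far cheaper; a re-simulation mode exists in
`simulate_neuron`), the convex hull of their somas is converted at
288 um/degree, and an OLS line of deg^2 versus multiple is reported.

The statistics module implements OLS with closed-form normal equations,
t/F inference and $R^2$, applied per predictor and jointly, plus the
predicted-versus-perceptual regression at $\alpha = 0.05$. Linear
mixed-model analyses are deliberately out of scope — they are routine fits
for external statistical tooling.

## Synthetic patients

Real per-electrode OCT tables from implanted eyes are not publicly
available, so `generate_synthetic_patient()` emulates them: ERD uniform on
10–440 um (the widest clinically observed range), thickness 100–350 um,
impedance 10–60 kOhm, fibrosis present on ~30% of electrodes (never
exceeding the ERD), ~5% of electrodes invisible on OCT, and a planted
threshold model `200 + 0.9*erd − 0.5*thickness + N(0, 30)` uA, which keeps
thresholds below the 677 uA compliance cutoff. The planted linear structure
makes regression recovery exactly testable (`noise_sd = 0` recovers the
coefficients to machine precision). What the generator does *not* emulate:
spatially correlated geometry across neighboring electrodes, cystoid edema
dynamics, measurement error in the OCT readings, or any nonlinear
threshold dependence — so passing tests demonstrate the pipeline's internal
correctness and the model's physics, not clinical predictive accuracy.

## Numerical choices and problem sizes

- Field solve: relative residual 1e-8 (conservation then holds to solver
  precision); typical desk-scale grids are ~90 x 90 x 40 cells and solve in
  a few seconds.
- Bisection: 0.1 uA convergence; ~20 cable simulations per neuron; a
  250-neuron population completes in about a minute on one core.
- The test-suite's long-running checks scale down where the property
  allows: monotonicity bands run 50-soma populations (the ordering is
  robust to population size), the phosphene-slope check 100 somas, while
  the absolute threshold band keeps the full 250.
- Degenerate inputs: fibrosis equal to ERD fills the gap; zero-thickness
  gaps and absent fibrosis skip their voxel layers; somas over sub-voxel
  or sub-55-um retina are flagged rather than simulated; empty activated
  sets yield zero hull area.

## Known limitations

- The slab is laterally flat; a thickness map hook exists
  (`thickness_fun`), but curved global eye geometry is not modelled.
- Only direct RGC activation is modelled — no bipolar/amacrine network
  contribution, so the model is not applicable to subretinal stimulation.
- Fibrosis is confined to the electrode footprint column; its lateral
  extent beyond the footprint is unmeasured in the source tables and
  configurable here.
- Perceptual thresholds involve criterion and cortical factors the neural
  surrogate cannot capture; predicted-versus-perceptual regressions on
  synthetic patients exercise the machinery, not the clinical claim.
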