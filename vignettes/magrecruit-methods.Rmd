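---
title: "Field-coupled force recruitment modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-coupled force recruitment modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`magrecruit` predicts the isometric force that neuromuscular magnetic
stimulation of the thigh extensors recruits, as a function of coil
geometry, coil–skin distance and stimulator output, and calibrates the
model's few free parameters against recruitment-curve data by joint maximum
likelihood. This vignette documents the model, the numerical choices, and
the judgement calls made where the design was genuinely open — and states
what the synthetic studies shipped with the package do and do not
demonstrate.

## The physical model

All fields are quasi-static. A winding is a set of closed polyline loops,
one loop per physical turn; collapsing a spiral winding to one equivalent
loop distorts the near field exactly where the muscle sits, so each turn is
kept. For a sinusoidal current pulse of frequency $f$ (default 5 kHz) the
induced field is evaluated at the pulse's peak slew rate: the magnetic
vector potential $\mathbf A$ follows from Biot–Savart summation over
straight segments (exact finite-segment kernels, not midpoint quadrature),
and the peak of $\partial_t \mathbf A$ is $2\pi f \mathbf A$. Whether a
threshold refers to the peak or the RMS field is a convention; this package
uses the peak throughout, so threshold values are peak-field thresholds.

Because tissue conductivities are small, the secondary field of the eddy
currents is neglected and the electric field decouples into

$$\mathbf E = -\partial_t \mathbf A - \nabla\varphi, \qquad
  \nabla\cdot(\sigma\nabla\varphi) = -\partial_t\mathbf A\cdot\nabla\sigma ,$$

i.e. a Poisson problem for the charge-redistribution potential with sources
where the conductivity varies. Displacement currents are ignored: the
tissue table stores relative permittivities, but only $\sigma$ enters the
solve.

### Discretization

The labelled voxel anatomy carries one tissue per cell. The right-hand
side uses second-order central differences of $\sigma$ contracted with
$\partial_t\mathbf A$, which requires the zero-conductivity background
padding the grid provides. The operator is the conservative 7-point
face-flux form: face conductivity is the harmonic mean of the adjacent
cells, which is exact for layered media and makes a face against
$\sigma = 0$ carry zero flux — the natural Neumann boundary condition needs
no extra treatment. The operator is symmetric with zero row sums; its null
space is the constant, so the right-hand side is projected by mean
subtraction and the potential is gauge-fixed to zero mean over the body.
Every reported field is gauge independent (tested to machine precision).

Two solvers are provided: Jacobi-preconditioned conjugate gradients (the
default) and plain Gauss–Seidel sweeps, which mirror the method such
formulations were historically solved with and serve as a cross-check; both
stop at a relative residual of $10^{-8}$. On grids up to roughly $10^6$
cells the CG path solves in seconds on one CPU.

The continuity diagnostic deserves a note. In the decoupled scheme the
discrete statement of $\nabla\cdot(\sigma\mathbf E) = 0$ is
$L\varphi + fV = 0$: the $\partial_t\mathbf A$ part of $\sigma\mathbf E$
enters through the assembled source $f$. `divergence_residual()` therefore
reports $\lVert L\varphi + fV\rVert$ (normalized by
$\lVert\sigma\mathbf E\rVert/h$), which a converged solve bounds by a
small multiple of the solver tolerance. A naive face-flux divergence
computed from the interpolated $\mathbf E$ alone mixes two different
discretizations of the same continuum operator and plateaus at
discretization-error level (~1%); it would say nothing about solver
convergence.

### Accuracy against the analytic cylinder

For a homogeneous conducting cylinder under uniform axial $dB/dt$ the exact
field is azimuthal with $\lVert\mathbf E\rVert = (r/2)\,dB/dt$. At 2 mm
pitch the solver matches this within 5% at interior voxels; errors
concentrate at the staircased surface, decaying roughly as $O(h)$ there and
$O(h^2)$ inside. With a radially layered conductivity (fat annulus over
muscle) the analytic field is unchanged because $\nabla\sigma$ is radial
and $\mathbf E$ azimuthal; discretely the staircase makes the source only
approximately zero, so the package tests field invariance away from the
interface rings rather than pretending the discrete source vanishes
identically. The perturbation is a halo around each staircased interface:
profiled against distance to the ring at 2 mm pitch, the deviation from
the homogeneous solution falls from roughly 40% on the ring itself to
about 3% beyond four voxels, which is the margin the invariance checks
exclude.

## The phantom

The anatomy is a parametric concentric cylinder: femur core, a muscle
annulus split into angular wedges, subcutaneous fat, and a skin shell of
approximately 2 mm. Eleven-odd muscles of a real thigh are reduced to
eight wedges; the four quadriceps heads occupy the anterior half and carry
their physiological pennation angles (+10° rectus femoris, +8° vastus
lateralis, −8° vastus intermedius, +15° vastus medialis); the posterior
wedges exist as conducting tissue but carry no force parameter. Angular
extents are free phantom parameters — no published layout fixes them — and
the defaults are plausible rather than subject-specific. Optional vessel
or nerve rods are omitted by default: they are not the stimulation target
and barely perturb the field at these pitches. Conductivities (S/m, kHz
range): skin 2.0·10⁻⁴, fat 0.024, muscle 0.34, vessels 0.31, nerve 0.03,
bone 0.082.

The default study grid uses a 0.18 m long, 0.065 m radius phantom at 2 mm
pitch (≈ 440k voxels). This is the desk-scale working point: it resolves
the 2 mm skin layer (the voxel pitch may never exceed a layer thickness —
the builder rejects such specs), keeps a single eddy-current solve near
ten seconds, and leaves the recruitment geometry smooth enough for the
calibration studies below. Pitch is a configuration knob; the convergence
tests quantify what coarsening costs.

## Coils and placement

Four parametric topologies are built as closed polylines: circular,
racetrack (stadium), figure-of-eight with counter-circulating wings, and a
saddle conforming to a cylinder, the shape used for coils that wrap the
thigh. Dimensions of the commercial devices these topologies represent are
not published as winding coordinates; the defaults (e.g. 45 mm mean radius,
10 turns for the round coil; 140° arc, 13 cm axial length for the saddle)
are documented as plausible, chosen so the four field patterns — local
round, elongated racetrack, focal figure-of-eight, large conforming saddle
— are realistic. Placement is strictly rigid: flat coils lie tangent on
the skin with their normal along the outward surface normal, are lifted by
the coil–skin distance $d$ (0/5/10/15 mm in the study design) along that
normal, and laterally rotated by 5° about the femur-parallel axis through
the contact point. Rigidity (all intra-winding distances preserved) and
the exactness of the lift translation are tested to $10^{-12}$ m.

The drive default of 3 kA peak per turn was chosen once so that, at full
stimulator output, peak extensor fields reach a few hundred V/m and a
65 V/m threshold is crossed at roughly a quarter of the output range —
the regime in which recruitment experiments actually operate. The wire
guard radius (1 mm) only affects user point evaluations; coil vertices lie
in the non-conducting background, so the singular kernel never meets the
solver's source term in a way that matters.

## From field to force

A muscle point is recruited when $\lVert\mathbf E(r)\rVert > E_\mathrm{th}$
(strict inequality — the tie set has measure zero, and strictness fixes the
convention for exact tests). Only the amplitude-to-threshold ratio
matters: scaling the output fraction $x$ and $E_\mathrm{th}$ together
leaves the activation mask unchanged, exactly.

Two force bases are implemented. The volume basis takes
$F = v_i V_\mathrm{eff}$ with $V_\mathrm{eff}$ the supra-threshold extensor
volume. The cross-section basis reflects that parallel myofibrils, not
series volume, set tendon force: per muscle, planes perpendicular to that
muscle's pennation-tilted fiber axis are scanned and the largest
supra-threshold intersection area taken; $A_\mathrm{eff}$ sums these maxima
over the four quadriceps compartments and $F = f_i A_\mathrm{eff}$. The
per-muscle-max-then-sum reading is a design decision: recruitment sums
across muscles acting in parallel on the same tendon, while within a muscle
the weakest link along the fibers is the largest activated section. One
force scale per subject is shared across the group, keeping the model
parsimonious.

Plane scanning uses nearest-voxel sampling of a plane raster at voxel-pitch
resolution with plane spacing equal to the voxel pitch; no interpolation
scheme is published for this construction, and nearest-voxel sampling makes
the mask-level and threshold-profile code paths agree bit-for-bit. The
field library stores, per (coil, distance), exact step functions of
$A_\mathrm{eff}$ and $V_\mathrm{eff}$ versus threshold (per plane, sorted
field values), so a calibration likelihood evaluation costs microseconds
instead of re-scanning masks.

The per-subject distance offset $APL0_i$ of the conforming coil enters as a
shift of the effective distance, resolved by linear interpolation between
the two bracketing library distances; no re-solve per subject. The 5 mm
library spacing bounds the interpolation error, and offsets are
box-constrained so every effective distance stays inside the library span
(no extrapolation, ever).

## Calibration

The likelihood is a single i.i.d. zero-mean Gaussian over all present
records: the simplest noise model consistent with maximum-likelihood
regression when nothing more is known about the error term. Missing
(subject, coil) cells contribute nothing; the sample count $n$ counts only
present records. "Mixed effects" is realized as shared parameters
($E_\mathrm{th}$, noise scale) plus free per-subject effects
($f_i$/$v_i$, optionally $APL0_i$) maximized jointly in one likelihood —
not a random-effects integral, for which no distributional prior on $f_i$
is available. Heteroscedastic extensions are deliberately out of scope.

Thresholding a finite voxel set makes the likelihood piecewise flat in
$E_\mathrm{th}$, so gradient methods are useless there. The optimizer is a
multi-start jittered grid over $E_\mathrm{th}$ (restart offsets drawn from
the recorded seed) with local refinement; for each candidate threshold the
force scales have the closed form
$\hat f_i = \max(0, \sum g F / \sum g^2)$, the noise scale is profiled
analytically, and each subject's $APL0_i$ is found by box-constrained 1-D
search. Because the offset only moves the interpolation weight between
fixed library distances, the basis values at all library distances are
computed once per candidate threshold and the inner search reduces to
arithmetic. The fit is deterministic given its seed; permuting record
order changes nothing beyond floating-point summation order.

Model selection uses the Schwarz criterion $S_\mathrm{BIC} = k\ln n - 2L$,
with $k$ counting the shared threshold, the noise scale, one force scale
per subject, and one offset per subject that actually has conforming-coil
records in the variant where offsets are free; ties break toward fewer
parameters. `summarize_threshold()` reports mean, SD and median across
fits with a >2 SD outlier flag; a single estimate reports SD 0 by
convention.

## The synthetic cohorts

The generator exists so that every calibration claim is testable without
any experimental data. Its defaults are the study conditions: 10 subjects;
true threshold 65 V/m (the order of magnitude established for neural
threshold fields); log-normal force scales with median 3·10⁵ N/m²
(≈ 30 N/cm², a textbook maximal muscle stress) and dispersion 0.25,
reflecting that maximal force per cross-section is strongly individual;
zero-mean normal distance offsets with 3 mm SD; observation noise of 10%
CV, applied as a homoscedastic SD equal to 0.1 times the mean positive
noiseless force; a 4-condition design (round coil at 0 and 10 mm, saddle at
5 and 10 mm) with 15 amplitudes spanning 0.1–1.0. Volume-basis cohorts use
a median of 1.7·10⁶ N/m³, matching the same maximal force over the
phantom's extensor volume. Whole coils go missing per subject with a
configurable probability, emulating incomplete experimental coverage; at
least one coil per subject is always retained.

Forces are treated as baseline-corrected sensor readings: Gaussian noise is
added without clipping, so sub-threshold records can be slightly negative.
Clipping at zero would bias every sub-threshold record upward by about
0.4 SD and drag the fitted threshold with it, which would contaminate the
recovery studies the generator exists for.

What the passing studies show: on data with exactly the model's structure,
the pipeline recovers a shared 65 V/m threshold within ±10% and individual
force scales within ±15% in at least 80% of 20 noisy cohorts (noiseless
cohorts recover within 1%), and BIC identifies the generating force basis
in at least 80% of replicates in both directions. What they do not show:
anything about real thighs. The phantom is a cylinder, the noise is
Gaussian and homoscedastic, the true threshold is genuinely shared, and
the forward model generating the data is the model being fitted. The
studies validate the machinery — identifiability, optimizer robustness,
selection consistency — not the biology.

## Numerical conventions and degenerate inputs

* Lengths are SI metres internally; distances in observation tables and
  library keys are millimetres (the field's habitual unit); NIfTI headers
  use millimetres.
* Coordinates are right-handed with $z$ the femur axis (distal→proximal);
  voxels are 0-based half-open boxes; all grids carry one background voxel
  of padding on every face (enforced by the constructor).
* Strict threshold inequality; zero amplitude or zero force scale yields
  exactly zero force; an empty muscle compartment contributes zero area,
  not an error.
* Solver failures carry the achieved residual in the error message; the
  potential solve refuses quietly wrong answers (a residual more than 10×
  the tolerance is an error, not a warning).
* Random draws always flow through explicit seeds; identical seeds yield
  byte-identical serialized observations.

## Known limitations

* The phantom's angular muscle layout is schematic; compartment volumes and
  their distances to the coil differ from any real thigh, so absolute
  forces and coil-ranking margins are phantom-specific even though the
  orderings tested (conforming coil steeper and earlier-saturating than
  round, figure-of-eight shallowest) are robust.
* Staircase voxelization limits field accuracy near tissue interfaces to
  first order; tetrahedral meshing is deliberately out of scope.
* No membrane dynamics, twitch summation, fatigue, fiber-type structure or
  non-isometric mechanics: the model predicts the peak isometric
  recruitment curve, nothing temporal.
* The likelihood assumes homoscedastic Gaussian noise; real force plates
  and rectified EMG-triggered measures are messier.
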