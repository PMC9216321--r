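# magrecruit

Coupled field and force-recruitment modelling for neuromuscular magnetic
stimulation of the thigh extensors.

Magnetic stimulation of the quadriceps evokes isometric knee-extension force
by inducing eddy currents in the muscle that excite the intramuscular axon
tree. How much force a given coil at a given stimulator output recruits is
determined almost entirely by the induced electric-field distribution and
the muscle anatomy. `magrecruit` implements the full chain from coil
geometry to predicted force, plus the statistical machinery to calibrate
the model against measured recruitment curves:

1. **Phantom** — a labelled cylindrical voxel thigh (skin ≈ 2 mm, fat,
   four quadriceps compartments with pennation axes, flexor wedges, femur)
   with tissue conductivities at the stimulation frequency.
2. **Coils** — parametric multi-turn windings of the four common topologies
   (circular, racetrack, figure-of-eight, cylinder-conforming saddle), each
   turn modelled as its own polyline loop; fields by Biot–Savart summation.
3. **Eddy-current solve** — the decoupled quasi-static formulation

   `E = −∂A/∂t − ∇φ,   ∇·(σ∇φ) = −∂A/∂t · ∇σ`

   discretized with a conservative 7-point finite-volume scheme
   (harmonic-mean face conductivities, natural Neumann boundaries) and
   solved by preconditioned conjugate gradients or Gauss–Seidel.
4. **Recruitment** — the threshold condition `‖E(r)‖ > E_th` marks active
   muscle; predicted force is either `F = f_i · A_eff` (maximal
   supra-threshold cross-section perpendicular to each muscle's
   pennation-tilted fiber axis, summed over the extensor group) or
   `F = v_i · V_eff` (supra-threshold volume). The four model variants
   1A/1B/2A/2B pair the two force bases with an optional per-subject
   distance offset `APL0_i` for the conforming saddle coil.
5. **Calibration** — joint maximum likelihood over all subjects at once
   (shared `E_th` and noise scale, individual `f_i`/`v_i` and `APL0_i`),
   tolerant of missing (subject, coil) cells, with Schwarz-BIC
   (`S_BIC = k ln n − 2L`) model selection, and a synthetic-cohort
   generator for parameter-recovery and model-recovery studies.

## Worked example

Build the study phantom and a field library, simulate a 10-subject cohort
from the cross-section model, and let BIC pick the generating model back
out:

```r
library(magrecruit)

an <- build_cylindrical_phantom(phantom_spec(
  length = 0.18, outer_radius = 0.065, voxel_pitch = 0.002))

coils <- list(
  round        = make_circular_coil(0.045, 10, 0.0015, 64),
  saddle       = make_saddle_coil(0.07, 140, 0.13, 6, 0.002, 128),
  figure_eight = make_figure_eight_coil(0.035, 9, turn_spacing = 0.0015,
                                        n_segments = 64))
placements <- list(round        = coil_placement(0, 0.12, 0, 5),
                   saddle       = coil_placement(0, 0.09, 0, 5),
                   figure_eight = coil_placement(0, 0.12, 0, 5))

lib <- build_field_library(an, coils,
  distances_mm = list(round = c(0, 10), saddle = c(0, 5, 10, 15),
                      figure_eight = 0),
  placement = placements)          # ~1.5 min: 7 eddy-current solves

pop <- generate_population(population_spec(10, seed = 42))
des <- design_spec(data.frame(coil = c("round", "round", "saddle", "saddle"),
                              distance_mm = c(0, 10, 5, 10)),
                   amplitudes = seq(0.1, 1, length.out = 15))
obs <- generate_observations(pop, des,
                             recruitment_model_spec("cross_section"),
                             lib, seed = 8, e_th = 65, noise_cv = 0.1)

fits <- lapply(c("1A", "1B", "2A", "2B"), function(m)
  fit_model(model_by_name(m), obs, lib, fit_control(seed = 1)))
select_model(fits)
```

```
  model    logLik  k   n      bic     e_th
1    1A -3267.861 12 600 6612.485 65.23528
2    1B -3263.595 22 600 6667.922 65.54729
3    2B -3483.322 22 600 7107.376 53.41987
4    2A -3638.002 12 600 7352.767 55.50393
```

The generating model (1A: cross-section basis, no distance shift) wins the
BIC ranking, and its fitted threshold field (65.24 V/m) recovers the
generating value of 65 V/m to 0.4% despite 10% observation noise; the
richer 1B gains a little likelihood but not enough to pay its ten extra
parameters, and both volume-basis models fall far behind. Individual force
scales come back within a few percent of the generating `f_i`:

```r
print(fits[[1]])
#> recruit_fit model 1A: L = -3267.86, k = 12, n = 600, BIC = 6612.49
#>   E_th = 65.24 V/m, noise = 56.1 N
```

A predicted recruitment curve for any coil/distance comes from the same
library:

```r
par <- parameter_set(e_th = 65, force_scale = c(S01 = 3e5))
cu <- recruitment_curve(recruitment_model_spec("cross_section"), par, lib,
                        "round", 0, seq(0.05, 1, by = 0.05))
attr(cu, "threshold_amplitude")   # 0.25 at skin contact; 0.40 lifted 10 mm
```

A thin command-line front end chains the same stages from a JSON
configuration (see `inst/scripts/magrecruit`): `phantom`, `field`, `curve`,
`simulate`, `calibrate`, `select`.

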