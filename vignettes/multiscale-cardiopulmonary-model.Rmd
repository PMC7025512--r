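---
title: "A closed-loop multiscale model of ventricular-arterial coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop multiscale model of ventricular-arterial coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vacoupler` simulates the cardiopulmonary circulation as a closed loop of
eight lumped compartments in which the two ventricles and the two proximal
arteries can be represented by finite-element (FE) continuum models instead
of lumped elements.  This vignette is the package's own account of the
science: the governing models and their assumptions, the parameters that
matter, what the synthetic geometries do and do not emulate, the numerical
choices, and the known limitations.

## The closed loop

Eight compartments — left ventricle (LV), systemic arteries, systemic
veins, right atrium, right ventricle (RV), pulmonary arteries, pulmonary
veins, left atrium — exchange volume through eight segmental flows.  Mass
balance couples them: each flow drains one compartment and fills the next,
so the total blood volume is conserved exactly, by construction, at every
explicit step.  The four valves are diode-resistors (flow
`(P_up - P_down)/R` when the gradient is forward, zero otherwise); the four
vessel segments are linear resistors; the two venous beds are linear
compliances `P = (V - V_0)/C`; the two atria follow a time-varying
elastance that blends a linear end-systolic and an exponential
end-diastolic pressure-volume relation through the driving function
`e(t)` — a half-sine rise/fall followed by exponential relaxation,
continuous at the switch, bounded in [0, 1].

The update order per time step is strictly explicit: volumes from the
previous flows, pressures from the new volumes, flows from the new
pressures.  Ventricular and arterial pressures at prescribed volumes come
either from time-varying-elastance surrogates or from the FE models below.

**Units.** Internally Pa, ml, ms (lengths mm); reports convert to mmHg
(133.322 Pa).  One printed source value deserves a flag: the venous
compliances appear in the literature table with an inconsistent unit
("Pa·ml"). The package treats configured venous compliances as true
compliances in ml/Pa and ships defaults (`C_sv` = 0.6, `C_pv` = 0.15
ml/Pa) that put venous pressures in the physiologic few-mmHg range at the
default 5.2 l total blood volume, alongside the printed resting volumes
(3570 / 485 ml).

**Timing.** The cycle length is 690 ms (87 bpm).  Atrial activation onset
defaults to the start of the cycle and ventricular activation resets at the
start of the cycle; neither offset is constrained by the source material,
and both are configurable.

## Myocardium

Passive myocardium is the Guccione transversely isotropic Fung-type law,
`W = C/2 (exp(Q) - 1)` with `Q` quadratic in the Green-Lagrange strain
expressed in fiber/sheet/sheet-normal coordinates.  The stress scales are
`C` = 280 Pa for the LV free wall and septum and 170 Pa for the RV free
wall.  The exponents (`b_ff` = 29.9, `b_xx` = 13.3, `b_fx` = 26.6) are a
common literature set — they are not part of the printed parameter table —
and are configurable.

Active stress follows a sarcomere contraction model: a contractile element
of length `l_c` in series with an elastic element of stiffness `E_a`
connects to the sarcomere length `l_s` (fiber stretch times the relaxed
length `l_s0` = 1.9 um).  The developed stress is
`P_a = (l_s/l_s0) f_iso(l_c) f_twitch(t, l_s) (l_s - l_c) E_a`, applied as
a rank-one tensor along the deformed fiber direction.  `l_c` evolves by
`dl_c/dt = (E_a (l_s - l_c) - 1) v_0` and is stored per quadrature point,
advanced with the global explicit step.

Two printed details required a decision, both configurable and both
resolved in favor of a functioning heartbeat:

* The isometric curve is printed with its active branch *below* the
  threshold length `a_7`.  The operation implements the printed form as
  its default, but at the (not-from-table) defaults `a_7` = 1.5 um and
  operating sarcomere lengths of 1.8–2.2 um the printed branch develops no
  tension at all.  The driver's default cardiac configuration therefore
  uses the documented "ascending-limb" variant (active for `l_c > a_7`),
  which is the physiologic orientation of the tension-length curve.
* The twitch-duration slope is printed as `b` = 0.17 ms/um, which yields a
  sub-millisecond twitch at physiologic lengths.  The contraction-model
  lineage uses seconds per micron; the shipped default is 170 ms/um
  (0.17 s/um), giving twitch durations of roughly 400 ms.

## Artery wall

The proximal arteries are 3D membranes with a constrained-mixture strain
energy: an elastin-dominated neo-Hookean matrix (its trace term completed
by the incompressibility-determined thickness stretch), four collagen
fiber families (longitudinal, circumferential, ±45°) with the exponential
energy `M c_2/(4 c_3)(exp[c_3 (λ² - 1)²] - 1)`, and circumferential smooth
muscle of the same form with `(c_4, c_5)`.  Mass fractions weight the
terms: 10% of collagen in each axial family and 40% in each diagonal
family.  Per-family mass is `split_i · φ_c · ρ` — the printed per-family
relation would multiply the collagen fraction in twice; the parenthetical
family definitions in the parameter table fix the reading used here.
Because every term is proportional to the tissue density, `ρ` is kept at a
normalized value of 1 and the stiffness coefficients carry the magnitude;
supplying a real density simply rescales stresses.

Compressed fibers (`λ < 1`) store energy per the printed symmetric form; a
tension-only variant can be obtained by zeroing those contributions but is
not the default.  Wall thicknesses are not printed; defaults are 2.0 mm
(aorta) and 1.5 mm (pulmonary artery).

## Finite-element formulations

**Biventricle.** Displacement and incompressibility pressure are
discretized with Taylor-Hood P2/P1 tetrahedra.  The cavity volumes are
enforced by scalar Lagrange multipliers whose converged values *are* the
cavity pressures; a vector multiplier pair removes mean translation and
rotation; basal nodes move only in the z = 0 plane (their vertical dofs
are eliminated).  Cavity volumes are computed by the divergence theorem
over the deformed endocardial surface; the basal closure lies in the
basal plane where `x · n = 0`, so it contributes nothing.  The sign of the
two cavity terms in the printed Lagrangian differs; both are implemented
identically (pressure conjugate to cavity volume), which is what the
printed first variation requires.

**Arteries.** Linear membrane triangles carry `h · W` per reference area;
bending is neglected.  The lumen volume is closed by virtual flat caps
fanned from a fixed point in each inlet/outlet ring plane (rings move only
in-plane, so the caps stay planar).  A transverse-displacement penalty of
relative magnitude 1e-6 regularizes the bending-free modes; it is
numerical regularization, not physics.  Each vessel carries one uniform
cavity pressure.

**Numerics.** Element residuals are analytic; element tangents are finite
differences of the residual in compiled code (central differences for the
membrane, forward for the solid).  The bordered saddle system is factored
as a quasi-definite LDL' (supernodal CHOLMOD) with iterative refinement,
falling back to sparse LU; the vessel systems are small and always use LU.
The incompressibility constraint is integrated with a degree-4 Keast rule,
which is exact for the cubic Jacobian of a P2 displacement, while the
stress terms use a 4-point degree-2 rule.  Newton tolerances: residual
1e-8 relative with a small absolute force floor, cavity volumes to 1e-3 ml;
volume increments above 2 ml (solid) / 3 ml (membrane) are sub-stepped.
Inside the coupled loop the factored tangent is reused across steps and
refreshed adaptively when convergence slows — the physics does not change,
only the iteration count.

**Coupling.** The driver can run each ventricle pair and artery as
elastance surrogates or FE models.  Because the membrane is elastic and
history-independent, the vessel response inside the loop is evaluated
through a precomputed pressure-volume curve (a monotone spline over an FE
inflation ramp, sampled adaptively up to 16 kPa), which is equivalent to a
per-step FE solve up to interpolation error; per-step solves remain
available (`artery_mode = "fe_direct"`).  The biventricle, whose active
state is history-dependent, is solved at every step in FE mode.

## Synthetic geometries

The generator emulates the anatomies of an image-based study at
desk-scale resolution:

* **Biventricle** — a truncated thick-walled half-ellipsoid LV (base plane
  z = 0) with an RV cavity formed as a crescent gap between the LV
  epicardium and an attached RV free wall shell spanning a circumferential
  sector.  Cells are labelled LVFW / septum (LV wall under the RV sector) /
  RVFW; passive stiffness and contractility are shared between LVFW and
  septum.  Default cavity volumes match the measured end-diastolic volumes
  (72 / 77 ml); the RV gap amplitude is solved by root finding so the
  discrete cavity volume hits the target exactly.  Meshing extrudes a
  structured surface grid transmurally into prisms split by a
  smallest-vertex face-diagonal rule that guarantees conforming
  tetrahedra.  The normalized transmural depth is available in closed form
  from the parametric construction, so the customary Laplace solve for the
  rule-based fiber coordinate is unnecessary; the helix angle runs
  linearly from +60° (endo) to −60° (epi).
* **Vessels** — straight cylinders and a symmetric bifurcation stitched
  watertight through a saddle junction band (one inlet, two outlets),
  with per-element longitudinal/circumferential frames for the fiber
  families and named slice planes for effective-diameter waveforms.
* **Sphere shells** — single-cavity analogs used to verify the chamber
  solver against a 1D incompressible thick-shell quadrature of the same
  (isotropic-exponent) material law.

Generation is deterministic: identical specifications give identical
meshes.  What the fixtures do *not* emulate: patient-specific shape and
regional wall thickness, valve planes, trabeculation, image-derived fiber
fields, branched arterial trees, or any residual stress (the reference
configuration is treated as stress-free).  Passing tests on these
geometries therefore demonstrate correctness of the numerics and
sign-level physiology, not patient-specific accuracy; the headline
patient-matched numbers of the imaging study depend on the reconstructed
anatomy and calibration and are out of scope here.

## Default problem sizes

Chosen once as the package's desk-scale working points: biventricle
default 32 × 16 surface resolution with two transmural layers (about 7,900
tetrahedra; sub-percent cavity-volume discretization error), a coarse
10 × 5 single-layer variant (about 380 tetrahedra, the coarsest grid whose
crescent right ventricle still works as a pump) for in-loop FE runs,
vessel membranes at 12–20 circumferential segments, explicit step 0.5 ms
(1 ms for in-loop FE runs), periodicity tolerance 0.1 ml on all compartment
volume traces.  The incompressibility quality metric is reported at the
3% inflation working point, where the 16 × 8 × 3 shell sits inside its
validated interpolation regime.  The surrogate-mode loop settles to cycle-to-cycle
periodicity in roughly 20–30 cycles from the shipped initial volumes; FE
scenario comparisons use a matched number of cycles from a matched initial
state when strict periodicity would be too costly at desk scale, which is
sufficient for the sign-level questions they answer.

## Scenario experiments

Three configuration edits mirror hallmarks of pulmonary arterial
hypertension progression:

1. **Collagen accumulation** — PA collagen mass fraction 0.42 → 0.70 with
   elastin 0.35 → 0.15 and smooth muscle 0.23 → 0.15 (fractions still sum
   to one).  Requires the FE pulmonary artery (the surrogate has no
   microstructure).
2. **Reduced RV contractility** — `T_0,RV` halved (1800 → 900 kPa); the RV
   elastance surrogate is scaled by the same factor so surrogate runs
   reproduce the sign of the effect.
3. **Raised distal resistance** — `R_pa` × 1.5, equivalent by Poiseuille's
   law to about a 10% reduction in distal lumen diameter
   (`(1 - 1.5^(-1/4)) · 100 ≈ 9.6%`).

The package asserts the *directions* of the responses (pulse pressure up
under collagen accumulation; RV ejection fraction, peak pressure and fiber
stress down under reduced contractility; RV and PA pressures up under
raised resistance).  Magnitudes at desk scale differ from the
patient-specific study — in particular the idealized single-segment
arteries under-supply arterial compliance, so pulse pressures run high and
diastolic pressures low, the same bias (amplified) that the source
framework reported for its segment-only arteries.

## Known limitations

* Pure membrane arteries: no bending stiffness, no fluid shear, uniform
  thickness, single cavity pressure per vessel.
* No inertances, nonlinear valves, baroreflex, conduction delay, or
  myofiber remodeling; scenarios change parameters instantaneously.
* The explicit coupling scheme requires `dt` below the smallest
  pressure-flow time constant (about 1–2 ms at the shipped parameters);
  the solver refuses a step that drives a compartment volume non-positive
  and names the compartment.
* Quadratic tetrahedra with finite-difference tangents trade some Newton
  robustness for implementation transparency; volume sub-stepping and the
  LU fallback recover the difficult cases.

## Example

```{r example}
library(vacoupler)

cfg <- sim_config(max_cycles = 30)
rec <- run_closed_loop(cfg)
metrics <- hemodynamic_metrics(rec)
metrics
glance(rec)
autoplot(rec, "pv")

# PAH scenario, surrogate mode
rec_r <- run_closed_loop(apply_scenario(cfg, "resistance_increase"))
hemodynamic_metrics(rec_r)
```
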