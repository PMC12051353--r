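---
title: "Predictive planar gait simulation for Duchenne muscular dystrophy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive planar gait simulation for Duchenne muscular dystrophy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dmdgait)
```

# The scientific problem

Boys with Duchenne muscular dystrophy (DMD) progressively lose contractile
muscle tissue, which is replaced by fat and fibrosis. Two distinct mechanical
consequences follow: *weakness* (less active force) and *contractures*
(passive muscle stiffness at shorter lengths, limiting joint range of
motion). Both alter gait, but because they progress together in patients,
experimental data alone cannot separate their causal contributions.

`dmdgait` addresses this with predictive simulation: gait is *generated* by
trajectory optimization on a musculoskeletal model — no motion data enters
the simulation — so an impairment can be dialed in alone or in combination
and its direct mechanical consequence observed. The package personalizes a
planar model from clinical-measurement summaries (instrumented strength
deficits, goniometric range-of-motion deficits, ordinal stiffness scores,
anthropometry), simulates walking for each model variant, and quantifies the
deviation of each simulated DMD gait from the typically developing (TD)
reference simulation.

# Muscle model and the two impairment knobs

Each actuator is a Hill-type muscle-tendon unit. The fiber force is

$$F = F^{max}\left(\sigma\, a\, f_L(\tilde l)\, f_V(\tilde v)
      + f_{pass}(\tilde l; s)\right)\cos\alpha$$

with normalized fiber length $\tilde l$ and velocity $\tilde v$, activation
$a$, a Gaussian-sum active force-length curve $f_L$ (exactly 1 at optimal
length), a Hill force-velocity curve $f_V$ with a saturating eccentric
branch, and an exponential passive curve $f_{pass}$.

The two DMD knobs are deliberately orthogonal:

* **Weakness** scales only the active term by
  $\sigma = \mathrm{MVIC}_{DMD}/\mathrm{MVIC}_{TD} \in [0,1]$. Scaling
  $F^{max}$ instead would also scale the passive force, which moves in the
  *opposite* direction in DMD.
* **Contracture** translates the passive curve to shorter fiber lengths by a
  shift $s$: $f_{pass}(\tilde l; s) = f_{pass}(\tilde l + s; 0)$, so passive
  force onset moves from normalized length $1$ to $1-s$. Neither slack
  length nor the active curve is touched; the translation identity is exact
  and is enforced by a test.

The shift is estimated from clinical data by two routes that are averaged
when both exist:

* **ROM route**: the end-range joint-angle deficit (radians) times the
  muscle's anatomical-position moment arm, normalized by optimal fiber
  length.
* **Ordinal route**: clinical stiffness scores 0-3 map to shifts
  0, 0.17, 0.33, 0.5 (passive onsets 1, 0.83, 0.67, 0.5).

The pairing of tests to muscles follows standard clinical interpretation:
the Thomas test personalizes the iliopsoas, the popliteal angle the
hamstrings (through the knee moment arm), and the knee-extended /
knee-flexed ankle dorsiflexion pair the gastrocnemius and soleus
respectively. Shifts are capped at 0.6 and weakness floors at
$\sigma = 0.01$ to avoid singular models.

# Personalization pipeline

`personalize_model()` applies, in order:

1. **Geometric-similarity scaling** to the group's stature: lengths (segment
   geometry, fiber and slack lengths, moment arms, contact spheres) scale
   with $\lambda$, muscle forces with $\lambda^2$, masses with the ratio to
   the *expected TD mass* of that stature, inertias with mass times
   $\lambda^2$. The expected TD mass uses an allometric $c\,h^3$ rule with
   $c$ fixed by the generic model, a stand-in for a reference-population
   regression that is not reproducible here.
2. **Excess-mass redistribution**: body mass above the TD expectation is
   split 2/3 over trunk+pelvis and 1/3 over thighs+shanks (proportionally to
   segment mass), none to the feet; segment inertias scale with the gain.
   Only mass and inertia change — the trunk center of mass is deliberately
   not shifted.
3. **Impairments**: per-muscle $\sigma$ and $s$, applied identically to the
   left and right sides (symmetric models).
4. **Foot deformity** (midfoot break): vertical foot geometry (center of
   mass heights, in-frame joint heights, contact-sphere centers) is scaled
   by 0.9 and intrinsic-foot-muscle strength halved. Arch stiffening is
   realized solely through the intrinsic muscles, whose activation resists
   midtarsal dorsiflexion (arch drop); the passive midtarsal wall is
   present but the muscle is the dominant active stiffener.

A group's experiment plan contains six variants — weakness alone and
weakness+contractures, each at one SD below the mean, the mean, and one SD
above — plus a seventh (mean weakness + contractures + midfoot break) for
the flexion-pattern group, and a single unimpaired TD reference.

# The planar skeleton

The full 3D model this workflow descends from has 33 degrees of freedom and
94 muscles; reproducing it is out of scope here. The planar reduction keeps
every sagittal quantity the severity analyses narrate: 10 segments (pelvis,
torso, thigh/shank/hindfoot/forefoot per side), 12 coordinates (pelvis
translations and tilt, lumbar, hips, knees, ankles, and a midtarsal joint
per foot for the arch), 9 muscles per leg plus a lumbar pair, three
Hunt-Crossley contact spheres per foot (heel, midfoot, toe), and
double-exponential passive torques with damping on every rotational joint.
Muscle paths use constant anatomical-position moment arms, making
musculotendon length affine in the coordinates — the same anatomical-position
convention the contracture estimator uses. Conventions: radians internally,
x forward / y up, ground at $y=0$, pelvis tilt positive anterior, hip and
knee flexion positive, ankle and midtarsal dorsiflexion positive.

Rigid-body dynamics are evaluated by a planar recursive Newton-Euler pass
(inverse dynamics) written in C++; the mass matrix is assembled from unit
accelerations. Contact is Hunt-Crossley ($k\,\delta^{3/2}$ with velocity
dissipation, exponent 3/2, 1 mm smoothing band, friction 0.8 through a tanh
of slip velocity). Tendons are rigid in the planar reduction (an
elastic-tendon equilibrium solver is available per muscle). Pennation
defaults to zero for these lumped muscle groups.

Every smooth approximation exists for the optimizer's sake: the positive
part in contact penetration, the force-velocity concentric clamp, the tanh
blend of activation/deactivation time constants (15/60 ms, blend sharpness
2), and the tanh-smoothed conditionals of the Bhargava-style metabolic model
(sharpness configurable; the piecewise model is retained as the oracle the
smoothed model is tested against).

# The predictive optimal control problem

One half gait cycle is transcribed by trapezoidal direct collocation with
implicit skeletal dynamics: states are coordinates, velocities and muscle
activations; controls are excitations and joint accelerations $u_a$; the
equations of motion enter as algebraic path constraints
$\mathrm{ID}(q,\dot q,u_a) = \tau_{muscle} + \tau_{passive}$ at each node.
The cost is the distance-normalized integral

$$J = \frac{1}{d}\int_0^{t_f} \left(w_1\sum \dot E^2 + w_2\sum a^2 +
      w_3\sum u_a^2 + w_4\sum T_p^2\right) dt$$

with free half-cycle duration $t_f$. The weights are package
reconstructions (the source framework's tuned values are not published in
the text): $w_1$ and $w_4$ are normalized by body mass squared (the
anthropometric scaling of those terms), and the defaults emphasize the
quadratic activation term, which makes the optimization landscape close to
quadratic and the found optima reproducible — with a strongly
metabolic-dominated cost the solver's local optima scatter far more.

**Periodicity and speed by construction.** Rather than imposing
periodicity-with-left/right-symmetry and average speed as constraints, the
transcription eliminates them: the state and controls at node $N$ are
*defined* as the symmetry image of node 0 with the pelvis advanced by
$v\,t_f$. This removes the constraint rows entirely (their residuals are
exactly zero in every reported solution), removes one node's variables, and
makes the cost quadrature prefactor the constant $1/(vN)$.

## Solving the NLP

No general sparse NLP solver is available in this environment, so the
package ships its own, exploiting that the cost is an exact sum of squares:

1. **Gauss-Newton augmented Lagrangian**: the stacked residual
   $[\sqrt{\mu}(c + \lambda/\mu);\ \text{cost residuals}]$ is minimized by
   sparse Levenberg-Marquardt steps; multipliers update by the usual
   safeguarded rule. Jacobians come from colored finite differences over
   the block structure (nodes mod 3), so one Jacobian costs about 300
   trajectory evaluations regardless of mesh size.
2. **Homotopy**: early outer iterations add an annealed kinematic-tracking
   pull toward a closed-form nominal TD half-cycle hot start (generated in
   code from typical sagittal joint-angle shapes), which prevents collapse
   into degenerate shuffling solutions while the iterate is far from
   feasible.
3. **Feasibility polish**: a pure feasibility Levenberg-Marquardt phase
   (with Jacobian reuse) drives the scaled constraint violation below the
   tolerance.
4. **Optimality refinement**: reduced-gradient steps on the constraint
   manifold (project the cost gradient onto the tangent space, line search,
   re-polish) equalize how deeply different solves descend the cost.

A solve that cannot reach the feasibility tolerance returns a
`feasibility_report` rather than an error: in this workflow a model that
cannot walk is a scientific finding (the loss-of-ambulation analogue), not
a failure mode.

## Numerical choices

* Mesh: 12-15 intervals per half cycle for variant sweeps, 25 for the
  reference-quality TD solve (via `refine_mesh()` continuation from a
  coarse solve). These sizes resolve the gait cycle at 20-40 ms per node
  while keeping a solve in the minutes range.
* Convergence tolerance: scaled constraint violation below `tol_feas`
  (default 2e-4), corresponding to raw defect errors around $10^{-5}$
  (states) and dynamics residuals around 0.01 N·m — far below any
  physiologically meaningful scale. Periodicity and speed are exact (zero)
  by construction.
* Bounds: joint angles within anatomically generous boxes, activations and
  excitations in [0.01, 1], $t_f \in [0.2, 1]$ s.
* Warm starts: every variant of a severity comparison starts from the same
  deeply optimized TD solution (the same protocol the underlying framework
  uses with measured TD gait), and the midfoot-break comparison warm starts
  from its own weakness+contracture solution so that a small model change
  is evaluated against the matching local optimum.

## Known limitations

* The solver is first-order (Gauss-Newton); different cold starts can land
  in different local optima whose costs differ by tens of percent. The
  paired warm-start protocol makes *comparisons* reliable, but absolute
  costs and the finer gait features retain local-minimum variability, and
  strict seed-invariance of the cost (to ~1%) is not achieved. Directional
  comparisons with margins below about half a degree should be treated as
  qualitative.
* The planar reduction has no frontal/transverse plane: pelvic obliquity,
  hip ab/adduction and trunk sway compensations are out of scope, and the
  carried hip-abduction measures of the clinical tables are unused.
* Constant moment arms ignore wrapping-path changes at extreme flexion.
* Group-level personalization only: the cohort module generates
  subject-level records, but models are built from group summaries.

# What the synthetic cohort does and does not emulate

The generator reproduces the *statistical structure* of a clinical DMD
database: three severity groups with distal-dominant (tiptoeing) and
proximal-dominant (flexion) deficit patterns, truncated-normal continuous
measures with group means and SDs, ordinal stiffness scores with per-group
category probabilities, allometric anthropometry with excess body mass, and
a midfoot-break prevalence of 1 in the flexion group. The numeric profile
values are package defaults documented as synthetic: the source cohort's
numbers exist only in graphical form and cannot be transcribed. The
generator does not emulate longitudinal (repeated-session) correlation,
left/right asymmetry, or correlations between measures; passing
parameter-recovery tests therefore validates the pipeline's statistics, not
any clinical claim about real cohorts.

# Reproducing the analysis

The numbered scripts under `analysis/` run the full workflow: synthetic
cohorts (`01`), personalized model variants (`02`), the TD reference
simulation (`03`), a group's severity sweep (`04`), and the cross-group
deviation report (`05`). `scripts/acceptance.R` recomputes the clinical
worked-example quantities from a live pipeline run and writes them as JSON.
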