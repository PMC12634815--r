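---
title: "Pulsatile CSF flow and mixing in the cerebral aqueduct: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsatile CSF flow and mixing in the cerebral aqueduct: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(csfmix)
```

## The scientific problem

Cerebrospinal fluid (CSF) oscillates through the cerebral aqueduct — the
narrow channel between the third and fourth ventricles — in synchrony with
the cardiac cycle. Two descriptors summarize a subject's aqueductal flow:
the stroke volume (the volume displaced per cycle, bidirectional
convention) and the maximum Reynolds number

$$\mathrm{Re} = \frac{\rho U D}{\mu},$$

with $D$ the aqueduct diameter, $U$ the peak area-averaged velocity, and
water-like CSF properties $\rho = 10^3\,$kg/m$^3$,
$\mu = 10^{-3}\,$Pa·s (so the kinematic viscosity is 1 mm$^2$/s and Re is
numerically $U[\mathrm{mm/s}] \times D[\mathrm{mm}]$). In healthy adults
the two raw quantities vary several-fold, but they co-vary: wider aqueducts
carry slower flow, approximately $U = a/D$, so Re is a similarity
parameter of the healthy population. Hyperdynamic flow in idiopathic
normal-pressure hydrocephalus (iNPH) breaks this similarity: Re roughly
doubles and decouples from $D$. Because inter-ventricular solute exchange
depends on how much the oscillating flow *mixes*, the package couples a
cohort model of these descriptors to a CFD + particle-tracking pipeline
that quantifies aqueductal mixing with a multiscale exchange norm, and a
statistics layer that reproduces the population-level analysis.

The pipeline is fully synthetic: no subject data ship with the package.
Every stage is driven by a parametric cohort generator whose defaults
emulate the published healthy summary statistics, so the whole chain is
testable end to end.

## Synthetic cohort model

`cohort_params()` parameterizes one group. All marginals (age, weight,
ventricle volumes, aqueduct diameter $D$, cardiac period $T_c$) are
independent Gaussians truncated at zero — summary tables report only means
and SDs, so the Gaussian is the minimal assumption, and no cross-correlations
are published that would justify a joint model. Defaults for the healthy
group: age $52 \pm 18$ y, weight $60 \pm 11$ kg, lateral/third/fourth
ventricle volumes $23.3 \pm 11.8$ / $1.1 \pm 0.5$ / $1.6 \pm 0.3$ ml,
$D = 2.82 \pm 0.56$ mm, 19 male / 28 female of 47.

The velocity model is the substantive part:

* **healthy**: $U = a/D + \varepsilon$, $a = 26.4$ mm$^2$/s,
  $\varepsilon \sim N(0, \sigma_U)$ — the inverse relation holds in
  expectation, so `fit_inverse()` recovers $a$;
* **iNPH**: $\mathrm{Re} \sim N(58.0, 27.6)$ truncated positive and
  $U = \mathrm{Re}/D$ — no inverse relation.

The velocity noise default $\sigma_U = 4.6$ mm/s is derived from the
published Re spread: with $\mathrm{Re} = UD = a + \varepsilon D$,
$\mathrm{sd}(\mathrm{Re}) \approx \sigma_U \sqrt{E[D^2]} = 13.3$.
Two consequences are worth stating plainly. First, the generated mean Re
is $a = 26.4$, slightly below the printed $28.6$ — real cohort data deviate
from the exact inverse law, and a generator that enforces the law in
expectation cannot match both numbers; we keep the inverse law, since it is
the hypothesis the analysis tests. Second, the per-subject stroke volume is
*derived*, not drawn: the waveform peak is set to $Q_0 = U A$ (so the
waveform's `representative_velocity()` equals the drawn $U$ exactly) and a
sinusoid then carries $SV = Q_0 T_c/\pi = a D T_c / 4 + O(\varepsilon)$.
With $T_c = 0.85 \pm 0.12$ s (resting heart rate ~70 bpm; the source tables
print no period) the emergent SV marginal is $\approx 16 \pm 9$ µl against
the printed $15.3 \pm 7.8$ µl. Keeping $U$, $SV$, Re and the waveform
mutually consistent was judged more valuable than matching the SV marginal
to the third digit; the parameter-recovery tests depend on that
consistency.

Waveforms are cardiac-gated with 8 phases by default (the typical gated
reconstruction count), zero net volume per cycle by construction, with a
`biphasic` two-harmonic option for a sharper systolic peak. The iNPH
aqueduct diameter ($3.2 \pm 0.6$ mm) is a synthetic assumption — only
distribution plots, not numbers, are published for it.

## Idealized geometry

Patient geometries are unavailable, so `build_geometry()` constructs a
smooth body of revolution: lateral-ventricle and third-ventricle bulges
proximally, the straight circular aqueduct (diameter $D$, length 12 mm —
not reported by volumetry; anatomically plausible and configurable), and a
fourth-ventricle bulge whose distal cap carries two outlet disks standing in
for the foramina of Luschka and Magendie. Each bulge's revolved volume is
matched to the (scaled) subject volumetrics by a one-dimensional root solve,
to better than 0.1%; the constriction where the profile returns to the
aqueduct radius between the lateral and third chambers plays the role of the
foramen of Monro. At desk scale the chamber volumes are reduced tenfold
(`chamber_scale = 0.1`) while the aqueduct stays at true scale: Re and the
aqueduct dynamics are preserved, wall displacements shrink (helpful for the
linearized ALE below), and tracer counts stay manageable.

Meshing (`mesh_geometry()`) extrudes a structured triangulated disk along
the axis, scaling each node ring by the local profile radius, and splits
each prism into three tetrahedra with the minimum-vertex diagonal rule
(conforming by construction). Resolution is tied to the aqueduct — ring
count $\lceil D/2h \rceil + 2$, axial spacing $h$ — so the
coarse/medium/fine protocol (base sizes 1.4/0.7/0.35 mm, scaled by
$D/2.82$) refines both directions while chamber size costs nothing. The
axial spacing is halved over the distal cap, where the outflow jets through
the foramina disks carry the steepest gradients. Optional graded outer
rings stand in for prism boundary layers; they are off by default, near-wall
resolution being enforced through the base size instead.

## Flow solver

`solve_cycle()` integrates the incompressible Navier–Stokes equations in
the arbitrary Lagrangian–Eulerian (ALE) form — continuity
$\nabla\cdot\mathbf v = 0$ and momentum
$\rho(\partial_t\mathbf v + \tilde{\mathbf v}\cdot\nabla\mathbf v)
= -\nabla p + \mu\nabla^2\mathbf v$, where $\tilde{\mathbf v}$ is the
velocity relative to the moving mesh — with P1 tetrahedral elements for
velocity and pressure and a fractional-step scheme:

1. tentative velocity: explicit advection with streamline-upwind
   Petrov–Galerkin (SUPG) stabilization, Crank–Nicolson implicit diffusion,
   and the lagged pressure gradient (incremental pressure-correction);
2. pressure Poisson solve for the increment, homogeneous Neumann on walls
   and 0 Pa on the outlets;
3. lumped-mass velocity correction, iterated `n_projection = 4` times
   because the lumped correction only approximately annihilates the P1
   divergence.

Three implementation choices deserve explanation.

* **Boundary forcing.** The driving waveform enters as a moving-wall
  program on the lateral-ventricle boundary: $\mathbf w = \alpha(t)\,
  \mathbf n(x)$ with uniform normal speed $\alpha(t) = -Q(t)/A_\mathrm{eff}$,
  where $A_\mathrm{eff}$ is the *discrete* flux area of the nodal normal
  field, so the wall volume change matches $-Q(t)$ to machine precision.
  The spatial distribution of wall motion is not observable from flow
  measurements; uniform normal speed is the least-informative choice. The
  whole wall is no-slip; outlet pressure is 0 Pa.
* **Linearized ALE.** At cohort conditions the wall displacement amplitude
  is $SV/A_\mathrm{wall} \sim 0.01$–$0.1$ mm, far below the 0.35–1.4 mm
  element sizes. Mesh motion (the harmonic extension of the wall program,
  `ale_mesh_motion()`) therefore enters the advective velocity
  $\tilde{\mathbf v} = \mathbf v - \mathbf v_\mathrm{mesh}$ and the stored
  phase coordinates, but the FE operators are assembled once on the
  reference configuration. This keeps one sparse Cholesky factorization per
  run and is the leading-order ALE consistent with displacements this
  small. It would *not* be appropriate for geometries whose deformation is
  comparable to the element size.
* **Outlet treatment.** The 0 Pa condition is imposed at pressure nodes
  strictly interior to the outlet disks; the junction-ring nodes shared
  with the no-slip wall keep their continuity rows tested. Together with
  the projection iterations and the distal cap refinement this keeps the
  global wall+outlet flux imbalance below 1% of the peak flow rate at the
  default resolution (it is logged every step as `mass_residual`).

The time step comes from the advective CFL condition with target Courant
number 0.5 (estimated peak velocity $2Q_\mathrm{max}/A$, the parabolic
centerline factor), bounded to 60–2000 steps per cycle and rounded to the
stored-phase grid; the solver aborts if the realized Courant number ever
exceeds four times the target. Three cycles are run and the last is stored
(40 phases), the first two discarding the start-up transient; the
cycle-start/cycle-end $L^2$ residual is reported as `periodicity`
(typically < 1%). The waveform is interpolated to the solver grid with a
periodic cubic spline.

Two analytic oracles gate the solver. Steady tube flow at Re 30 must
reproduce the Poiseuille centerline $2Q/\pi R^2$ (observed +1.5% at base
size $D/8$); oscillatory tube flow at Womersley number
$\alpha = R\sqrt{\omega/\nu} \approx 2$ must match the analytic Womersley
profile (complex Bessel series, evaluated independently in the test) in
amplitude and phase (observed within ~2% and 0.005 rad). Both benchmarks
drive the tube with the same piston machinery used for the ventricles.

## Particle tracking and the mix-norm

Massless tracers are seeded on a cubic lattice anchored at the bounding-box
corner (`seed_particles()`; strictly interior points only) and advected
through the stored cycle, reused periodically, for 20 cardiac cycles —
`advect_particles()` uses RK4 with 2 substeps per stored phase and linear
time interpolation (periodic cubic optional). The desk-scale default
spacing is 0.5 mm (~20k tracers in the default geometry); 0.25 mm
reproduces the full-resolution protocol. Tracers crossing an outlet are
frozen there and marked exited — they never re-enter and count as outside
every evaluation subdomain; near-wall tracers use the containing element's
interpolant (no collision model; no-slip keeps those velocities small).
Integrator exactness for constant fields, closure of solid-body-rotation
orbits, forward/backward reversibility and local-density preservation under
divergence-free fields are all tested.

Mixing is quantified in the tight axis-aligned bounding box $\Gamma$ of the
aqueduct, partitioned at scales $i \in \{2,4,6,8,10\}$ into $i^3$ equal
subdomains $\Gamma_{i,j}$ (half-open binning, top faces closed). For each
subdomain, among the tracers whose *final* position lies inside, $N_b$
originated inside and $N_o$ outside, and the exchange ratio is

$$c_{i,j} = \frac{N_o}{N_b + N_o} \in [0, 1],$$

0 for empty subdomains (no evidence of exchange; a `drop` option excludes
them instead). The per-scale norm $m_i$ is the root mean square of the
$c_{i,j}$ over the $i^3$ subdomains and the aggregate mix-norm $m$ the RMS
of the five $m_i$, so $m$ runs from 0 (completely separated — a zero
velocity field gives exactly 0) to 1 (completely mixed — a uniform
reshuffle saturates it). A variant that takes plain roots of unnormalized
sums at both levels is retained behind `normalization = "printed"` for
comparison with the formula as sometimes typeset; it is not bounded by 1
and the RMS form is the default precisely because the index is described
as a [0,1] root mean square. A brute-force double-loop implementation
(`mix_norm_brute()`) serves as an independent oracle; the optimized path
must agree with it exactly on counts.

Whether exchange should be attributed to final-time occupants (as here) or
to initial residents is ambiguous in prose descriptions of such indices;
the occupant reading matches the $N_\mathrm{in}/N_\mathrm{out}$ definitions
and is the default, and the identity $m = 0$ for zero displacement holds
either way.

## Statistics layer

`mann_whitney()` implements the two-tailed rank-sum test: exact p-values by
full enumeration (subset-sum DP) for untied samples with $\min(n) \le 8$,
otherwise the normal approximation with midranks, tie-corrected variance
and continuity correction (verified against `wilcox.test` and by a type-I
error simulation at the cohort's $n = (19, 28)$). `fit_inverse()` fits
$U = a/D$ without intercept ($a = \sum U/D \big/ \sum 1/D^2$), reporting
$R^2$ against the mean baseline, which may legitimately be negative for the
iNPH group. `flag_outliers()` implements the literal quartile rule —
outside $[Q_1, Q_3]$, median-exclusive quartiles — with the conventional
1.5×IQR fence as an option, since the literal rule flags ~half of any
sample and is unusual. Age splits use the 65-year boundary (≥ 65 is
older). No multiple-testing correction is applied, mirroring the analysis
being reproduced; the report metadata says so.

`run_subject()`/`run_cohort()` orchestrate the chain with content-hash
caching and per-subject crash isolation; subjects whose four-section
consistency error exceeds 25% (strict) are excluded from cohort statistics
but retained in the exclusion log.

## Numerical choices and problem sizes

Defaults were chosen so a full single-subject chain (solve + track + mix)
runs in well under a minute and the three-level mesh-independency protocol
in a few minutes on one core: base size 0.7 mm (25k tetrahedra at
$D = 2.82$), 40 stored phases, 3 solver cycles, 20 tracking cycles, 0.5 mm
seeding. The acceptance script reports the medium-vs-fine relative
difference in peak area-averaged aqueduct velocity (observed well under the
5% the protocol requires; the quantity is strongly protected by mass
conservation, which is the point of the consistency check) and the
zero-field mix-norm (exactly 0).

## Known limitations

* The geometry is an axisymmetric idealization; real aqueducts are curved
  and asymmetric, which promotes secondary flows and mixing. Absolute
  mix-norm values from this pipeline should be compared across conditions,
  not interpreted as patient-level predictions.
* The distal chamber must be long enough that the outlet disks sit beyond
  the largest per-cycle tracer excursion (~$SV/A$, about 10 mm at Re ≈ 90):
  with a short fourth-ventricle segment the freeze-at-exit rule censors
  exactly the fast-core trajectories that carry the Lagrangian drift, and
  the measured mix-norm is biased downward at high stroke volumes — enough
  to mask the Re–mixing trend. The default template therefore uses a 14 mm
  fourth-ventricle segment; with it, mixing increases monotonically with Re
  over the 10–90 range (saturating near the top, where much of the box is
  fully exchanged). The trend's direction, not its slope, is what the
  qualitative check asserts.
* Fluid–structure interaction is out of scope: wall motion is prescribed,
  not computed, and only the lateral-ventricle wall moves.
* No respiratory forcing, beat-to-beat variability, or solute diffusion
  (tracers are strictly advective).
* The cohort generator draws independent marginals; published tables
  quantify no correlations (for example, age–ventricle-volume), so none are
  modeled.
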