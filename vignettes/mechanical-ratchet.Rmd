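---
title: "The mechanical ratchet of unilateral cytokinesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechanical ratchet of unilateral cytokinesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandratchet)
```

## The problem

Large yolk-rich embryonic cells, such as the first blastomere of the
zebrafish embryo, divide unilaterally: instead of a closed actomyosin ring,
an open-ended contractile band forms on one side of the cell and ingresses
into the cytoplasm. An open band under tension should collapse by pulling
its own ends together, so something must anchor it. The working model this
package implements is a *mechanical ratchet*: in interphase the bulk
cytoplasm — stiffened by cell-spanning microtubule asters — anchors the
band, which grows along the equator but barely ingresses; in M-phase the
asters disassemble, the cytoplasm fluidizes, and the band ingresses
rapidly while its unanchored ends retract. Alternating phases repeat until
division completes.

`bandratchet` packages the three quantitative pillars of that picture:

1. a spherical-mesh simulator of a growing contractile band in a
   viscoelastic cytoplasm (`build_mesh()`, `run_cycle()`);
2. the in vivo microrheology pipeline that produced the material
   parameters — magnetic-tweezers pulse analysis, creep-compliance
   machinery, and oscillatory-spectrum fits (`analyze_track()`,
   `fit_jeffreys()`, `creep_to_modulus()`, `fit_fractional_kv()`);
3. laser-ablation recoil and band-end kinematics (`fit_recoil()`,
   `detect_band_ends()`, `end_kinematics()`).

A seeded synthetic-data module generates every input these pipelines
consume, so the full analysis runs and is testable without any
experimental download.

## The cytoplasm as a Jeffreys material

All mechanics rest on the three-parameter Jeffreys model: a Kelvin–Voigt
unit (spring $k$ in parallel with dashpot $\gamma_1$) in series with a
second dashpot $\gamma_2$. It is the minimal model with both transient
elasticity (recovery after a force pulse) and long-time flow (no finite
equilibrium stiffness), which is what bead pulses in embryonic cytoplasm
show. Units are fixed as $k$ in pN/µm and $\gamma_{1,2}$ in pN·s/µm so
$k t/\gamma_1$ is dimensionless and $F_0/k$ is in µm; the measured
parameter values are then used verbatim. The phase-specific sets are
exposed as `interphase_params()` ($k=32.4$, $\gamma_1=56.1$,
$\gamma_2=189.8$) and `mphase_params()` ($k=21.4$, $\gamma_1=27.0$,
$\gamma_2=41.7$).

For a rectangular force pulse of amplitude $F_0$ and duration $t_p$, the
loading branch is $x(t) = \frac{F_0}{k}(1-e^{-kt/\gamma_1}) +
\frac{F_0 t}{\gamma_2}$ and the relaxation branch decays from $x(t_p)$
toward $(1-a)\,x(t_p)$, with the recovery fraction

$$a = 1-\frac{1}{1+\frac{\gamma_2}{k t_p}\left(1-e^{-k t_p/\gamma_1}\right)}.$$

One convention deserves a note: we write the relaxation branch as
$x(t_p)\left(a e^{-k(t-t_p)/\gamma_1} + (1-a)\right)$, with the clock
restarted at the pulse end and a plus sign on $(1-a)$. This is the unique
form that is continuous at $t=t_p$, decays to the unrecovered viscous
displacement, and is consistent with both the definition of $a$ and the
underlying spring–dashpot mechanics.

```{r recovery}
jeffreys_recovery(interphase_params(), tp = 5)
jeffreys_recovery(mphase_params(), tp = 5)
```

Interphase cytoplasm recovers about half of a 5-s pulse; M-phase less
than a third — the single most compact statement of the stiffness switch.

## The mesh simulator

The cell is a sphere of radius 350 µm whose edges are Jeffreys elements
obeying, per edge $i$ with strain $\epsilon_i = (l_i - l_{i,0})/l_{i,0}$,

$$\sigma_i+\frac{\gamma_1+\gamma_2}{k}\dot{\sigma_i}
  = \gamma_2\dot{\epsilon_i}+\frac{\gamma_1\gamma_2}{k}\ddot{\epsilon_i}.$$

The band is a line tension $\lambda_i = \Lambda p_i$ on equatorial edges,
where $p_i\in[0,1]$ is the fraction of edge $i$ covered. Each time step
(dt = 0.01 min) the band grows by $G = g\,\mathrm{d}t$ per arc
($g = 25$ µm/min) walking outward from the band centre along both
equatorial arcs — a covered edge is skipped, a partially coverable edge
absorbs what fits — and then the vertices are moved along their forces
$f_j = \sum_i (\sigma_i + \lambda_i)\hat{t}_i$ until the largest
per-vertex force is below $10^{-5}$. The discretized constitutive law is
solved explicitly for $\sigma_i(t_n)$; under constant strain the stress
decays by the factor $1 - k\,\mathrm{d}t/(\gamma_1+\gamma_2)$ per step, and
under steady strain rate it approaches the fluid stress
$\gamma_2\dot{\epsilon}$. Damping coefficients are converted from seconds
to minutes internally so that one unit system runs the discretization.

We read the growth budget as *per arc* (the growth procedure is applied
to the second arc in full, so total band length grows at $2g$ before
saturation); the budget-conservation invariant in the test suite pins
this reading.

### Mesh construction

Two requirements drive the geometry. First, the mesh must contain an
exact closed edge cycle in the symmetry plane — the "line of springs"
the band lives on. Second, the mesh must be *volumetric*: the Jeffreys
parameters are bulk cytoplasm moduli, and a hollow spring shell has soft
bending modes and no interior support, so a contractile band deforms it
in a qualitatively wrong way (we verified this: on a surface mesh the
band tears a discrete sawtooth furrow and the per-phase ingression rates
bear no resemblance to the measured ones, under either unit reading of
the damping coefficients).

The default `build_mesh(type = "ball")` therefore builds a deterministic
lattice ball: the vertices are the integer lattice points of the L1 ball
$|i|+|j|+|k| \le m$, connected along the three axis directions and the
twelve face diagonals (a rigid, fully triangulated lattice), then mapped
radially onto the Euclidean ball of radius $R$ by scaling each point by
its L1/L2 norm ratio. The map sends the lattice boundary exactly onto
the sphere, and the boundary cross-section in the $z=0$ plane is an
exact planar cycle of $4m$ edges — the equatorial spring ring. The mesh
is mirror-symmetric across that plane by construction, and $m$ is chosen
so the equatorial edge length is as close as possible to the target. At
the default 35 µm target this gives $m = 16$: 6,017 vertices and 49,248
edges, with the equator ring within 2% of $2\pi R$.

The corresponding hollow sphere is kept as `type = "shell"` (midpoint
subdivision of an octahedron, whose square equator stays a planar edge
cycle under subdivision; an icosahedron has none). It is used for cheap
geometric tests and for comparison, not for the physics.

### Numerical choices in the relaxation

Within one time step the stress history is frozen, so the discretized
constitutive law makes each edge stress *affine* in its current strain,
$\sigma_i = C\epsilon_i + h_i$, and the per-vertex forces are the exact
negative gradient of a scalar step energy. "Move along the forces until
the largest per-vertex force is below tol" is thus energy minimisation,
and two behaviours of the model drive how it is done:

* **Band edges collapse.** A covered edge carries a constant tension
  $\Lambda p_i$ while the Jeffreys material flows indefinitely, so edges
  near the band centre contract without bound — this is the model's own
  "band shortening", not an artifact. At zero length the edge direction
  loses smoothness, so all edge lengths enter the energy through the
  regularised form $\tilde l = \sqrt{l^2 + \delta^2}$ with
  $\delta = 10^{-2} l_0$ (and strain is measured from the regularised
  rest length, so the reference state is an exact equilibrium). Edges
  longer than a few percent of rest length are essentially untouched; an
  almost-collapsed edge exerts a force that fades linearly with its
  length, so coincident vertices sit in a genuine smooth equilibrium
  while band tension keeps transmitting through their other edges — the
  continuum picture of a band running through a point.
* **The landscape has soft modes.** A spring sphere mixes stiff
  stretching modes with nearly inextensional soft modes, and first-order
  descent (fixed-step steepest descent, Barzilai–Borwein steps, and the
  FIRE scheme were all tried) stalls far above the $10^{-5}$ force
  tolerance. The relaxation therefore takes damped Newton-CG steps:
  conjugate-gradient solves of the Newton system with analytic
  Hessian-vector products (exact for this energy), an Eisenstat–Walker
  forcing rule, fallback to the gradient direction on negative
  curvature, Armijo backtracking, and a hard cap — one tenth of the
  shortest rest length — on any per-vertex displacement per iteration.
  The move direction degenerates to the force whenever the Newton
  direction is unusable, and the converged state is the same energy
  minimum either way (zero net force on every vertex). Because the
  Newton step can be tiny relative to the total energy, the Armijo test
  uses an exact edge-wise closed form for the energy *difference* rather
  than subtracting two energy totals, which would lose the decrease to
  floating-point cancellation. Hard steps converge in tens of
  iterations; a full study cycle takes about three minutes.

Ingression is measured as the inward displacement of the band-centre
vertex along its initial outward normal, and the per-phase ingression
velocity is the least-squares slope of that displacement over the phase
window. The single free parameter $\Lambda$ is chosen by scanning
tensions and minimising the mean squared error against a target
displacement curve (`fit_band_tension()`); the study value is
$\Lambda = 1.5$.

At the study configuration (6,017 vertices, one 15 + 10 min cycle,
$\Lambda = 1.5$) the simulator's M-phase ingression slope is
9.95 µm/min, within 8% of the measured 10.80 µm/min, with the band
growing through interphase and shortening in M-phase — the ratchet
signature. The interphase slope extracted over the *single-run* phase
window is 1.42 µm/min, below the measured 2.43. The discrepancy is a
bookkeeping effect, not a material one: in a mixed run the band is far
longer during M-phase than on average during interphase, so the two
phase windows compare different loadings. Instantaneous ingression rates
at matched band lengths give a speed ratio of about 4.6 (close to
$\gamma_2^{I}/\gamma_2^{M} = 4.55$), and an all-interphase-material run
analysed over the same late window as the M-phase — matched loading —
gives 2.28 µm/min and a ratio of 4.36, reproducing the measured pair
(2.43, ratio ≈ 4.4) to within a few percent. The shipped defaults follow
the plain single-run protocol; `scripts/acceptance.R` recomputes both
single-run slopes from scratch.

## The magnetic-tweezers pipeline

Raw inputs are bead tracks (tracker-export CSV) plus a manifest of pulse
schedules and calibrations. The steps, each its own function:

* **Force calibration** (`fit_force_calibration()`): beads dragged
  through glycerol (η = 1.412 Pa·s at 20 °C) give instantaneous
  Stokes-drag forces $f = 6\pi\eta R v$; the (distance, force) cloud is
  fitted with $f(x)=a_1e^{-k_1x}+a_2e^{-k_2x}$, amplitudes constrained
  non-negative so the law is monotone.
* **Segmentation** (`segment_pulses()`): 5 s force, 15 s rest, tiled
  from the schedule start; partial trailing cycles dropped.
* **Drift correction** (`drift_correct()`): the slow cytoplasmic flow is
  fitted linearly on the last 5 s of the rest period preceding each
  pulse and subtracted. The first pulse has no preceding rest; we use
  the tail of its own following rest and flag the measurement. Because a
  Jeffreys material never relaxes *exactly*, this correction carries a
  small inherent bias (about 0.005 in recovery at the study
  parameters); the closure tests budget for it.
* **Per-pulse summaries** (`summarize_pulse()`): displacement at pulse
  end, recovery = relaxation/displacement, normalized displacement =
  displacement / mean force. Displacement is measured along the
  bead-to-tip axis (the force direction); pulses with non-positive
  displacement are flagged invalid. `filter_force_range()` keeps the
  20–60 pN band (inclusive) where both phases are well sampled.
* **Embryo averaging and statistics**: `embryo_average()` averages per
  embryo and phase with track counts as weights;
  `weighted_welch_ttest()` normalises weights to sum to the embryo count
  (reducing exactly to the ordinary Welch test under equal weights), and
  `weighted_bootstrap_mean()` resamples embryos with
  probability proportional to weight, 1,000 replicates, percentile 95%
  intervals, bit-reproducible under a fixed seed.

## Creep compliance and the complex modulus

The averaged pulse gives the creep compliance $J(t)=6\pi R\,x(t)/f(t)$
(µm²/pN is numerically 1/Pa). Its tail is fitted with the
phenomenological form $b + a t + c e^{-d t}$, giving the instantaneous
compliance $J(0)=b+c$ and steady-state viscosity $\eta = 1/a$. The
discrete direct conversion to $G^*(\omega)$ is

$$\frac{i\omega}{G^{*}(\omega)} = i\omega J(0)
 + \frac{(1-e^{-i\omega t_1})[J_1-J(0)]}{t_1}
 + \frac{e^{-i\omega t_N}}{\eta}
 + \sum_{k=2}^{N}\frac{J_k-J_{k-1}}{t_k-t_{k-1}}
   \left(e^{-i\omega t_{k-1}}-e^{-i\omega t_k}\right).$$

The sum treats $J$ as piecewise linear with a pure-fluid tail beyond
$t_N$, so it is reliable only for $\omega$ between roughly $2\pi/t_N$ and
$\pi/\Delta t$; `creep_to_modulus()` warns outside that window. Two
practical accuracy notes, both verified against the closed-form Jeffreys
modulus: the record must be long enough for the elastic transient to
decay (the tail term assumes $\dot J = 1/\eta$ beyond $t_N$), and when
$G''\gg G'$ the small storage modulus needs $\omega\,\Delta t \ll 1$ to
survive the cancellation. Within those limits agreement is well under 1%.

Oscillatory spectra are modelled as fractional Kelvin–Voigt,
$G^*(\omega)=c_\alpha(i\omega)^\alpha+c_\beta(i\omega)^\beta$ with
$0\le\alpha\le\beta\le1$. `fit_fractional_kv()` fits $\log G'$ and
$\log G''$ jointly with equal weight — the measured spectra span 3.5
decades (0.5–2,056 Hz), and log-space fitting keeps the decades balanced.
Phase contrast at low frequency is quantified by
`low_freq_fold_change()`: bootstrap over measurement resampling, mean
$G'$ (and $G''$) ratio over 0.5–16 Hz.

## Ablation and band kinematics

Severed band ends recoil as $y = A(1-e^{-x/x_0})+c$; the initial recoil
velocity $A/x_0$ is the band-tension proxy (`fit_recoil()`; the fit is
scale-equivariant, so the velocity inherits the recoil's units). Recoil
and healing are put on a common scale by min–max normalising the recoil
and dividing the between-ends grey value by its pre-cut reference.

Band-end kinematics start from PIV velocity fields aligned with the band
along the y axis: `band_axis_average()` averages within 25 µm of the
axis, `detect_band_ends()` takes the per-frame extrema of the along-band
speed (ties broken toward the previous frame's end for continuity), and
`end_kinematics()` decomposes end motion into contractile flow at the
ends plus band growth, `growth = end velocity − flow`, all oriented
outward. The outward sign of each end is taken from the sign of its mean
position — the speed-extremum label alone does not identify which side
an end is on when flows reverse between growth and retraction.
`retraction_velocity()` and `ingression_slope()` are the corresponding
slope estimators with their reported errors.

## What the synthetic data emulate — and what they do not

Every generator is seeded and emits its ground truth beside the data:

* `gen_bead_cohort()`: 8 embryos per phase, ~50 tracks per embryo, 8
  pulses per track (the study's cohort shape), force from the
  calibration law at the bead's distance, Jeffreys response by linear
  superposition of pulse responses (so viscous creep accumulates),
  Gaussian position noise (0.05 µm) and a slow per-track drift.
* `gen_glycerol_calibration()`: Stokes-drag tracks under the
  double-exponential tip law.
* `gen_recoil_traces()`, `gen_modulus_spectra()`,
  `gen_velocity_fields()`: saturating-exponential recoils, fractional-KV
  spectra with multiplicative noise, and two-bump flow fields with
  prescribed end trajectories.

Noise is additive Gaussian (multiplicative for spectra) at 5% of signal
range by default — a choice, since the measurements do not constrain the
noise family. What the generators deliberately do **not** emulate:
heterogeneity of the cytoplasm (one parameter set per phase), bead-size
and bead-surface variability, tracking outliers and gaps, force-law
miscalibration, or any imaging physics. Passing closure tests therefore
demonstrates that the pipeline recovers truth *under the model's own
assumptions*; they say nothing about model misspecification on real
embryos.

## Problem sizes and tolerances used by the tests

The unit suite runs coarse meshes (129-vertex balls and coarse shells,
2–4 simulated minutes) for qualitative invariants and the full
6,017-vertex, 25-minute configuration once for the headline slopes; the
latter dominates the suite's runtime. Fit round-trips are asserted at 1% on noiseless data and
10% at measurement-scale noise; the creep-to-modulus oracle equivalence
at 5% inside the resolvable band; budget conservation and force balance
at $10^{-9}$; bootstrap determinism bit-for-bit.

## Known limitations

* No membrane, cortex, or yolk mechanics; the cell is a bare spring
  mesh, and rest lengths never remodel (permanent deformation enters
  only through the $\gamma_2$ dashpot).
* The length regularisation $\delta = 10^{-2} l_0$ means a fully
  collapsed edge retains about 1% of its rest length; sub-percent band
  geometry near collapsed vertices is below the model's resolution.
* The force tolerance $10^{-5}$ is expressed in the simulation's
  internal stress units. For a volumetric spring ball the effective
  continuum stiffness and viscosity scale with the lattice spacing, so
  the *absolute* ingression slopes are resolution-dependent by
  construction: doubling the edge length to 70 µm under the full
  protocol moves (interphase, M-phase) from (1.42, 9.95) to
  (4.15, 12.93) µm/min — the published pair lies between the two
  resolutions. The single-run window-slope ratio inherits the loading
  confound described above and is not resolution-stable either (only
  the loading-matched instantaneous ratio is, at ≈ 4.6). The test
  suite *reports* this dependence and asserts the qualitative
  invariants (positive slopes, M-phase faster) at both resolutions; an
  absolute-slope stability bound would be meaningless for this mesh
  family.
* The pipeline consumes extracted traces and velocity fields; particle
  detection, PIV cross-correlation and kymograph segmentation are out of
  scope.
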