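---
title: "Two-phase coronary haemodynamics with a compliant two-layer wall: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase coronary haemodynamics with a compliant two-layer wall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemofsi)
```

# What the package models

Whole blood in medium-sized arteries is a dense suspension: roughly 45% of
its volume is red blood cells (RBCs) carried by plasma. `hemofsi` models a
coronary-artery segment with an Eulerian–Eulerian two-phase description —
plasma as a Newtonian continuous phase, RBCs as a granular solid phase closed
by the kinetic theory of granular flow (KTGF) — two-way coupled to a
two-layer viscohyperelastic vessel wall, and post-processes the wall shear
stress (WSS) field into the standard haemodynamic indices (TAWSS, OSI, a
low-shear vulnerability mask) and von Mises wall stress.  Single-phase
comparator modes (Newtonian, power-law, Quemada) run on the same numerical
machinery so that two-phase vs single-phase differences are attributable to
the blood model alone.

# The two-phase flow model

Each phase $i \in \{p, \mathrm{RBC}\}$ carries a volume fraction
$\epsilon_i$ (with $\epsilon_p + \epsilon_{RBC} = 1$), density $\rho_i$ and
velocity $\vec v_i$.  Mass and momentum balances per phase share one pressure
$P$ and exchange momentum through a drag coefficient $\beta$:

$$\rho_i \epsilon_i \frac{D\vec v_i}{Dt} =
  -\epsilon_i \nabla P + \nabla\!\cdot\!\bar{\bar\tau}_i
  + \beta (\vec v_j - \vec v_i) \;(-\nabla P_{RBC}\ \text{for the RBC phase}).$$

The RBC phase's stresses come from KTGF closures driven by the granular
temperature $\theta$ (m²/s²), a variance-like measure of RBC velocity
fluctuations:

* radial distribution at contact
  $g_0 = [1 - (\epsilon/\epsilon_{max})^{1/3}]^{-1}$ (packing limit
  $\epsilon_{max} = 0.7$);
* solids pressure
  $P_{RBC} = \epsilon\rho\theta + 2\rho(1+e)\epsilon^2 g_0 \theta$;
* bulk viscosity
  $\lambda_{RBC} = \tfrac43 \epsilon\rho d g_0 (1+e) \sqrt{\theta/\pi}$;
* shear viscosity: a collisional part $\propto \epsilon^2\sqrt\theta$ plus a
  kinetic part $\propto \sqrt\theta/g_0$ with the dense-correction bracket;
* Gidaspow drag: the Ergun form for $\epsilon_p \le 0.8$ and the Wen–Yu form
  (with $C_D = \frac{24}{\epsilon_p Re_p}[1 + 0.15(\epsilon_p Re_p)^{0.687}]$)
  above it.  The branch switch is a hard switch, faithful to the piecewise
  law; optional tanh blending over a configurable band is available.  At zero
  slip the Wen–Yu branch evaluates the analytic Stokes limit
  $\beta \to 18\epsilon\mu_p/d^2 \cdot \epsilon_p^{-2.65}$: the product
  $C_D\,|\Delta v|$ tends to a finite value, not zero, so the drag
  coefficient is continuous in the slip speed.
* The granular-temperature balance closes with the Lun dissipation
  $\gamma = 12(1-e^2) g_0 \rho \epsilon^2 \theta^{3/2}/(d\sqrt\pi)$, the
  Gidaspow conductivity $k_s$, and the interphase exchange
  $\Phi = -3\beta\theta$.  These three expressions are not tabulated with
  the rest of the closure set and are supplied from the standard
  Gidaspow/Lun forms.

Default material constants: plasma $\rho_p = 1003$ kg/m³,
$\mu_p = 10^{-3}$ Pa·s; RBCs $d = 8\,\mu$m, $\rho = 1096$ kg/m³, restitution
$e = 0.99999$, wall restitution $0.9999$, specularity $0.6$; patch
initialisation $\epsilon_{RBC} = 0.45$, $\theta = 10^{-4}$ m²/s².

## The desk-scale reduction

The reference formulation of this class of problem is a full 3D finite-volume
/ finite-element FSI solve on an image-derived geometry.  `hemofsi` instead
makes one central, deliberate reduction: **each centerline station carries a
radially resolved, locally fully developed axisymmetric profile**, and
stations are coupled axially only through conservation of the instantaneous
mixture flow rate (the inlet waveform times the inlet area).  The axial
pressure is assembled by integrating each station's pressure gradient from
the outlet anchor (8 kPa).  This is a lubrication-style approximation: it is
what makes the model run in seconds on one core, and it restricts validity
to gently varying lumens (a warning is issued when $|dR/dz| \ge 0.2$).
Consequences:

* no secondary or recirculating flows — post-stenotic separation, Dean
  vortices and bifurcation flows are outside the model;
* the flow is laminar.  Coronary Reynolds numbers in the demo conditions are
  a few hundred; a turbulence model would in any case be meaningless in a
  radially-1D profile solver;
* the inlet velocity profile shape is irrelevant: only the flow rate enters.

Radial RBC migration is modelled by a terminal-drift closure rather than a
full radial momentum equation: the radial balance between the granular
pressure gradient and drag gives a drift velocity
$u = -(\partial P_{RBC}/\partial r)/\beta$, which advects
$\epsilon_{RBC}$ in conservative upwind form (zero flux at axis and wall, so
the station's mean RBC fraction is conserved to rounding).  This is the
minimal mechanism that produces the Fåhræus–Lindqvist near-wall depletion
with the correct sign and localisation.

## Numerics

Cell-centered finite volumes on $[0, R]$ ($n_r = 24$ cells by default;
64 for the analytic-benchmark tests).  Interior fluxes use central
differences; the wall flux uses a second-order one-sided gradient that is
exact for quadratics, so steady Poiseuille flow under a prescribed pressure
gradient is reproduced to solver tolerance, and flow-rate-forced runs carry
only the $O(h^2)$ midpoint flux-quadrature bias ($h^2/2R^2 \approx 5\times
10^{-4}$ at $n_r = 32$), which converges away at second order.  Momentum is
advanced semi-implicitly: radial diffusion by backward Euler (a
Crank–Nicolson option exists and is used for the Womersley accuracy tests),
the drag exchange fully implicitly as a coupled $2n_r$ system (the drag is
numerically stiff: $\beta \sim 10^9$ kg m⁻³ s⁻¹ at 45% haematocrit and 8 µm
particles), and all nonlinear closures lagged one step.  Flow-rate forcing
exploits linearity: the step is solved for two right-hand sides (zero and
unit pressure gradient) and the exact gradient matching the target flux is
obtained from the affine relation.

The granular-temperature update is positivity preserving: production
($\epsilon\mu_{RBC}(\partial v/\partial r)^2 \ge 0$) is explicit, conduction
implicit, and both sinks (dissipation, exchange) implicit and linear in the
new $\theta$, so $\theta \ge 0$ cannot be violated; any rounding-level
negative values are clipped and counted.  The volume-fraction transport is
upwind with a CFL guard (error with a suggested time step if the drift would
violate it).

Wall boundary conditions: plasma no-slip; the RBC phase gets the
Johnson–Jackson partial-slip condition, in which the granular wall shear
balances the specularity-coefficient collision flux
$\frac{\pi\sqrt3}{6}\phi \frac{\epsilon}{\epsilon_{max}}\rho g_0
\sqrt\theta\, u_{slip}$, implemented as a Robin row of the implicit operator;
$\phi = 0$ recovers free slip and $\phi \to \infty$ no slip.  The
granular-temperature wall flux carries the matching slip production and the
$(1 - e_{wall}^2)$ inelastic wall dissipation.

## What the two-phase model does (and does not) predict here

With the tabulated constants, the interphase drag is so strong that the
exchange sink $\Phi = -3\beta\theta$ collapses the granular temperature to
$10^{-13}$–$10^{-8}$ m²/s² within milliseconds; the granular shear viscosity
is then far below the plasma viscosity, and the mixture's effective momentum
diffusivity is close to $\epsilon_p \mu_p \approx 5.5\times10^{-4}$ Pa·s.
Two consequences are worth stating plainly:

* two-phase wall shear is systematically **lower** than the single-phase
  comparators (power-law $\approx 2$–$4\times10^{-3}$ Pa·s at wall shear
  rates of a few hundred per second; Quemada higher still at 45%
  haematocrit).  This ordering — two-phase < power-law < Quemada at the
  stenosis throat, with a common argmax station — is the package's central
  comparative property and is asserted by the tests;
* near-wall RBC depletion is produced with the correct sign but small
  magnitude over three cardiac cycles, because the drift scales as
  $1/\beta$.  The depletion diagnostic therefore reports the *apparent
  suspension viscosity* of the local composition — the Quemada law evaluated
  at the local haematocrit and a fixed reference shear rate (100 s⁻¹ by
  default) — which is the quantity the Fåhræus–Lindqvist effect is phrased
  in.  The raw momentum-equation coefficient
  $\epsilon_p\mu_p + \epsilon\mu_{RBC}$ is also exposed
  (`mixture_viscosity()`); it *increases* slightly toward the wall under
  these closures (depletion raises $\epsilon_p$, wall-peaked $\theta$ raises
  $\mu_{RBC}$), which is a faithful property of the parameter set, not a
  bug.

# The inlet waveform

The inlet velocity is a truncated Fourier series
$V(t) = \alpha_0 + \sum_{n=1}^{11} \alpha_n\cos(2\pi nt/T)
+ \beta_n\sin(2\pi nt/T)$ with period $T = 1.4$ s (43 bpm).  `fit_fourier()`
performs a QR least-squares fit so digitised, non-uniformly sampled
waveforms are handled; `synthesize_coronary_waveform()` generates a
deterministic-for-seed stand-in with coronary character (brief systolic dip,
dominant diastolic hump), rescaled so the cycle mean and the pulsatility
index $(\max-\min)/\text{mean}$ are met exactly.  The synthetic waveform is
labelled as such; it claims no correspondence to any measured subject.

# The wall model

Each station's wall is two concentric layers (defaults 0.24 mm and 0.66 mm —
intima plus transition zone, and media plus adventitia).  Each layer is an
isotropic five-parameter Mooney–Rivlin solid,

$$W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) + C_{20}(\bar I_1 - 3)^2
 + C_{11}(\bar I_1 - 3)(\bar I_2 - 3) + C_{02}(\bar I_2 - 3)^2
 + \tfrac1d (J - 1)^2,$$

with the `holzapfel_lcx` preset constants (MPa): layer 1
$(-0.19, 2.03, 11.30, -0.19, 20.10)$, layer 2
$(-0.17, 0.21, 5.02, -1.88, 13.5)$, $d = 10^{-5}$ Pa⁻¹.  Individual
constants are negative — normal for fitted polynomial models — so
non-negativity of $W$ is *not* assumed; what is asserted (and tested) is the
physically required property that the tangent modulus is positive over
$\lambda \in [0.85, 1.3]$ for both layers.  Only $\bar I_2 = J^{-4/3} I_2$
is given explicitly in the source material for the isochoric invariants; the
standard $\bar I_1 = J^{-2/3} I_1$ completes the pair.  Stress evaluations
use exact incompressibility; the volumetric term is retained in
`strain_energy()` for completeness.

Viscoelasticity is a five-term Prony shear-relaxation series,
$G(t) = G_0[\alpha_\infty + \sum \alpha_i e^{-t/\tau_i}]$, with relative
moduli $(6.28\times10^{-13}, 0.53, 7.15\times10^{-15}, 0.47,
3.67\times10^{-16})$ and relaxation times $(10.906, 0.8558, 5.556, 27.358,
86.51)$ s.  The tabulated moduli sum to $1 + 6.4\times10^{-13}$, so
$\alpha_\infty = 1 - \sum\alpha_i$ — computed exactly at load and logged —
is essentially zero: the material is fully relaxing, which is physically odd
for an artery but is kept as given rather than overridden.  Two practical
consequences: the wall creeps under sustained load on the 1–90 s relaxation
time scales (visible as a slow cycle-to-cycle radius drift), and strict
steady-state cycle-identity checks must use the elastic mode.  The bulk
relaxation term is omitted throughout.  No separate instantaneous shear
modulus is tabulated, so $G_0 = 2(C_{10} + C_{01})$ per layer (the
Mooney–Rivlin tangent at the reference state); this is configurable.  The
hereditary integral is advanced by the per-term exponential recursion that
is exact for strain paths piecewise linear in time; a strain jump is applied
with `dt = 0`.

## Structural reduction

The 3D wall FEM is reduced to quasi-static thin-wall (Laplace-law) inflation:
both layers share the circumferential stretch $\lambda$ (bonded, thin-wall),
axial stretch fixed at 1, incompressibility giving $\lambda_r = 1/\lambda$.
Layer $k$ supports the pressure difference across it via
$\Delta p_k = S_k(\lambda)\,(t_k/\lambda)/(\lambda r_{k,0})$ with
$S_k = \sigma_\theta - \sigma_r = 2(\lambda^2 - \lambda^{-2})(W_1 + W_2)$;
the interlayer pressure is an internal unknown eliminated by summing the two
equilibria, and the stated muscular-tone tractions (3 kPa and 0.8 kPa) load
the outer surfaces of layers 1 and 2.  The scalar equilibrium is solved by
safeguarded bracketing (`uniroot`), with a diagnostic error if no root exists
in the expanded bracket.  Mid-wall radial stress is approximated as the mean
of the layer's surface pressures; principal stresses
$(\sigma_r, \sigma_\theta, \sigma_z)$ feed the von Mises formula.  Wall
inertia is neglected (quasi-static): the wall mass time scale is far below
the 7 ms step, and the pressure load dominates.  Residual stress / axial
pre-stretch are not modelled.

# Coupling and protocol

Partitioned two-way coupling per time step: fluid sweep at current radii →
station pressures (outlet anchored at 8 kPa) → wall response → under-relaxed
radius update (factor 0.7), iterated until the maximum relative radius change
drops below $10^{-4}$ (cap 50, divergence raises an error carrying the
residual trace).  Fluid states are re-stepped from the same start-of-step
state each subiteration; the wall's viscoelastic internal variables are
committed once, at convergence.  The coronary wall is stiff
(compliance $\sim 10^{-3}$ relative radius per 4 kPa), so the fixed point
contracts in one or two subiterations in practice.  Velocity profiles ride
on the normalised radial grid as the radius moves; the associated profile
rescaling is a second-order effect at these radius excursions.

The schedule matches the standard protocol: $\Delta t = 7$ ms, $T = 1.4$ s,
three cycles — 200 steps per cycle, 600 in total — with **only the final
cycle reported**, the first two serving to wash out initialisation (and to
build up an effective wall pre-stress).  Periodicity is logged as the
relative L2 difference of the wall-shear field between the last two cycles
(about $10^{-3}$ on the demo fixture, versus the 2% acceptance bound).
Systole/diastole snapshots are defined as the waveform argmax/argmin within
the final cycle, since no numeric snapshot instants are published.

# Indices

Over the last cycle, per station: $\mathrm{TAWSS} = \frac1T\int_0^T
|\tau|\,dt$ and $\mathrm{OSI} = \tfrac12(1 - |\int\tau\,dt| /
\int|\tau|\,dt)$, by trapezoidal quadrature on the saved grid.  In this
axisymmetric reduction the wall shear is a signed axial scalar, so the
vector integrals reduce exactly.  A station with identically zero shear gets
OSI = 0 by convention (logged).  Stations with TAWSS strictly below 0.4 Pa
are flagged atherosclerosis-prone; the threshold comparison is strict `<`,
so exactly 0.4 Pa is not flagged.  For the reference asymmetric square wave
(half-cycle $+A$, half-cycle $-A/2$) these definitions give
$\mathrm{OSI} = \tfrac12(1 - \frac{AT/4}{3AT/4}) = 1/3$, which the tests
assert against an independent piecewise integration.

# Synthetic data, problem sizes, and what passing tests show

The vessel generator produces straight, tapered, Gaussian-stenosis and
sinusoidal lumens at 2 mm station spacing; the shipped demo is a 20 mm
segment of 1.5 mm base radius with a 50% Gaussian stenosis ($\sigma$ = 4 mm,
keeping $|dR/dz| < 0.2$), driven by the synthetic waveform (mean 0.15 m/s,
pulsatility 1.2).  These are plausible coronary numbers chosen once, not
fits to any subject; together with the reduction above, passing tests
demonstrate the *constitutive fidelity, conservation structure, analytic
limits and comparative orderings* of the implementation — not agreement
with any patient-specific 3D computation, whose geometry, secondary flows
and absolute WSS magnitudes are outside this model class.  Default problem
sizes (radial resolution 24, 11 stations, 600 steps; benchmark runs at
$n_r$ = 16–64) were chosen so the full demo suite solves in minutes on one
core while keeping every reported property well inside its tolerance.

# Numerical choices and edge cases

* Strain-rate floor $10^{-6}$ s⁻¹ for the shear-thinning laws
  (configurable); Quemada errors out if $\tfrac12 k(\dot\gamma)H \ge 1$.
* The Picard iteration on shear-thinning viscosity stops at $10^{-10}$
  relative velocity change (cap 40).
* `eps_rbc` at or above the packing limit raises an error (the $g_0$
  closure diverges there); frictional closures beyond packing are out of
  scope.
* Gravity is off: the segment orientation is unspecified, and a body force
  would add an arbitrary hydrostatic tilt.
* Determinism: the solver contains no randomness; the only seeded component
  is the synthetic waveform generator, which restores the caller's RNG
  state.

# Known limitations

Beyond the reduction itself: no bifurcations (a bifurcation can be
approximated as independent runs with split flow), no centerline-curvature
dynamics, no imposed heart-motion wall displacement, no residual stress, a
single RBC size, no platelet/leukocyte phases, and index definitions
restricted to TAWSS/OSI (no RRT).  The Quemada parameter set
($k_0 = 4.33$, $k_\infty = 1.88$, $\dot\gamma_c = 1.82$ s⁻¹,
$\eta_p = 10^{-3}$ Pa·s) is the literature-standard calibration, supplied
because no specific values accompany the comparator description; it is
overridable in the configuration.
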