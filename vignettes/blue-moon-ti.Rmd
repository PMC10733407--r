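---
title: "Blue-moon thermodynamic integration on a toy branching active site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blue-moon thermodynamic integration on a toy branching active site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the constrained
free-energy machinery, the toy model it runs on, the estimator and
numerical choices, and what the tests do and do not establish.

## The observable and the estimator

The branching reaction is followed along a single reaction coordinate,
the difference of the breaking and forming P–O bond lengths at the
scissile phosphate, $\xi = d_2 - d_1$. The Helmholtz profile $F(\xi)$ is
reconstructed by blue-moon sampling: dynamics run under the holonomic
constraint $\sigma(\mathbf r) = (d_2 - d_1) - \xi = 0$, enforced by
SHAKE position projection plus RATTLE velocity projection, and the
Lagrange multiplier $\lambda$ is recorded every step. The mean force is

$$\frac{dF}{d\xi} \;=\;
\frac{\langle Z^{-1/2}(\lambda + k_BT\,\kappa)\rangle}
     {\langle Z^{-1/2}\rangle},
\qquad
Z = \sum_i \frac{1}{m_i}\Big|\frac{\partial\sigma}{\partial\mathbf r_i}\Big|^2,$$

where $\kappa$ is the geometric (Fixman) term assembled from the
constraint Hessian. For the three-atom difference constraint both $Z$
and $\kappa$ have closed forms in the two bond unit vectors and the
O–P–O angle; for a plain distance constraint $Z$ is constant and
$\kappa$ vanishes, so the correction is exactly the identity (a unit
test pins this). Profiles are obtained by trapezoid integration of the
mean force over the window grid — deliberately trapezoid only, matching
the protocol being reproduced — with window standard errors propagated
in quadrature from the gauge point,
$\sigma_F^2(\xi_k) = \sum_i (\Delta\xi_i/2)^2({SE}_i^2 + {SE}_{i+1}^2)$.

Conventions worth stating because the literature is inconsistent:

* **$\lambda$ bookkeeping.** Under velocity Verlet the position
  projection supplies only half of the constraint impulse; the recorded
  $\lambda$ is the *total* SHAKE + RATTLE impulse per step divided by
  $dt$, i.e. the coefficient of $\nabla\sigma$ in the applied force.
* **Sign.** The sign convention is fixed so that $dF/d\xi$ equals the
  window-averaged multiplier. It is validated by a zero-temperature
  test: a damped constrained system relaxes until $\lambda$ equals the
  analytic restoring force $\partial V/\partial\xi$ of the transversally
  relaxed potential.
* **Standard error.** The SE of a window mean uses the statistical
  inefficiency $g = (1+\phi)/(1-\phi)$ from the lag-1 autocorrelation
  $\phi$ of the retained multiplier series
  (${SE} = {SD}\sqrt{g/n}$). A naive ${SD}/\sqrt n$ and a plain
  ${SD}$ mode are available (`se_mode`), because the reference protocol
  states only that errors derive from the SD of the constraint force.
* **Convergence.** A window is flagged converged when every running
  mean over the second half of the retained series stays within
  0.5 kcal/mol/Å of the full retained mean — a flag, not a failure,
  since the reference protocol gives no criterion.
* **Correction policy.** The metric correction is always computed and
  reported, and applied by default (`correction = "apply"`); with
  `"report"` the raw mean force is integrated instead, reproducing the
  omit-after-checking behaviour. On every production window with a
  substantial mean force (|f| > 5 kcal/mol/Å) the correction is below
  0.3% here, consistent with the <1% observation that justified
  omitting it.

## The toy model

The reactive core is reduced to the three atoms that define $\xi$:
nucleophile O2', phosphorus, leaving O3'. They interact through an
analytic surface $V(d_1, d_2)$; everything else — the proton, both
Mg²⁺, the monovalent ion and the U6 ligand oxygens — are spectators
held by harmonic site restraints that do not depend on $\xi$ and
therefore cancel in free-energy differences. The reactant build places
the core at the equilibrated distances (forming bond 3.3 Å, breaking
bond 1.6 Å), the metal cluster at M1–M2 = 4.1 Å with the monovalent
site 4.3 / 6.2 Å from M2 / M1, Mg–ligand contacts at 2.0–2.3 Å and
K–ligand contacts at 2.8–3.4 Å; the lithium variant sits in binding
pose 1 (G52 + U80) at ~2 Å contacts.

$V$ is a sum of three anisotropic Gaussian wells (reactant,
phosphorane-like intermediate, product) written in the rotated
coordinates $(\xi, s{=}d_1{+}d_2)$, an $r^{-12}$ inner wall on each bond
length, a quadratic outer confinement standing in for the active-site
cage, and a one-dimensional *shaping term* $U(\xi)$ (tabulated cubic
Hermite, clamped outside its knots) discussed below. Because every term
seen by the reactive atoms depends on their Cartesian coordinates only
through $(d_1, d_2)$, integrating out the core's rotations and
translations leaves the configurational measure $d_1^2 d_2^2$ and the
exact profile is a one-dimensional quadrature:

$$F(\xi) = -k_BT \ln \int d_1^2\,(d_1{+}\xi)^2\,
e^{-V(d_1,\,d_1+\xi)/k_BT}\,dd_1 + \text{const}.$$

This oracle is evaluated by composite Simpson quadrature with interval
halving until the profile moves by less than 0.02 kcal/mol (the test
suite cross-checks it against adaptive quadrature), and the gauge fixes
the reactant-region minimum to zero.

## Calibration and why the shaping term exists

Calibration targets are the five profile features: the reactant at the
left grid edge, TS1 at $\xi = -0.4$ Å (stated for the first transition
state), the intermediate at $\xi = 0$ (where the bidirectional
sampling starts), TS2 at $\xi = +0.6$ Å (where the second proton
transfer occurs and sampling was extended), and the product near
$\xi = 1.4$ Å. Barrier heights and reaction free energies are the
reported values (K⁺: 13.6, ~2, −4.2 kcal/mol; Li⁺: 16.2, ~3.2,
−2.3 kcal/mol). The absolute level of the intermediate is not printed;
it is set so that the second barrier has its reported height while TS1
remains rate limiting.

A first stage adjusts basin depths, reaction-coordinate widths and the
interior basin centers by bounded Levenberg–Marquardt least squares on
the oracle features. A pure sum-of-wells landscape, however, cannot be
left there: with wells deep enough to carry a 13.6 kcal/mol barrier,
the profile maxima are near-cusps (the soft minimum of two steep well
walls, smoothed only over $\sim k_BT$), and the measurement protocol
itself — trapezoid integration on a 0.2 Å grid — under-resolves them by
up to >1 kcal/mol. That error is a property of the landscape, not of
the estimator. The second stage therefore exploits an exact identity:
any term of the potential that depends on the reactive atoms only
through $\xi$ shifts $F(\xi)$ by exactly that term. A designed curve
$F^*(\xi)$ is built whose node values and node derivatives satisfy the
trapezoid consistency relation $f_k + f_{k+1} = 2(F^*_{k+1}-F^*_k)/h$
on the sampling grid (so trapezoid integration of the exact mean force
reproduces the node free energies without discretisation bias), whose
interior feature nodes have near-symmetric neighbours (so three-point
parabolic refinement returns the feature values), and which is monotone
between extrema (verified against the Fritsch–Carlson bounds; the
construction is an equality-constrained linear least squares problem).
The shaping term $U = F^* - F_0$ then pins the profile to this curve.
The calibrated surfaces match all five features to better than
0.01 kcal/mol and the deterministic recovery error of the 16-window
protocol drops below 0.04 kcal/mol. The price is aesthetic: between
grid nodes the designed mean force can be lumpy (the product-side
descent concentrates into a steep drop near $\xi \approx 1$ Å), which
is physically unobjectionable and fully sampled.

Calibration is deterministic given the starting point, and idempotent:
a surface already matching the targets is returned unchanged.

## Sampling protocol and parameters

Units are Å, fs, amu, kcal/mol, K, with
$k_B = 0.0019872041$ kcal/(mol·K); temperature 300 K throughout.
Defaults follow the reference protocol: timestep 0.5 fs; 16 windows from
−1.4 to 1.6 Å in 0.2 Å steps, executed outward from $\xi = 0$ with each
window seeded from its neighbour's endpoint dragged at 0.003 Å/fs
(0.2 Å in 134 steps); 5 ps windows with a 2 ps equilibration discard
(7 ps / 4 ps at $\xi = \pm0.6$), which retains exactly 6000 steps per
default-protocol window. The thermostat is Langevin (friction 0.01 fs⁻¹) —
simpler than a rescaling thermostat and canonically correct for a toy
system; friction 0 gives NVE dynamics, under which the integrator's
energy drift is bounded by the symplectic test. Constraint tolerance is
10⁻⁸ Å with at most 500 projection iterations; every stored frame's
residual is checked. Each window draws from its own RNG stream derived
from (master seed, window index), so schedules are reproducible window
by window and across replicates.

Production runs (the analysis scripts and the acceptance recomputation)
use 12 ps windows — 20,000 retained steps after the 2 ps discard — and
three replicate seeds per ion, pooled per window with SEs combined in
quadrature. These sizes keep a full two-ion study around a minute on
one CPU while leaving the statistical error of every extracted feature
near 0.15–0.3 kcal/mol.

## Scripted trajectories: what they emulate

Classical dynamics on $V(d_1,d_2)$ cannot transfer protons or exchange
ion coordination; those observables are exercised on *scripted*
trajectories, a first-class fixture generator that realises a
frame-by-frame geometric script exactly (up to requested jitter on
atoms the script does not drive) and records the injected events as
ground truth: hydrogen-bond frames under the distance/angle criteria
(below 2.2 Å, within 180 ± 50°), the first sustained
closer-to-acceptor frame (dwell window, default 10 frames, to suppress
recrossing noise), sub-site occupancy for the lithium shuttling between
G52+U80 and A59+G60+U80, and scripted pair distances such as the
product-state M1–M2 opening to 4.4 Å. Every analysis operator is
required, by test, to reproduce the script metadata exactly. The
electric-field analysis is a bare-Coulomb sum with a uniform dielectric
(there is no solvent in the toy model) reporting field vectors at the
reactive atoms and signed projections onto the bond unit vectors.

What passing these tests shows is that the *operators* are correct —
counting, detection, classification, superposition and field algebra —
on geometry whose truth is known exactly. It does not show that the toy
model reproduces the conformational statistics of the real active
site: spectators are harmonically tethered, there is no solvent, no
electronic structure, and the proton chemistry is injected, not
emergent.

## Numerical details and degenerate inputs

* Quadrature: Simpson with halving, tolerance 0.02 kcal/mol;
  non-integrable surfaces (confinement off) raise a diagnostic.
* Feature extraction: grid extrema with parabolic refinement through
  each interior extremum's three points; edge minima are taken as-is;
  profiles with fewer than two maxima degrade gracefully to one-TS or
  minimum-only reports; features are invariant under an additive
  constant.
* Pose classification ties (both sub-sites within cutoff) go to the
  smaller mean ion–ligand distance and the frames are reported.
* Cutoffs: 2.5 Å (Li⁺) and 3.5 Å (K⁺) ion–ligand contact defaults.
* The temperature estimator uses equipartition over all momenta minus
  the single constraint.

## Known limitations

The model is a verification instrument, not a predictive one. The
profile between grid nodes is designed, so only node-level and feature
quantities are meaningful; the intermediate's absolute free energy is a
choice; the transverse geometry of the intermediate channel is looser
than the real phosphorane's 1.8 ± 0.1 Å bonds; partial charges are
nominal force-field-like values used only by the Coulomb surrogate; and
Li⁺/K⁺ differences in the monovalent pocket enter through calibration
targets and scripted observables rather than through ion–ligand
energetics.
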