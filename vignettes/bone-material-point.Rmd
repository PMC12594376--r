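---
title: "An orthotropic visco-plasto-damage material point for bone tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An orthotropic visco-plasto-damage material point for bone tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonevpd)
```

## The model

`bonevpd` simulates a single material point of bone tissue governed by a
small-strain orthotropic visco-plasto-damage constitutive law. Three
equations define the response:

* **Damaged elasticity.** Stress follows
  $\sigma = (1 - D(\kappa))\,\mathbb{S}\,(\varepsilon - \varepsilon^p)$,
  with $\mathbb{S}$ the orthotropic stiffness and $D \in [0,1)$ a scalar
  damage variable representing microcrack-induced stiffness loss.
* **Associated viscoplastic flow.**
  $\dot\varepsilon^p = \gamma\, \nabla_\sigma Y(\sigma, \kappa)$, where the
  consistency parameter follows the Perzyna form
  $\gamma = (Y^2 + mY)/\eta$: plastic flow accelerates with the overstress
  $Y > 0$ and is damped by the viscosity $\eta$.
* **A Tsai-Wu-type yield surface.**
  $Y(\sigma, \kappa) = \sqrt{(\sigma - r(\kappa) A) : \mathbb{A} :
  (\sigma - r(\kappa) A)} - r(\kappa)$, combining kinematic hardening (the
  centre $r A$ translates) and isotropic hardening/softening (the radius
  scales with $r$).

The internal variables are the plastic strain $\varepsilon^p$, the
accumulated plastic strain $\kappa = \int |\dot\varepsilon^p|\,d\tau$
(tensor norm, so engineering shear components enter with weight 1/2), and
the derived damage
$D(\kappa) = 1 - e^{-k_p(\kappa - k_0)}$ for $\kappa \ge k_0$, zero below
the activation threshold $k_0$.

The hardening function is
$r(\kappa) = 1 + (y_r - 1)(1 - e^{-s_h \kappa})$ up to the softening onset
$k_s$ and $r(k_s)\, e^{-s_s(\kappa - k_s)}$ beyond it, continuous at the
switch. The `"original"` mode keeps the monotone branch everywhere; the
`"softening"` mode (the default, and the calibrated behaviour for both
presets) reproduces the post-peak decay seen in compression tests on bone.

Inverting the Perzyna relation gives the overstress function
$\phi(\gamma) = -m/2 + \sqrt{m^2/4 + \eta\gamma}$ and the *generalized*
yield function $\bar Y = Y - \phi(\gamma)$, whose zero level set, together
with $\gamma \ge 0$ and $\gamma \bar Y = 0$, forms the generalized
Kuhn-Tucker conditions. Overstress is admissible transiently and decays at
fixed strain, which is the model's only relaxation mechanism: there is no
viscoelasticity, so an elastic state does not relax at all.

### Two conventions worth stating

*Square root in the yield function.* The quadric form of the criterion is
implemented under a square root, making $Y$ dimensionless, degree-1
homogeneous about the centre and directly comparable with $\phi(\gamma)$,
which carries the same dimension. Without the root the two sides of
$\bar Y = 0$ would have inconsistent dimensions.

*Voigt order and Poisson placement.* Vectors use the order
(11, 22, 33, 12, 23, 31) with engineering shear strains; the internal
stress unit is MPa (cortical moduli tabulated in GPa are converted when
the preset is loaded). The compliance couplings are $-\nu_{12}/E_1$,
$-\nu_{23}/E_2$ and $-\nu_{31}/E_1$: the 31-plane ratio is attached to the
stiff axis 1. Under this placement the condition $E_2 = E_3$,
$G_{12} = G_{31}$, $\nu_{12} = \nu_{31}$ — satisfied by both presets —
yields exact transverse isotropy about axis 1 ($C_{2222} = C_{3333}$),
which is the stated symmetry of the calibrated tissues; attaching
$\nu_{31}$ to $E_3$ instead would silently break it. The assembled
stiffness must be symmetric positive definite; inadmissible parameter sets
are rejected at construction with the offending eigenvalue.

### Construction of the yield tensors

The source model defines $A$ and $\mathbb{A}$ through a fabric-tensor
formulation whose full recipe is not reproduced here; `bonevpd` uses a
documented centred-quadric construction instead, validated by its
postcondition rather than trusted:

1. yield stresses from yield strains, $\sigma^+_{0i} = E_i\,\epsilon_0^+$
   and $\sigma^-_{0i} = E_i\,\epsilon_0^-$, and shear yield stresses
   $\tau_{0ij} = G_{ij}\sqrt{\epsilon_0^+\epsilon_0^-}$ (a geometric-mean
   stand-in: no shear yield strain is tabulated);
2. Tsai-Wu coefficients $F_i = 1/\sigma^+_{0i} - 1/\sigma^-_{0i}$,
   $F_{ii} = 1/(\sigma^+_{0i}\sigma^-_{0i})$, normal-normal interaction
   $F_{ij} = -\xi_0\sqrt{F_{ii}F_{jj}}$ and shear diagonal
   $1/\tau_{0ij}^2$;
3. conversion to centred form, $A = c = -\tfrac12 F^{-1}\vec F$ on the
   normal-stress subspace and $\mathbb{A} = F/(1 + c\!:\!F\!:\!c)$.

`build_yield_tensors()` verifies at construction that the surface passes
through all six uniaxial calibration states to within $10^{-8}$ and that
the quadric is convex (an over-strong $\xi_0$ is rejected). When the
fabric vectors differ from the global axes the tensors are assembled in
the material frame and mapped through the 6×6 stress rotation, so all
evaluations take global-frame stresses.

## Stress integration

`integrate_step()` is a strain-driven elastic-predictor/plastic-corrector
update. The elastic trial freezes the internal variables; if its yield
value is non-positive the trial is the answer. Otherwise Newton-Raphson
solves the 8-unknown system $x = [\sigma, \gamma, \kappa]$ with residual
blocks

* $\bar Y(\sigma, \kappa, \gamma) = 0$,
* $R = \mathbb{E}\sigma_t/(1 - D(\kappa_n)) -
  \mathbb{E}\sigma/(1 - D(\kappa)) - \Delta t\,\gamma\,\nabla_\sigma Y = 0$,
* $h = \kappa_n - \kappa + \Delta t\,\gamma\,|\nabla_\sigma Y| = 0$,

where $\mathbb{E}$ is the *undamaged compliance*, making $R$ a strain
residual — the unique reading under which the elastic trial zeroes $R$
exactly and the converged state satisfies the damaged-elastic law and the
flow rule simultaneously (both facts are asserted in the test suite).
Damage is evaluated at the unknown $\kappa$ inside the loop, consistent
with the coupling of current damage to current stress.

Numerical choices:

* Convergence requires the Euclidean norm of the stacked residual below
  `tol1 = 1e-6` *and* $|\bar Y|$ below `tol2 = 1e-8`. The norm (rather
  than the sum of squares) is the stricter reading and the standard one.
* The Jacobian is central finite differences with relative perturbation
  $10^{-7}$ by default; a closed-form Jacobian is available
  (`jacobian_mode = "analytic"`) and agrees with the differences to
  better than $10^{-5}$ relative, which the suite checks.
* Newton starts from the trial $x_0 = [\sigma_t, 0, \kappa_n]$;
  $d\phi/d\gamma$ is finite at $\gamma = 0$ ($\eta/m$), so no
  regularisation is needed. No line search; `max_iter = 50`.
* After both tolerances are met, one extra *polish* Newton step is taken
  (kept only if it reduces the residual). This drives the converged
  residual to near machine precision so that drivers which
  finite-difference the step response — the mixed-control uniaxial loop
  below — see a smooth function rather than solver truncation noise. The
  documented tolerances remain the contract.
* If Newton fails, the drivers bisect the strain increment (halving
  $\Delta t$ with it) up to 10 levels, preserving the step semantics while
  rescuing oversized increments.

## Test drivers

`run_strain_path()` integrates an explicit strain history.
`run_uniaxial()` ramps the axial strain while a 2-unknown Newton loop
(finite-difference Jacobian, reused across inner iterations) adjusts the
lateral normal strains until the transverse normal stresses vanish below
$10^{-6}$ MPa, reproducing the homogeneous core of a dumbbell or
cylindrical specimen; shear components stay identically zero. The
specimen tests behind the calibration are represented exactly this way;
converting imposed cross-head displacements to strains is left to the
user because gauge lengths are not part of the parameter tables.
`run_relaxation()` ramps and then holds the axial strain; the default hold
schedule coarsens from 10 s to 500 s out to $10^4$ s, mirroring the
variable stepping used for long relaxation analyses.

All drivers emit a `response_record` with one row per step (plus the
initial state): time, the six strains and stresses, $\kappa$, $D$, $Y$,
the regime, and the per-step solver diagnostics (iterations, residual,
$\gamma$, $\bar Y$).

Default problem sizes used throughout the package's own checks —
100–200 steps at $\Delta t = 0.01$ s for calibration-style ramps, a 100 s
ramp at $\Delta t = 1$ s for quasi-static comparisons, and $10^4$ s holds
for relaxation — are the sizes at which the documented behaviours
(softening peak, overstress decay, rate-limit agreement) are cleanly
resolved at material-point cost.

## Viscous calibration from relaxation curves

Experimental relaxation data for bone are mostly elastic-range, so the
viscous component is calibrated indirectly: normalized relaxation curves
are fitted with a power law $s(t) = a\,t^{-b}$ (ordinary least squares in
log-log space) and extrapolated to a $10^6$ s horizon; the percentage
reduction $100(1 - s(\text{horizon})/s(t_{\text{ref}}))$ is averaged over
the nine reference curves (27, 23, 24, 9, 3, 39, 62, 25, 7 percent),
rounded to the nearest whole percent — giving 24% — and applied as a
multiplicative factor of 0.24 to the tensile and compressive yield
strains. The scaled strains define the *equilibrium* yield surface, the
one approached under infinitely slow loading once all overstress has
relaxed; the unreduced calibrated strains play the role of the
instantaneous (fast-loading) limit curves.

Two caveats are deliberate. A pure power law has no finite nonzero
asymptote, so "asymptotic value" is operationalized as the value at the
conventional $10^6$ s horizon relative to the first sample time; the
prefactor cancels in the ratio. And one tabulated reduced value (the
cortical tensile strain, 0.00044) differs from the product
$0.0018 \times 0.24 = 0.000432$ in its last digit — a rounding whose
provenance is unclear — so `preset_parameters(reduced = TRUE)` transcribes
the tabulated number verbatim while `scale_yield_parameters()` computes
the product; the two are not forced to agree.

## Octree assignment of material axes

CT-derived orientation data arrive as a point cloud with an orthonormal
axis triad at every point, and each integration point of a mesh must
receive the triad of its nearest cloud point. `build_octree()` wraps the
cloud in its tight bounding cube and splits recursively into eight
congruent octants until each leaf holds at most `capacity` points.
Conventions: points exactly on a splitting plane go to the lower octant
(so every point is indexed exactly once); subdivision stops at depth 21
regardless, so duplicate-point clouds terminate; ties at exactly equal
query distance resolve to the smallest cloud index, and the brute-force
scan `brute_force_nearest()` — the correctness oracle the octree is tested
against — applies the same rule. The leaf capacity used in production runs
of the source workflow is not documented (the illustrative example uses
2), so it is exposed as a parameter with default 8. Search efficiency is
asserted by counting point-distance evaluations, never by wall-clock time.

Assigned triads are re-orthonormalized through the polar factor of the
SVD with handedness forced positive, and are carried as data: no
interpolation or averaging between neighbours, since the assignment is
defined as a single minimizer.

## Synthetic fixtures

Every input the tests and demos need is generated deterministically from
a seed: the two calibrated presets (shipped as YAML and transcribed from
the calibration tables), power-law relaxation series with known exponent
and multiplicative Gaussian noise, strain programs, and orientation
clouds over simple analytic solids (cylindrical shell, half-torus) whose
frame fields are known in closed form. The analytic fields are what makes
the 5-degree orientation-fidelity check meaningful: ground truth exists at
every query point. These fixtures do *not* emulate CT noise, resolution,
segmentation artefacts or anatomical geometry — passing the fidelity test
shows the nearest-neighbour machinery tracks a smooth field from a dense
cloud, not that CT-derived fields of real bones are this clean.
Likewise the material-point drivers exercise homogeneous states only;
stress gradients, contact and structural effects are outside the package's
scope by design.

## Known limitations

* Damage is scalar; anisotropic damage and damage-coupled softening are
  intentionally absent.
* Small-strain kinematics only; no algorithmic consistent tangent is
  exported (there is no FE assembly here).
* The model has no viscoelastic branch, so it cannot relax elastic
  stresses; its predictive window for relaxation is limited to the
  plastic overstress it stores.
* No bone remodelling or self-repair: damage only accumulates.
* The yield-tensor construction is a validated stand-in for the original
  fabric-tensor recipe; it reproduces the six uniaxial calibration states
  exactly and reduces to a centred ellipsoid for symmetric yield strains,
  but shear calibration rests on the geometric-mean rule.

## A worked step

```{r example}
params <- preset_parameters("cortical")
prog <- loading_program("uniaxial", axis = 1, amplitude = 0.004,
                        t_ramp = 1, dt_schedule = data.frame(until = 1, dt = 0.01))
rec <- run_uniaxial(prog, params)
summary_rows <- rec[c(2, 50, 101), c("t", "eps_11", "sig_11", "kappa", "D", "Y", "regime")]
print(summary_rows, digits = 4)
```

The run enters the plastic regime once the axial stress passes
$E_1 \epsilon_0^+ \approx 35.8$ MPa, accumulates plastic strain and a
small amount of damage, and carries a positive overstress while flowing —
the three signatures the test suite pins down quantitatively.
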