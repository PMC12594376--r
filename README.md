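# bonevpd

Material-point simulation of an orthotropic visco-plasto-damage
constitutive model for bone tissue, in R.

Bone responds to load with orthotropic (usually transversely isotropic)
elasticity, yields asymmetrically in tension and compression, hardens and
then softens as plastic strain accumulates, loses stiffness through
microcrack damage, and relaxes stress over time because plastic flow is
rate-dependent. Finite-element studies of bones and implants need a
constitutive point model that captures all of this *and* a way to orient
the material axes everywhere in a CT-derived geometry. `bonevpd`
implements both ingredients outside of any FE solver, for researchers in
computational biomechanics who want to calibrate, test and understand the
material model at a single point before (or instead of) embedding it in a
full simulation.

## The model

A single material point evolves under three coupled equations
(Voigt order 11, 22, 33, 12, 23, 31; engineering shear strains; MPa):

- damaged orthotropic elasticity
  `sigma = (1 - D(kappa)) * S * (eps - eps_p)`, with scalar damage
  `D = 1 - exp(-kp*(kappa - k0))` above the activation threshold `k0`;
- associated Perzyna viscoplasticity
  `deps_p/dt = gamma * dY/dsigma`, `gamma = (Y^2 + m*Y)/eta`;
- a Tsai-Wu-type yield surface
  `Y = sqrt((sigma - r*A) : AA : (sigma - r*A)) - r(kappa)` with kinematic
  hardening (centre `r*A`) and isotropic hardening/softening
  `r(kappa)` (saturating growth to `yr`, exponential decay past `ks`).

One time step is integrated by an elastic-predictor/plastic-corrector
return mapping: the 8-unknown system `[sigma, gamma, kappa]` is solved by
Newton-Raphson to a stacked-residual norm below `1e-6` and a generalized
yield residual below `1e-8`.

Around the point model the package provides:

- **drivers** — strain paths, mixed-control uniaxial tests (transverse
  stresses driven below `1e-6` MPa) and ramp-and-hold relaxation;
- **viscous calibration** — power-law fitting of normalized relaxation
  curves, extrapolated percentage reduction at a `1e6` s horizon, and
  scaling of the yield strains to their long-time equilibrium values;
- **octree axis assignment** — nearest-neighbour search over orientation
  point clouds with a brute-force oracle and triad re-orthonormalization;
- **calibrated presets** — `"cortical"` and `"trabecular"` parameter sets
  (YAML, transcribed from the published calibration), plus deterministic
  synthetic generators for every input the tests need.

## Worked example

```r
library(bonevpd)

params <- preset_parameters("cortical")
prog <- loading_program("uniaxial", axis = 1, amplitude = 0.004,
                        t_ramp = 1, dt_schedule = data.frame(until = 1, dt = 0.01))
rec <- run_uniaxial(prog, params)
rec[c(2, 50, 101), c("t", "eps_11", "sig_11", "kappa", "D", "Y", "regime")]
#>        t  eps_11 sig_11     kappa         D         Y  regime
#> 2   0.01 0.00004  0.796 0.0000000 0.000e+00 -0.047003 elastic
#> 50  0.49 0.00196 37.876 0.0001173 8.649e-05  0.002763 plastic
#> 101 1.00 0.00400 44.220 0.0035798 1.725e-02  0.004587 plastic
```

The point loads elastically at slope `E1 = 19900` MPa, yields once the
axial stress passes `E1 * eps0p = 35.8` MPa (the negative `Y` turns
positive: an overstress is being carried), then accumulates plastic strain
`kappa` and damage `D` while hardening towards 44 MPa at 0.4% strain.

The viscous calibration chain, on the nine published relaxation
reductions:

```r
frac <- mean_reduction(c(27, 23, 24, 9, 3, 39, 62, 25, 7))
frac
#> 0.24
scale_yield_parameters(params$yield, frac)$eps0m
#> 0.0036          # equilibrium compressive yield strain for cortical bone

fit <- fit_power_law(make_relaxation_series(a = 1, b = 0.05, n = 50,
                                            noise_sd = 0.01, seed = 42))
fit$b
#> 0.0511          # exponent recovered from 1%-noise data
stress_reduction(fit, t_ref = 1)
#> 50.66           # % reduction extrapolated to 1e6 s
```

And axis assignment from a synthetic cylindrical orientation field:

```r
cloud <- make_orientation_cloud("cylindrical", n = 5000, seed = 1)
queries <- make_orientation_cloud("cylindrical", n = 10, seed = 2)$points
asg <- assign_axes(queries, cloud, capacity = 8)
asg$source_index[1]; asg$distance[1]
#> 3890
#> 0.532           # mm to the nearest cloud point, whose triad is assigned
```

A thin command-line front end over the same functions lives at
`inst/cli/bonevpd` (subcommands `simulate-path`, `uniaxial`, `relax`,
`fit-relaxation`, `assign-axes`, `fixtures`).

The methods vignette (`vignettes/bone-material-point.Rmd`) documents the
model equations, the numerical choices in the return mapping and the
drivers, the yield-tensor construction, and the limitations of the
synthetic fixtures.

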