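# Shared fixtures for the suite. Presets are loaded once; small helper
# constructors keep individual tests terse.

cortical <- preset_parameters("cortical")
trabecular <- preset_parameters("trabecular")

# isotropic degenerate elastic set (E, nu) with consistent shear modulus
iso_elastic <- function(E = 10000, nu = 0.3) {
  G <- E / (2 * (1 + nu))
  elastic_parameters(E, E, E, nu, nu, nu, G, G, G)
}

# a tension-compression symmetric yield set (A = 0) on isotropic elasticity
symmetric_yield_case <- function(eps0 = 0.002, xi0 = 0) {
  ep <- iso_elastic()
  list(ep = ep,
       yt = build_yield_tensors(yield_parameters(eps0, eps0, xi0), ep))
}

# random rotation matrix (uniform-ish, det +1)
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

vl <- c("11", "22", "33", "12", "23", "31")  # Voigt component labels

# short uniform-dt uniaxial program
uniax_prog <- function(amplitude, t_ramp = 1, n = 100, axis = 1) {
  loading_program("uniaxial", axis = axis, amplitude = amplitude,
                  t_ramp = t_ramp,
                  dt_schedule = data.frame(until = t_ramp, dt = t_ramp / n))
}
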