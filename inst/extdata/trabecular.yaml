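# Calibrated material parameters for trabecular (human lumbar spine) bone.
# Elastic constants already in MPa.
tissue: trabecular
elastic:
  units: MPa
  E1: 280.0
  E2: 160.0
  E3: 160.0
  nu12: 0.22
  nu23: 0.48
  nu31: 0.22
  G12: 80.0
  G23: 60.0
  G31: 80.0
damage:
  kp: 5.0
  k0: 0.0001
hardening:
  yr: 5.5
  ks: 0.005
  sh: 20.0
  ss: 4.5
  mode: softening
viscosity:
  m: 5.0
  eta: 0.01
yield:
  eps0p: 0.005
  eps0m: 0.0075
  xi0: 0.25
  m1: [1.0, 0.0, 0.0]
  m2: [0.0, 1.0, 0.0]
  m3: [0.0, 0.0, 1.0]
# Equilibrium (long-time) yield strains after viscous reduction.
reduced_yield:
  eps0p: 0.0012
  eps0m: 0.0018
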