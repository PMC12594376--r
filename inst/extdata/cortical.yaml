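# Calibrated material parameters for cortical (bovine femoral) bone.
# Elastic constants in GPa (converted to MPa at load time).
tissue: cortical
elastic:
  units: GPa
  E1: 19.9
  E2: 11.2
  E3: 11.2
  nu12: 0.3
  nu23: 0.4
  nu31: 0.3
  G12: 5.7
  G23: 4.3
  G31: 5.7
damage:
  kp: 5.0
  k0: 0.0001
hardening:
  yr: 5.0
  ks: 0.01
  sh: 10.5
  ss: 1.5
  mode: softening
viscosity:
  m: 5.0
  eta: 0.01
yield:
  eps0p: 0.0018
  eps0m: 0.015
  xi0: 0.25
  m1: [1.0, 0.0, 0.0]
  m2: [0.0, 1.0, 0.0]
  m3: [0.0, 0.0, 1.0]
# Equilibrium (long-time) yield strains after viscous reduction.
reduced_yield:
  eps0p: 0.00044
  eps0m: 0.0036
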