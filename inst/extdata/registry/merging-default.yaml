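model: merging
entry: merging-default
description: >
  Default parameter set for the simplified merging-pathway model under
  antithetic feedback regulation.  All amounts are molecules per cell, time
  in minutes.  Values are package defaults calibrated so that the closed
  loop reaches a steady product level and partially recovers after a 60%
  step reduction of the secondary substrate.
units:
  K_S1: molecules/min
  kcat: 1/min
  Km_S1: molecules
  Km_S2: molecules
  S2_level: molecules
  CN: copies
  a0: molecules/min/copy
  a1: molecules/min/copy
  kd20: molecules
  k_sigma: molecules/min/copy
  gamma: 1/(molecules*min)
  k_asigma: molecules/min/copy
  kdp: molecules
  TF_total: molecules
  d_E: 1/min
  d_sigma: 1/min
  d_asigma: 1/min
  mu: 1/min
  Xmax: cells
params:
  K_S1: 1.0e+4
  kcat: 10.0
  Km_S1: 1.0e+5
  Km_S2: 1.0e+4
  S2_level: 1.0e+4
  CN: 10.0
  a0: 0.0
  a1: 125.0
  kd20: 2.25e+5
  k_sigma: 800.0
  gamma: 1.0e-3
  k_asigma: 1100.0
  kdp: 300.0
  TF_total: 1.0e+4
  d_E: 0.02
  d_sigma: 0.01
  d_asigma: 0.01
  mu: 0.0075
  Xmax: 1.0e+9
initial_state:
  S1: 0.0
  P: 0.0
  E: 0.0
  sigma: 0.0
  asigma: 0.0
  X: 1.0e+7
protocol:
  t_end: 7800.0
  t_pert: 3900.0
  target: S2_level
  reduction: 0.6
  n_points: 1041
mop:
  target_titer: 6.0
  K: 1.0e-5
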