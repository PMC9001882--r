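model: naringenin
entry: naringenin-default
description: >
  Default parameter set for the naringenin pathway with the extended
  kaempferol/QdoR biosensor, the realistic antithetic controller and the
  AHL/LuxR reference input.  All amounts are molecules per cell (Ae is
  molecules in the external volume), time in minutes.  Values are package
  defaults calibrated so that the closed loop approaches the 1 g/L titer
  target and shows the characteristic post-perturbation response (sigma
  rises, CHS transiently increases, naringenin partially recovers) after a
  60% reduction in malonyl-CoA availability at 65 h.
units:
  metabolic:
    K_Lt: molecules/min
    kcat_TAL: 1/min
    kcat_4CL: 1/min
    kcat_CHS: 1/min
    kcat_CHI: 1/min
    kcat_F3H: 1/min
    kcat_FLS: 1/min
    Km_Lt: molecules
    Km_pC: molecules
    Km_pA: molecules
    Km_Ma: molecules
    Km_Nc: molecules
    Km_N: molecules
    Km_Di: molecules
    TAL: molecules
    FCL: molecules
    CHI: molecules
    F3H: molecules
    FLS: molecules
    Ma_level: molecules
  biosensor:
    pQ: 1/min
    kQ: 1/min
    dmQ: 1/min
    dQ: 1/min
    kdq: molecules
    kdk: molecules
    CN: copies
  controller:
    p_sigma: 1/min
    k_sigma_n: 1/min
    dm_sigma: 1/min
    d_sigma: 1/min
    alpha: fraction
    kdlux: molecules
    kd2: molecules
    kdc: molecules
    k_minus_c: 1/min
    d_c: 1/min
    p_asigma: 1/min
    CN_asigma: copies
    k_asigma_n: 1/min
    dm_asigma: 1/min
    d_asigma: 1/min
  actuator:
    beta: fraction
    p_Hc: 1/min
    p_H: 1/min
    CN_h: copies
    k_H: 1/min
    dm_H: 1/min
    d_H: 1/min
    kd20_n: molecules
    kd_sigma: molecules
  ahl:
    p_R: 1/min
    k_R: 1/min
    dm_R: 1/min
    d_R: 1/min
    D: 1/min
    Vcell: L
    Vext: L
    d_A: 1/min
    d_Ae: 1/min
    Ae_dose: molecules
  global:
    mu: 1/min
    xmax: cells
    mw: g/mol
    Av: 1/mol
params:
  metabolic:
    K_Lt: 2.0e+6
    kcat_TAL: 100.0
    kcat_4CL: 100.0
    kcat_CHS: 200.0
    kcat_CHI: 100.0
    kcat_F3H: 10.0
    kcat_FLS: 10.0
    Km_Lt: 1.0e+6
    Km_pC: 1.0e+6
    Km_pA: 1.0e+6
    Km_Ma: 1.3e+4
    Km_Nc: 1.0e+6
    Km_N: 5.0e+8
    Km_Di: 2.0e+7
    TAL: 1.0e+5
    FCL: 1.0e+5
    CHI: 1.0e+5
    F3H: 3.9e+5
    FLS: 2.0e+5
    Ma_level: 1.3e+4
  biosensor:
    pQ: 0.5
    kQ: 3.0
    dmQ: 0.14
    dQ: 0.01
    kdq: 100.0
    kdk: 1.6e+8
    CN: 10.0
  controller:
    p_sigma: 5.0
    k_sigma_n: 5.0
    dm_sigma: 0.14
    d_sigma: 0.01
    alpha: 0.05
    kdlux: 1.5e+3
    kd2: 1.5e+3
    kdc: 100.0
    k_minus_c: 2.0
    d_c: 0.001
    p_asigma: 5.0
    CN_asigma: 5.0
    k_asigma_n: 9.0
    dm_asigma: 0.14
    d_asigma: 0.01
  actuator:
    beta: 0.1
    p_Hc: 5.0
    p_H: 5.0
    CN_h: 5.0
    k_H: 6.0
    dm_H: 0.14
    d_H: 0.005
    kd20_n: 100.0
    kd_sigma: 6.4e+5
  ahl:
    p_R: 0.5
    k_R: 3.0
    dm_R: 0.14
    d_R: 0.01
    D: 2.0
    Vcell: 1.1e-15
    Vext: 1.0
    d_A: 0.001
    d_Ae: 1.0e-4
    Ae_dose: 1.2e+18
  global:
    mu: 0.0115
    xmax: 2.0e+13
    mw: 272.25
    Av: 6.02214076e+23
initial_state:
  Lt: 0.0
  pC: 0.0
  pA: 0.0
  Nc: 0.0
  "N": 0.0   # quoted: bare N is YAML for false
  Di: 0.0
  Ka: 0.0
  Q: 0.0
  sigma: 0.0
  asigma: 0.0
  complex_sa: 0.0
  CHS: 0.0
  R: 0.0
  A: 0.0
  Ae: 1.2e+18
  x: 2.0e+11
protocol:
  t_end: 7800.0
  t_pert: 3900.0
  target: Ma_level
  reduction: 0.6
  n_points: 1041
mop:
  target_titer: 1.0
  sigma_min_uM: 4.5
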