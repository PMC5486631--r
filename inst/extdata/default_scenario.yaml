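geometry:
  liver_diameter: 0.1
  liver_height: 0.1
  tumor_diameter: 0.01
  needle_diameter: 0.001
  electrode_spacing: 0.0054
  active_length: 0.006
  tumor_center:
  - 0.0
  - 0.0
  - 0.0
materials:
  liver:
    rho: 1080.0
    cp: 3540.0
    k: 0.52
    sigma_base: 0.067
    sigma_porated: 0.241
    omega_b: 0.0005
    q_met: 4200.0
  tumor:
    rho: 1220.0
    cp: 4180.0
    k: 0.6
    sigma_base: 0.135
    sigma_porated: 0.426
    omega_b: 0.002
    q_met: 42000.0
  electrode:
    rho: 7010.0
    cp: 450.0
    k: 18.0
    sigma_base: 100000000.0
    sigma_porated: 100000000.0
    omega_b: 0.0
    q_met: 0.0
  insulation:
    rho: 6450.0
    cp: 840.0
    k: 0.026
    sigma_base: 1.0e-05
    sigma_porated: 1.0e-05
    omega_b: 0.0
    q_met: 0.0
blood:
  rho_b: 1000.0
  c_b: 4200.0
  t_b: 37.0
protocol:
  voltage: 4000.0
  pulse_width: 500.0
  rep_rate: 1000.0
  burst_length: 100.0
  burst_rate: 1.0
  n_bursts: 1
conductivity:
  e_threshold: 80000.0
  alpha: 0.015
  t_ref: 37.0
solver:
  fine_h: 0.0003
  tumor_h: 0.001
  coarse_h: 0.0035
  fine_margin: 0.0012
  grade_ratio: 1.5
  dt_burst: 1.0e-08
  dt_cool: 0.001
  t_end: 1.0
  cg_tol: 1.0e-08
  cg_maxit: 50000.0
  refresh_dT: 1.0
  porate_maxit: 50.0
  macro_stride: 1.0e-06
  printed_perfusion_sign: no
initial_temperature: 37.0

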