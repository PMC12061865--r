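# Default parameter configuration: published values in printed units.
# Time constants in ms; gamma in its per-ms convention; Vmax in nM/s;
# currents in nA; concentrations in nM. The loader converts to the internal
# seconds-based frame.
pfc:
  I_thr_E: 0.4
  I_thr_I: 0.286
  g_E: 310.0
  g_I: 615.0
  d_E: 0.16
  d_I: 0.087
  J_NMDA: 0.15
  J: 1.135
  w_plus: 1.4
  W_E: 1.0
  W_I: 0.7
  W5HT_E: 0.48
  W5HT_I: 0.47
  R: 0.6
  Io: 0.32
  tau_NMDA_ms: 100.0
  tau_GABA_ms: 10.0
  gamma_per_ms: 0.000641
  C_in: 0.01
scc:
  I_thr_E: 0.4
  I_thr_I: 0.286
  g_E: 310.0
  g_I: 615.0
  d_E: 0.16
  d_I: 0.087
  J_NMDA: 0.33
  J: 1.135
  w_plus: 1.4
  W_E: 1.0
  W_I: 0.8
  W5HT_E: 0.19
  W5HT_I: 0.19
  R: 0.6
  Io: 0.45
  tau_NMDA_ms: 100.0
  tau_GABA_ms: 10.0
  gamma_per_ms: 0.000641
  C_in: 0.005
serotonin:
  alpha: 5.0
  C_BR: 15.0
  Vmax: 1300.0
  Km: 170.0
  tau_5HT_ms: 120.0
  J_5HT: 1.0
  beta: 0.008
  c1_pfc: 5.0
  c1_scc: 4.0
  m: 2.0
  c2: 0.019
inflammation:
  degree: 1.0
  B: 1.0
simulation:
  dt_ms: 0.1
  duration_s: 7.0
  transient_s: 1.0
  sigma: 0.01
  n_reps: 100
  base_seed: 42
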