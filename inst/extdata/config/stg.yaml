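# Study conditions for the STG model: sampling ranges (axis maxima of the
# published conductance-space scatter plots; CaT and leak ranges are not
# printed anywhere and are package choices), electrophysiological acceptance
# windows for the bursting phenotype, DIC generation targets and
# neuromodulation states (calibrated against the bundled kinetics).
model: STG
ranges:
  Na: [0.0, 8000.0]
  Kd: [0.0, 350.0]
  CaT: [0.0, 12.0]      # assumed (not printed)
  A: [0.0, 600.0]
  CaS: [0.0, 50.0]
  KCa: [0.0, 250.0]
  H: [0.0, 0.7]
  leak: [0.003, 0.02]   # assumed (not printed)
acceptance:
  pattern: bursting
  peak_V: [0.0, 200.0]
  hyperpol_V: [-90.0, -50.0]
  spikes_per_burst: [3.0, 10.0]
  interburst_freq: [0.5, 3.0]
  burstiness: [0.5, 1.0]
simulation:
  duration: 8000.0
  transient: 2000.0
dic:
  Vth: -51.0
  targets: {gf: 0.0, gs: -7.0, gu: 1.0}     # calibrated: regular burster
  solve_channels: [Na, CaS, H]
neuromodulation:
  pair: [A, CaS]
  # calibrated slow-DIC targets per neuromodulated state (gu kept per member)
  states: {spiking: -3.0, light_bursting: -9.0, strong_bursting: -14.0}
analysis:
  V_ref: -70.0
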