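# Study conditions for the DA model: sampling ranges (axis maxima of the
# published conductance-space scatter plots; the Na range is not printed and
# is a package choice), acceptance windows for the slow-tonic phenotype, DIC
# generation targets and neuromodulation states (calibrated against the
# bundled kinetics).
model: DA
ranges:
  Na: [0.0, 60.0]       # assumed (not printed)
  Kd: [0.0, 20.0]
  CaL: [0.0, 0.1]
  CaN: [0.0, 0.12]
  ERG: [0.0, 0.25]
  leak: [0.003, 0.02]
acceptance:
  pattern: tonic
  peak_V: [0.0, 200.0]
  hyperpol_V: [-100.0, -50.0]
  spike_freq: [0.5, 8.0]
simulation:
  duration: 12000.0
  transient: 4000.0
dic:
  Vth: -66.0
  targets: {gf: 0.0, gs: -0.05, gu: 0.5}    # calibrated: slow tonic spiking
  solve_channels: [Na, CaL, ERG]
neuromodulation:
  pair: [CaL, CaN]
  states: {spiking: -0.05, light_bursting: -0.085, strong_bursting: -0.12}
analysis:
  V_ref: -80.0
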