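# Midbrain dopaminergic (DA) neuron model, SK current blocked.
# RECONSTRUCTION: a single-compartment model with the channel complement,
# timescale roles and conductance magnitudes of the adapted DA pacemaker
# models used in the dynamic-input-conductance literature (fast Na and
# delayed-rectifier spike currents, subthreshold L- and N-type calcium
# currents providing slow positive feedback, an ultraslowly activating
# ERG potassium current, and an NMDA current kept at a fixed baseline and
# excluded from the conductance-space analysis). Gating curves are
# parameterized here from the dopaminergic pacemaker modelling literature
# rather than copied verbatim from a single source; the file is therefore a
# synthetic transcription calibrated so that mid-range conductances produce
# slow tonic spiking and an increased slow DIC produces bursting.
# Units: mS/cm2, mV, ms, uA/cm2.
name: DA
capacitance: 1.0
leak:
  E: -55.0
dic_references:
  fast: Na.m
  slow: Kd.m
  ultraslow: max
excluded_from_analysis: [NMDA]
excluded_baseline:
  NMDA: 0.01
channels:
  - name: Na
    a: 3
    b: 1
    E: 60.0
    m_inf:  {form: boltz,  p: [30.0, -9.7]}
    tau_m:  {form: sigtau, p: [0.05, 0.9, 30.0, 10.0]}
    h_inf:  {form: boltz,  p: [54.0, 10.8]}
    tau_h:  {form: sigtau, p: [0.4, 15.0, 40.0, 7.0]}
  - name: Kd
    a: 4
    b: 0
    E: -85.0
    m_inf:  {form: boltz,  p: [25.0, -12.0]}
    tau_m:  {form: sigtau, p: [0.5, 6.0, 38.0, 10.0]}
  - name: CaL
    a: 2
    b: 1
    E: 60.0
    m_inf:  {form: boltz,  p: [50.0, -4.0]}
    tau_m:  {form: sigtau, p: [30.0, 40.0, 45.0, 5.0]}
    # slow calcium/voltage-dependent inactivation at depolarized potentials
    h_inf:  {form: boltz,  p: [45.0, 7.0]}
    tau_h:  {form: sigtau, p: [200.0, 300.0, 40.0, -8.0]}
  - name: CaN
    a: 1
    b: 1
    E: 60.0
    m_inf:  {form: boltz,  p: [30.0, -7.0]}
    tau_m:  {form: sigtau, p: [20.0, 30.0, 40.0, 5.0]}
    # ultraslow calcium/voltage-dependent inactivation
    h_inf:  {form: boltz,  p: [60.0, 6.0]}
    tau_h:  {form: sigtau, p: [800.0, 1200.0, 55.0, -10.0]}
  - name: ERG
    a: 1
    b: 0
    E: -85.0
    m_inf:  {form: boltz,  p: [40.0, -6.0]}
    tau_m:  {form: sigtau, p: [300.0, 2500.0, 40.0, 8.0]}
  - name: NMDA
    a: 1
    b: 0
    E: 0.0
    instantaneous: true
    # magnesium block 1/(1 + [Mg]/3.57 * exp(-0.062 V)) at [Mg] = 1.4 mM,
    # rewritten as a Boltzmann curve
    m_inf:  {form: boltz,  p: [15.1, -16.129]}
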