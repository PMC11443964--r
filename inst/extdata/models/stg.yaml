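# Isolated crab stomatogastric-ganglion (STG) neuron model.
# Single-compartment model with seven voltage/calcium-gated channels plus leak,
# transcribed from the classic Liu/Golowasch/Abbott/Marder model family
# (gating tables in density units: mS/cm2, mV, ms, uA/cm2, uM).
# Curve forms:
#   boltz:     1 / (1 + exp((V + p1)/p2))
#   sigtau:    p1 + p2 / (1 + exp((V + p3)/p4))
#   dblexptau: p1 + p2 / (exp((V + p3)/p4) + exp((V + p5)/p6))
#   prodtau:   (p1 / (1 + exp((V + p2)/p3))) * (p4 + p5 / (1 + exp((V + p6)/p7)))
name: STG
capacitance: 1.0
leak:
  E: -50.0
calcium:
  # tau_Ca * dCa/dt = -f * (I_CaT + I_CaS) - Ca + ca_rest   (Ca in uM)
  tau: 200.0
  f: 9.4
  ca_rest: 0.05
  reversal:
    # E_Ca = coef * ln(ca_out / Ca)  (Nernst, divalent)
    coef: 12.199
    ca_out: 3000.0
dic_references:
  fast: Na.m
  slow: Kd.m
  ultraslow: max
channels:
  - name: Na
    a: 3
    b: 1
    E: 50.0
    m_inf:  {form: boltz,  p: [25.5, -5.29]}
    tau_m:  {form: sigtau, p: [1.32, -1.26, 120.0, -25.0]}
    h_inf:  {form: boltz,  p: [48.9, 5.18]}
    tau_h:  {form: prodtau, p: [0.67, 62.9, -10.0, 1.5, 1.0, 34.9, 3.6]}
  - name: Kd
    a: 4
    b: 0
    E: -80.0
    m_inf:  {form: boltz,  p: [12.3, -11.8]}
    tau_m:  {form: sigtau, p: [7.2, -6.4, 28.3, -19.2]}
  - name: CaT
    a: 3
    b: 1
    E: calcium
    calcium_source: true
    m_inf:  {form: boltz,  p: [27.1, -7.2]}
    tau_m:  {form: sigtau, p: [21.7, -21.3, 68.1, -20.5]}
    h_inf:  {form: boltz,  p: [32.1, 5.5]}
    tau_h:  {form: sigtau, p: [105.0, -89.8, 55.0, -16.9]}
  - name: A
    a: 3
    b: 1
    E: -80.0
    m_inf:  {form: boltz,  p: [27.2, -8.7]}
    tau_m:  {form: sigtau, p: [11.6, -10.4, 32.9, -15.2]}
    h_inf:  {form: boltz,  p: [56.9, 4.9]}
    tau_h:  {form: sigtau, p: [38.6, -29.2, 38.9, -26.5]}
  - name: CaS
    a: 3
    b: 1
    E: calcium
    calcium_source: true
    m_inf:  {form: boltz,  p: [33.0, -8.1]}
    tau_m:  {form: dblexptau, p: [1.4, 7.0, 27.0, 10.0, 70.0, -13.0]}
    h_inf:  {form: boltz,  p: [60.0, 6.2]}
    tau_h:  {form: dblexptau, p: [60.0, 150.0, 55.0, 9.0, 65.0, -16.0]}
  - name: KCa
    a: 4
    b: 0
    E: -80.0
    # m_inf is multiplied by Ca / (Ca + ca_half)
    ca_half: 3.0
    m_inf:  {form: boltz,  p: [28.3, -12.6]}
    tau_m:  {form: sigtau, p: [90.3, -75.1, 46.0, -22.7]}
  - name: H
    a: 1
    b: 0
    E: -20.0
    m_inf:  {form: boltz,  p: [75.0, 5.5]}
    tau_m:  {form: dblexptau, p: [0.0, 2.0, 169.7, -11.6, -26.7, 14.3]}
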