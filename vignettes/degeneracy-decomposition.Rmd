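---
title: "Decomposing conductance-space degeneracy: models, conventions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing conductance-space degeneracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the membrane model
and its assumptions, the dynamic-input-conductance (DIC) machinery, the
population generators and the study conditions they encode, the numerical
conventions, and — importantly — what the pipeline does and does not
establish about real neurons.

## The membrane model

Both bundled models are single-compartment conductance-based models,

$$C\dot V = -\sum_{ion}\bar g_{ion}\, m_{ion}^a h_{ion}^b\,(V-E_{ion})
  - g_{leak}(V-E_{leak}) + I_{ext},$$

with first-order gating kinetics
$\tau_x(V)\,\dot x = x_\infty(V)-x$. Units are mS/cm², mV, ms, µA/cm²,
µF/cm² and µM throughout. Kinetics are declarative: each steady-state and
time-constant curve is one of a small family of closed parametric forms
(Boltzmann sigmoids, sigmoid and double-exponential time constants, one
product form) stored in a YAML model-definition file; the same encoding is
interpreted by the compiled right-hand side used for integration, so R and
C share a single source of kinetic truth.

* **STG** — the classic isolated crab stomatogastric neuron model with
  channels Na, Kd, CaT, A, CaS, KCa, H plus leak (analysis dimension
  N = 8). Intracellular calcium follows
  $\tau_{Ca}\dot{[Ca]} = -f\,(I_{CaT}+I_{CaS}) - [Ca] + Ca_0$
  with $\tau_{Ca}=200$ ms, $f=9.4\ \mu M/( \mu A\,cm^{-2})$,
  $Ca_0=0.05\ \mu M$; the calcium reversal is Nernstian with
  $[Ca]_{out}=3$ mM. KCa activation is multiplied by $[Ca]/([Ca]+3\,\mu M)$.
* **DA** — a midbrain dopaminergic pacemaker with analysis channels Na, Kd,
  CaL, CaN, ERG plus leak (N = 6) and an NMDA current held at a fixed
  baseline (0.01 mS/cm², an assumed value) that is simulated but excluded
  from the conductance-space analysis. **Provenance caveat:** the DA
  kinetics file is a *reconstruction*, not a verbatim transcription of a
  single published table. It preserves the channel complement, the
  timescale roles (fast Na/Kd spike machinery; slow subthreshold L- and
  N-type calcium providing slow positive feedback; ultraslowly activating
  ERG), and the published conductance magnitudes, and it was calibrated
  once so that mid-range conductances produce slow tonic spiking
  (0.5–8 Hz) with bursting reachable through the slow DIC. Three
  reconstruction choices deserve mention because they were forced by the
  dynamics rather than free: CaN carries ultraslow inactivation (without a
  restorative ultraslow component the two-conductance neuromodulation
  solve for (CaL, CaN) at fixed ultraslow DIC is structurally infeasible),
  CaL carries slow inactivation at depolarized potentials (otherwise
  strong slow feedback creates a depolarization-block fixed point), and
  the delayed rectifier is comparatively fast (a slow Kd produces a deep
  after-hyperpolarization that prevents burst grouping).

Simulations use `deSolve::lsoda` (stiff-capable, variable step) on the
compiled right-hand side with `rtol = 1e-6`, `atol = 1e-8`, output every
0.05 ms, gating initialized at steady state for $V_0=-65$ mV, a discarded
transient (default 2 s), and integration restarts at current-step
discontinuities. Identical inputs give identical traces.

## Firing metrics

Spikes are upward crossings of 0 mV with a 2 ms refractory minimum. Bursts
are groups separated by interspike intervals longer than 3× the median ISI.
Burstiness is `1 - n_bursts/n_spikes` when the split produces genuine
groups and 0 otherwise — 0 for a regular tonic train, approaching 1 as
spikes concentrate into few bursts. This is a deliberately simple,
configurable metric chosen to be monotone in spike grouping; it is not a
transcription of any published burstiness formula. Patterns are classified
silent / tonic / bursting / irregular (tonic requires ISI CV ≤ 0.5).

## Dynamic input conductances

The sensitivity matrix is built gate by gate. At voltage $V$, channel $j$
contributes its instantaneous steady-state conductance
$m_\infty^a h_\infty^b$ to the fast row, and each of its gating variables
$x$ contributes $w_{i,x}(V)\,\frac{\partial I_j}{\partial x}\,
\frac{dx_\infty}{dV}$ to row $i$, everything evaluated at the frozen
steady state for $V$ and divided by $g_{leak}$. Positive entries are
restorative (negative feedback). The leak column carries only its passive
fast term, so a fully passive membrane has DICs exactly $(1,0,0)$.
Channels excluded from the analysis (NMDA) do not enter the DIC map at
all — the linear system lives on the analysis conductances only, which is
what makes it exactly linear and scale-invariant.

The timescale weights $w_{i,x}(V)$ form a partition of unity per gate,
interpolating linearly in $\log\tau$ between three voltage-dependent
reference timescales: the fast sodium activation time constant, the
delayed-rectifier activation time constant, and the slowest gating time
constant in the model. Gates at or below the fast reference get $(1,0,0)$,
at or above the ultraslow reference $(0,0,1)$; instantaneous gates are
fast by definition. The references are configuration points of the model
file (`dic_references`).

The threshold voltage is the subthreshold zero crossing of $g_f(V)$,
located by coarse bracketing on a 1 mV grid and bisection to $10^{-6}$ mV.
`compensate()` solves the 3-unknown (generation) or 2-unknown
(neuromodulation) subsystem of $S(V_{th})\cdot\bar g = targets$, guards the
subsystem condition number ($<10^8$), and reports negative solutions as a
rejection signal rather than an error.

**Frozen-calcium convention.** In the STG model the gating steady states
entering $S$ depend on the calcium steady state, which itself depends on
$\bar g_{CaT}, \bar g_{CaS}$ — strictly, the DIC map is only *affinely*
linear. All population-level solves therefore freeze the calcium state at
the value a reference neuron attains at the population threshold voltage
(recorded in population provenance). Under this convention the linear
system is exactly linear: generated members meet their targets to solver
precision, scaling-only subsets are exactly proportional, and
neuromodulatory paths are exactly collinear. Simulation always uses free
calcium. Without freezing, `compensate()` iterates the solve to a fixed
point of the self-consistent calcium state.

## Population generators: the study conditions

The generators are the package's synthetic-data source; their defaults
*are* the study conditions and live in `inst/extdata/config/{stg,da}.yaml`.

* **Sampling ranges** are the published conductance-space axis maxima
  (STG: Na 8000, Kd 350, A 600, CaS 50, KCa 250, H 0.7; DA: Kd 20,
  CaL 0.1, CaN 0.12, ERG 0.25, leak up to 0.02 mS/cm²). Values with no
  published anchor are package choices, marked `assumed` in the config:
  STG CaT ∈ [0, 12] and leak ∈ [0.003, 0.02]; DA Na ∈ [0, 60]. The leak
  floor is positive because DIC values are leak-normalized.
* **Acceptance windows** (random sampling post-processing) are package
  choices fixed once from a candidate survey, since no numeric windows are
  published: STG bursting with peak > 0 mV, trough in [−90, −50] mV,
  3–10 spikes/burst, burst cycle 0.5–3 Hz, burstiness ≥ 0.5 (≈5%
  acceptance); DA slow tonic spiking at 0.5–8 Hz with peak > 0 mV and
  trough < −50 mV (≈20% acceptance).
* **DIC generation targets**, calibrated once against each model's
  accepted random members: STG $(g_f,g_s,g_u)(V_{th}{=}-51) = (0,-7,1)$
  (bursting); DA $(0,-0.05,0.5)$ at $V_{th}=-66$ (tonic, at the spiking
  edge so that neuromodulation can move members into bursting). Solved
  channels are one per timescale: STG (Na, CaS, H); DA (Na, CaL, ERG).
  Imposing $g_f(V_{th})=0$ makes the chosen voltage the threshold by
  construction. Free conductances are drawn uniformly and multiplied by
  `gleak / mean(gleak range)`, which couples homogeneous scaling into the
  set exactly as the slow/ultraslow structure couples conductance ratios.
* **Neuromodulation states** (slow-DIC targets at threshold, ultraslow
  kept per member) were placed by simulating modulated members across a
  target sweep and reading off the spiking-to-bursting transition:
  STG spiking −3, light bursting −9, strong bursting −14; DA −0.05,
  −0.085, −0.12. The DA transition is narrow, so its three states are
  close together and the attained patterns remain mixed across members;
  the STG states separate cleanly in median burstiness.
* `V_ref` for input-resistance work is −70 mV (STG) and −80 mV (DA; at
  −70 the NMDA negative-slope region renders some members' input
  conductance non-positive, and such members are excluded with a log
  message rather than imputed).

## Neuromodulation rule

For each member the threshold is recomputed, the member's own ultraslow
DIC value is read out, and the two modulated conductances are re-solved so
the slow DIC reaches the state target with the ultraslow DIC unchanged.
Along a *continuous path* the threshold is kept at the neuron's initial
value, which makes the path exactly linear in the modulated-pair plane —
the neuromodulation direction is constant along a path and varies only
between neurons. Re-solving the pair from a scaling-only population is an
exact multiplicative rule (a rotation of the cloud); from a ratio-only
population it is an exact additive rule (a translation): both follow
directly from the linearity of the frozen system, and `classify_rule()`
recovers them at numerical precision.

## Analysis conventions

PCA is centered covariance PCA on raw conductances (all coordinates share
mS/cm² units; variable scaling is exposed but off by default), with loading
signs fixed so the largest-magnitude entry is positive. The
homogeneous-scaling direction is the unit vector from the origin to the
population mean — the total-least-squares direction without intercept.
Alignment is the absolute cosine, invariant to loading sign. Correlation
graphs drop edges with |r| below 1/N and never impute undefined
correlations.

A consequence of the covariance convention deserves emphasis: the bundled
kinetics put the sampled conductances on wildly different scales (Na up to
8000 vs H up to 0.7 mS/cm²), so the raw covariance spectrum is dominated
by the sodium axis and PC1 captures ~99% of the variance in the
random-sampling populations, with a PC1/scaling alignment near 0.99 for
the STG set. Published analyses of this kind report a PC1 share near 40%
and alignments of 0.8–0.9, which implies some per-channel normalization
before the decomposition; we evaluated correlation-matrix, range-box and
log-conductance variants and none reproduces all of the published summary
statistics at once under this package's kinetics, so the package keeps the
unambiguous covariance convention and documents the discrepancy rather
than tuning a convention to the numbers.

## What the generators emulate — and what they do not

The random-sampling generator emulates the field's standard "sample
uniformly, keep what matches the phenotype" construction; the
DIC-constrained generator emulates the fast constructive alternative whose
members share threshold DIC values exactly. Neither emulates biological
channel-expression noise, homeostatic regulation dynamics, temperature or
neuromodulator fluctuations, or measurement error; passing tests therefore
show that the *geometric decomposition* (scaling vs ratio variability and
its interference) behaves as designed, not that real neurons are sampled
this way. DIC equality at one voltage does not pin down the full dynamics:
a minority of generated members express patterns other than the targeted
one, which is visible in `spot_check_population()` output and strongest in
the DA model.

## Known limitations

* The DA model is a calibrated reconstruction (above); quantities that
  depend on its exact kinetics — state correlations in particular — carry
  that uncertainty. Orderings (the rise of r(CaL, CaN) toward zero with
  burstiness) are robust across seeds; the values scatter by ~±0.1 at
  n = 500.
* In the STG model, homogeneous scaling is not an exact symmetry of the
  dynamics: calcium influx scales with the conductances, shifting the
  Nernst calcium reversal by $\approx 12.2\,\ln\alpha$ mV and saturating
  KCa activation. Doubling all conductances preserves burst metrics and
  halves the input resistance; a tenfold scaling halves $R_{in}$ tenfold
  but silences most bursters (2 of 16 survive in a generated set), so the
  textbook scaling-invariance picture holds only locally.
* With this package's honestly pattern-calibrated states, the STG pair
  correlation r(A, CaS) *falls monotonically* from spiking (0.99) through
  light (0.93) to strong bursting (0.86); the published rise-then-fall
  ordering would require a "spiking" state on the far side of the
  alignment peak, where most members are silent rather than spiking.
* The fixed NMDA baseline in the DA membrane (excluded from the analysis
  space) makes the input conductance an affine, not linear, function of
  the analysis conductances: Rin normalization collapses DA scaling-only
  subsets only approximately (~20%), and the normalized-data TLS
  directions align with the secondary PCs at ~0.8 rather than >0.9
  (STG: >0.99).

## Problem sizes and numerical tolerances

The test suite and the acceptance script use random-sampling populations
of n = 100 per model (a size at which the PCA and alignment summaries are
stable to a few percent) and DIC-constrained populations of n = 500, the
dataset size used for the published figures. Linear-algebra invariants are
asserted at solver precision (1e-8 or better), finite-difference oracles
at 1e-4 relative, phenotype-level properties at the tolerances stated in
the tests. The compensation condition-number guard (1e8), threshold
bisection tolerance (1e-6 mV), and integrator tolerances (1e-6/1e-8) are
package defaults chosen for headroom, not tuned quantities.
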