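# Shared fixtures: memoized models/populations (expensive objects built once
# per test run) and programmatic toy model-definition files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

get_model <- function(name) memo(paste0("model_", name), build_model(name))

get_dic_pop <- function(name, n = 60, seed = 101)
  memo(sprintf("dicpop_%s_%d_%d", name, n, seed),
       generate_dic_population(get_model(name), n = n, seed = seed))

get_scaling_pop <- function(name, n = 15, seed = 51)
  memo(sprintf("scal_%s_%d_%d", name, n, seed),
       scaling_only_subset(get_model(name), n = n, seed = seed))

get_ratio_pop <- function(name, n = 40, seed = 61)
  memo(sprintf("ratio_%s_%d_%d", name, n, seed),
       ratio_only_subset(get_model(name), n = n, seed = seed))

# Toy model with constant gating time constants at 1 / 10 / 100 ms plus a
# probe gate at the log-midpoint of fast and slow, and a channel pair (S, Q)
# with identical kinetics (equal slow sensitivities). Used for exact weight
# and zero-sensitivity-direction arithmetic.
toy_timescale_model <- function() memo("toy_ts", {
  path <- file.path(tempdir(), "toy_timescales.yaml")
  writeLines(c(
    "name: TOY",
    "capacitance: 1.0",
    "leak: {E: -50.0}",
    "dic_references: {fast: F.m, slow: S.m, ultraslow: U.m}",
    "channels:",
    "  - name: F",
    "    a: 1",
    "    E: 50.0",
    "    m_inf:  {form: boltz, p: [40.0, -5.0]}",
    "    tau_m:  {form: const, p: [1.0]}",
    "  - name: S",
    "    a: 1",
    "    E: -80.0",
    "    m_inf:  {form: boltz, p: [30.0, -9.0]}",
    "    tau_m:  {form: const, p: [10.0]}",
    "  - name: Q",
    "    a: 1",
    "    E: -80.0",
    "    m_inf:  {form: boltz, p: [30.0, -9.0]}",
    "    tau_m:  {form: const, p: [10.0]}",
    "  - name: U",
    "    a: 1",
    "    E: -80.0",
    "    m_inf:  {form: boltz, p: [35.0, -7.0]}",
    "    tau_m:  {form: const, p: [100.0]}",
    sprintf("  - name: P"),
    "    a: 1",
    "    E: -80.0",
    "    m_inf:  {form: boltz, p: [30.0, -9.0]}",
    sprintf("    tau_m:  {form: const, p: [%.17g]}", sqrt(10))
  ), path)
  build_model(path)
})

# Minimal two-coordinate model (one gated channel + leak) for geometry toys.
toy_plane_model <- function() memo("toy_plane", {
  path <- file.path(tempdir(), "toy_plane.yaml")
  writeLines(c(
    "name: PLANE",
    "capacitance: 1.0",
    "leak: {E: -60.0}",
    "dic_references: {fast: A.m, slow: A.m, ultraslow: max}",
    "channels:",
    "  - name: A",
    "    a: 1",
    "    E: 50.0",
    "    m_inf:  {form: boltz, p: [40.0, -5.0]}",
    "    tau_m:  {form: const, p: [1.0]}"
  ), path)
  build_model(path)
})

toy_plane_population <- function(mat) {
  m <- toy_plane_model()
  condegen:::new_population(m, mat, list(generator = "manual"))
}

zeroed_conductances <- function(model, leak = 0.01) {
  g <- setNames(numeric(length(model$analysis_channels)),
                model$analysis_channels)
  g["leak"] <- leak
  structure(g, class = "cond_vector")
}

scale_vector <- function(g, a) structure(a * unclass(g),
                                         class = "cond_vector")

# Random-sampling study populations shared by the acceptance checks
# (reduced n = 100, fixed seed; the expensive objects of the suite).
get_random_pop <- function(name, n = 100, seed = 1)
  memo(sprintf("rand_%s_%d_%d", name, n, seed),
       sample_random_population(get_model(name), n = n, seed = seed))
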