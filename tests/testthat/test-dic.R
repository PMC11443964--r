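test_that("timescale weights form a log-linear partition of unity", {
  toy <- toy_timescale_model()
  tw <- timescale_weights(toy, -50)
  expect_equal(unname(tw$refs), c(1, 10, 100))
  # gate at the fast reference, at the ultraslow reference, at the midpoint
  expect_equal(unname(tw$w[, "F.m"]), c(1, 0, 0))
  expect_equal(unname(tw$w[, "U.m"]), c(0, 0, 1))
  expect_equal(unname(tw$w[, "P.m"]), c(0.5, 0.5, 0), tolerance = 1e-9)
  expect_equal(unname(tw$w[, "S.m"]), c(0, 1, 0))

  # partition of unity across random voltages in both real models
  set.seed(1)
  for (mn in c("STG", "DA"))
    for (V in runif(6, -80, -20)) {
      w <- timescale_weights(get_model(mn), V)$w
      expect_equal(unname(colSums(w)), rep(1, ncol(w)), tolerance = 1e-12)
      expect_true(all(w >= 0 & w <= 1))
    }
})

test_that("non-monotone reference timescales are rejected", {
  path <- file.path(tempdir(), "bad_refs.yaml")
  writeLines(c(
    "name: BADREFS", "capacitance: 1.0", "leak: {E: -50.0}",
    "dic_references: {fast: S.m, slow: F.m, ultraslow: max}",
    "channels:",
    "  - name: F", "    a: 1", "    E: 50.0",
    "    m_inf:  {form: boltz, p: [40.0, -5.0]}",
    "    tau_m:  {form: const, p: [1.0]}",
    "  - name: S", "    a: 1", "    E: -80.0",
    "    m_inf:  {form: boltz, p: [30.0, -9.0]}",
    "    tau_m:  {form: const, p: [10.0]}"
  ), path)
  expect_error(timescale_weights(build_model(path), -50),
               "tau_f < tau_s < tau_u")
})

test_that("sensitivity columns match finite differences of the DIC map", {
  for (mn in c("STG", "DA")) {
    model <- get_model(mn)
    g <- if (mn == "STG") stg_reference_neuron() else da_reference_neuron()
    ca <- if (mn == "STG")
      condegen:::population_ca_ref(model, -50) else NULL
    S <- sensitivity_matrix(model, g, -50, Ca = ca)
    for (ch in setdiff(colnames(S), "leak")) {
      h <- 1e-5 * max(g[[ch]], 1)
      g1 <- g; g1[ch] <- g1[ch] + h
      g2 <- g; g2[ch] <- g2[ch] - h
      fd <- (dic_at(model, g1, -50, Ca = ca) -
               dic_at(model, g2, -50, Ca = ca)) / (2 * h)
      expect_equal(unname(fd), unname(S[, ch]), tolerance = 1e-4,
                   label = paste(mn, ch))
    }
    # leak contributes exactly its passive term to the fast row
    expect_equal(S["fast", "leak"] * g[["leak"]], 1)
    expect_equal(unname(S[c("slow", "ultraslow"), "leak"]), c(0, 0))
  }
})

test_that("DIC values are linear in the conductances and scale-invariant", {
  stg <- get_model("STG")
  g <- stg_reference_neuron()
  ca <- condegen:::population_ca_ref(stg, -50)

  # all gated conductances zero: purely passive fast DIC of exactly 1
  expect_equal(unname(dic_at(stg, zeroed_conductances(stg), -50)),
               c(1, 0, 0), tolerance = 1e-12)

  # matrix-vector identity
  S <- sensitivity_matrix(stg, g, -50, Ca = ca)
  expect_equal(unname(dic_at(stg, g, -50, Ca = ca)),
               unname(drop(S %*% g[colnames(S)])), tolerance = 1e-12)

  # excluded baseline channels (DA's NMDA) do not enter the DIC map:
  # a fully passive analysis vector has DICs (1, 0, 0) there too
  da <- get_model("DA")
  expect_equal(unname(dic_at(da, zeroed_conductances(da), -60)),
               c(1, 0, 0), tolerance = 1e-12)

  # homogeneous scaling leaves frozen-calcium DICs unchanged
  for (a in c(0.5, 3, 10))
    expect_equal(dic_at(stg, scale_vector(g, a), -50, Ca = ca),
                 dic_at(stg, g, -50, Ca = ca), tolerance = 1e-10)
})

test_that("threshold detection brackets the fast-DIC zero crossing", {
  stg <- get_model("STG")
  g <- stg_reference_neuron()
  vth <- threshold_voltage(stg, g)
  expect_gt(vth, -60); expect_lt(vth, -30)
  expect_gt(dic_at(stg, g, vth - 1)[["gf"]], 0)
  expect_lt(dic_at(stg, g, vth + 1)[["gf"]], 0)

  # scale invariance of the threshold (frozen calcium)
  ca <- condegen:::population_ca_ref(stg, -50)
  expect_equal(threshold_voltage(stg, scale_vector(g, 2), Ca = ca),
               threshold_voltage(stg, g, Ca = ca), tolerance = 5e-3)

  # a passive membrane has no threshold
  expect_error(threshold_voltage(stg, zeroed_conductances(stg)),
               "no threshold")
})

test_that("compensation round-trips and flags infeasible targets", {
  for (mn in c("STG", "DA")) {
    model <- get_model(mn)
    g <- if (mn == "STG") stg_reference_neuron() else da_reference_neuron()
    unknowns <- unlist(model_config(model)$dic$solve_channels)
    vth <- threshold_voltage(model, g)
    targets <- dic_at(model, g, vth)

    # identity: solving for the neuron's own DIC values returns the neuron
    sol <- compensate(model, g, unknowns, unname(targets), vth)
    expect_true(sol$feasible)
    expect_equal(unclass(sol$g), unclass(g), tolerance = 1e-8)
    expect_lt(sol$residual, 1e-8)

    # random feasible perturbed targets keep the residual at solver precision
    set.seed(42)
    for (k in 1:5) {
      tt <- targets * runif(3, 0.8, 1.2)
      sol <- compensate(model, g, unknowns, unname(tt), vth)
      if (sol$feasible) expect_lt(sol$residual, 1e-8)
    }
  }
  # force a negative solution: demand strong slow positive feedback with the
  # slow channel capped by a huge restorative target elsewhere
  stg <- get_model("STG")
  g <- stg_reference_neuron()
  vth <- threshold_voltage(stg, g)
  bad <- compensate(stg, g, c("Na", "CaS", "H"), c(0, +50, 1), vth)
  expect_false(bad$feasible)
})

test_that("zero-sensitivity directions are orthogonal to the slow sensitivities", {
  toy <- toy_timescale_model()
  gt <- setNames(rep(1, length(toy$analysis_channels)),
                 toy$analysis_channels)
  gt["leak"] <- 0.01
  gt <- structure(gt, class = "cond_vector")
  # identical channels: equal slow sensitivities, direction (1, -1)/sqrt(2)
  d <- zero_sensitivity_direction(toy, gt, c("S", "Q"), Vth = -50)
  expect_equal(unname(d), c(1, -1) / sqrt(2), tolerance = 1e-12)

  stg <- get_model("STG")
  g <- stg_reference_neuron()
  ca <- condegen:::population_ca_ref(stg, -51)
  vth <- -51
  dz <- zero_sensitivity_direction(stg, g, c("A", "CaS"), Vth = vth)
  # A and CaS push the slow DIC in opposite directions: positive slope
  expect_gt(dz[1] * dz[2], 0)

  # first-order invariance: a frozen-calcium step along the direction leaves
  # gs unchanged (the map is linear), a perpendicular step does not
  eps <- 1e-3 * g[["CaS"]]
  g_along <- g; g_perp <- g
  g_along[c("A", "CaS")] <- g_along[c("A", "CaS")] + eps * dz
  g_perp[c("A", "CaS")] <- g_perp[c("A", "CaS")] + eps * rev(dz) * c(1, -1)
  gs0 <- dic_at(stg, g, vth, Ca = ca)[["gs"]]
  expect_lt(abs(dic_at(stg, g_along, vth, Ca = ca)[["gs"]] - gs0), 1e-10)
  expect_gt(abs(dic_at(stg, g_perp, vth, Ca = ca)[["gs"]] - gs0), 1e-6)

  # DA: L- and N-type calcium push the slow DIC the same way: negative slope
  da <- get_model("DA")
  dd <- zero_sensitivity_direction(da, da_reference_neuron(), c("CaL", "CaN"),
                                   Vth = -66)
  expect_lt(dd[1] * dd[2], 0)
})
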