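test_that("bundled models expose the expected channel complements", {
  stg <- get_model("STG")
  expect_equal(stg$analysis_channels,
               c("Na", "Kd", "CaT", "A", "CaS", "KCa", "H", "leak"))
  expect_length(stg$analysis_channels, 8L)
  expect_false(is.null(stg$calcium))

  da <- get_model("DA")
  expect_equal(da$analysis_channels,
               c("Na", "Kd", "CaL", "CaN", "ERG", "leak"))
  expect_length(da$analysis_channels, 6L)
  expect_equal(da$excluded, "NMDA")
  expect_true(da$channels$NMDA$instantaneous)
  expect_gt(da$excluded_baseline[["NMDA"]], 0)

  expect_error(build_model("HH"), "unknown model name")

  bad <- file.path(tempdir(), "bad_model.yaml")
  writeLines(c("name: BAD", "capacitance: 1.0"), bad)
  expect_error(build_model(bad), "missing field")
})

test_that("gating curves stay within bounds across the physiological range", {
  V <- seq(-120, 60, by = 2.5)
  for (mn in c("STG", "DA")) {
    model <- get_model(mn)
    for (ch in model$channels) {
      m <- eval_curve(ch$m_inf, V)
      expect_true(all(m >= 0 & m <= 1), label = paste(mn, ch$name, "m_inf"))
      if (!ch$instantaneous)
        expect_true(all(eval_curve(ch$tau_m, V) > 0),
                    label = paste(mn, ch$name, "tau_m"))
      if (ch$b > 0) {
        h <- eval_curve(ch$h_inf, V)
        expect_true(all(h >= 0 & h <= 1), label = paste(mn, ch$name, "h_inf"))
        expect_true(all(eval_curve(ch$tau_h, V) > 0),
                    label = paste(mn, ch$name, "tau_h"))
      }
    }
  }
})

test_that("analytic curve derivatives match finite differences", {
  V <- seq(-90, -20, by = 7)
  h <- 1e-5
  for (ch in get_model("STG")$channels) {
    for (cv in c("m_inf", "h_inf")) {
      curve <- ch[[cv]]
      if (is.null(curve)) next
      fd <- (eval_curve(curve, V + h) - eval_curve(curve, V - h)) / (2 * h)
      expect_equal(eval_curve_dV(curve, V), fd, tolerance = 1e-6)
    }
  }
})

test_that("a passive membrane relaxes to the leak reversal with gin = gleak", {
  stg <- get_model("STG")
  g0 <- zeroed_conductances(stg, leak = 0.01)
  tr <- simulate_neuron(stg, g0, duration = 6000, transient = 4000)
  expect_lt(max(abs(tr$V - stg$E_leak)), 1e-6)
  expect_identical(firing_metrics(tr)$pattern, "silent")

  ic <- input_conductance(stg, g0)
  expect_equal(ic$gin, 0.01, tolerance = 1e-9)
  expect_equal(ic$Rin, 100, tolerance = 1e-6)

  # linearity of gin in the conductances (passive case)
  ic3 <- input_conductance(stg, scale_vector(g0, 3))
  expect_equal(ic3$gin, 0.03, tolerance = 1e-9)
})

test_that("simulation is deterministic and reference neurons show their nominal patterns", {
  stg <- get_model("STG")
  g <- stg_reference_neuron()
  tr1 <- simulate_neuron(stg, g, duration = 5000, transient = 2000)
  tr2 <- simulate_neuron(stg, g, duration = 5000, transient = 2000)
  expect_identical(tr1$V, tr2$V)

  m <- firing_metrics(tr1)
  expect_identical(m$pattern, "bursting")
  expect_gt(m$peak_V, 0)      # spikes cross the 0 mV reference line
  expect_lt(m$hyperpol_V, -50)

  da <- get_model("DA")
  md <- firing_metrics(simulate_neuron(da, da_reference_neuron(),
                                       duration = 9000, transient = 3000))
  expect_identical(md$pattern, "tonic")
  expect_gt(md$spike_freq, 0.5)
  expect_lt(md$spike_freq, 8)
})

test_that("firing metrics recover constructed spike trains exactly", {
  mk_trace <- function(spike_times, total = 10000, dt = 0.5) {
    t <- seq(0, total, by = dt)
    V <- rep(-65, length(t))
    for (s in spike_times) V[which.min(abs(t - s))] <- 30
    data.frame(t = t, V = V)
  }
  # regular tonic train
  m <- firing_metrics(mk_trace(seq(500, 9500, by = 500)))
  expect_identical(m$pattern, "tonic")
  expect_equal(m$burstiness, 0)
  expect_equal(m$spikes_per_burst, 1)
  expect_equal(m$spike_freq, 2, tolerance = 1e-6)

  # groups of five spikes (25 ms ISI) separated by 1 s gaps
  bursts <- unlist(lapply(seq(500, 8500, by = 1000),
                          function(t0) t0 + 25 * (0:4)))
  m <- firing_metrics(mk_trace(bursts))
  expect_identical(m$pattern, "bursting")
  expect_equal(m$spikes_per_burst, 5)
  expect_equal(m$n_bursts, 9L)
  expect_equal(m$burstiness, 1 - 9 / 45)
  expect_equal(m$intraburst_freq, 40, tolerance = 1e-6)
  expect_equal(m$interburst_freq, 1, tolerance = 1e-6)

  # silent trace
  m <- firing_metrics(data.frame(t = seq(0, 1000, 0.5), V = -65))
  expect_identical(m$pattern, "silent")
  expect_length(m$spike_times, 0L)
})

test_that("input conductance matches a voltage-clamp relaxation oracle", {
  # oracle: integrate the gating/calcium ODEs at clamped V in R (independent
  # of the closed-form steady-state route) and finite-difference the relaxed
  # current over V
  stg <- get_model("STG")
  g <- stg_reference_neuron()
  fg <- condegen:::full_conductances(stg, g)
  clamp_current <- function(V) {
    state <- condegen:::steady_states(stg, fg$gbar, -80) # far-off start
    m <- state$m; h <- state$h; Ca <- state$Ca
    dt <- 2
    for (i in seq_len(10000)) {
      for (ch in stg$channels) {
        nm <- ch$name
        mi <- eval_curve(ch$m_inf, V)
        if (ch$ca_half > 0) mi <- mi * Ca / (Ca + ch$ca_half)
        am <- 1 - exp(-dt / eval_curve(ch$tau_m, V))
        m[nm] <- m[nm] + am * (mi - m[nm])
        if (ch$b > 0) {
          ah <- 1 - exp(-dt / eval_curve(ch$tau_h, V))
          h[nm] <- h[nm] + ah * (eval_curve(ch$h_inf, V) - h[nm])
        }
      }
      cal <- stg$calcium
      E_ca <- cal$reversal$coef * log(cal$reversal$ca_out / max(Ca, 1e-9))
      ica <- 0
      for (nm in c("CaT", "CaS")) {
        ch <- stg$channels[[nm]]
        ica <- ica + fg$gbar[[nm]] * m[nm]^ch$a * h[nm]^ch$b * (V - E_ca)
      }
      Ca <- Ca + dt * (-cal$f * ica - Ca + cal$ca_rest) / cal$tau
    }
    E_ca <- stg$calcium$reversal$coef *
      log(stg$calcium$reversal$ca_out / max(Ca, 1e-9))
    I <- fg$gleak * (V - stg$E_leak)
    for (ch in stg$channels) {
      E <- if (ch$E_calcium) E_ca else ch$E
      hh <- if (ch$b > 0) h[ch$name] else 1
      I <- I + fg$gbar[[ch$name]] * m[ch$name]^ch$a * hh^ch$b * (V - E)
    }
    I
  }
  dV <- 0.05
  gin_oracle <- unname((clamp_current(-70 + dV) -
                          clamp_current(-70 - dV)) / (2 * dV))
  expect_equal(input_conductance(stg, g, V_ref = -70)$gin, gin_oracle,
               tolerance = 1e-3)
})

test_that("an inhibitory step is attenuated after doubling all conductances", {
  stg <- get_model("STG")
  g <- stg_reference_neuron()
  step <- list(amp = -0.5, t_on = 4000, t_off = 5500)
  dip <- function(gg) {
    tr <- simulate_neuron(stg, gg, duration = 6500, transient = 2000,
                          step = step)
    min(tr$V[tr$Iext != 0])
  }
  v1 <- dip(g)
  v2 <- dip(scale_vector(g, 2))
  expect_lt(v1, v2)  # doubled membrane responds less to the same current
})
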