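#' Extract firing-pattern metrics from a voltage trace
#'
#' Detects spikes as upward crossings of `spike_threshold` (with a refractory
#' minimum between detections), groups them into bursts by an
#' interspike-interval rule (a gap longer than `burst_gap_factor` times the
#' median ISI starts a new burst), and classifies the firing pattern as
#' `silent`, `tonic`, `bursting` or `irregular`.
#'
#' Burstiness is `1 - n_bursts / n_spikes` when the gap rule splits the train
#' into two or more groups of which at least one holds several spikes, and 0
#' otherwise; it is 0 for a perfectly regular tonic train and grows toward 1
#' as more spikes concentrate into fewer bursts.
#'
#' @param trace a `voltage_trace` from [simulate_neuron()] (or any data.frame with
#'   columns `t`, `V`)
#' @param spike_threshold spike-detection voltage (mV)
#' @param burst_gap_factor multiple of the median ISI above which a gap
#'   separates bursts
#' @param refractory minimum time between detected spikes (ms)
#' @param tonic_cv_max maximum ISI coefficient of variation for an unsplit
#'   train to count as tonic
#' @return list of class `firing_metrics`: `pattern`, `spike_times` (ms),
#'   `n_spikes`, `peak_V`, `hyperpol_V` (mV), `spike_freq` (Hz),
#'   `intraburst_freq`, `interburst_freq` (Hz), `spikes_per_burst`,
#'   `n_bursts`, `burstiness`, `isi_cv`.
#' @examples
#' tr <- data.frame(t = seq(0, 1000, 0.1),
#'                  V = -60 + 80 * (sin(2 * pi * seq(0, 1000, 0.1) / 100) > 0.99))
#' firing_metrics(tr)$pattern
#' @export
firing_metrics <- function(trace, spike_threshold = 0, burst_gap_factor = 3,
                           refractory = 2, tonic_cv_max = 0.5) {
  t <- trace$t
  V <- trace$V
  up <- which(V[-length(V)] < spike_threshold & V[-1] >= spike_threshold) + 1L
  spikes <- numeric(0)
  for (i in up) {
    ti <- t[i]
    if (!length(spikes) || ti - spikes[length(spikes)] >= refractory)
      spikes <- c(spikes, ti)
  }
  res <- list(pattern = "silent", spike_times = spikes,
              n_spikes = length(spikes),
              peak_V = max(V), hyperpol_V = min(V),
              spike_freq = NA_real_, intraburst_freq = NA_real_,
              interburst_freq = NA_real_, spikes_per_burst = NA_real_,
              n_bursts = 0L, burstiness = NA_real_, isi_cv = NA_real_)
  class(res) <- "firing_metrics"
  if (length(spikes) < 2) {
    if (length(spikes) == 1) res$pattern <- "irregular"
    return(res)
  }
  isi <- diff(spikes)
  res$isi_cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else 0
  res$spike_freq <- 1000 * (length(spikes) - 1) / (spikes[length(spikes)] -
                                                     spikes[1])
  gap <- isi > burst_gap_factor * stats::median(isi)
  burst_id <- cumsum(c(0, gap))
  sizes <- as.integer(table(burst_id))
  n_bursts <- length(sizes)
  if (n_bursts >= 2 && mean(sizes) >= 2) {
    res$pattern <- "bursting"
    res$n_bursts <- n_bursts
    res$spikes_per_burst <- mean(sizes)
    res$burstiness <- 1 - n_bursts / length(spikes)
    intra <- isi[!gap]
    res$intraburst_freq <- if (length(intra)) 1000 / mean(intra) else NA_real_
    # burst cycle frequency: first spike of one burst to the next
    starts <- spikes[!duplicated(burst_id)]
    res$interburst_freq <- 1000 / mean(diff(starts))
  } else if (n_bursts == 1) {
    res$pattern <- if (res$isi_cv <= tonic_cv_max) "tonic" else "irregular"
    res$n_bursts <- length(spikes)
    res$spikes_per_burst <- 1
    res$burstiness <- 0
  } else {
    # every gap long: sparse train; treat as tonic if regular
    res$pattern <- if (res$isi_cv <= tonic_cv_max) "tonic" else "irregular"
    res$n_bursts <- n_bursts
    res$spikes_per_burst <- mean(sizes)
    res$burstiness <- 0
  }
  res
}

#' @export
print.firing_metrics <- function(x, ...) {
  cat("Firing pattern:", x$pattern, "\n")
  cat(sprintf("  %d spikes, peak %.1f mV, trough %.1f mV\n",
              x$n_spikes, x$peak_V, x$hyperpol_V))
  if (x$pattern == "bursting")
    cat(sprintf(paste0("  %.1f spikes/burst, intraburst %.1f Hz, ",
                       "burst cycle %.2f Hz, burstiness %.2f\n"),
                x$spikes_per_burst, x$intraburst_freq, x$interburst_freq,
                x$burstiness))
  if (x$pattern == "tonic")
    cat(sprintf("  %.2f Hz tonic, ISI CV %.2f\n", x$spike_freq, x$isi_cv))
  invisible(x)
}

#' Steady-state membrane current of a model at a clamped voltage
#'
#' Total membrane current (uA/cm2, outward positive) with every gating
#' variable, and calcium where present, at its steady state for `V`.
#' @inheritParams simulate_neuron
#' @param V clamped voltage (mV), vectorized
#' @export
steady_state_current <- function(model, g, V) {
  fg <- full_conductances(model, g)
  vapply(V, function(v) {
    ss <- steady_states(model, fg$gbar, v)
    I <- fg$gleak * (v - model$E_leak)
    for (ch in model$channels) {
      E <- channel_reversal(model, ch, ss$Ca)
      m <- ss$m[[ch$name]]
      h <- if (ch$b > 0) ss$h[[ch$name]] else 1
      I <- I + fg$gbar[[ch$name]] * m^ch$a * h^ch$b * (v - E)
    }
    I
  }, numeric(1))
}

#' Input conductance and input resistance at a reference voltage
#'
#' The input conductance is the slope of the steady-state current-voltage
#' relation, `gin(V_ref) = dI_ss/dV`, evaluated by central finite difference;
#' the input resistance is its inverse. For a passive membrane `gin` equals
#' `gleak` exactly; homogeneous scaling of all conductances by a factor
#' `alpha` scales `gin` by `alpha` and `Rin` by `1/alpha`.
#'
#' @inheritParams simulate_neuron
#' @param V_ref reference voltage (mV), below the spike-threshold region
#' @param h finite-difference step (mV)
#' @return list with `gin` (mS/cm2) and `Rin` (kOhm cm2)
#' @export
input_conductance <- function(model, g, V_ref = -70, h = 0.01) {
  gin <- (steady_state_current(model, g, V_ref + h) -
            steady_state_current(model, g, V_ref - h)) / (2 * h)
  if (gin <= 0)
    stop("input conductance is non-positive at V_ref = ", V_ref,
         " mV (unstable point); choose another reference voltage")
  list(gin = gin, Rin = 1 / gin)
}
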