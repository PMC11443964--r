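#' @useDynLib condegen, .registration = TRUE
NULL

CG_HEAD <- 15L
CG_BLK <- 40L

encode_curve <- function(curve) {
  out <- numeric(8)
  if (is.null(curve)) return(out)
  out[1] <- curve_form_id(curve)
  p <- curve$p
  out[1 + seq_along(p)] <- p
  out
}

#' Flatten a model + conductance vector + current protocol into the numeric
#' encoding interpreted by the compiled derivative routine.
#' @keywords internal
encode_model <- function(model, g, Iext = 0, step_amp = 0, t_on = Inf,
                         t_off = Inf) {
  fg <- full_conductances(model, g)
  nch <- length(model$channels)
  parms <- numeric(CG_HEAD + nch * CG_BLK)
  cal <- model$calcium
  parms[1:15] <- c(model$C, fg$gleak, model$E_leak, nch,
                   as.numeric(!is.null(cal)),
                   cal$tau %||% 0, cal$f %||% 0, cal$ca_rest %||% 0,
                   as.numeric(!is.null(cal$reversal)),
                   cal$reversal$coef %||% 0, cal$reversal$ca_out %||% 0,
                   Iext, step_amp, t_on, t_off)
  for (j in seq_len(nch)) {
    ch <- model$channels[[j]]
    off <- CG_HEAD + (j - 1L) * CG_BLK
    parms[off + 1:8] <- c(fg$gbar[[ch$name]], ch$a, ch$b,
                          as.numeric(ch$E_calcium),
                          if (ch$E_calcium) 0 else ch$E,
                          as.numeric(ch$calcium_source), ch$ca_half,
                          as.numeric(ch$instantaneous))
    parms[off + 8 + 1:8] <- encode_curve(ch$m_inf)
    parms[off + 16 + 1:8] <- encode_curve(ch$tau_m)
    parms[off + 24 + 1:8] <- encode_curve(ch$h_inf)
    parms[off + 32 + 1:8] <- encode_curve(ch$tau_h)
  }
  parms
}

#' Names and initial values of the state vector (V first, gates in channel
#' order, calcium last), initialized at gating steady state for V0.
#' @keywords internal
initial_state <- function(model, g, V0 = -65) {
  ss <- steady_states(model, g, V0)
  y <- c(V = V0)
  for (ch in model$channels) {
    if (ch$a > 0 && !ch$instantaneous)
      y[paste0("m_", ch$name)] <- ss$m[[ch$name]]
    if (ch$b > 0)
      y[paste0("h_", ch$name)] <- ss$h[[ch$name]]
  }
  if (!is.null(model$calcium)) y["Ca"] <- ss$Ca
  y
}

#' Simulate a conductance-based neuron model
#'
#' Integrates the membrane equation
#' \eqn{C \dot V = -\sum_{ion} \bar g_{ion} m^a h^b (V - E_{ion})
#' - g_{leak}(V - E_{leak}) + I_{ext}}
#' with first-order gating kinetics (and an intracellular-calcium state where
#' the model requires one) using a stiff-capable variable-step integrator
#' (`deSolve::lsoda`) with a compiled right-hand side. Gating variables are
#' initialized at their steady state for `V0` and the initial transient is
#' discarded.
#'
#' @param model a `cb_model` from [build_model()]
#' @param g conductance vector covering the model's analysis channels + leak
#' @param Iext constant applied current (uA/cm2)
#' @param duration total simulated time (ms)
#' @param transient initial time span discarded from the returned trace (ms)
#' @param step optional current step, a list `list(amp =, t_on =, t_off =)`
#'   (times in absolute simulation time)
#' @param dt output sampling interval (ms)
#' @param V0 initial voltage (mV)
#' @param rtol,atol integration tolerances
#' @param keep_states if `TRUE`, gating/calcium states are kept in the trace
#' @return a `voltage_trace`: data.frame with columns `t` (ms, measured from
#'   the end of the transient), `V` (mV), `Iext` (uA/cm2) and optionally the
#'   state variables.
#' @examples
#' \donttest{
#' stg <- build_model("STG")
#' g <- stg_reference_neuron()
#' tr <- simulate_neuron(stg, g, duration = 4000, transient = 1000)
#' range(tr$V)
#' }
#' @export
simulate_neuron <- function(model, g, Iext = 0, duration = 10000, transient = 2000,
                     step = NULL, dt = 0.05, V0 = -65,
                     rtol = 1e-6, atol = 1e-8, keep_states = FALSE) {
  stopifnot(inherits(model, "cb_model"), duration > transient, transient >= 0)
  step_amp <- if (is.null(step)) 0 else step$amp
  t_on <- if (is.null(step)) Inf else step$t_on
  t_off <- if (is.null(step)) Inf else step$t_off
  parms <- encode_model(model, g, Iext, step_amp, t_on, t_off)
  .Call("cg_set_parms", as.numeric(parms), PACKAGE = "condegen")
  y0 <- initial_state(model, g, V0)
  times <- seq(0, duration, by = dt)
  # restart integration at current-step discontinuities so lsoda never
  # interpolates across them
  brk <- sort(unique(c(0, t_on, t_off, duration)))
  brk <- brk[brk >= 0 & brk <= duration & is.finite(brk)]
  out_list <- list()
  y <- y0
  for (i in seq_len(length(brk) - 1L)) {
    tt <- times[times >= brk[i] & times <= brk[i + 1L]]
    tt <- sort(unique(c(brk[i], tt, brk[i + 1L])))
    seg <- deSolve::lsoda(y, tt, func = "cg_derivs", parms = NULL,
                          dllname = "condegen", rtol = rtol, atol = atol,
                          hmax = 5)
    if (attr(seg, "istate")[1] < 0 || any(!is.finite(seg[nrow(seg), ])))
      stop("integration failure in model '", model$name,
           "' (non-finite state: ",
           paste(colnames(seg)[!is.finite(seg[nrow(seg), ])],
                 collapse = ", "), ")")
    y <- seg[nrow(seg), -1]
    out_list[[i]] <- seg[-nrow(seg), , drop = FALSE]
  }
  out <- rbind(do.call(rbind, out_list), seg[nrow(seg), , drop = FALSE])
  out <- out[out[, "time"] >= transient & out[, "time"] %in% times, ,
             drop = FALSE]
  tvec <- out[, "time"] - transient
  ivec <- rep(Iext, length(tvec))
  if (!is.null(step)) {
    on <- out[, "time"] >= t_on & out[, "time"] < t_off
    ivec[on] <- ivec[on] + step_amp
  }
  tr <- data.frame(t = tvec, V = out[, "V"], Iext = ivec)
  if (keep_states)
    tr <- cbind(tr, as.data.frame(out[, setdiff(colnames(out),
                                                c("time", "V")),
                                      drop = FALSE]))
  class(tr) <- c("voltage_trace", "data.frame")
  attr(tr, "model") <- model$name
  tr
}

#' Reference STG bursting neuron
#'
#' A hand-picked maximal-conductance vector producing regular bursting in the
#' bundled STG model; used as a seed point for calibration and examples.
#' @return a `cond_vector`
#' @export
stg_reference_neuron <- function() {
  conductance_vector(build_model("STG"),
                     Na = 700, Kd = 70, CaT = 2.2, A = 25, CaS = 4,
                     KCa = 90, H = 0.06, leak = 0.01)
}

#' Reference DA tonic-spiking neuron
#' @return a `cond_vector`
#' @export
da_reference_neuron <- function() {
  conductance_vector(build_model("DA"),
                     Na = 30, Kd = 8, CaL = 0.05, CaN = 0.05, ERG = 0.12,
                     leak = 0.01)
}
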