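#' Timescale weights of the gating variables
#'
#' Each gating variable's influence on membrane dynamics is apportioned to
#' three timescales (fast / slow / ultraslow) according to the logarithmic
#' distance of its time constant from three voltage-dependent reference
#' timescales: the fast reference (activation time constant of the fast
#' sodium current), the slow reference (activation time constant of the
#' delayed rectifier), and the ultraslow reference (the slowest gating time
#' constant in the model). Weights interpolate linearly in log-tau between
#' neighbouring references and form a partition of unity per gating variable;
#' a variable at or below the fast reference gets weight (1, 0, 0), at or
#' above the ultraslow reference (0, 0, 1). Instantaneous gates are assigned
#' to the fast timescale.
#'
#' @param model a `cb_model`
#' @param V voltage (mV), scalar
#' @return list with `w` (3 x n-gates matrix, rows fast/slow/ultraslow,
#'   columns named `channel.gate`), `tau` (gate time constants, ms) and
#'   `refs` (the three reference timescales at `V`).
#' @export
timescale_weights <- function(model, V) {
  gates <- gating_table(model)
  tau <- vapply(gates, function(gt)
    if (gt$instantaneous) 0 else eval_curve(gt$tau, V), numeric(1))
  refs <- reference_timescales(model, V, tau)
  if (!(refs[1] < refs[2] && refs[2] < refs[3]))
    stop("reference timescales must satisfy tau_f < tau_s < tau_u (got ",
         paste(signif(refs, 4), collapse = ", "), ")")
  lr <- log(refs)
  w <- vapply(tau, function(tx) {
    if (tx <= refs[1]) return(c(1, 0, 0))
    if (tx >= refs[3]) return(c(0, 0, 1))
    lt <- log(tx)
    if (tx <= refs[2]) {
      wf <- (lr[2] - lt) / (lr[2] - lr[1])
      c(wf, 1 - wf, 0)
    } else {
      ws <- (lr[3] - lt) / (lr[3] - lr[2])
      c(0, ws, 1 - ws)
    }
  }, numeric(3))
  rownames(w) <- c("fast", "slow", "ultraslow")
  colnames(w) <- names(gates)
  list(w = w, tau = setNames(tau, names(gates)), refs = refs)
}

# one entry per gating variable: channel.m / channel.h
gating_table <- function(model) {
  gates <- list()
  for (ch in model$channels) {
    if (ch$a > 0)
      gates[[paste0(ch$name, ".m")]] <-
        list(channel = ch$name, gate = "m", inf = ch$m_inf, tau = ch$tau_m,
             instantaneous = ch$instantaneous, ca_half = ch$ca_half)
    if (ch$b > 0)
      gates[[paste0(ch$name, ".h")]] <-
        list(channel = ch$name, gate = "h", inf = ch$h_inf, tau = ch$tau_h,
             instantaneous = FALSE, ca_half = 0)
  }
  gates
}

reference_timescales <- function(model, V, tau_all = NULL) {
  refs <- model$dic_references
  get_ref <- function(key) {
    if (identical(key, "max")) {
      if (is.null(tau_all)) stop("gate taus needed for 'max' reference")
      return(max(tau_all))
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ch <- model$channels[[parts[1]]]
    curve <- if (parts[2] == "m") ch$tau_m else ch$tau_h
    eval_curve(curve, V)
  }
  c(fast = get_ref(refs$fast), slow = get_ref(refs$slow),
    ultraslow = get_ref(refs$ultraslow))
}

#' Sensitivity matrix of the dynamic input conductances
#'
#' Builds the 3 x N matrix `S(V)` mapping maximal conductances to the three
#' dynamic input conductances, `(gf, gs, gu)(V) = S(V) . gbar`, normalized by
#' the leak conductance so that DIC values are dimensionless. Each gated
#' channel contributes (i) its instantaneous steady-state conductance to the
#' fast row and (ii) one term per gating variable, equal to the derivative of
#' its current with respect to the gate times the voltage slope of the
#' gate's steady state, split across timescales by [timescale_weights()].
#' Derivatives are evaluated with all gates (and intracellular calcium) frozen
#' at their steady state for `V`; positive entries are restorative (negative
#' feedback). The leak column carries only the passive fast term. Channels
#' simulated at fixed baseline but excluded from the conductance-space
#' analysis (NMDA in the DA model) do not enter the DIC accounting: the DIC
#' map covers the analysis conductances only.
#'
#' @inheritParams simulate_neuron
#' @param V evaluation voltage (mV), scalar
#' @param Ca optional frozen intracellular-calcium value (uM); by default the
#'   calcium state is the self-consistent steady state for `V` given `g`
#' @return 3 x N matrix (rows fast/slow/ultraslow, columns the model's
#'   analysis conductances, leak last)
#' @export
sensitivity_matrix <- function(model, g, V, Ca = NULL) {
  validate_conductances(model, g)
  gleak <- unname(g[["leak"]])
  if (gleak <= 0) stop("sensitivity matrix undefined: gleak must be > 0")
  fg <- full_conductances(model, g)
  ss <- steady_states(model, fg$gbar, V, Ca = Ca)
  tw <- timescale_weights(model, V)
  cols <- c(names(model$channels), "leak")
  S <- matrix(0, 3, length(cols),
              dimnames = list(c("fast", "slow", "ultraslow"), cols))
  for (ch in model$channels) {
    E <- channel_reversal(model, ch, ss$Ca)
    m <- ss$m[[ch$name]]
    h <- if (ch$b > 0) ss$h[[ch$name]] else 1
    a <- ch$a; b <- ch$b
    col <- c(m^a * h^b, 0, 0)            # instantaneous conductance, fast row
    if (a > 0) {
      dminf <- eval_curve_dV(ch$m_inf, V)
      if (ch$ca_half > 0) dminf <- dminf * ss$Ca / (ss$Ca + ch$ca_half)
      dIdm <- a * m^(a - 1) * h^b * (V - E)
      wm <- if (ch$instantaneous) c(1, 0, 0)
            else tw$w[, paste0(ch$name, ".m")]
      col <- col + wm * dIdm * dminf
    }
    if (b > 0) {
      dhinf <- eval_curve_dV(ch$h_inf, V)
      dIdh <- b * m^a * h^(b - 1) * (V - E)
      col <- col + tw$w[, paste0(ch$name, ".h")] * dIdh * dhinf
    }
    S[, ch$name] <- col / gleak
  }
  S["fast", "leak"] <- 1 / gleak
  S <- S[, model$analysis_channels, drop = FALSE]
  attr(S, "V") <- V
  S
}

#' Dynamic input conductances of a neuron at a voltage
#'
#' Computes `(gf, gs, gu)` at voltage `V` as the matrix-vector product of the
#' sensitivity matrix with the maximal-conductance vector. At the threshold
#' voltage the
#' signs and values of the three DICs determine the firing pattern: `gs < 0`
#' (net slow positive feedback) with `gu > 0` produces bursting, `gs >= 0`
#' tonic spiking.
#'
#' @inheritParams sensitivity_matrix
#' @param V evaluation voltage (mV); defaults to the neuron's threshold
#'   voltage
#' @param Ca optional frozen calcium value (uM), see [sensitivity_matrix()]
#' @return named numeric vector `c(gf, gs, gu)` (dimensionless,
#'   leak-normalized)
#' @export
dic_at <- function(model, g, V = NULL, Ca = NULL) {
  if (is.null(V)) V <- threshold_voltage(model, g, Ca = Ca)
  S <- sensitivity_matrix(model, g, V, Ca = Ca)
  setNames(drop(S %*% g[colnames(S)]), c("gf", "gs", "gu"))
}

#' Dynamic input conductance curves on a voltage grid
#' @inheritParams sensitivity_matrix
#' @param V_grid voltages (mV)
#' @return data.frame with columns `V`, `gf`, `gs`, `gu`
#' @export
dic_curve <- function(model, g, V_grid = seq(-80, -20, by = 0.5)) {
  vals <- t(vapply(V_grid, function(v) dic_at(model, g, v), numeric(3)))
  data.frame(V = V_grid, gf = vals[, 1], gs = vals[, 2], gu = vals[, 3])
}

#' Threshold voltage of a neuron
#'
#' The threshold voltage is the subthreshold zero crossing of the fast
#' dynamic input conductance: the voltage at which net fast positive feedback
#' (regenerative sodium activation) overcomes the passive and restorative
#' fast conductances. Located by sign-change bracketing on a grid followed by
#' bisection. Homogeneous scaling of all conductances leaves it unchanged.
#'
#' @inheritParams sensitivity_matrix
#' @param range search interval (mV)
#' @param tol bisection tolerance (mV)
#' @param Ca optional frozen calcium value (uM), see [sensitivity_matrix()]
#' @return threshold voltage (mV)
#' @export
threshold_voltage <- function(model, g, range = c(-80, -20), tol = 1e-6,
                              Ca = NULL) {
  grid <- seq(range[1], range[2], by = 1)
  gf <- vapply(grid, function(v) dic_at(model, g, v, Ca = Ca)[["gf"]],
               numeric(1))
  cross <- which(gf[-length(gf)] > 0 & gf[-1] <= 0)
  if (!length(cross))
    stop("no threshold: the fast DIC has no subthreshold zero crossing in [",
         range[1], ", ", range[2], "] mV")
  i <- cross[1]
  stats::uniroot(function(v) dic_at(model, g, v, Ca = Ca)[["gf"]],
                 c(grid[i], grid[i + 1]), tol = tol)$root
}

#' Solve for compensating conductances at fixed DIC targets
#'
#' Given a conductance vector with `length(unknowns)` designated unknown
#' channels, solves the linear system `S(Vth) . gbar = targets` for the
#' unknowns so that the neuron attains prescribed DIC values at `Vth`. With
#' three unknowns all three DICs are imposed; with two unknowns the slow and
#' ultraslow rows are imposed (the neuromodulation solve). Because the
#' sensitivity matrix of a calcium-bearing model depends weakly on the
#' unknown calcium conductances through the calcium steady state, the solve
#' is iterated to a fixed point. A solution with any negative conductance is
#' returned with `feasible = FALSE` (a rejection signal for samplers, not an
#' error); an ill-conditioned subsystem is an error.
#'
#' @inheritParams sensitivity_matrix
#' @param g conductance vector supplying the known channels (unknown entries
#'   are used as the iteration starting point)
#' @param unknowns character vector of 2 or 3 analysis channel names
#' @param targets numeric DIC targets: length 3 `(gf, gs, gu)` for three
#'   unknowns, length 2 `(gs, gu)` for two
#' @param Vth threshold voltage at which targets are imposed
#' @param max_cond condition-number guard for the subsystem
#' @param max_iter,tol fixed-point iteration controls
#' @param Ca optional frozen calcium value (uM); with it the system is
#'   exactly linear and the solve is exact in one step
#' @return list with `g` (full conductance vector), `feasible`, `residual`
#' @export
compensate <- function(model, g, unknowns, targets, Vth,
                       max_cond = 1e8, max_iter = 50, tol = 1e-10,
                       Ca = NULL) {
  validate_conductances(model, g)
  stopifnot(length(unknowns) %in% c(2L, 3L),
            length(targets) == length(unknowns),
            all(unknowns %in% setdiff(model$analysis_channels, "leak")))
  rows <- if (length(unknowns) == 3L) 1:3 else 2:3
  g_cur <- g
  if (!is.null(Ca) || is.null(model$calcium)) max_iter <- 1L
  for (it in seq_len(max_iter)) {
    S <- sensitivity_matrix(model, g_cur, Vth, Ca = Ca)
    known <- setdiff(colnames(S), unknowns)
    rhs <- targets - drop(S[rows, known, drop = FALSE] %*% g_cur[known])
    A <- S[rows, unknowns, drop = FALSE]
    cn <- kappa(A, exact = TRUE)
    if (!is.finite(cn) || cn > max_cond)
      stop("compensation subsystem ill-conditioned (condition number ",
           signif(cn, 3), ") for unknowns ", paste(unknowns, collapse = ", "))
    x <- solve(A, rhs)
    delta <- max(abs(x - g_cur[unknowns]))
    g_cur[unknowns] <- x
    if (any(x < 0)) break              # infeasible: stop iterating, report
    if (delta < tol * (1 + max(abs(x)))) break
  }
  g_new <- g_cur
  feasible <- all(g_new[unknowns] >= 0)
  resid <- if (feasible) {
    max(abs(dic_at(model, g_new, Vth, Ca = Ca)[rows] - targets))
  } else NA_real_
  list(g = g_new, feasible = feasible, residual = resid)
}

#' Zero-sensitivity direction of the slow DIC for a channel pair
#'
#' Direction in the plane of two maximal conductances along which the slow
#' dynamic input conductance at threshold is unchanged to first order:
#' the unit vector orthogonal to the slow-row sensitivities of the pair,
#' with non-negative first component. Populations that vary conductance
#' ratios at fixed DIC targets spread along these directions; a pair whose
#' slow sensitivities have opposite signs has a positive-slope direction
#' (positive pairwise correlation) and vice versa.
#'
#' @inheritParams sensitivity_matrix
#' @param pair character vector of two analysis channel names
#' @param Vth evaluation voltage; defaults to the neuron's threshold
#' @return unit 2-vector named by the pair
#' @export
zero_sensitivity_direction <- function(model, g, pair, Vth = NULL) {
  stopifnot(length(pair) == 2L)
  if (is.null(Vth)) Vth <- threshold_voltage(model, g)
  S <- sensitivity_matrix(model, g, Vth)
  s <- S["slow", pair]
  if (all(abs(s) < 1e-12))
    stop("zero-sensitivity direction undefined: both slow sensitivities ",
         "vanish for (", paste(pair, collapse = ", "), ")")
  d <- c(-s[2], s[1])
  d <- d / sqrt(sum(d^2))
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  setNames(d, pair)
}
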