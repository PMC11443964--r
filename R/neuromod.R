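#' Neuromodulate a degenerate population to a new excitability state
#'
#' Implements the reliable (indirect) neuromodulation rule: for each member,
#' the threshold voltage is recomputed, the member's current ultraslow DIC
#' value there is read out, and the two modulated maximal conductances are
#' re-solved from the slow/ultraslow rows of the DIC linear system so that
#' the slow DIC reaches `gs_target` while the ultraslow DIC is kept unchanged
#' (or set to `gu_target`). All other conductances are untouched. Members for
#' which the solve yields a negative conductance (or no threshold) are
#' flagged infeasible and excluded from the returned population.
#'
#' @param pop a `neuron_population`
#' @param gs_target slow-DIC value at threshold defining the state; a state
#'   name (`"spiking"`, `"light_bursting"`, `"strong_bursting"`) is looked up
#'   in the model configuration
#' @param pair the two modulated channels; default from [model_config()]
#'   (A-type and slow-calcium in STG, L- and N-type calcium in DA)
#' @param gu_target optional common ultraslow target; default: keep each
#'   member's own value
#' @return a `neuron_population`; provenance records the state, pair, and
#'   indices of infeasible members
#' @export
modulate_population <- function(pop, gs_target, pair = NULL,
                                gu_target = NULL) {
  model <- build_model(attr(pop, "model"))
  cfg <- model_config(model)
  if (is.character(gs_target)) {
    st <- cfg$neuromodulation$states[[gs_target]]
    if (is.null(st)) stop("unknown neuromodulation state: ", gs_target)
    label <- gs_target
    gs_target <- st
  } else label <- "custom"
  pair <- pair %||% unlist(cfg$neuromodulation$pair)
  stopifnot(length(pair) == 2L,
            all(pair %in% setdiff(model$analysis_channels, "leak")))
  ca_ref <- attr(pop, "provenance")$ca_ref
  rows <- vector("list", nrow(pop))
  infeasible <- integer(0)
  for (i in seq_len(nrow(pop))) {
    g <- member(pop, i)
    sol <- tryCatch({
      vth <- threshold_voltage(model, g, Ca = ca_ref)
      gu_i <- gu_target %||% dic_at(model, g, vth, Ca = ca_ref)[["gu"]]
      compensate(model, g, pair, c(gs_target, gu_i), vth, Ca = ca_ref)
    }, error = function(e) NULL)
    if (is.null(sol) || !sol$feasible) {
      infeasible <- c(infeasible, i)
    } else {
      rows[[i]] <- sol$g[model$analysis_channels]
    }
  }
  keep <- setdiff(seq_len(nrow(pop)), infeasible)
  pv <- attr(pop, "provenance")
  pv$neuromodulation <- list(state = label, gs_target = gs_target,
                             pair = pair, gu_target = gu_target,
                             infeasible = infeasible, kept = keep)
  new_population(model, do.call(rbind, rows[keep]), pv)
}

#' Continuous neuromodulatory path of a single neuron
#'
#' Moves one neuron through a schedule of slow-DIC targets (tonic spiking
#' toward increasing burstiness), re-solving the modulated pair at each step
#' with the neuron's ultraslow DIC held at its initial value and the
#' threshold voltage fixed at the neuron's initial threshold, which makes the
#' path exactly linear in the modulated-pair plane: the neuromodulation
#' direction is constant along a path and varies only between neurons.
#'
#' @param model a `cb_model`
#' @param neuron a `cond_vector`
#' @param schedule monotone sequence of slow-DIC targets; default: 20 evenly
#'   spaced values between the model's spiking and strong-bursting states
#' @param pair the two modulated channels; default from [model_config()]
#' @param Ca optional frozen calcium value (uM)
#' @return data.frame of class `neuromod_path`: columns `step`, `gs_target`
#'   and the two pair conductances; infeasible steps truncate the path with
#'   a warning
#' @export
neuromod_path <- function(model, neuron, schedule = NULL, pair = NULL,
                          Ca = NULL) {
  cfg <- model_config(model)
  pair <- pair %||% unlist(cfg$neuromodulation$pair)
  if (is.null(schedule)) {
    st <- cfg$neuromodulation$states
    schedule <- seq(st$spiking, st$strong_bursting, length.out = 20)
  }
  if (is.unsorted(schedule) && is.unsorted(rev(schedule)))
    stop("schedule must be monotone")
  vth <- threshold_voltage(model, neuron, Ca = Ca)
  gu0 <- dic_at(model, neuron, vth, Ca = Ca)[["gu"]]
  out <- data.frame(step = seq_along(schedule), gs_target = schedule)
  out[[pair[1]]] <- NA_real_
  out[[pair[2]]] <- NA_real_
  for (k in seq_along(schedule)) {
    sol <- tryCatch(
      compensate(model, neuron, pair, c(schedule[k], gu0), vth, Ca = Ca),
      error = function(e) NULL)
    if (is.null(sol) || !sol$feasible) {
      warning("path truncated at step ", k, " (infeasible solve)")
      out <- out[seq_len(k - 1L), , drop = FALSE]
      break
    }
    out[[pair[1]]][k] <- sol$g[[pair[1]]]
    out[[pair[2]]][k] <- sol$g[[pair[2]]]
  }
  class(out) <- c("neuromod_path", "data.frame")
  attr(out, "pair") <- pair
  attr(out, "Vth") <- vth
  out
}

#' Classify the direct neuromodulation rule relating two population states
#'
#' Fits, per modulated channel, both a multiplicative rule
#' `g_mod = alpha * g_init` and an additive rule `g_mod = g_init + beta`
#' across paired members, and reports which rule achieves the lower relative
#' residual. Populations whose variability is homogeneous scaling are
#' modulated multiplicatively (a rotation of the data cloud); populations
#' whose variability lies in conductance ratios are modulated additively
#' (a translation).
#'
#' @param pop_before,pop_after member-paired populations (same members, in
#'   order, before and after neuromodulation)
#' @param pair the two modulated channels
#' @return list with per-channel `alpha`, `beta`, relative residuals
#'   `residual_multiplicative`, `residual_additive`, and `rule` (the winner
#'   per channel: `"multiplicative"`, `"additive"`, or `"mixed"` when neither
#'   fits within `tol`)
#' @param tol relative-residual threshold below which a rule counts as
#'   fitting exactly
#' @export
classify_rule <- function(pop_before, pop_after, pair = NULL, tol = 1e-6) {
  model <- build_model(attr(pop_before, "model"))
  pair <- pair %||%
    attr(pop_after, "provenance")$neuromodulation$pair %||%
    unlist(model_config(model)$neuromodulation$pair)
  kept <- attr(pop_after, "provenance")$neuromodulation$kept
  b <- unclass(pop_before)
  if (!is.null(kept)) b <- b[kept, , drop = FALSE]
  a <- unclass(pop_after)
  if (nrow(a) != nrow(b))
    stop("populations are not member-paired")
  res <- list(pair = pair)
  for (ch in pair) {
    x <- b[, ch]; y <- a[, ch]
    alpha <- sum(x * y) / sum(x * x)
    beta <- mean(y - x)
    sc <- sqrt(mean(y^2)) + 1e-300
    rm_ <- sqrt(mean((y - alpha * x)^2)) / sc
    ra_ <- sqrt(mean((y - (x + beta))^2)) / sc
    res$alpha[ch] <- alpha
    res$beta[ch] <- beta
    res$residual_multiplicative[ch] <- rm_
    res$residual_additive[ch] <- ra_
    res$rule[ch] <- if (rm_ < tol && ra_ < tol) "either"
      else if (rm_ <= ra_ && rm_ < tol) "multiplicative"
      else if (ra_ < rm_ && ra_ < tol) "additive"
      else if (rm_ <= ra_) "multiplicative" else "additive"
  }
  res$overall <- if (all(res$rule == "multiplicative")) "multiplicative"
    else if (all(res$rule == "additive")) "additive"
    else if (all(res$rule == "either")) "either" else "mixed"
  res
}
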