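#' Build a conductance-based neuron model from a model-definition file
#'
#' Reads a declarative YAML description of a single-compartment
#' conductance-based model (channels, gating exponents, steady-state
#' activation and time-constant curves, reversal potentials, capacitance,
#' optional intracellular-calcium dynamics) and returns a validated model
#' object. Two models ship with the package: `"STG"`, a crab stomatogastric
#' ganglion burster with seven gated channels plus leak (analysis dimension
#' N = 8), and `"DA"`, a midbrain dopaminergic pacemaker with five analysis
#' channels plus leak (N = 6) whose NMDA current is simulated at a fixed
#' baseline but excluded from the conductance-space analysis.
#'
#' @param name model identifier, `"STG"` or `"DA"`, or the path of a custom
#'   model-definition YAML file.
#' @param kinetics_source optional explicit path to a model-definition file
#'   overriding the bundled one for `name`.
#' @return an object of class `cb_model` with elements `name`, `channels`
#'   (ordered channel specifications), `C` (capacitance, uF/cm2), `E_leak`
#'   (mV), `calcium` (calcium-dynamics description or `NULL`),
#'   `analysis_channels` (conductance-space coordinate names, leak last) and
#'   `excluded_baseline` (named baseline conductances of channels simulated
#'   but excluded from analysis).
#' @examples
#' stg <- build_model("STG")
#' stg$analysis_channels
#' @export
build_model <- function(name, kinetics_source = NULL) {
  if (is.null(kinetics_source)) {
    bundled <- c(STG = "stg.yaml", DA = "da.yaml")
    if (name %in% names(bundled)) {
      kinetics_source <- system.file("extdata", "models", bundled[[name]],
                                     package = "condegen", mustWork = TRUE)
    } else if (file.exists(name)) {
      kinetics_source <- name
    } else {
      stop("unknown model name: '", name,
           "' (bundled models: ", paste(names(bundled), collapse = ", "), ")")
    }
  }
  spec <- yaml::read_yaml(kinetics_source)
  validate_model_spec(spec)

  channels <- lapply(spec$channels, function(ch) {
    ch$a <- as.integer(ch$a)
    ch$b <- as.integer(ch$b %||% 0L)
    ch$E_calcium <- identical(ch$E, "calcium")
    if (ch$E_calcium) ch$E <- NA_real_
    ch$calcium_source <- isTRUE(ch$calcium_source)
    ch$instantaneous <- isTRUE(ch$instantaneous)
    ch$ca_half <- ch$ca_half %||% 0
    ch
  })
  names(channels) <- vapply(spec$channels, `[[`, "", "name")

  excluded <- unlist(spec$excluded_from_analysis) %||% character(0)
  model <- structure(list(
    name = spec$name,
    source = kinetics_source,
    channels = channels,
    C = spec$capacitance,
    E_leak = spec$leak$E,
    calcium = spec$calcium,
    dic_references = spec$dic_references,
    excluded = excluded,
    excluded_baseline = unlist(spec$excluded_baseline) %||% numeric(0),
    analysis_channels = c(setdiff(names(channels), excluded), "leak")
  ), class = "cb_model")
  model
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_model_spec <- function(spec) {
  req <- c("name", "capacitance", "leak", "channels")
  miss <- setdiff(req, names(spec))
  if (length(miss))
    stop("malformed model-definition file: missing field(s) ",
         paste(miss, collapse = ", "))
  for (ch in spec$channels) {
    if (is.null(ch$name) || is.null(ch$a) || is.null(ch$m_inf))
      stop("malformed channel specification (needs name, a, m_inf)")
    if (ch$a < 0 || (ch$b %||% 0) < 0)
      stop("channel ", ch$name, ": gating exponents must be non-negative")
    if ((ch$b %||% 0) > 0 && (is.null(ch$h_inf) || is.null(ch$tau_h)))
      stop("channel ", ch$name, ": b > 0 requires h_inf and tau_h")
    if (ch$a > 0 && !isTRUE(ch$instantaneous) && is.null(ch$tau_m))
      stop("channel ", ch$name, ": non-instantaneous gate requires tau_m")
    for (cv in intersect(c("m_inf", "tau_m", "h_inf", "tau_h"), names(ch)))
      curve_form_id(ch[[cv]])
  }
  invisible(TRUE)
}

#' @export
print.cb_model <- function(x, ...) {
  cat("Conductance-based model '", x$name, "' (", length(x$channels),
      " gated channels + leak)\n", sep = "")
  cat("  analysis conductances (N = ", length(x$analysis_channels), "): ",
      paste(x$analysis_channels, collapse = ", "), "\n", sep = "")
  if (length(x$excluded))
    cat("  simulated at fixed baseline, excluded from analysis: ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a maximal-conductance vector for a model
#'
#' @param model a `cb_model`
#' @param ... named conductances (mS/cm2), or a single named numeric vector;
#'   must cover exactly the model's analysis channels (including `leak`).
#' @return named numeric vector in model channel order, class `cond_vector`.
#' @examples
#' stg <- build_model("STG")
#' g <- conductance_vector(stg, Na = 700, Kd = 70, CaT = 4, A = 50, CaS = 8,
#'                         KCa = 100, H = 0.1, leak = 0.01)
#' @export
conductance_vector <- function(model, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1]])))
    dots <- as.list(dots[[1]])
  g <- unlist(dots)
  validate_conductances(model, g)
  structure(g[model$analysis_channels], class = "cond_vector")
}

validate_conductances <- function(model, g) {
  want <- model$analysis_channels
  if (!setequal(names(g), want))
    stop("conductance vector must name exactly: ",
         paste(want, collapse = ", "))
  if (any(!is.finite(g)) || any(g < 0))
    stop("maximal conductances must be finite and non-negative")
  invisible(TRUE)
}

#' Steady-state gating values of a model at a clamped voltage
#'
#' Returns all gating steady states (and the self-consistent intracellular
#' calcium concentration and calcium reversal where the model has calcium
#' dynamics) for a voltage-clamped membrane.
#'
#' @inheritParams conductance_vector
#' @param g conductance vector (needed only for calcium-dependent models)
#' @param V clamped voltage (mV), scalar
#' @param Ca optional frozen intracellular-calcium value (uM); skips the
#'   self-consistent calcium solve
#' @return list with `m`, `h` (named per channel), `Ca` (uM or NA), `E_ca`
#' @keywords internal
steady_states <- function(model, g, V, Ca = NULL) {
  if (!is.null(Ca) && !is.null(model$calcium)) {
    cal <- model$calcium
    E_ca <- cal$reversal$coef * log(cal$reversal$ca_out / max(Ca, 1e-9))
    return(gating_steady(model, V, Ca, E_ca))
  }
  Ca <- NA_real_
  E_ca <- NA_real_
  if (!is.null(model$calcium)) {
    cal <- model$calcium
    Ca <- cal$ca_rest
    # fixed-point iteration: Ca_inf depends on E_Ca(Ca) through I_Ca
    for (i in 1:50) {
      E_ca <- cal$reversal$coef * log(cal$reversal$ca_out / max(Ca, 1e-9))
      ica <- 0
      for (ch in model$channels) {
        if (!ch$calcium_source) next
        m <- eval_curve(ch$m_inf, V)
        h <- if (ch$b > 0) eval_curve(ch$h_inf, V) else 1
        ica <- ica + g[[ch$name]] * m^ch$a * h^ch$b * (V - E_ca)
      }
      Ca_new <- max(cal$ca_rest - cal$f * ica, 1e-9)
      if (abs(Ca_new - Ca) < 1e-12 * (1 + Ca)) { Ca <- Ca_new; break }
      Ca <- Ca_new
    }
    E_ca <- cal$reversal$coef * log(cal$reversal$ca_out / Ca)
  }
  gating_steady(model, V, Ca, E_ca)
}

gating_steady <- function(model, V, Ca, E_ca) {
  m <- h <- setNames(rep(NA_real_, length(model$channels)),
                     names(model$channels))
  for (ch in model$channels) {
    mi <- eval_curve(ch$m_inf, V)
    if (ch$ca_half > 0) mi <- mi * Ca / (Ca + ch$ca_half)
    m[ch$name] <- mi
    if (ch$b > 0) h[ch$name] <- eval_curve(ch$h_inf, V)
  }
  list(m = m, h = h, Ca = Ca, E_ca = E_ca)
}

#' Full conductance (analysis + excluded-baseline) for simulation
#' @keywords internal
full_conductances <- function(model, g) {
  validate_conductances(model, g)
  gb <- setNames(numeric(length(model$channels)), names(model$channels))
  for (nm in names(gb))
    gb[nm] <- if (nm %in% model$excluded) model$excluded_baseline[[nm]]
              else g[[nm]]
  list(gbar = gb, gleak = unname(g[["leak"]]))
}

#' Channel reversal potential at a given calcium state
#' @keywords internal
channel_reversal <- function(model, ch, Ca) {
  if (ch$E_calcium) {
    cal <- model$calcium
    cal$reversal$coef * log(cal$reversal$ca_out / max(Ca, 1e-9))
  } else ch$E
}
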