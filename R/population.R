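#' Bundled study configuration for a model
#'
#' Loads the packaged YAML configuration holding the study conditions for a
#' model: uniform sampling ranges (figure-caption axis maxima where printed),
#' electrophysiological acceptance windows, DIC generation targets with the
#' threshold voltage and solved channels, neuromodulation states, and
#' analysis options.
#'
#' @param model a `cb_model` or model name
#' @param path optional custom configuration file
#' @return nested list mirroring the YAML structure
#' @export
model_config <- function(model, path = NULL) {
  name <- if (inherits(model, "cb_model")) model$name else model
  if (is.null(path))
    path <- system.file("extdata", "config",
                        paste0(tolower(name), ".yaml"),
                        package = "condegen", mustWork = TRUE)
  yaml::read_yaml(path)
}

new_population <- function(model, members, provenance = list()) {
  members <- as.matrix(members)
  colnames(members) <- model$analysis_channels
  structure(members, class = c("neuron_population", "matrix"),
            model = model$name, provenance = provenance)
}

#' @export
print.neuron_population <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("Population of", nrow(x), attr(x, "model"), "neurons (generator:",
      pv$generator %||% "unknown", ")\n")
  cat("  conductances:", paste(colnames(x), collapse = ", "), "\n")
  if (!is.null(pv$seed)) cat("  seed:", pv$seed, "\n")
  if (!is.null(pv$acceptance_rate))
    cat("  acceptance rate:", signif(pv$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Members of a population as conductance vectors
#' @param pop a `neuron_population`
#' @param i member index
#' @return a `cond_vector`
#' @export
member <- function(pop, i) {
  structure(pop[i, ], class = "cond_vector")
}

accept_metrics <- function(metrics, criteria) {
  if (!is.null(criteria$pattern) && metrics$pattern != criteria$pattern)
    return(FALSE)
  for (field in setdiff(names(criteria), "pattern")) {
    lim <- criteria[[field]]
    val <- metrics[[field]]
    if (is.null(val) || is.na(val) || val < lim[1] || val > lim[2])
      return(FALSE)
  }
  TRUE
}

#' Generate a degenerate population by random sampling with post-processing
#'
#' Draws candidate maximal-conductance vectors uniformly within per-channel
#' ranges, simulates each candidate, computes its firing metrics, and retains
#' only candidates whose metrics satisfy the phenotype acceptance windows
#' (bursting for the STG model, slow tonic spiking for the DA model).
#'
#' @param model a `cb_model`
#' @param n number of accepted members required
#' @param seed RNG seed (reproducible populations)
#' @param ranges named list of `c(low, high)` sampling ranges per analysis
#'   channel; defaults from [model_config()]
#' @param criteria acceptance windows (named list: `pattern` plus
#'   `c(low, high)` intervals on firing-metric fields); defaults from
#'   [model_config()]
#' @param max_candidates candidate budget before aborting
#' @param duration,transient simulation protocol (ms); defaults from config
#' @param progress print a progress line every 50 candidates
#' @return a `neuron_population` with acceptance provenance
#' @export
sample_random_population <- function(model, n, seed = 1L, ranges = NULL,
                                     criteria = NULL, max_candidates = 400 * n,
                                     duration = NULL, transient = NULL,
                                     progress = FALSE) {
  stopifnot(n >= 2)
  cfg <- model_config(model)
  ranges <- ranges %||% cfg$ranges
  criteria <- criteria %||% cfg$acceptance
  duration <- duration %||% cfg$simulation$duration
  transient <- transient %||% cfg$simulation$transient
  chans <- model$analysis_channels
  if (!all(chans %in% names(ranges)))
    stop("sampling ranges must cover all analysis conductances")
  set.seed(seed)
  accepted <- matrix(NA_real_, n, length(chans),
                     dimnames = list(NULL, chans))
  labels <- vector("list", n)
  n_acc <- 0L
  n_try <- 0L
  nearest <- NULL
  while (n_acc < n && n_try < max_candidates) {
    n_try <- n_try + 1L
    g <- vapply(chans, function(ch)
      stats::runif(1, ranges[[ch]][1], ranges[[ch]][2]), numeric(1))
    m <- tryCatch({
      tr <- simulate_neuron(model, structure(g, class = "cond_vector"),
                            duration = duration, transient = transient)
      firing_metrics(tr)
    }, error = function(e) NULL)
    if (is.null(m)) next
    nearest <- m
    if (accept_metrics(m, criteria)) {
      n_acc <- n_acc + 1L
      accepted[n_acc, ] <- g
      labels[[n_acc]] <- m
    }
    if (progress && n_try %% 50L == 0L)
      message("candidates: ", n_try, ", accepted: ", n_acc)
  }
  if (n_acc < n)
    stop("random sampling exhausted its candidate budget (", max_candidates,
         ") with only ", n_acc, "/", n, " acceptances; last candidate was '",
         if (is.null(nearest)) "integration failure" else nearest$pattern,
         "'. Relax the acceptance windows or enlarge the budget.")
  pop <- new_population(model, accepted,
                        provenance = list(generator = "random_sampling",
                                          seed = seed, ranges = ranges,
                                          criteria = criteria,
                                          acceptance_rate = n / n_try,
                                          n_candidates = n_try))
  attr(pop, "labels") <- labels
  pop
}

# calcium reference used to keep the DIC linear algebra exactly linear
# across a generated population (frozen-calcium convention); NULL for
# calcium-free models
population_ca_ref <- function(model, Vth, g_ref = NULL) {
  if (is.null(model$calcium)) return(NULL)
  if (is.null(g_ref))
    g_ref <- switch(model$name, STG = stg_reference_neuron(),
                    stop("calcium reference neuron needed for model ",
                         model$name))
  steady_states(model, full_conductances(model, g_ref)$gbar, Vth)$Ca
}

#' Generate a degenerate population with fixed DIC values at threshold
#'
#' Fast constructive alternative to random sampling. For each member: the
#' leak conductance is drawn uniformly from its physiological range; the free
#' voltage-gated conductances are drawn uniformly and scaled in proportion to
#' the member's leak conductance (`gleak / mean(gleak range)`), which couples
#' homogeneous scaling into the set; the remaining three conductances (one
#' dominant channel per DIC timescale) are solved from the linear system
#' `S(Vth) . gbar = targets` so that every member attains the same fast,
#' slow and ultraslow DIC values at the population threshold voltage.
#' Candidate solutions with a negative conductance are rejected and
#' resampled. For a calcium-bearing model the sensitivity matrix is evaluated
#' under the population's frozen-calcium convention (see Details).
#'
#' @details The DIC linear system is exactly linear in the maximal
#' conductances only when the gating steady states entering `S(Vth)` do not
#' themselves depend on the conductances. For the STG model the intracellular
#' calcium at threshold introduces such a dependence; the generator therefore
#' freezes the calcium state at the value of a reference neuron at `Vth`
#' (stored in provenance), which makes every member satisfy its targets
#' exactly and makes scaling-only subsets exactly proportional.
#'
#' @inheritParams sample_random_population
#' @param targets named DIC targets `c(gf, gs, gu)` at `Vth`; defaults from
#'   [model_config()]
#' @param Vth population threshold voltage (mV) at which targets are imposed
#' @param solve_channels three analysis channels solved from the linear
#'   system (one per timescale)
#' @param gleak_range overrides the leak range from `ranges`
#' @param max_attempts rejection-sampling budget
#' @return a `neuron_population`; provenance records targets, `Vth`, solved
#'   channels, the calcium reference and the rejection rate
#' @export
generate_dic_population <- function(model, n, seed = 1L, targets = NULL,
                                    Vth = NULL, solve_channels = NULL,
                                    ranges = NULL, gleak_range = NULL,
                                    max_attempts = 200 * n) {
  cfg <- model_config(model)
  ranges <- ranges %||% cfg$ranges
  targets <- unlist(targets %||% cfg$dic$targets)
  Vth <- Vth %||% cfg$dic$Vth
  solve_channels <- solve_channels %||% unlist(cfg$dic$solve_channels)
  gleak_range <- gleak_range %||% ranges$leak
  stopifnot(length(solve_channels) == 3L, length(targets) == 3L)
  chans <- model$analysis_channels
  free <- setdiff(chans, c("leak", solve_channels))
  ca_ref <- population_ca_ref(model, Vth)
  set.seed(seed)
  members <- matrix(NA_real_, n, length(chans),
                    dimnames = list(NULL, chans))
  gleak_mean <- mean(gleak_range)
  n_acc <- 0L
  n_try <- 0L
  while (n_acc < n && n_try < max_attempts) {
    n_try <- n_try + 1L
    g <- setNames(numeric(length(chans)), chans)
    g["leak"] <- stats::runif(1, gleak_range[1], gleak_range[2])
    scale <- g[["leak"]] / gleak_mean
    for (ch in free)
      g[ch] <- scale * stats::runif(1, ranges[[ch]][1], ranges[[ch]][2])
    # starting iterate: scaled mid-range values for the solved channels
    for (ch in solve_channels)
      g[ch] <- scale * mean(ranges[[ch]])
    sol <- tryCatch(
      compensate(model, structure(g, class = "cond_vector"), solve_channels,
                 targets, Vth, Ca = ca_ref),
      error = function(e) NULL)
    if (is.null(sol) || !sol$feasible) next
    n_acc <- n_acc + 1L
    members[n_acc, ] <- sol$g[chans]
  }
  if (n_acc < n)
    stop("DIC-constrained generation rejected too many candidates (",
         n_try - n_acc, "/", n_try, "); choose different solve channels, ",
         "targets or ranges")
  new_population(model, members,
                 provenance = list(generator = "dic_constrained", seed = seed,
                                   targets = targets, Vth = Vth,
                                   solve_channels = solve_channels,
                                   ranges = ranges, ca_ref = ca_ref,
                                   rejection_rate = 1 - n / n_try))
}

#' Scaling-only subset: variability solely in the leak conductance
#'
#' Same constructive scheme as [generate_dic_population()] but with the free
#' voltage-gated conductances held at shared deterministic base values (still
#' scaled by each member's leak factor), so the only randomness is in
#' `gleak`. All members are proportional: the subset isolates homogeneous
#' scaling and lies on a ray through the origin of conductance space.
#'
#' @inheritParams generate_dic_population
#' @param base_free named base values for the free channels; default: the
#'   free-channel values of a feasible member generated at the mean leak
#'   conductance (mid-range base values can be infeasible for some models)
#' @return a `neuron_population`
#' @export
scaling_only_subset <- function(model, n, seed = 1L, targets = NULL,
                                Vth = NULL, solve_channels = NULL,
                                ranges = NULL, gleak_range = NULL,
                                base_free = NULL, max_attempts = 200 * n) {
  cfg <- model_config(model)
  ranges <- ranges %||% cfg$ranges
  targets <- unlist(targets %||% cfg$dic$targets)
  Vth <- Vth %||% cfg$dic$Vth
  solve_channels <- solve_channels %||% unlist(cfg$dic$solve_channels)
  gleak_range <- gleak_range %||% ranges$leak
  chans <- model$analysis_channels
  free <- setdiff(chans, c("leak", solve_channels))
  if (is.null(base_free)) {
    m0 <- mean(gleak_range)
    seed_pop <- generate_dic_population(model, n = 1, seed = seed,
                                        targets = targets, Vth = Vth,
                                        solve_channels = solve_channels,
                                        ranges = ranges,
                                        gleak_range = c(m0, m0))
    base_free <- unclass(seed_pop)[1, free]
  }
  base_free <- unlist(base_free)[free]
  ca_ref <- population_ca_ref(model, Vth)
  set.seed(seed)
  members <- matrix(NA_real_, n, length(chans),
                    dimnames = list(NULL, chans))
  gleak_mean <- mean(gleak_range)
  n_acc <- 0L; n_try <- 0L
  while (n_acc < n && n_try < max_attempts) {
    n_try <- n_try + 1L
    g <- setNames(numeric(length(chans)), chans)
    g["leak"] <- stats::runif(1, gleak_range[1], gleak_range[2])
    scale <- g[["leak"]] / gleak_mean
    g[free] <- scale * base_free
    for (ch in solve_channels) g[ch] <- scale * mean(ranges[[ch]])
    sol <- tryCatch(
      compensate(model, structure(g, class = "cond_vector"), solve_channels,
                 targets, Vth, Ca = ca_ref),
      error = function(e) NULL)
    if (is.null(sol) || !sol$feasible) next
    n_acc <- n_acc + 1L
    members[n_acc, ] <- sol$g[chans]
  }
  if (n_acc < n)
    stop("scaling-only generation failed: infeasible base values or targets")
  new_population(model, members,
                 provenance = list(generator = "scaling_only", seed = seed,
                                   targets = targets, Vth = Vth,
                                   solve_channels = solve_channels,
                                   base_free = base_free, ca_ref = ca_ref))
}

#' Ratio-only subset: variability exclusively in conductance ratios
#'
#' Same constructive scheme as [generate_dic_population()] but with the leak
#' conductance fixed across members, so homogeneous scaling is absent and
#' all remaining variability lies along DIC zero-sensitivity directions in
#' the voltage-gated conductances. Pairwise correlations within this subset
#' are set by the relative signs of the channels' slow-DIC sensitivities.
#'
#' @inheritParams generate_dic_population
#' @param gleak_fixed the shared leak conductance; default: mid-range
#' @return a `neuron_population`
#' @export
ratio_only_subset <- function(model, n, seed = 1L, targets = NULL,
                              Vth = NULL, solve_channels = NULL,
                              ranges = NULL, gleak_fixed = NULL,
                              max_attempts = 200 * n) {
  cfg <- model_config(model)
  ranges <- ranges %||% cfg$ranges
  targets <- unlist(targets %||% cfg$dic$targets)
  Vth <- Vth %||% cfg$dic$Vth
  solve_channels <- solve_channels %||% unlist(cfg$dic$solve_channels)
  gleak_fixed <- gleak_fixed %||% mean(ranges$leak)
  chans <- model$analysis_channels
  free <- setdiff(chans, c("leak", solve_channels))
  ca_ref <- population_ca_ref(model, Vth)
  set.seed(seed)
  members <- matrix(NA_real_, n, length(chans),
                    dimnames = list(NULL, chans))
  scale <- gleak_fixed / mean(ranges$leak)
  n_acc <- 0L; n_try <- 0L
  while (n_acc < n && n_try < max_attempts) {
    n_try <- n_try + 1L
    g <- setNames(numeric(length(chans)), chans)
    g["leak"] <- gleak_fixed
    for (ch in free)
      g[ch] <- scale * stats::runif(1, ranges[[ch]][1], ranges[[ch]][2])
    for (ch in solve_channels) g[ch] <- scale * mean(ranges[[ch]])
    sol <- tryCatch(
      compensate(model, structure(g, class = "cond_vector"), solve_channels,
                 targets, Vth, Ca = ca_ref),
      error = function(e) NULL)
    if (is.null(sol) || !sol$feasible) next
    n_acc <- n_acc + 1L
    members[n_acc, ] <- sol$g[chans]
  }
  if (n_acc < n)
    stop("ratio-only generation rejected too many candidates")
  new_population(model, members,
                 provenance = list(generator = "ratio_only", seed = seed,
                                   targets = targets, Vth = Vth,
                                   solve_channels = solve_channels,
                                   gleak_fixed = gleak_fixed,
                                   ca_ref = ca_ref))
}

#' Spot-check a population's firing phenotype by simulation
#'
#' Simulates a random subset of members and reports their firing metrics;
#' used to validate that DIC-generated members attain the intended phenotype.
#'
#' @inheritParams sample_random_population
#' @param pop a `neuron_population`
#' @param fraction fraction of members to simulate (at least one)
#' @return data.frame with one row per checked member (`index`, `pattern`,
#'   `burstiness`, `spike_freq`, `spikes_per_burst`)
#' @export
spot_check_population <- function(pop, fraction = 0.1, seed = 1L,
                                  duration = NULL, transient = NULL) {
  model <- build_model(attr(pop, "model"))
  cfg <- model_config(model)
  duration <- duration %||% cfg$simulation$duration
  transient <- transient %||% cfg$simulation$transient
  set.seed(seed)
  idx <- sort(sample(nrow(pop), max(1L, ceiling(fraction * nrow(pop)))))
  rows <- lapply(idx, function(i) {
    m <- firing_metrics(simulate_neuron(model, member(pop, i),
                                        duration = duration,
                                        transient = transient))
    data.frame(index = i, pattern = m$pattern, burstiness = m$burstiness,
               spike_freq = m$spike_freq,
               spikes_per_burst = m$spikes_per_burst)
  })
  do.call(rbind, rows)
}
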